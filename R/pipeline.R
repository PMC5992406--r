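#' Named wavenumber-region presets
#'
#' Modelling regions shipped with the package, transcribed from validated
#' content models for amoxicillin / clavulanate / water in oral dosage forms
#' (intervals in cm-1, high-to-low as conventionally tabulated). Use them as
#' starting points; region choice is a per-model decision.
#'
#' @param name Preset name; call with no arguments to list the names.
#' @return A [wn_regions()] (or character vector of names).
#' @export
region_preset <- function(name) {
  presets <- list(
    amoxicillin_universal  = list(c(9426.6, 8273.4), c(7702.5, 7124.0), c(6549.3, 5970.7)),
    amoxicillin_library    = list(c(9426.6, 7124.0), c(6549.3, 5396.0), c(4825.2, 4246.6)),
    amoxicillin_narrow     = list(c(7702.5, 7124.0), c(6549.3, 5396.0), c(4825.2, 4246.6)),
    amoxicillin_disptab    = list(c(8277.2, 7698.7), c(5399.9, 4821.2)),
    amoxicillin_allforms   = list(c(6549.3, 5970.7), c(4825.2, 4246.6)),
    amoxicillin_granule    = list(c(5797.2, 5276.5)),
    amoxicillin_granule_allforms = list(c(8851.9, 8273.4), c(6549.3, 5970.7)),
    clavulanate_universal  = list(c(7702.5, 7124.0), c(6549.3, 5970.7)),
    clavulanate_library    = list(c(10001.3, 8848.1), c(6549.3, 5396.0)),
    water_universal        = list(c(9403.5, 7498.1)),
    water_library          = list(c(10502.8, 9951.2), c(7752.7, 5546.4)),
    capsule_amoxicillin    = list(c(7702.5, 7124.0), c(6549.3, 5970.7), c(4825.2, 4246.6)),
    capsule_water          = list(c(9955.1, 8848.1), c(7752.7, 7197.3))
  )
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets))
    nir_stop(sprintf("unknown region preset '%s'", name), "config")
  do.call(wn_regions, presets[[name]])
}

#' Pipeline configuration
#'
#' Everything a model build needs beyond the library itself. Two routes are
#' supported: `"library"` (r_T-spacing selection anchored at the target
#' median, 2/3-1/3 split) and `"conventional"` (Ward clustering into
#' `n_groups`, 2 calibration + 1 validation sample per cluster).
#'
#' @param analyte `"amoxicillin"`, `"clavulanate"` or `"water"`.
#' @param route `"library"` or `"conventional"`.
#' @param spacing Adjacent-r_T spacing, percentage points (library route).
#' @param n_groups Ward cluster count (conventional route, default 19).
#' @param n_min Minimum calibration-set size for the library route.
#' @param differ_threshold Prediction-difference threshold (%) above which a
#'   test sample is transferred during optimization (default 5).
#' @param max_transfer_rounds Cap on optimization rounds (default 5).
#' @param regions Optional [wn_regions()] (default: full grid).
#' @param preprocess A [preprocess_config()].
#' @param seed Integer seed for every stochastic step.
#' @param rank_policy `"ftest"` (LOOCV + F-test on PRESS) or `"fixed"`.
#' @param rank Rank cap under `"ftest"` (default 10; reported model ranks in
#'   this problem class run 2-6) or the fixed rank under `"fixed"`.
#' @param alpha F-test level for rank selection.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(analyte = c("amoxicillin", "clavulanate", "water"),
                            route = c("library", "conventional"),
                            spacing = 1.25, n_groups = 19, n_min = 30,
                            differ_threshold = 5, max_transfer_rounds = 5,
                            regions = NULL, preprocess = preprocess_config(),
                            seed = 1, rank_policy = c("ftest", "fixed"),
                            rank = 10, alpha = 0.25) {
  analyte <- match.arg(analyte)
  route <- match.arg(route)
  rank_policy <- match.arg(rank_policy)
  if (differ_threshold <= 0) nir_stop("differ_threshold must be > 0", "config")
  if (spacing < 0) nir_stop("spacing must be >= 0", "config")
  if (n_min < 3) nir_stop("n_min must be >= 3", "config")
  if (rank < 1) nir_stop("rank must be >= 1", "config")
  if (!is.null(regions) && !inherits(regions, "wn_regions"))
    regions <- wn_regions(regions)
  structure(list(analyte = analyte, route = route, spacing = spacing,
                 n_groups = as.integer(n_groups), n_min = as.integer(n_min),
                 differ_threshold = differ_threshold,
                 max_transfer_rounds = as.integer(max_transfer_rounds),
                 regions = regions, preprocess = preprocess,
                 seed = as.integer(seed), rank_policy = rank_policy,
                 rank = as.integer(rank), alpha = alpha),
            class = "pipeline_config")
}

# Rank selection + fit for a training set of entries.
fit_for_entries <- function(train, cfg) {
  X <- build_features(lapply(train, `[[`, "spectrum"), cfg$regions)
  y <- assay_values(train, cfg$analyte)
  n <- nrow(X)
  if (cfg$rank_policy == "fixed") {
    rank <- min(cfg$rank, n - 1, ncol(X))
    cv <- NULL
  } else {
    max_rank <- min(cfg$rank, n - 2, ncol(X))
    cv <- loocv_pls1(X, y, max_rank)
    rank <- select_rank_ftest(cv$press, n, cfg$alpha)
  }
  model <- fit_pls1(X, y, rank, regions = cfg$regions,
                    preprocess = cfg$preprocess, analyte = cfg$analyte)
  list(model = model, cv = cv)
}

entry_predictions <- function(model, entries) {
  X <- build_features(lapply(entries, `[[`, "spectrum"), model$regions)
  predict(model, X)
}

#' Build a content model from a spectral library
#'
#' End-to-end model construction: select calibration samples
#' (route-dependent), split into calibration and test sets, extract
#' region-restricted normalized features, choose the rank (LOOCV + F-test on
#' PRESS, or fixed), fit the PLS1 model, and validate on the test set.
#' Fully reproducible from `(lib, targets, cfg)`; the result records the
#' config hash and seed.
#'
#' @param lib Indexed [spectral_library()] whose entries carry the analyte's
#'   assay (entries without it are dropped; none left is an error).
#' @param targets Target spectra for the library route (the samples to be
#'   measured); ignored by the conventional route.
#' @param cfg A [pipeline_config()].
#' @return Object of class `nir_model_build`: `model`, `report` (test-set
#'   [validation_metrics()]), `selection` (or `clusters`), `train`, `test`,
#'   `cv`, `config`, `config_hash`.
#' @export
build_model <- function(lib, targets = NULL, cfg = pipeline_config()) {
  if (!inherits(lib, "nir_library") || !isTRUE(lib$indexed))
    nir_stop("lib must be an indexed nir_library")
  has_assay <- !is.na(assay_values(lib$entries, cfg$analyte))
  if (!any(has_assay))
    nir_stop(sprintf("no entries carry a %s assay", cfg$analyte), "data")
  usable <- lib$entries[has_assay]

  selection <- NULL; clusters <- NULL
  if (cfg$route == "library") {
    if (is.null(targets))
      nir_stop("the library route needs target spectra (samples to be measured)",
               "config")
    sub <- lib; sub$entries <- usable
    selection <- select_for_targets(sub, targets, spacing = cfg$spacing,
                                    n_min = cfg$n_min)
    sets <- split_train_test(selection)
  } else {
    X_all <- build_features(lapply(usable, `[[`, "spectrum"), cfg$regions)
    clusters <- ward_cluster(X_all, cfg$n_groups)
    draw <- sample_from_clusters(clusters, 3, cfg$seed)
    sets <- list(train = usable[draw$calibration], test = usable[draw$validation])
  }
  fitted <- fit_for_entries(sets$train, cfg)
  preds <- entry_predictions(fitted$model, sets$test)
  report <- validation_metrics(assay_values(sets$test, cfg$analyte), preds,
                               mode = "tsv")
  structure(list(model = fitted$model, report = report, selection = selection,
                 clusters = clusters, train = sets$train, test = sets$test,
                 cv = fitted$cv, config = cfg, seed = cfg$seed,
                 config_hash = config_hash(cfg)),
            class = "nir_model_build")
}

#' @export
print.nir_model_build <- function(x, ...) {
  cat(sprintf("<nir_model_build> %s, route %s, train %d / test %d, rank %d\n",
              x$config$analyte, x$config$route, length(x$train),
              length(x$test), x$model$rank))
  print(x$report)
  invisible(x)
}

#' Optimize a model by transferring poorly predicted test spectra
#'
#' Iterates up to `cfg$max_transfer_rounds`: predict the test set, move every
#' sample whose absolute prediction difference exceeds
#' `cfg$differ_threshold` into the calibration set, re-select the rank and
#' refit. Stops when no test sample exceeds the threshold, or when the
#' transfer would shrink the test set below 20% of the combined set (the
#' validation surface is preserved; the stop reason is recorded).
#'
#' @param model A fitted `pls1_model`.
#' @param train,test Disjoint lists of [library_entry()] objects.
#' @param cfg A [pipeline_config()].
#' @return List: `model`, `train`, `test`, `log` (one row per transferred
#'   sample), `converged` (TRUE iff no test sample exceeds the threshold),
#'   `stopped_by` (`"converged"`, `"size_floor"` or `"max_rounds"`), `report`.
#' @export
optimize_model <- function(model, train, test, cfg = pipeline_config()) {
  if (length(intersect(entry_ids(train), entry_ids(test))))
    nir_stop("train and test sets must be disjoint")
  log <- data.frame(round = integer(0), sample_id = character(0),
                    differ = numeric(0))
  stopped_by <- "max_rounds"
  for (round in seq_len(cfg$max_transfer_rounds)) {
    preds <- entry_predictions(model, test)
    differs <- assay_values(test, cfg$analyte) - preds
    off <- which(abs(differs) > cfg$differ_threshold)
    if (!length(off)) { stopped_by <- "converged"; break }
    if (length(test) - length(off) < 0.2 * (length(train) + length(test))) {
      stopped_by <- "size_floor"
      break
    }
    log <- rbind(log, data.frame(round = round,
                                 sample_id = entry_ids(test)[off],
                                 differ = differs[off]))
    train <- c(train, test[off])
    test <- test[-off]
    model <- fit_for_entries(train, cfg)$model
  }
  if (stopped_by == "max_rounds") {
    preds <- entry_predictions(model, test)
    if (!any(abs(assay_values(test, cfg$analyte) - preds) > cfg$differ_threshold))
      stopped_by <- "converged"
  }
  report <- validation_metrics(assay_values(test, cfg$analyte),
                               entry_predictions(model, test), mode = "tsv")
  list(model = model, train = train, test = test, log = log,
       converged = identical(stopped_by, "converged"),
       stopped_by = stopped_by, report = report)
}

#' Evaluate a model on assayed samples
#'
#' Predicts every sample and reports the accuracy summary (R^2, RMSEP,
#' fractions of samples with absolute prediction difference above 5% / below
#' 1%, mean absolute difference).
#'
#' @param model A `pls1_model`.
#' @param samples List of [library_entry()] objects, or a list of
#'   `list(spectrum =, assay =)` pairs.
#' @param threshold_hi,threshold_lo Fraction thresholds (%), defaults 5 and 1.
#' @return A [validation_metrics()] report.
#' @export
evaluate_model <- function(model, samples, threshold_hi = 5, threshold_lo = 1) {
  if (inherits(samples, "library_entry")) samples <- list(samples)
  field <- paste0(model$analyte, "_pct")
  y <- vapply(samples, function(s) {
    v <- s$assay[[field]]
    if (is.null(v) || is.na(v))
      nir_stop(sprintf("sample %s lacks a %s assay",
                       s$spectrum$meta$sample_id, model$analyte), "data")
    as.numeric(v)
  }, numeric(1))
  preds <- entry_predictions(model, samples)
  validation_metrics(y, preds, mode = "tsv",
                     threshold_hi = threshold_hi, threshold_lo = threshold_lo)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `pls1_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  obj <- list(rank = model$rank,
              x_weights = model$x_weights, x_loadings = model$x_loadings,
              y_loadings = model$y_loadings,
              x_mean = model$x_mean, y_mean = model$y_mean,
              regression_vector = model$regression_vector,
              regions = if (is.null(model$regions)) NULL
                        else as.data.frame(model$regions),
              preprocess = if (is.null(model$preprocess)) NULL
                           else unclass(model$preprocess),
              analyte = model$analyte, n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `pls1_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- if (is.null(obj$regions)) NULL else wn_regions(as.matrix(obj$regions))
  prep <- if (is.null(obj$preprocess)) NULL else
    preprocess_config(obj$preprocess$sg_window, obj$preprocess$sg_polyorder,
                      normalize = obj$preprocess$normalize,
                      regions = if (is.null(obj$preprocess$regions)) NULL
                                else wn_regions(as.matrix(obj$preprocess$regions)))
  structure(list(rank = as.integer(obj$rank),
                 x_weights = as.matrix(obj$x_weights),
                 x_loadings = as.matrix(obj$x_loadings),
                 y_loadings = as.numeric(obj$y_loadings),
                 x_mean = as.numeric(obj$x_mean), y_mean = obj$y_mean,
                 regression_vector = as.numeric(obj$regression_vector),
                 regions = regions, preprocess = prep,
                 analyte = obj$analyte, n_train = obj$n_train),
            class = "pls1_model")
}
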