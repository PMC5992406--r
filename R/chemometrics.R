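# Core NIPALS extraction for single-response PLS with X-deflation.
# Returns weights W (p x a), loadings P (p x a), y-loadings q (a), and the
# training scores T. For one response the weight step is a single exact
# least-squares direction per component; no inner iteration is needed.
nipals_pls1 <- function(Xc, yc, rank) {
  p <- ncol(Xc)
  W <- matrix(0, p, rank); P <- matrix(0, p, rank)
  q <- numeric(rank); Tm <- matrix(0, nrow(Xc), rank)
  E <- Xc
  for (a in seq_len(rank)) {
    w <- drop(crossprod(E, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      nir_stop(sprintf("X deflated to noise before component %d; lower the rank", a),
               "rank")
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24)
      nir_stop(sprintf("vanishing score vector at component %d", a), "rank")
    pa <- drop(crossprod(E, t)) / tt
    q[a] <- sum(yc * t) / tt
    E <- E - tcrossprod(t, pa)
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t
  }
  list(W = W, P = P, q = q, scores = Tm)
}

# Regression vector in centred feature space: b = W (P'W)^-1 q.
pls1_regression_vector <- function(W, P, q) {
  drop(W %*% solve(crossprod(P, W), q))
}

#' Fit a single-response PLS model
#'
#' PLS1 regression of one content variable on preprocessed spectral feature
#' vectors: X and y are mean-centred, latent variables are extracted one at a
#' time (NIPALS with X-deflation), and the regression vector maps a centred
#' feature vector to a centred prediction. The rank is the number of latent
#' variables.
#'
#' @param X Numeric matrix, n samples x p features (rows from
#'   `build_features()` or any preprocessed vectors).
#' @param y Numeric vector of n reference contents (%), no missing values.
#' @param rank Number of latent variables, `1 <= rank <= min(n - 1, p)`.
#' @param regions Optional [wn_regions()] recorded for prediction-time
#'   feature extraction.
#' @param preprocess Optional [preprocess_config()] recorded for
#'   prediction-time preprocessing.
#' @param analyte `"amoxicillin"`, `"clavulanate"` or `"water"` (metadata).
#' @return Object of class `pls1_model`.
#' @export
fit_pls1 <- function(X, y, rank, regions = NULL, preprocess = NULL,
                     analyte = NA_character_) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) nir_stop("need at least 2 training samples")
  if (length(y) != n) nir_stop("X and y disagree on the number of samples")
  if (anyNA(y) || anyNA(X)) nir_stop("missing values in training data")
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(n - 1, p))
    nir_stop(sprintf("rank must be in [1, %d], got %d", min(n - 1, p), rank),
             "rank")
  if (stats::sd(y) == 0)
    nir_stop("y has zero variance; nothing to model", "degenerate")
  x_mean <- colMeans(X); y_mean <- mean(y)
  fit <- nipals_pls1(sweep(X, 2, x_mean), y - y_mean, rank)
  structure(list(rank = rank,
                 x_weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
                 x_mean = x_mean, y_mean = y_mean,
                 regression_vector = pls1_regression_vector(fit$W, fit$P, fit$q),
                 regions = regions, preprocess = preprocess,
                 analyte = analyte, n_train = n),
            class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model> analyte %s, rank %d, %d features, n_train %d\n",
              x$analyte, x$rank, length(x$regression_vector), x$n_train))
  invisible(x)
}

#' Predict content from a spectrum or feature matrix
#'
#' For an [nir_spectrum()], the model's full preprocessing chain is applied
#' (Savitzky-Golay derivative if the spectrum is raw, then region extraction
#' and vector normalization over the model regions) before the linear
#' prediction `y_mean + b' (x - x_mean)`.
#'
#' @param object A `pls1_model`.
#' @param newdata An `nir_spectrum`, a list of them, or a numeric feature
#'   matrix with one row per sample.
#' @param ... Unused.
#' @return Numeric vector of predicted contents (%).
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  if (is_nir_spectrum(newdata)) newdata <- list(newdata)
  if (is.list(newdata) && all(vapply(newdata, is_nir_spectrum, logical(1)))) {
    cfg <- if (is.null(object$preprocess)) preprocess_config() else object$preprocess
    deriv <- lapply(newdata, function(s) {
      if (isTRUE(s$meta$derivative)) s else sg_first_derivative(s, cfg)
    })
    newdata <- build_features(deriv, object$regions)
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$regression_vector))
    nir_stop(sprintf("feature length %d does not match the model's %d",
                     ncol(X), length(object$regression_vector)))
  drop(object$y_mean +
         sweep(X, 2, object$x_mean) %*% object$regression_vector)
}

#' Validation metrics for a set of predictions
#'
#' Per-sample prediction differences `Differ_i = Y_true,i - Y_pred,i`, their
#' squared sum PRESS, the coefficient of determination
#' `R^2 = 100 (1 - PRESS / TSS)` (% of reference variance reproduced), and
#' the root-mean-square error `sqrt(PRESS / M)` reported as RMSEP (test-set
#' validation) or RMSECV (leave-one-out) depending on `mode`. Accuracy is
#' additionally summarised by the fractions of samples with absolute
#' prediction difference above 5% and below 1% and the mean absolute
#' difference.
#'
#' @param true,predicted Equal-length numeric vectors of contents (%).
#' @param mode `"tsv"` (test-set validation) or `"loocv"`.
#' @param threshold_hi,threshold_lo Prediction-difference thresholds (%) for
#'   the reported fractions (defaults 5 and 1).
#' @return Object of class `validation_report`.
#' @export
validation_metrics <- function(true, predicted, mode = c("tsv", "loocv"),
                               threshold_hi = 5, threshold_lo = 1) {
  mode <- match.arg(mode)
  true <- as.numeric(true); predicted <- as.numeric(predicted)
  if (length(true) != length(predicted))
    nir_stop("true and predicted lengths differ")
  if (!length(true)) nir_stop("empty prediction set")
  differs <- true - predicted
  press <- sum(differs^2)
  tss <- sum((true - mean(true))^2)
  r2 <- if (tss > 0) 100 * (1 - press / tss) else NA_real_
  rmse <- sqrt(press / length(true))
  structure(list(n = length(true), differs = differs, press = press,
                 r_squared = r2,
                 rmsep = if (mode == "tsv") rmse else NA_real_,
                 rmsecv = if (mode == "loocv") rmse else NA_real_,
                 frac_gt_5pct = mean(abs(differs) > threshold_hi),
                 frac_lt_1pct = mean(abs(differs) < threshold_lo),
                 mean_abs_differ = mean(abs(differs)),
                 mode = mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  lab <- if (x$mode == "tsv") c("RMSEP", x$rmsep) else c("RMSECV", x$rmsecv)
  cat(sprintf("<validation_report> n = %d (%s)\n", x$n, x$mode))
  cat(sprintf("  R^2 = %.2f%%   %s = %.4g%%\n",
              x$r_squared, lab[1], as.numeric(lab[2])))
  cat(sprintf("  |Differ| > 5%%: %.1f%%   < 1%%: %.1f%%   mean |Differ| = %.2f%%\n",
              100 * x$frac_gt_5pct, 100 * x$frac_lt_1pct, x$mean_abs_differ))
  invisible(x)
}

#' Leave-one-out cross validation over PLS ranks
#'
#' For each rank up to `max_rank`, every sample is held out once, the model
#' is refitted on the rest, and the held-out sample predicted. One NIPALS
#' decomposition per left-out sample serves all ranks (components are
#' nested), so the cost is n fits, not n x max_rank.
#'
#' @param X Feature matrix (n x p), `n >= 3`.
#' @param y Reference contents.
#' @param max_rank Highest rank to evaluate, `<= min(n - 2, p)`.
#' @return List with `rank`, `press` and `rmsecv` vectors (one value per
#'   rank) and the n x max_rank matrix of held-out predictions.
#' @export
loocv_pls1 <- function(X, y, max_rank) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) nir_stop("LOOCV needs at least 3 samples")
  max_rank <- as.integer(max_rank)
  if (max_rank < 1 || max_rank > min(n - 2, ncol(X)))
    nir_stop(sprintf("max_rank must be in [1, %d]", min(n - 2, ncol(X))), "rank")
  preds <- matrix(NA_real_, n, max_rank)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    fit <- nipals_pls1(sweep(Xi, 2, xm), yi - ym, max_rank)
    # accumulate the held-out prediction component by component
    e <- X[i, ] - xm
    acc <- ym
    for (a in seq_len(max_rank)) {
      t_new <- sum(e * fit$W[, a])
      acc <- acc + t_new * fit$q[a]
      e <- e - t_new * fit$P[, a]
      preds[i, a] <- acc
    }
  }
  press <- colSums((y - preds)^2)
  list(rank = seq_len(max_rank), press = press,
       rmsecv = sqrt(press / n), predictions = preds)
}

#' Parsimonious rank selection by a one-sided F-test on PRESS
#'
#' Haaland-Thomas style rule: let `r*` minimise PRESS; the chosen rank is the
#' smallest `r` whose PRESS ratio to the minimum does not exceed the upper
#' `1 - alpha` quantile of an F(n, n) distribution. With `alpha = 0.25` this
#' prefers fewer latent variables whenever their cross-validation error is
#' statistically indistinguishable from the best.
#'
#' @param press_by_rank Positive PRESS values, one per candidate rank
#'   (rank = position).
#' @param n Number of cross-validation samples (degrees of freedom).
#' @param alpha One-sided test level (default 0.25).
#' @return Integer rank.
#' @export
select_rank_ftest <- function(press_by_rank, n, alpha = 0.25) {
  press <- as.numeric(press_by_rank)
  if (!length(press)) nir_stop("press_by_rank is empty")
  if (any(!is.finite(press) | press <= 0))
    nir_stop("PRESS values must be positive and finite")
  if (n < 2) nir_stop("n must be >= 2")
  threshold <- min(press) * stats::qf(1 - alpha, n, n)
  as.integer(which(press <= threshold)[1])
}

#' PCA scores of calibration spectra
#'
#' Scores of the mean-centred feature matrix on its leading principal axes
#' (coordinates of the calibration samples, used to inspect how a calibration
#' set covers the sample space). Component variances are non-increasing and
#' the sign of each axis is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param X Feature matrix (n x p), `n >= 2`.
#' @param n_components Number of axes, `<= min(n - 1, p)`.
#' @return n x n_components score matrix with the loadings in the
#'   `loadings` attribute.
#' @export
pca_scores <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) nir_stop("PCA needs at least 2 samples")
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(n - 1, ncol(X)))
    nir_stop(sprintf("n_components must be in [1, %d]", min(n - 1, ncol(X))),
             "rank")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  sc <- pr$x[, seq_len(n_components), drop = FALSE]
  for (a in seq_len(n_components)) {
    j <- which.max(abs(rot[, a]))
    if (rot[j, a] < 0) { rot[, a] <- -rot[, a]; sc[, a] <- -sc[, a] }
  }
  structure(sc, loadings = rot)
}
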