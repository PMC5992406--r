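# Order entries ascending by r_T (%), ties broken by sample_id so the sweep
# is deterministic without a seed.
sort_by_rt <- function(entries) {
  r <- vapply(entries, function(e) e$r_t, numeric(1))
  if (anyNA(r)) nir_stop("entries must be indexed (r_t present) before selection")
  entries[order(100 * r, entry_ids(entries), method = "radix")]
}

selection_result <- function(selected, spacing, anchor = NULL,
                             target_range = NULL, flags = character(0)) {
  selected <- sort_by_rt(selected)
  rt <- rt_values(selected)
  structure(list(selected = selected,
                 rt_pct = rt,
                 adjacent_gaps = if (length(rt) > 1) diff(rt) else numeric(0),
                 spacing = spacing,
                 target_median_rt = anchor,
                 target_rt_range = target_range,
                 flags = flags),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d spectra, r_T %.2f-%.2f%%, spacing %.2f%%\n",
              length(x$selected), min(x$rt_pct), max(x$rt_pct), x$spacing))
  if (!is.null(x$target_median_rt))
    cat(sprintf("  target median r_T %.2f%%\n", x$target_median_rt))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Greedy one-directional sweep over rt (%) starting after `from_rt`;
# returns indices (into the sorted vector) accepted at gaps >= spacing.
sweep_dir <- function(rt, start_idx, spacing, dir) {
  tol <- 1e-9
  acc <- integer(0)
  last <- rt[start_idx]
  i <- start_idx + dir
  while (i >= 1 && i <= length(rt)) {
    if (dir * (rt[i] - last) >= spacing - tol) {
      acc <- c(acc, i)
      last <- rt[i]
    }
    i <- i + dir
  }
  acc
}

#' Select calibration spectra by fixed r_T spacing
#'
#' All entries are sequenced by r_T and swept greedily: an entry is accepted
#' iff its r_T differs from the last accepted one by at least `spacing`
#' percentage points. Without an anchor the sweep starts at the lowest r_T;
#' with an anchor it starts at the entry nearest the anchor and grows outward
#' alternately (upward first), so the selected median hugs the anchor.
#' Equal r_T values keep only the lexicographically smallest sample id
#' (for positive spacing). Deterministic.
#'
#' @param entries List of indexed [library_entry()] objects.
#' @param spacing Minimum adjacent r_T difference, percentage points
#'   (the workable band is about 1.0-1.5).
#' @param anchor Optional r_T (%) to centre the sweep on.
#' @return A `selection_result`.
#' @export
select_by_spacing <- function(entries, spacing, anchor = NULL) {
  if (!length(entries)) nir_stop("no entries to select from", "empty_selection")
  if (spacing < 0) nir_stop("spacing must be >= 0")
  sorted <- sort_by_rt(entries)
  rt <- unname(rt_values(sorted))
  if (is.null(anchor)) {
    keep <- c(1L, sweep_dir(rt, 1L, spacing, +1L))
  } else {
    start <- which.min(abs(rt - anchor))
    up <- sweep_dir(rt, start, spacing, +1L)
    dn <- sweep_dir(rt, start, spacing, -1L)
    keep <- sort(c(start, up, dn))
  }
  if (spacing == 0) keep <- seq_along(rt)
  selection_result(sorted[keep], spacing, anchor = anchor)
}

#' Select calibration spectra for a set of target samples
#'
#' The general spectral-library recipe: compute the r_T of the samples to be
#' measured against the library reference, then select library spectra by
#' [select_by_spacing()] anchored at the target median r_T, growing outward
#' until the selection covers the target r_T range and holds at least
#' `n_min` spectra. The library entries bracketing the target r_T extremes
#' are forced into the selection first and the greedy sweep fills inward and
#' outward around them, so coverage never has to break the spacing contract
#' at the range ends. Shortfalls are flagged on the result, not silently
#' fixed: if fewer than `n_min` entries are reachable at the requested
#' spacing, the library's endpoint entries are added and `n_min_shortfall`
#' (plus `spacing_violated` where applicable) is flagged. A target r_T
#' outside the library span raises a coverage error naming the uncovered
#' side.
#'
#' @param lib Indexed [spectral_library()].
#' @param targets List of preprocessed (derivative) target spectra on the
#'   library grid, or a numeric vector of target r_T values in %.
#' @param spacing Adjacent-r_T spacing in percentage points (default 1.25,
#'   the midpoint of the workable 1.0-1.5 band).
#' @param n_min Minimum calibration-set size (default 30).
#' @return A `selection_result` with target median/range populated.
#' @export
select_for_targets <- function(lib, targets, spacing = 1.25, n_min = 30) {
  if (!inherits(lib, "nir_library") || !isTRUE(lib$indexed))
    nir_stop("lib must be an indexed nir_library")
  if (is.numeric(targets)) {
    t_rt <- as.numeric(targets)
  } else {
    if (is_nir_spectrum(targets)) targets <- list(targets)
    if (!length(targets)) nir_stop("no target spectra given", "empty_selection")
    t_rt <- vapply(targets, function(s)
      correlation_coefficient(s, lib$reference_spectrum, lib$rt_region,
                              as_pct = TRUE), numeric(1))
  }
  if (!length(t_rt)) nir_stop("no target spectra given", "empty_selection")
  med <- stats::median(t_rt)
  t_min <- min(t_rt); t_max <- max(t_rt)
  sorted <- sort_by_rt(lib$entries)
  rt <- unname(rt_values(sorted))
  tol <- 1e-9
  if (t_max > max(rt) + tol)
    nir_stop(sprintf(
      "library cannot cover the target r_T range above %.4f%% (library max %.4f%%)",
      t_max, max(rt)), "coverage")
  if (t_min < min(rt) - tol)
    nir_stop(sprintf(
      "library cannot cover the target r_T range below %.4f%% (library min %.4f%%)",
      t_min, min(rt)), "coverage")

  flags <- character(0)
  start <- which.min(abs(rt - med))
  # entries bracketing the target range are forced into the calibration set:
  # selecting them first and filling greedily inward keeps coverage AND the
  # spacing contract, instead of discovering at the extremes that no entry a
  # full spacing away remains.
  hi_end <- which(rt >= t_max - tol)[1]
  lo_cand <- which(rt <= t_min + tol); lo_end <- lo_cand[length(lo_cand)]
  keep <- unique(c(start, hi_end, lo_end))
  # greedy outward from the anchor, alternately upward/downward, skipping
  # candidates that would crowd a forced endpoint closer than the spacing
  lo_last <- start; hi_last <- start
  lo_next <- start - 1L; hi_next <- start + 1L
  step <- function(side) {
    if (side > 0) {
      while (hi_next <= length(rt)) {
        if (hi_next == hi_end) {  # forced endpoint becomes the sweep frontier
          hi_last <<- hi_end; hi_next <<- hi_next + 1L; next
        }
        ok <- rt[hi_next] - rt[hi_last] >= spacing - tol &&
          (hi_next > hi_end || rt[hi_end] - rt[hi_next] >= spacing - tol)
        if (ok) { keep <<- c(keep, hi_next); hi_last <<- hi_next
                  hi_next <<- hi_next + 1L; return(TRUE) }
        hi_next <<- hi_next + 1L
      }
    } else {
      while (lo_next >= 1L) {
        if (lo_next == lo_end) {
          lo_last <<- lo_end; lo_next <<- lo_next - 1L; next
        }
        ok <- rt[lo_last] - rt[lo_next] >= spacing - tol &&
          (lo_next < lo_end || rt[lo_next] - rt[lo_end] >= spacing - tol)
        if (ok) { keep <<- c(keep, lo_next); lo_last <<- lo_next
                  lo_next <<- lo_next - 1L; return(TRUE) }
        lo_next <<- lo_next - 1L
      }
    }
    FALSE
  }
  repeat {
    if (length(unique(keep)) >= n_min) break
    up <- step(+1L)
    if (length(unique(keep)) >= n_min) break
    dn <- step(-1L)
    if (!up && !dn) break
  }
  keep <- sort(unique(keep))
  if (length(keep) < n_min) {
    keep <- sort(unique(c(keep, 1L, length(rt))))
    flags <- c(flags, "n_min_shortfall")
  }
  gaps <- diff(rt[keep])
  if (length(gaps) && any(gaps < spacing - tol))
    flags <- unique(c(flags, "spacing_violated"))
  selection_result(sorted[keep], spacing, anchor = med,
                   target_range = c(t_min, t_max), flags = flags)
}

#' Split a selection into calibration and test sets
#'
#' Deterministic interleaved split over the r_T-sorted selection: every third
#' entry (indices 2, 5, 8, ... of the sorted list) goes to the test set, so
#' two-thirds form the calibration (training) set; the endpoint entries are
#' always kept in training so the calibration spans the full r_T range.
#'
#' @param selected A `selection_result` or list of indexed entries (>= 3).
#' @param train_fraction Training fraction; the interleave period is
#'   `round(1 / (1 - train_fraction))` (default 2/3 -> every third).
#' @return List with elements `train` and `test` (lists of entries).
#' @export
split_train_test <- function(selected, train_fraction = 2 / 3) {
  entries <- if (inherits(selected, "selection_result")) selected$selected
             else sort_by_rt(selected)
  n <- length(entries)
  if (n < 3) nir_stop("need at least 3 entries to split", "size")
  if (train_fraction <= 0 || train_fraction >= 1)
    nir_stop("train_fraction must be in (0, 1)")
  period <- max(2L, as.integer(round(1 / (1 - train_fraction))))
  test_idx <- which(seq_len(n) %% period == 2L %% period)
  test_idx <- setdiff(test_idx, c(1L, n))
  list(train = entries[setdiff(seq_len(n), test_idx)],
       test = entries[test_idx])
}

#' Ward hierarchical clustering of spectra
#'
#' Agglomerative clustering with Euclidean distance and the Ward
#' minimum-variance criterion, cut at `n_groups` clusters; the conventional
#' calibration-set strategy groups the whole sample set this way (19 groups
#' by default).
#'
#' @param X Numeric matrix, one feature vector per row (use
#'   `build_features()` output or any equal-length vectors).
#' @param n_groups Number of clusters to cut the tree at.
#' @return Integer vector of cluster labels (1-based, in `stats::cutree`
#'   numbering), deterministic.
#' @export
ward_cluster <- function(X, n_groups = 19) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_groups < 1) nir_stop("n_groups must be >= 1", "size")
  if (n < n_groups)
    nir_stop(sprintf("need at least n_groups = %d rows, got %d", n_groups, n),
             "size")
  hc <- stats::hclust(stats::dist(X, method = "euclidean"), method = "ward.D2")
  as.integer(stats::cutree(hc, k = n_groups))
}

#' Draw calibration/validation samples from clusters
#'
#' Per cluster, draws up to `per_cluster` members with a seeded generator;
#' the first two drawn go to the calibration set and the third (when the
#' cluster is large enough) to the validation set. Clusters of size 1-2
#' contribute to calibration only.
#'
#' @param labels Cluster labels from [ward_cluster()].
#' @param per_cluster Members drawn per cluster (default 3).
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return List with integer index vectors `calibration` and `validation`.
#' @export
sample_from_clusters <- function(labels, per_cluster = 3, seed) {
  if (missing(seed)) nir_stop("seed is required")
  labels <- as.integer(labels)
  cal <- integer(0); val <- integer(0)
  with_seed(seed, {
    for (k in sort(unique(labels))) {
      members <- which(labels == k)
      take <- min(per_cluster, length(members))
      drawn <- if (length(members) == 1) members else sample(members, take)
      cal <- c(cal, drawn[seq_len(min(2L, take))])
      if (take >= 3) val <- c(val, drawn[3])
    }
  })
  list(calibration = cal, validation = val)
}
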