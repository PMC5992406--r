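#' Recognised oral dosage forms
#'
#' Character vector of the dosage-form labels a library may carry.
#' @export
DOSAGE_FORMS <- c("tablet", "dispersible_tablet", "chewable_tablet",
                  "granule", "oral_suspension", "capsule_granule")

#' Canonical wavenumber grid
#'
#' Uniform 4 cm-1 grid from 4,000 to 12,000 cm-1 (2,001 points). All library
#' entries are resampled to this grid on ingestion so that vector operations
#' (correlation, PLS feature extraction) are defined point-for-point.
#'
#' @return Numeric vector of wavenumbers in cm-1, ascending.
#' @export
canonical_grid <- function() seq(4000, 12000, by = 4)

#' Construct an NIR spectrum
#'
#' A spectrum is a pair of equal-length vectors (wavenumbers in cm-1,
#' absorbance in arbitrary absorbance units) plus acquisition metadata.
#' Wavenumbers must be strictly monotonic and all values finite.
#'
#' @param wavenumbers Numeric vector, cm-1, strictly monotonic, length >= 2.
#' @param absorbance Numeric vector, same length as `wavenumbers`.
#' @param sample_id Sample identifier string.
#' @param dosage_form One of [DOSAGE_FORMS] or `NA`.
#' @param manufacturer,batch Free-text provenance strings.
#' @param replicate_index Integer >= 0 for raw replicate scans; `NA` for
#'   averaged spectra.
#' @param derivative Logical flag marking a spectrum that has already been
#'   through the Savitzky-Golay derivative step.
#' @return Object of class `nir_spectrum`.
#' @export
nir_spectrum <- function(wavenumbers, absorbance, sample_id = NA_character_,
                         dosage_form = NA_character_,
                         manufacturer = NA_character_, batch = NA_character_,
                         replicate_index = NA_integer_, derivative = FALSE) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    nir_stop("wavenumbers and absorbance must have equal length")
  if (length(wavenumbers) < 2)
    nir_stop("a spectrum needs at least 2 points")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance)))
    nir_stop("spectrum contains non-finite values")
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0)))
    nir_stop("wavenumber grid must be strictly monotonic")
  if (!is.na(dosage_form) && !dosage_form %in% DOSAGE_FORMS)
    nir_stop(sprintf("unknown dosage_form '%s'", dosage_form))
  structure(
    list(
      wavenumbers = wavenumbers,
      absorbance = absorbance,
      meta = list(sample_id = as.character(sample_id),
                  dosage_form = as.character(dosage_form),
                  manufacturer = as.character(manufacturer),
                  batch = as.character(batch),
                  replicate_index = if (is.na(replicate_index)) NA_integer_
                                    else as.integer(replicate_index),
                  derivative = isTRUE(derivative))
    ),
    class = "nir_spectrum"
  )
}

is_nir_spectrum <- function(x) inherits(x, "nir_spectrum")

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum> %s  %d points, %.1f-%.1f cm-1%s\n",
              x$meta$sample_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers),
              if (isTRUE(x$meta$derivative)) "  [derivative]" else ""))
  invisible(x)
}

# Return a copy with an ascending wavenumber grid.
ensure_ascending <- function(s) {
  if (s$wavenumbers[1] > s$wavenumbers[2]) {
    s$wavenumbers <- rev(s$wavenumbers)
    s$absorbance <- rev(s$absorbance)
  }
  s
}

#' Wavenumber region set
#'
#' An ordered list of non-overlapping (low, high) wavenumber intervals in
#' cm-1, used to restrict correlation and modelling to sub-ranges of the grid.
#'
#' @param ... Each argument a numeric vector `c(low, high)`, or a single
#'   2-column matrix/data.frame of intervals.
#' @return Object of class `wn_regions`: a data.frame with columns `low`,
#'   `high` in the listed order.
#' @examples
#' wn_regions(c(4200, 10000))
#' wn_regions(c(9426.6, 8273.4), c(7702.5, 7124.0))  # order within a pair is free
#' @export
wn_regions <- function(...) {
  args <- list(...)
  if (length(args) == 1 && (is.matrix(args[[1]]) || is.data.frame(args[[1]]))) {
    m <- as.matrix(args[[1]])
    args <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, 1:2]))
  }
  ivs <- lapply(args, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2 || !all(is.finite(p)))
      nir_stop("each region must be a finite (low, high) pair")
    sort(p)
  })
  low <- vapply(ivs, `[`, numeric(1), 1)
  high <- vapply(ivs, `[`, numeric(1), 2)
  if (any(low >= high)) nir_stop("region low must be < high")
  o <- order(low)
  if (any(high[o][-length(o)] > low[o][-1]))
    nir_stop("regions must not overlap")
  structure(data.frame(low = low, high = high), class = c("wn_regions", "data.frame"))
}

# Indices of grid points falling inside any interval; `per_interval = TRUE`
# returns a list (interval order kept, points sorted descending in wavenumber
# as in the feature-vector convention).
region_indices <- function(wavenumbers, regions, per_interval = FALSE) {
  if (is.null(regions)) {
    idx <- seq_along(wavenumbers)
    return(if (per_interval) list(idx[order(-wavenumbers[idx])]) else idx)
  }
  if (!inherits(regions, "wn_regions")) regions <- wn_regions(regions)
  per <- lapply(seq_len(nrow(regions)), function(i) {
    idx <- which(wavenumbers >= regions$low[i] & wavenumbers <= regions$high[i])
    idx[order(-wavenumbers[idx])]
  })
  if (per_interval) return(per)
  sort(unique(unlist(per)))
}

#' Resample a spectrum onto a new grid
#'
#' Piecewise-linear interpolation onto `grid`; metadata is preserved. The new
#' grid must lie within the closed span of the source grid (no extrapolation).
#'
#' @param s An [nir_spectrum()].
#' @param grid Numeric vector of target wavenumbers (cm-1).
#' @return An `nir_spectrum` on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  if (!is_nir_spectrum(s)) nir_stop("s must be an nir_spectrum")
  grid <- as.numeric(grid)
  lo <- min(s$wavenumbers); hi <- max(s$wavenumbers)
  if (any(grid < lo) || any(grid > hi))
    nir_stop(sprintf("grid extends beyond source span [%.6g, %.6g]", lo, hi),
             class = "range")
  sa <- ensure_ascending(s)
  a <- stats::approx(sa$wavenumbers, sa$absorbance, xout = grid,
                     method = "linear", ties = "ordered")$y
  out <- s
  out$wavenumbers <- grid
  out$absorbance <- a
  out
}
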