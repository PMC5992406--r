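#' Preprocessing configuration
#'
#' The pretreatment chain applied to every library spectrum: replicate
#' averaging, Savitzky-Golay first derivative with 17-point smoothing, then
#' vector normalization (centre to zero mean, scale to unit Euclidean norm)
#' over the active wavenumber region.
#'
#' @param sg_window Odd filter length in points (default 17).
#' @param sg_polyorder Polynomial order of the smoothing fit (default 2).
#' @param derivative_order Fixed at 1 (first derivative).
#' @param normalize Apply vector normalization after the derivative.
#' @param regions Optional [wn_regions()]; `NULL` means the full grid.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 17, sg_polyorder = 2,
                              derivative_order = 1, normalize = TRUE,
                              regions = NULL) {
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2 != 1) nir_stop("sg_window must be odd")
  if (sg_window < sg_polyorder + 2)
    nir_stop("sg_window must be >= sg_polyorder + 2")
  if (derivative_order != 1) nir_stop("only first derivatives are supported")
  if (!is.null(regions) && !inherits(regions, "wn_regions"))
    regions <- wn_regions(regions)
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 derivative_order = 1L, normalize = isTRUE(normalize),
                 regions = regions),
            class = "preprocess_config")
}

#' Average replicate scans of one sample
#'
#' Pointwise arithmetic mean of replicate spectra acquired on the same grid
#' for the same sample (three scans per sample in routine acquisition).
#'
#' @param replicates List of [nir_spectrum()] objects with identical grids
#'   and a common `sample_id`.
#' @return Averaged `nir_spectrum` with `replicate_index` absent.
#' @export
average_replicates <- function(replicates) {
  if (is_nir_spectrum(replicates)) replicates <- list(replicates)
  if (!length(replicates)) nir_stop("need at least one replicate")
  ref <- replicates[[1]]
  for (s in replicates[-1]) {
    if (!isTRUE(all.equal(s$wavenumbers, ref$wavenumbers)))
      nir_stop("replicates must share an identical wavenumber grid")
    if (!identical(s$meta$sample_id, ref$meta$sample_id))
      nir_stop("replicates must share a sample_id")
  }
  avg <- rowMeans(vapply(replicates, `[[`, numeric(length(ref$absorbance)),
                         "absorbance"))
  out <- ref
  out$absorbance <- as.numeric(avg)
  out$meta$replicate_index <- NA_integer_
  out
}

# Savitzky-Golay convolution coefficients for derivative `deriv` of a
# least-squares polynomial of order `polyorder` over a centred window.
# Returned in offset order -m..m; the derivative w.r.t. the abscissa is
# sum(coef * y) / h^deriv for grid spacing h.
savgol_coefficients <- function(window, polyorder, deriv = 1) {
  m <- (window - 1L) %/% 2L
  j <- -m:m
  A <- outer(j, 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))      # (p+1) x window; row k+1 gives coeff of j^k
  C[deriv + 1L, ] * factorial(deriv)
}

#' Savitzky-Golay first derivative
#'
#' First derivative with respect to wavenumber via a Savitzky-Golay filter on
#' a uniform grid. The filter coefficients are divided by the grid spacing, so
#' output units are absorbance per cm-1 (immaterial once vector-normalized).
#' The half-window is dropped at each end rather than padded: the output has
#' `sg_window - 1` fewer points and a correspondingly trimmed grid.
#'
#' @param s An [nir_spectrum()] on a uniform grid with at least `sg_window`
#'   points.
#' @param cfg A [preprocess_config()].
#' @return Derivative `nir_spectrum` (flagged via `meta$derivative`).
#' @export
sg_first_derivative <- function(s, cfg = preprocess_config()) {
  if (!is_nir_spectrum(s)) nir_stop("s must be an nir_spectrum")
  s <- ensure_ascending(s)
  d <- diff(s$wavenumbers)
  h <- mean(d)
  if (max(abs(d - h)) > 1e-6 * abs(h))
    nir_stop("Savitzky-Golay derivative requires a uniform grid")
  w <- cfg$sg_window
  n <- length(s$absorbance)
  if (n < w) nir_stop(sprintf("need at least %d points for sg_window = %d", w, w))
  cc <- savgol_coefficients(w, cfg$sg_polyorder, deriv = 1L)
  m <- (w - 1L) %/% 2L
  filt <- as.numeric(stats::filter(s$absorbance, rev(cc), sides = 2))
  keep <- (m + 1L):(n - m)
  out <- s
  out$wavenumbers <- s$wavenumbers[keep]
  out$absorbance <- filt[keep] / h
  out$meta$derivative <- TRUE
  out
}

#' Vector normalization
#'
#' Centres the spectrum to zero mean and scales it to unit Euclidean norm,
#' computed over the points inside `regions` (full grid when `NULL`). The
#' returned spectrum is restricted to those points. Normalizing over the
#' active region only keeps excluded spectral range from leaking into a
#' model's feature scaling.
#'
#' @param s An [nir_spectrum()].
#' @param regions Optional [wn_regions()].
#' @return Normalized `nir_spectrum` restricted to `regions`.
#' @export
vector_normalize <- function(s, regions = NULL) {
  if (!is_nir_spectrum(s)) nir_stop("s must be an nir_spectrum")
  idx <- region_indices(s$wavenumbers, regions)
  if (length(idx) < 2)
    nir_stop("region must select at least 2 points", "region")
  v <- s$absorbance[idx]
  centred <- v - mean(v)
  nrm <- sqrt(sum(centred^2))
  if (nrm < 1e-12 * (abs(mean(v)) + 1))
    nir_stop("zero-variance spectrum cannot be vector-normalized", "degenerate")
  out <- s
  out$wavenumbers <- s$wavenumbers[idx]
  out$absorbance <- centred / nrm
  out
}

#' Extract region-restricted feature values
#'
#' Concatenates the absorbance values whose wavenumber falls in any interval,
#' points ordered by descending wavenumber within an interval and intervals
#' in their listed order (the convention of high-to-low wavenumber tables).
#'
#' @param s An [nir_spectrum()].
#' @param regions A [wn_regions()].
#' @return Numeric feature vector with a `wavenumbers` attribute.
#' @export
extract_regions <- function(s, regions) {
  if (!is_nir_spectrum(s)) nir_stop("s must be an nir_spectrum")
  per <- region_indices(s$wavenumbers, regions, per_interval = TRUE)
  empty <- which(vapply(per, length, integer(1)) == 0)
  if (length(empty))
    nir_stop(sprintf("region %d selects no grid points", empty[1]), "region")
  idx <- unlist(per)
  structure(s$absorbance[idx], wavenumbers = s$wavenumbers[idx])
}

#' Full preprocessing chain for one sample
#'
#' Averages replicates (if a list of raw scans is given), applies the
#' Savitzky-Golay first derivative, and optionally vector-normalizes over
#' `cfg$regions`. Averaging precedes the derivative, and the derivative
#' precedes normalization; the order is fixed.
#'
#' @param x An [nir_spectrum()] or list of replicate spectra.
#' @param cfg A [preprocess_config()].
#' @return Preprocessed `nir_spectrum`.
#' @export
preprocess_spectrum <- function(x, cfg = preprocess_config()) {
  s <- if (is_nir_spectrum(x)) x else average_replicates(x)
  if (!isTRUE(s$meta$derivative)) s <- sg_first_derivative(s, cfg)
  if (cfg$normalize) s <- vector_normalize(s, cfg$regions) else s
}

# Feature matrix for modelling: region extraction on derivative spectra,
# then centre + unit-norm per row over exactly the extracted points.
build_features <- function(spectra, regions = NULL) {
  rows <- lapply(spectra, function(s) {
    v <- as.numeric(extract_regions(s, regions))
    if (length(v) < 2)
      nir_stop("model region selects fewer than 2 points", "region")
    centred <- v - mean(v)
    nrm <- sqrt(sum(centred^2))
    if (nrm < 1e-12 * (abs(mean(v)) + 1))
      nir_stop(sprintf("zero-variance features for sample %s", s$meta$sample_id),
               "degenerate")
    centred / nrm
  })
  len <- unique(vapply(rows, length, integer(1)))
  if (length(len) != 1)
    nir_stop("spectra disagree on the model region grid")
  do.call(rbind, rows)
}
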