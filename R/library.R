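#' Reference assay values for one sample
#'
#' Contents determined by the external reference methods (HPLC for the two
#' actives, Karl Fischer for water), in % mass/mass. `NA` marks an absent
#' determination.
#'
#' @param amoxicillin_pct,clavulanate_pct,water_pct Real in \[0, 100\] or `NA`.
#' @return Object of class `reference_assay`.
#' @export
reference_assay <- function(amoxicillin_pct = NA_real_,
                            clavulanate_pct = NA_real_,
                            water_pct = NA_real_) {
  vals <- c(amoxicillin_pct = amoxicillin_pct,
            clavulanate_pct = clavulanate_pct, water_pct = water_pct)
  bad <- !is.na(vals) & (vals < 0 | vals > 100)
  if (any(bad))
    nir_stop(sprintf("assay value out of [0, 100]: %s",
                     paste(names(vals)[bad], collapse = ", ")))
  structure(as.list(vals), class = "reference_assay")
}

#' Library entry
#'
#' One batch in the spectral library: the averaged, derivative-preprocessed
#' spectrum, optionally the raw replicate scans, the reference assay, and the
#' similarity index `r_t` (a ratio in \[-1, 1\]; populated by
#' [index_library()]).
#'
#' @param spectrum Averaged preprocessed [nir_spectrum()].
#' @param assay A [reference_assay()].
#' @param raw_replicates Optional list of the raw replicate spectra.
#' @return Object of class `library_entry`.
#' @export
library_entry <- function(spectrum, assay = reference_assay(),
                          raw_replicates = NULL) {
  if (!is_nir_spectrum(spectrum)) nir_stop("spectrum must be an nir_spectrum")
  if (!inherits(assay, "reference_assay")) nir_stop("assay must be a reference_assay")
  structure(list(spectrum = spectrum, assay = assay,
                 raw_replicates = raw_replicates, r_t = NA_real_),
            class = "library_entry")
}

#' Spectral library
#'
#' Entries plus the reference spectrum the similarity index is computed
#' against and the wavenumber region the index is restricted to (default
#' 4,200-10,000 cm-1). All entries must share one grid.
#'
#' @param entries List of [library_entry()] objects.
#' @param reference_spectrum Optional [nir_spectrum()] on the entries' grid;
#'   typically built with [build_reference_spectrum()].
#' @param rt_region [wn_regions()] for the index (default 4,200-10,000 cm-1).
#' @return Object of class `nir_library`.
#' @export
spectral_library <- function(entries, reference_spectrum = NULL,
                             rt_region = wn_regions(c(4200, 10000))) {
  if (!length(entries)) nir_stop("library needs at least one entry", "empty_selection")
  if (!all(vapply(entries, inherits, logical(1), "library_entry")))
    nir_stop("entries must be library_entry objects")
  grid <- entries[[1]]$spectrum$wavenumbers
  same <- vapply(entries, function(e)
    isTRUE(all.equal(e$spectrum$wavenumbers, grid)), logical(1))
  if (!all(same))
    nir_stop(sprintf("entry %s is not on the common grid",
                     entries[[which(!same)[1]]]$spectrum$meta$sample_id))
  if (!is.null(reference_spectrum)) {
    if (!is_nir_spectrum(reference_spectrum))
      nir_stop("reference_spectrum must be an nir_spectrum")
    if (!isTRUE(all.equal(reference_spectrum$wavenumbers, grid)))
      nir_stop("reference_spectrum must be on the entries' grid")
  }
  if (!inherits(rt_region, "wn_regions")) rt_region <- wn_regions(rt_region)
  structure(list(entries = entries, reference_spectrum = reference_spectrum,
                 rt_region = rt_region, indexed = FALSE),
            class = "nir_library")
}

#' @export
print.nir_library <- function(x, ...) {
  forms <- table(vapply(x$entries, function(e) e$spectrum$meta$dosage_form,
                        character(1)))
  cat(sprintf("<nir_library> %d entries (%s)%s\n", length(x$entries),
              paste(names(forms), forms, sep = ":", collapse = ", "),
              if (isTRUE(x$indexed)) "  [indexed]" else ""))
  if (isTRUE(x$indexed)) {
    r <- rt_values(x)
    cat(sprintf("  r_T: %.2f-%.2f%%, mean %.2f%%\n", min(r), max(r), mean(r)))
  }
  invisible(x)
}

#' Correlation coefficient between two spectra
#'
#' The similarity index of the library: the ratio of the covariance of the
#' two spectra to the product of their standard deviations, evaluated over
#' the grid points inside `region`. It ranges from -1 (inverted spectra) to
#' +1 (identical spectra); population (1/n) moments are used, which cancels
#' in the ratio. Use `as_pct = TRUE` for the conventional percentage form.
#'
#' @param s1,s2 Spectra on one common grid.
#' @param region Optional [wn_regions()]; `NULL` uses the full grid.
#' @param as_pct Report as a percentage instead of a ratio.
#' @return Numeric scalar in \[-1, 1\] (or \[-100, 100\] when `as_pct`).
#' @export
correlation_coefficient <- function(s1, s2, region = NULL, as_pct = FALSE) {
  if (!is_nir_spectrum(s1) || !is_nir_spectrum(s2))
    nir_stop("inputs must be nir_spectrum objects")
  if (!isTRUE(all.equal(s1$wavenumbers, s2$wavenumbers)))
    nir_stop("spectra must share a common grid")
  idx <- region_indices(s1$wavenumbers, region)
  if (length(idx) < 2) nir_stop("region must select at least 2 points", "region")
  y1 <- s1$absorbance[idx]; y2 <- s2$absorbance[idx]
  c1 <- y1 - mean(y1); c2 <- y2 - mean(y2)
  n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0)
    nir_stop("zero-variance spectrum in correlation", "degenerate")
  r <- sum(c1 * c2) / (n1 * n2)
  r <- max(-1, min(1, r))
  if (as_pct) 100 * r else r
}

#' Build the library reference spectrum
#'
#' Pointwise mean of the preprocessed spectra of all entries of one dosage
#' form (default: plain tablets, the form the index is anchored to).
#'
#' @param entries List of [library_entry()] objects.
#' @param form Dosage form to average over.
#' @return An [nir_spectrum()] on the entries' grid.
#' @export
build_reference_spectrum <- function(entries, form = "tablet") {
  if (!form %in% DOSAGE_FORMS) nir_stop(sprintf("unknown dosage_form '%s'", form))
  sel <- Filter(function(e) identical(e$spectrum$meta$dosage_form, form), entries)
  if (!length(sel))
    nir_stop(sprintf("no entries with dosage_form '%s'", form), "empty_selection")
  grid <- sel[[1]]$spectrum$wavenumbers
  mat <- vapply(sel, function(e) e$spectrum$absorbance, numeric(length(grid)))
  ref <- sel[[1]]$spectrum
  ref$absorbance <- rowMeans(mat)
  ref$meta$sample_id <- sprintf("reference_%s_mean", form)
  ref$meta$replicate_index <- NA_integer_
  ref
}

#' Index a library by the correlation coefficient
#'
#' Computes `r_t` for every entry against the library's reference spectrum
#' over `rt_region` and stores it on the entry. A summary (min/max/mean, %)
#' is attached as the `rt_summary` attribute.
#'
#' @param lib An [spectral_library()] with a reference spectrum set.
#' @return The indexed library.
#' @export
index_library <- function(lib) {
  if (!inherits(lib, "nir_library")) nir_stop("lib must be an nir_library")
  if (is.null(lib$reference_spectrum))
    nir_stop("library has no reference spectrum; call build_reference_spectrum()")
  lib$entries <- lapply(lib$entries, function(e) {
    e$r_t <- tryCatch(
      correlation_coefficient(e$spectrum, lib$reference_spectrum, lib$rt_region),
      error = function(cond) nir_stop(
        sprintf("indexing failed for sample %s: %s",
                e$spectrum$meta$sample_id, conditionMessage(cond)),
        "degenerate")
    )
    e
  })
  lib$indexed <- TRUE
  r <- rt_values(lib)
  attr(lib, "rt_summary") <- c(min = min(r), max = max(r), mean = mean(r))
  lib
}

#' Indexed r_T values as percentages
#'
#' @param lib An indexed [spectral_library()] (or a list of entries).
#' @return Named numeric vector, % scale, in entry order.
#' @export
rt_values <- function(lib) {
  entries <- if (inherits(lib, "nir_library")) lib$entries else lib
  r <- vapply(entries, function(e) 100 * e$r_t, numeric(1))
  names(r) <- vapply(entries, function(e) e$spectrum$meta$sample_id, character(1))
  r
}

entry_ids <- function(entries)
  vapply(entries, function(e) e$spectrum$meta$sample_id, character(1))

assay_values <- function(entries, analyte) {
  field <- paste0(analyte, "_pct")
  vapply(entries, function(e) {
    v <- e$assay[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Serialize a library to a directory
#'
#' Writes `spectra.csv` (long format, entry spectra plus the reference
#' spectrum under id `__reference__`), `manifest.csv` (metadata + assays) and
#' `index.json` (r_T % per sample, region, provenance).
#'
#' @param lib An [spectral_library()].
#' @param dir Output directory (created if needed).
#' @export
write_library <- function(lib, dir) {
  if (!inherits(lib, "nir_library")) nir_stop("lib must be an nir_library")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- lapply(lib$entries, `[[`, "spectrum")
  if (!is.null(lib$reference_spectrum)) {
    ref <- lib$reference_spectrum
    ref$meta$sample_id <- "__reference__"
    spectra <- c(spectra, list(ref))
  }
  write_spectra_table(spectra, file.path(dir, "spectra.csv"))
  manifest <- do.call(rbind, lapply(lib$entries, function(e) {
    data.frame(sample_id = e$spectrum$meta$sample_id,
               dosage_form = e$spectrum$meta$dosage_form,
               manufacturer = e$spectrum$meta$manufacturer,
               batch = e$spectrum$meta$batch,
               amoxicillin_pct = as.numeric(e$assay$amoxicillin_pct),
               clavulanate_pct = as.numeric(e$assay$clavulanate_pct),
               water_pct = as.numeric(e$assay$water_pct))
  }))
  write_assay_manifest(manifest, file.path(dir, "manifest.csv"))
  idx <- list(
    indexed = isTRUE(lib$indexed),
    rt_region = as.data.frame(lib$rt_region),
    reference = if (is.null(lib$reference_spectrum)) NULL else
      lib$reference_spectrum$meta$sample_id,
    rt_pct = if (isTRUE(lib$indexed)) as.list(rt_values(lib)) else NULL
  )
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a library directory written by [write_library()]
#'
#' @param dir Directory path.
#' @return An [spectral_library()], indexed if the index file carries r_T.
#' @export
read_library <- function(dir) {
  spectra <- read_spectra_table(file.path(dir, "spectra.csv"), "csv",
                                manifest = file.path(dir, "manifest.csv"))
  manifest <- read_assay_manifest(file.path(dir, "manifest.csv"))
  idx <- jsonlite::read_json(file.path(dir, "index.json"))
  ids <- vapply(spectra, function(s) s$meta$sample_id, character(1))
  ref <- NULL
  if (!is.null(idx$reference)) {
    ref <- spectra[[which(ids == "__reference__")[1]]]
    ref$meta$sample_id <- idx$reference
    ref$meta$derivative <- TRUE
  }
  entries <- lapply(which(ids != "__reference__"), function(i) {
    s <- spectra[[i]]
    s$meta$derivative <- TRUE
    row <- manifest[manifest$sample_id == s$meta$sample_id, , drop = FALSE]
    assay <- reference_assay(row$amoxicillin_pct[1], row$clavulanate_pct[1],
                             row$water_pct[1])
    library_entry(s, assay)
  })
  region <- do.call(wn_regions, lapply(idx$rt_region, function(iv)
    c(iv$low, iv$high)))
  lib <- spectral_library(entries, reference_spectrum = ref, rt_region = region)
  if (isTRUE(idx$indexed)) lib <- index_library(lib)
  lib
}
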