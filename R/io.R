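#' Read spectra from a table file
#'
#' Reads a long-format CSV (`sample_id, replicate_index, wavenumber,
#' absorbance`) or a simple JCAMP-DX file into a list of spectra. Metadata
#' beyond the sample id lives in a separate assay manifest (the reference
#' assay comes from an external method, so spectra and assays are decoupled);
#' pass the manifest (path or data.frame) to populate dosage form,
#' manufacturer and batch.
#'
#' @param path Path to the file.
#' @param format `"csv"` (long format) or `"jcampdx"` (single `XYDATA` block,
#'   read-only interchange support).
#' @param manifest Optional manifest data.frame or CSV path; see
#'   [read_assay_manifest()].
#' @return List of [nir_spectrum()] objects.
#' @export
read_spectra_table <- function(path, format = c("csv", "jcampdx"),
                               manifest = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) nir_stop(sprintf("file not found: %s", path), "format")
  spectra <- if (format == "csv") read_spectra_csv(path) else list(read_jcampdx(path))
  if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- read_assay_manifest(manifest)
    spectra <- lapply(spectra, function(s) {
      row <- manifest[manifest$sample_id == s$meta$sample_id, , drop = FALSE]
      if (nrow(row) == 1) {
        for (f in c("dosage_form", "manufacturer", "batch"))
          if (f %in% names(row) && !is.na(row[[f]][1]))
            s$meta[[f]] <- as.character(row[[f]][1])
      }
      s
    })
  }
  spectra
}

read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavenumber", "absorbance")
  missing <- setdiff(need, names(df))
  if (length(missing))
    nir_stop(sprintf("spectra CSV is missing column(s): %s",
                     paste(missing, collapse = ", ")), "format")
  if (!"replicate_index" %in% names(df)) df$replicate_index <- NA_integer_
  if (!is.numeric(df$wavenumber) || !is.numeric(df$absorbance))
    nir_stop("wavenumber and absorbance columns must be numeric", "format")
  key <- paste(df$sample_id, df$replicate_index, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    nir_spectrum(df$wavenumber[idx], df$absorbance[idx],
                 sample_id = df$sample_id[idx][1],
                 replicate_index = df$replicate_index[idx][1])
  })
}

#' Write spectra to a long-format CSV
#'
#' Inverse of [read_spectra_table()] for the CSV dialect; `read` after
#' `write` reproduces values and ids exactly (up to numeric text precision,
#' controlled by R's default `write.csv` formatting at 15 significant digits).
#'
#' @param spectra List of [nir_spectrum()] objects.
#' @param path Output CSV path.
#' @export
write_spectra_table <- function(spectra, path) {
  if (is_nir_spectrum(spectra)) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    data.frame(sample_id = s$meta$sample_id,
               replicate_index = s$meta$replicate_index,
               wavenumber = s$wavenumbers,
               absorbance = s$absorbance)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an assay manifest CSV
#'
#' Columns: `sample_id, dosage_form, manufacturer, batch, amoxicillin_pct,
#' clavulanate_pct, water_pct`; empty cells mean "assay absent".
#'
#' @param path CSV path.
#' @return data.frame with one row per sample.
#' @export
read_assay_manifest <- function(path) {
  if (!file.exists(path)) nir_stop(sprintf("file not found: %s", path), "format")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    nir_stop("manifest is missing column: sample_id", "format")
  for (col in c("amoxicillin_pct", "clavulanate_pct", "water_pct"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write an assay manifest CSV
#'
#' @param manifest data.frame as returned by [read_assay_manifest()].
#' @param path Output path.
#' @export
write_assay_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

# Minimal JCAMP-DX reader: single ##XYDATA=(X++(Y..Y)) block with FIRSTX /
# LASTX / NPOINTS and optional XFACTOR / YFACTOR. Interchange convenience
# only; not a compliance implementation.
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(NA)
    sub(paste0("^##", name, "="), "", hit[1])
  }
  title <- get_field("TITLE")
  xf <- suppressWarnings(as.numeric(get_field("XFACTOR"))); if (is.na(xf)) xf <- 1
  yf <- suppressWarnings(as.numeric(get_field("YFACTOR"))); if (is.na(yf)) yf <- 1
  npoints <- suppressWarnings(as.numeric(get_field("NPOINTS")))
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) nir_stop("no ##XYDATA block found", "format")
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1
  body <- lines[(start[1] + 1):(end - 1)]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    nums <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]]))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 2) next
    firstx <- nums[1] * xf
    yvals <- nums[-1] * yf
    # X of subsequent points follows from FIRSTX/LASTX/NPOINTS spacing
    dx <- if (!is.na(npoints) && npoints > 1) {
      (as.numeric(get_field("LASTX")) * xf - as.numeric(get_field("FIRSTX")) * xf) /
        (npoints - 1)
    } else NA
    if (is.na(dx)) nir_stop("JCAMP-DX file lacks NPOINTS/FIRSTX/LASTX", "format")
    xs <- c(xs, firstx + dx * (seq_along(yvals) - 1))
    ys <- c(ys, yvals)
  }
  if (length(xs) < 2) nir_stop("JCAMP-DX XYDATA block is empty", "format")
  o <- order(xs)
  nir_spectrum(xs[o], ys[o], sample_id = if (is.na(title)) "jcamp" else title)
}
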