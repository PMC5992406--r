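EXCIPIENT_CLASSES <- c("excipient_tablet", "excipient_chewable",
                       "excipient_granule", "excipient_suspension")

# Dosage-form -> excipient-class map. Tablet-family forms share starch/
# cellulose-like matrices; granules and suspensions are sugar-rich, which is
# what makes their spectra visibly distinct from the tablet family.
FORM_EXCIPIENT <- c(tablet = "excipient_tablet",
                    dispersible_tablet = "excipient_tablet",
                    chewable_tablet = "excipient_chewable",
                    granule = "excipient_granule",
                    capsule_granule = "excipient_granule",
                    oral_suspension = "excipient_suspension")

# Candidate band windows (cm-1) per component. The active's bands sit in the
# C-H overtone (8,300-9,500), 5,300-6,500 and the 4,200-4,800 combination
# regions; water has its combination band near 5,200 and the first OH
# overtone near 7,000. Excipient windows are family-specific and disjoint
# enough that the two families separate and actives stay identifiable.
component_windows <- function(component) {
  switch(component,
    amoxicillin = list(c(8300, 9500), c(5300, 6500), c(4200, 4800)),
    clavulanate = list(c(4850, 5250), c(6550, 7050), c(7900, 8250), c(9600, 10200)),
    water = list(c(5150, 5250), c(6950, 7050), c(10200, 10600)),
    family_common = list(c(4100, 4500), c(5700, 6300), c(7300, 7900), c(8600, 9400), c(10300, 11300)),
    family_tablet = list(c(4000, 4400), c(5600, 6200), c(7100, 7800), c(9700, 11000)),
    family_granule = list(c(4450, 4950), c(6100, 6900), c(8300, 9200), c(10800, 11900)),
    excipient_tablet = list(c(4000, 4400), c(5600, 6200), c(7100, 7700)),
    excipient_chewable = list(c(4050, 4450), c(5500, 6100), c(10000, 11000)),
    excipient_granule = list(c(4450, 4900), c(6100, 6800), c(8300, 9100)),
    excipient_suspension = list(c(4500, 4950), c(6200, 6900), c(10900, 11900)),
    nir_stop(sprintf("unknown component '%s'", component))
  )
}

EXCIPIENT_FAMILY <- c(excipient_tablet = "family_tablet",
                      excipient_chewable = "family_tablet",
                      excipient_granule = "family_granule",
                      excipient_suspension = "family_granule")

#' Generator specification
#'
#' The stated world the synthetic library emulates: a multi-manufacturer,
#' multi-dosage-form library of linear-in-concentration mixture spectra with
#' baseline/slope/scatter artifacts and replicate noise. Defaults: assay
#' ranges amoxicillin 4.77-57.86%, clavulanate 1.03-20.17%, water
#' 0.24-9.30%; 0.5% relative pointwise noise; 3 replicates per sample; 150
#' entries split across forms in the composition of a real post-marketing
#' library (tablet-heavy plus granules and suspensions).
#'
#' @param n_per_form Named integer vector of batch counts per dosage form.
#' @param concentration_ranges Named list of `c(low, high)` assay ranges (%).
#' @param noise_rel_sd Pointwise noise SD relative to the mean signal.
#' @param baseline_sd SD of the per-replicate additive baseline offset.
#' @param slope_sd SD of the per-replicate linear baseline slope.
#' @param scatter_sd SD of the per-replicate multiplicative scatter factor.
#' @param n_replicates Replicate scans per sample (default 3).
#' @param seed Integer seed (required); all randomness derives from it.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_per_form = c(tablet = 30, dispersible_tablet = 31,
                                          chewable_tablet = 4, granule = 38,
                                          oral_suspension = 47),
                           concentration_ranges = list(
                             amoxicillin = c(4.77, 57.86),
                             clavulanate = c(1.03, 20.17),
                             water = c(0.24, 9.30)),
                           noise_rel_sd = 0.005, baseline_sd = 0.02,
                           slope_sd = 0.01, scatter_sd = 0.05,
                           n_replicates = 3, seed) {
  if (missing(seed)) nir_stop("generator_spec requires a seed", "config")
  if (is.null(names(n_per_form)) || !all(names(n_per_form) %in% DOSAGE_FORMS))
    nir_stop("n_per_form must be named by dosage form", "config")
  if (any(n_per_form < 0)) nir_stop("counts must be >= 0", "config")
  for (rg in concentration_ranges)
    if (rg[1] < 0 || rg[2] > 100 || rg[1] >= rg[2])
      nir_stop("concentration ranges must be within [0, 100] with low < high",
               "config")
  if (noise_rel_sd < 0 || baseline_sd < 0 || slope_sd < 0 || scatter_sd < 0)
    nir_stop("artifact standard deviations must be >= 0", "config")
  structure(list(n_per_form = n_per_form,
                 concentration_ranges = concentration_ranges,
                 noise_rel_sd = noise_rel_sd, baseline_sd = baseline_sd,
                 slope_sd = slope_sd, scatter_sd = scatter_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

gaussian_band_sum <- function(component, seed, windows) {
  grid <- canonical_grid()
  comp_seed <- (string_hash31(component) + as.numeric(seed) * 10007) %% 2147483647
  with_seed(comp_seed, {
    n_bands <- sample(max(5, length(windows)):15, 1)
    win_idx <- c(seq_along(windows),                       # one band per window
                 sample(seq_along(windows), n_bands - length(windows),
                        replace = TRUE))
    centres <- vapply(win_idx, function(i)
      stats::runif(1, windows[[i]][1], windows[[i]][2]), numeric(1))
    widths <- stats::runif(n_bands, 80, if (component == "water") 280 else 220)
    heights <- stats::runif(n_bands, 0.3, 1)
    a <- numeric(length(grid))
    for (b in seq_len(n_bands))
      a <- a + heights[b] * exp(-(grid - centres[b])^2 / (2 * widths[b]^2))
    a
  })
}

#' Pure-component synthetic spectrum
#'
#' A nonnegative sum of 5-15 Gaussian bands on the canonical grid, with at
#' least one band in each of the component's characteristic windows; band
#' widths (80-280 cm-1) match the broad overtone/combination bands of real
#' NIR spectra. An excipient-class spectrum is a 65/35 blend of its
#' family-base band set (shared by the tablet family or the
#' granule/suspension family) and its class-specific bands, so dosage-form
#' families are spectrally cohesive yet classes remain distinct.
#' Deterministic per `(component, seed)`.
#'
#' @param component `"amoxicillin"`, `"clavulanate"`, `"water"` or one of
#'   the four excipient classes (`"excipient_tablet"`, `"excipient_chewable"`,
#'   `"excipient_granule"`, `"excipient_suspension"`).
#' @param seed Integer seed.
#' @return An [nir_spectrum()] on the canonical grid.
#' @export
pure_component_spectrum <- function(component, seed) {
  windows <- component_windows(component)   # validates the component name
  if (component %in% names(EXCIPIENT_FAMILY)) {
    fam <- EXCIPIENT_FAMILY[[component]]
    common <- gaussian_band_sum("family_common", seed,
                                component_windows("family_common"))
    a <- 0.35 * common +
      0.40 * gaussian_band_sum(fam, seed, component_windows(fam)) +
      0.25 * gaussian_band_sum(component, seed, windows)
  } else {
    a <- gaussian_band_sum(component, seed, windows)
  }
  nir_spectrum(canonical_grid(), a, sample_id = paste0("pure_", component))
}

# Component set for a library, with design-time screening: the drawn band
# set must make the actives and excipient classes distinct but related after
# derivative preprocessing (the world the method assumes: same-API products
# are similar, families differ, water is not confusable with the API).
# Candidate seeds are derived deterministically from the spec seed, so the
# screened set is reproducible.
component_spectra <- function(spec) {
  comps <- c("amoxicillin", "clavulanate", "water", EXCIPIENT_CLASSES)
  rtreg <- wn_regions(c(4200, 10000))
  grid <- canonical_grid()
  for (attempt in 0:29) {
    cand_seed <- (as.numeric(spec$seed) + attempt * 1000003) %% 2147483647
    out <- lapply(comps, pure_component_spectrum, seed = cand_seed)
    names(out) <- comps
    mix <- function(form, amx) {
      f <- c(amx, 0.3 * amx, 5) / 100          # amox, clav, water (%)
      a <- f[1] * out$amoxicillin$absorbance +
        f[2] * out$clavulanate$absorbance + f[3] * out$water$absorbance +
        (1 - sum(f)) * out[[FORM_EXCIPIENT[[form]]]]$absorbance
      sg_first_derivative(nir_spectrum(grid, a, sample_id = form))
    }
    rcorr <- function(a, b) correlation_coefficient(a, b, rtreg)
    ref <- mix("tablet", 45)
    r_tab <- rcorr(mix("tablet", 31), ref)          # low-content tablet
    r_dtb <- rcorr(mix("dispersible_tablet", 18), ref)  # low-content disp. tablet
    r_grn <- rcorr(mix("granule", 14), ref)         # mid-content granule
    r_aw <- rcorr(sg_first_derivative(out$amoxicillin),
                  sg_first_derivative(out$water))
    # the accepted design reproduces the r_T architecture the method assumes:
    # a tight high tablet band, dispersible tablets reaching mid-range, the
    # granule family in a low-but-positive band, and water distinguishable
    # from the active
    if (r_tab > 0.80 && r_tab < 0.97 &&
        r_dtb > 0.45 && r_dtb < 0.75 &&
        r_grn > 0.20 && r_grn < 0.60 && r_aw < 0.90) break
  }
  out
}

# Per-form assay sub-band as fractions of the global range: each dosage form
# occupies a distinct concentration (hence r_T) band, emulating the wide
# spread of a multi-form library without reproducing any specific numbers.
FORM_CONC_BAND <- list(
  tablet = c(0.50, 1.00), dispersible_tablet = c(0.25, 0.85),
  chewable_tablet = c(0.20, 0.75), granule = c(0.00, 0.35),
  oral_suspension = c(0.00, 0.25), capsule_granule = c(0.05, 0.45))

# Family partner used for per-sample excipient composition jitter
# (manufacturers within a family vary their matrix recipe).
EXCIPIENT_PARTNER <- c(excipient_tablet = "excipient_chewable",
                       excipient_chewable = "excipient_tablet",
                       excipient_granule = "excipient_suspension",
                       excipient_suspension = "excipient_granule")

form_range <- function(spec, analyte, form) {
  rg <- spec$concentration_ranges[[analyte]]
  if (analyte == "water") return(rg)           # water varies freely per form
  band <- FORM_CONC_BAND[[form]]
  rg[1] + band * (rg[2] - rg[1])
}

#' Generate the replicate spectra of one sample
#'
#' The ideal spectrum is the Beer-Lambert mixture
#' `sum(fraction_c * pure_spectrum_c)` over amoxicillin, clavulanate, water
#' and the form's excipient class (excipient fraction = remainder to 100%).
#' Each replicate then receives an additive baseline offset, a linear
#' baseline slope, a multiplicative scatter factor and pointwise Gaussian
#' noise scaled to the mean signal, per the generator spec.
#'
#' @param form Dosage form.
#' @param assay A [reference_assay()] with all three contents present.
#' @param spec A [generator_spec()].
#' @param components Optional cached list from the same spec's pure
#'   components (built if omitted).
#' @param sample_id Sample identifier (also seeds the replicate substream).
#' @return List: `replicates` (list of spectra) and `assay`.
#' @export
generate_sample <- function(form, assay, spec, components = NULL,
                            sample_id = "sample") {
  if (!form %in% DOSAGE_FORMS) nir_stop(sprintf("unknown dosage_form '%s'", form))
  if (is.null(components)) components <- component_spectra(spec)
  f <- c(amoxicillin = assay$amoxicillin_pct, clavulanate = assay$clavulanate_pct,
         water = assay$water_pct) / 100
  if (anyNA(f) || any(f < 0) || sum(f) > 1)
    nir_stop("assay percentages must be present, nonnegative and sum to <= 100")
  exc <- FORM_EXCIPIENT[[form]]
  grid <- canonical_grid()
  # per-sample excipient recipe: mostly the form's class, blended with up to
  # 35% of the family partner class (manufacturer-to-manufacturer matrix
  # variation; spreads r_T continuously within a dosage form)
  mix_seed <- (string_hash31(paste0(sample_id, "/excipient")) +
                 as.numeric(spec$seed) * 10007) %% 2147483647
  v <- with_seed(mix_seed, stats::runif(1, 0, 0.35))
  exc_abs <- (1 - v) * components[[exc]]$absorbance +
    v * components[[EXCIPIENT_PARTNER[[exc]]]]$absorbance
  ideal <- f[["amoxicillin"]] * components$amoxicillin$absorbance +
    f[["clavulanate"]] * components$clavulanate$absorbance +
    f[["water"]] * components$water$absorbance +
    (1 - sum(f)) * exc_abs
  scale <- mean(ideal)
  rep_seed <- (string_hash31(paste0(sample_id, "/replicates")) +
                 as.numeric(spec$seed) * 10007) %% 2147483647
  replicates <- with_seed(rep_seed, {
    lapply(seq_len(spec$n_replicates), function(k) {
      scatter <- stats::rnorm(1, 1, spec$scatter_sd)
      offset <- stats::rnorm(1, 0, spec$baseline_sd)
      slope <- stats::rnorm(1, 0, spec$slope_sd)
      noise <- stats::rnorm(length(grid), 0, spec$noise_rel_sd * scale)
      nir_spectrum(grid,
                   scatter * ideal + offset + slope * (grid - 8000) / 4000 + noise,
                   sample_id = sample_id, dosage_form = form,
                   manufacturer = "synthetic", batch = sample_id,
                   replicate_index = k)
    })
  })
  list(replicates = replicates, assay = assay)
}

#' Generate a fully indexed synthetic spectral library
#'
#' Draws per-form assay values uniformly within the configured (per-form
#' banded) ranges, generates replicate spectra, averages them, applies the
#' Savitzky-Golay first derivative, builds the tablet-mean reference spectrum
#' and indexes every entry by r_T over 4,200-10,000 cm-1. Reproducible from
#' the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @param keep_replicates Store the raw replicate spectra on each entry.
#' @param preprocess A [preprocess_config()] for the derivative step.
#' @return An indexed [spectral_library()]; the generator spec is attached
#'   as the `generator` element.
#' @export
generate_library <- function(spec, keep_replicates = FALSE,
                             preprocess = preprocess_config()) {
  if (!inherits(spec, "generator_spec")) nir_stop("spec must be a generator_spec")
  counts <- spec$n_per_form[spec$n_per_form > 0]
  if (!("tablet" %in% names(counts)))
    nir_stop("the default reference policy needs at least one tablet entry",
             "config")
  components <- component_spectra(spec)
  abbrev <- c(tablet = "tab", dispersible_tablet = "dtb", chewable_tablet = "ctb",
              granule = "grn", oral_suspension = "osp", capsule_granule = "cap")
  entries <- list()
  for (form in names(counts)) {
    a_rg <- form_range(spec, "amoxicillin", form)
    c_rg <- form_range(spec, "clavulanate", form)
    w_rg <- form_range(spec, "water", form)
    for (i in seq_len(counts[[form]])) {
      sid <- sprintf("%s_%03d", abbrev[[form]], i)
      assay_seed <- (string_hash31(paste0(sid, "/assay")) +
                       as.numeric(spec$seed) * 10007) %% 2147483647
      assay <- with_seed(assay_seed, reference_assay(
        amoxicillin_pct = stats::runif(1, a_rg[1], a_rg[2]),
        clavulanate_pct = stats::runif(1, c_rg[1], c_rg[2]),
        water_pct = stats::runif(1, w_rg[1], w_rg[2])))
      smp <- generate_sample(form, assay, spec, components, sample_id = sid)
      avg <- average_replicates(smp$replicates)
      deriv <- sg_first_derivative(avg, preprocess)
      entries[[sid]] <- library_entry(
        deriv, assay,
        raw_replicates = if (keep_replicates) smp$replicates else NULL)
    }
  }
  entries <- unname(entries)
  ref <- build_reference_spectrum(entries, "tablet")
  lib <- spectral_library(entries, reference_spectrum = ref)
  lib <- index_library(lib)
  lib$generator <- spec
  lib
}
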