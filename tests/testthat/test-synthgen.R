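test_that("generator spec validates its stated world", {
  expect_error(generator_spec(), class = "nirlib_config_error")  # seed required
  expect_error(generator_spec(n_per_form = c(lozenge = 5), seed = 1),
               class = "nirlib_config_error")
  expect_error(generator_spec(concentration_ranges = list(
    amoxicillin = c(-1, 50)), seed = 1), class = "nirlib_config_error")
  spec <- generator_spec(seed = 1)
  expect_equal(spec$concentration_ranges$amoxicillin, c(4.77, 57.86))
  expect_equal(spec$concentration_ranges$clavulanate, c(1.03, 20.17))
  expect_equal(spec$concentration_ranges$water, c(0.24, 9.30))
  expect_identical(spec$n_replicates, 3L)
})

test_that("pure component spectra are deterministic, nonnegative and distinct", {
  a1 <- pure_component_spectrum("amoxicillin", 5)
  a2 <- pure_component_spectrum("amoxicillin", 5)
  expect_identical(a1$absorbance, a2$absorbance)
  expect_false(identical(pure_component_spectrum("amoxicillin", 6)$absorbance,
                         a1$absorbance))
  for (comp in c("amoxicillin", "clavulanate", "water", "excipient_tablet",
                 "excipient_granule")) {
    s <- pure_component_spectrum(comp, 3)
    expect_true(all(s$absorbance >= 0))
    expect_equal(s$wavenumbers, canonical_grid())
  }
  expect_error(pure_component_spectrum("unobtainium", 1),
               class = "nirlib_validation_error")
})

test_that("active and water are not confusable in the index region", {
  # design constraint checked at generator level: the screened component set
  # keeps the derivative correlation between the two well below 1
  for (seed in c(1, 2, 3)) {
    spec <- generator_spec(seed = seed)
    comps <- nirlib:::component_spectra(spec)
    r <- correlation_coefficient(sg_first_derivative(comps$amoxicillin),
                                 sg_first_derivative(comps$water),
                                 wn_regions(c(4200, 10000)))
    expect_lt(r, 0.95)
  }
})

test_that("sample generation is linear in composition and respects noise", {
  spec0 <- generator_spec(noise_rel_sd = 0, baseline_sd = 0, slope_sd = 0,
                          scatter_sd = 0, seed = 9)
  comps <- nirlib:::component_spectra(spec0)
  assay <- reference_assay(20, 5, 3)
  smp <- generate_sample("tablet", assay, spec0, comps, sample_id = "t1")
  expect_length(smp$replicates, 3)
  # zero artifact SDs: replicates are identical and equal the ideal mixture
  expect_identical(smp$replicates[[1]]$absorbance,
                   smp$replicates[[2]]$absorbance)

  # the mixture is linear in the active's fraction: equal concentration
  # increments produce equal spectral increments (same sample, so the same
  # excipient recipe applies throughout)
  s10 <- generate_sample("tablet", reference_assay(10, 5, 3), spec0, comps,
                         sample_id = "t1")$replicates[[1]]$absorbance
  s30 <- generate_sample("tablet", reference_assay(30, 5, 3), spec0, comps,
                         sample_id = "t1")$replicates[[1]]$absorbance
  s50 <- generate_sample("tablet", reference_assay(50, 5, 3), spec0, comps,
                         sample_id = "t1")$replicates[[1]]$absorbance
  expect_equal(s30 - s10, s50 - s30, tolerance = 1e-12)
  # and the increment direction is active minus excipient
  expect_false(isTRUE(all.equal(s30, s10)))

  expect_error(generate_sample("tablet", reference_assay(80, 15, 9),
                               spec0, comps),
               class = "nirlib_validation_error")
})

test_that("library generation honours counts, ranges and determinism", {
  lib <- small_library()
  forms <- entry_forms(lib)
  expect_identical(sum(forms == "tablet"), 30L)
  expect_identical(sum(forms == "dispersible_tablet"), 31L)
  expect_identical(sum(forms == "chewable_tablet"), 4L)
  expect_identical(sum(forms == "granule"), 38L)
  expect_identical(sum(forms == "oral_suspension"), 47L)

  amox <- sapply(lib$entries, function(e) e$assay$amoxicillin_pct)
  clav <- sapply(lib$entries, function(e) e$assay$clavulanate_pct)
  water <- sapply(lib$entries, function(e) e$assay$water_pct)
  expect_true(all(amox >= 4.77 & amox <= 57.86))
  expect_true(all(clav >= 1.03 & clav <= 20.17))
  expect_true(all(water >= 0.24 & water <= 9.30))

  lib2 <- generate_library(generator_spec(seed = 1))
  expect_equal(rt_values(lib2), rt_values(lib), tolerance = 0)
  expect_identical(lib2$entries[[10]]$spectrum$absorbance,
                   lib$entries[[10]]$spectrum$absorbance)

  expect_error(generate_library(generator_spec(
    n_per_form = c(granule = 10), seed = 1)), class = "nirlib_config_error")
})

test_that("tablet and granule families are separable by Ward clustering", {
  lib <- small_library()
  X <- nirlib:::build_features(lapply(lib$entries, `[[`, "spectrum"))
  labels <- ward_cluster(X, 2)
  family <- ifelse(entry_forms(lib) %in%
                     c("tablet", "dispersible_tablet", "chewable_tablet"),
                   1L, 2L)
  agreement <- max(mean(labels == family), mean(labels == 3L - family))
  expect_gte(agreement, 0.95)
})

test_that("held-out error degrades monotonically with noise", {
  rmsep_at <- function(noise, s) {
    spec <- generator_spec(n_per_form = c(tablet = 20, dispersible_tablet = 20,
                                          granule = 15, oral_suspension = 15),
                           noise_rel_sd = noise, seed = s)
    lib <- generate_library(spec)
    sets <- split_train_test(lib$entries)
    X <- nirlib:::build_features(lapply(sets$train, `[[`, "spectrum"))
    y <- sapply(sets$train, function(e) e$assay$amoxicillin_pct)
    m <- fit_pls1(X, y, 5)
    Xt <- nirlib:::build_features(lapply(sets$test, `[[`, "spectrum"))
    yt <- sapply(sets$test, function(e) e$assay$amoxicillin_pct)
    validation_metrics(yt, predict(m, Xt))$rmsep
  }
  meds <- vapply(c(0.005, 0.05, 0.2), function(noise)
    median(vapply(1:10, function(s) rmsep_at(noise, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(meds) > 0))
})
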