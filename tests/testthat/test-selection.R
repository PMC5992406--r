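test_that("spacing sweep follows the greedy contract", {
  entries <- mapply(make_rt_entry, c(70, 70.5, 71, 71.5, 72),
                    paste0("s", 1:5), SIMPLIFY = FALSE)
  sel <- select_by_spacing(entries, 1.0)
  expect_equal(unname(sel$rt_pct), c(70, 71, 72), tolerance = 1e-9)
  expect_true(all(sel$adjacent_gaps >= 1.0 - 1e-9))

  all_in <- select_by_spacing(entries, 0)
  expect_length(all_in$selected, 5)

  ties <- list(make_rt_entry(80, "zz"), make_rt_entry(80, "aa"))
  one <- select_by_spacing(ties, 0.5)
  expect_length(one$selected, 1)
  expect_identical(one$selected[[1]]$spectrum$meta$sample_id, "aa")

  expect_error(select_by_spacing(list(), 1),
               class = "nirlib_empty_selection_error")
})

test_that("spacing sweep output is a spaced subsequence for random inputs", {
  set.seed(21)
  for (rep in 1:15) {
    rt <- sort(runif(60, 30, 100))
    entries <- mapply(make_rt_entry, rt, sprintf("s%02d", 1:60),
                      SIMPLIFY = FALSE)
    spacing <- runif(1, 0.3, 3)
    sel <- select_by_spacing(entries, spacing)
    expect_true(all(sel$adjacent_gaps >= spacing - 1e-9))
    expect_true(all(names(sel$rt_pct) %in% sprintf("s%02d", 1:60)))
    # first entry is always selected; anchored sweep keeps the anchor
    expect_identical(names(sel$rt_pct)[1], "s01")
    anchored <- select_by_spacing(entries, spacing, anchor = median(rt))
    expect_true(all(anchored$adjacent_gaps >= spacing - 1e-9))
    expect_true(min(abs(anchored$rt_pct - median(rt))) <=
                  min(abs(rt - median(rt))) + 1e-9)
  }
})

test_that("target-anchored selection covers the target range at full spacing", {
  lib <- small_library()
  forms <- entry_forms(lib)
  targets <- lapply(lib$entries[forms == "dispersible_tablet"],
                    `[[`, "spectrum")
  sel <- select_for_targets(lib, targets, spacing = 1.25, n_min = 30)
  expect_gte(length(sel$selected), 30)
  expect_true(all(sel$adjacent_gaps >= 1.25 - 1e-9))
  expect_lte(min(sel$rt_pct), sel$target_rt_range[1] + 1e-9)
  expect_gte(max(sel$rt_pct), sel$target_rt_range[2] - 1e-9)
  expect_length(sel$flags, 0)
  # the sweep is anchored on the target median: the library entry nearest to
  # it is always part of the selection (the set then grows outward, so its
  # median can drift when the target median sits near the library edge)
  rt_all <- rt_values(lib)
  nearest <- names(rt_all)[which.min(abs(rt_all - sel$target_median_rt))]
  expect_true(nearest %in% names(sel$rt_pct))
  # deterministic
  sel2 <- select_for_targets(lib, targets, spacing = 1.25, n_min = 30)
  expect_identical(names(sel$rt_pct), names(sel2$rt_pct))
})

test_that("tiny libraries produce endpoint fallback with a shortfall flag", {
  entries <- mapply(make_rt_entry, c(70, 71, 72, 73, 74), paste0("e", 1:5),
                    SIMPLIFY = FALSE)
  ref <- make_rt_entry(72, "ref")
  lib <- spectral_library(lapply(entries, identity),
                          reference_spectrum = entries[[3]]$spectrum,
                          rt_region = wn_regions(c(4000, 4092)))
  lib$entries <- entries; lib$indexed <- TRUE
  sel <- select_for_targets(lib, targets = 72, spacing = 10, n_min = 30)
  expect_true("n_min_shortfall" %in% sel$flags)
  # nearest entry plus the library endpoints
  expect_setequal(names(sel$rt_pct), c("e1", "e3", "e5"))
})

test_that("targets outside the library span raise coverage errors", {
  lib <- small_library()
  expect_error(select_for_targets(lib, targets = 100.5, spacing = 1),
               "above", class = "nirlib_coverage_error")
  expect_error(select_for_targets(lib, targets = min(rt_values(lib)) - 5,
                                  spacing = 1),
               "below", class = "nirlib_coverage_error")
})

test_that("train/test split is interleaved with endpoints in training", {
  entries <- mapply(make_rt_entry, seq(40, 98, by = 2), sprintf("p%02d", 1:30),
                    SIMPLIFY = FALSE)
  sets <- split_train_test(entries)
  expect_length(sets$train, 20)
  expect_length(sets$test, 10)
  rt_all <- sort(sapply(entries, function(e) 100 * e$r_t))
  rt_train <- sapply(sets$train, function(e) 100 * e$r_t)
  expect_true(min(rt_all) %in% rt_train)
  expect_true(max(rt_all) %in% rt_train)
  expect_length(intersect(sapply(sets$train, function(e) e$spectrum$meta$sample_id),
                          sapply(sets$test, function(e) e$spectrum$meta$sample_id)), 0)

  three <- split_train_test(entries[1:3])
  expect_length(three$train, 2)
  expect_length(three$test, 1)
  expect_error(split_train_test(entries[1:2]), class = "nirlib_size_error")
})

test_that("Ward clustering recovers structure and honours cut sizes", {
  set.seed(31)
  cloud1 <- matrix(rnorm(20, 0, 0.2), ncol = 2)
  cloud2 <- matrix(rnorm(20, 5, 0.2), ncol = 2)
  X <- rbind(cloud1, cloud2)
  labels <- ward_cluster(X, 2)
  expect_true(same_partition(labels, rep(1:2, each = 10)))

  expect_length(unique(ward_cluster(X, nrow(X))), nrow(X))
  expect_length(unique(ward_cluster(X, 1)), 1)
  expect_error(ward_cluster(X, nrow(X) + 1), class = "nirlib_size_error")
})

test_that("cluster sampling follows the 2 + 1 rule deterministically", {
  labels <- rep(1:19, each = 3)
  draw <- sample_from_clusters(labels, seed = 5)
  expect_length(draw$calibration, 38)
  expect_length(draw$validation, 19)
  expect_length(intersect(draw$calibration, draw$validation), 0)
  expect_identical(draw, sample_from_clusters(labels, seed = 5))
  expect_false(identical(draw, sample_from_clusters(labels, seed = 6)))

  # singleton and pair clusters contribute to calibration only
  mixed <- c(1, 1, 1, 1, 2, 3, 3)
  d2 <- sample_from_clusters(mixed, seed = 1)
  expect_true(5 %in% d2$calibration)
  expect_false(5 %in% d2$validation)
  expect_length(intersect(c(6, 7), d2$calibration), 2)
  expect_lte(length(d2$validation), 1)
})
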