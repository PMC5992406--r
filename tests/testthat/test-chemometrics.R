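test_that("PLS1 fits exact linear data exactly at full rank", {
  set.seed(41)
  X <- matrix(rnorm(15 * 4), 15, 4)
  b <- c(2, -1, 0.5, 3)
  y <- drop(X %*% b) + 7
  m <- fit_pls1(X, y, rank = 4)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  expect_error(fit_pls1(X, y, rank = 5), class = "nirlib_rank_error")
  expect_error(fit_pls1(X, rep(1, 15), rank = 2),
               class = "nirlib_degenerate_error")
})

test_that("full-rank PLS1 equals the normal-equations least-squares solution", {
  set.seed(42)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20, sd = 3) + drop(X %*% rnorm(8))
    m <- fit_pls1(X, y, rank = 8)
    # independent oracle: explicit normal equations on centred data
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    b_ols <- solve(crossprod(Xc), crossprod(Xc, yc))
    pred_ols <- mean(y) + drop(Xc %*% b_ols)
    expect_lt(max(abs(predict(m, X) - pred_ols)), 1e-8)
  }
})

test_that("PLS1 predictions are invariant to training-sample order", {
  set.seed(43)
  X <- matrix(rnorm(18 * 6), 18, 6)
  y <- rnorm(18, 20, 5)
  perm <- sample(18)
  m1 <- fit_pls1(X, y, 3)
  m2 <- fit_pls1(X[perm, ], y[perm], 3)
  Xnew <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-8)
})

test_that("training residual error is non-increasing in rank", {
  set.seed(44)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  rss <- vapply(1:8, function(r)
    sum((y - predict(fit_pls1(X, y, r), X))^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("prediction applies the model's preprocessing to raw spectra", {
  lib <- small_library()
  entries <- lib$entries
  X <- nirlib:::build_features(lapply(entries[1:40], `[[`, "spectrum"))
  y <- sapply(entries[1:40], function(e) e$assay$amoxicillin_pct)
  m <- fit_pls1(X, y, 4, preprocess = preprocess_config())
  # a derivative spectrum routed through predict() must agree with the
  # feature-matrix path
  s <- entries[[41]]$spectrum
  expect_equal(predict(m, s),
               predict(m, nirlib:::build_features(list(s))),
               tolerance = 1e-12)
  # wrong feature length is refused
  expect_error(predict(m, matrix(0, 1, 5)), class = "nirlib_validation_error")
})

test_that("validation metrics reproduce the defining identities", {
  r <- validation_metrics(c(3, 5), c(2, 3), mode = "tsv")
  expect_equal(r$differs, c(1, 2))
  expect_equal(r$press, 5)
  expect_equal(r$rmsep, sqrt(2.5), tolerance = 1e-12)

  perfect <- validation_metrics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(perfect$r_squared, 100)
  expect_equal(perfect$frac_lt_1pct, 1)
  expect_equal(perfect$frac_gt_5pct, 0)
  expect_equal(perfect$mean_abs_differ, 0)

  mixed <- validation_metrics(c(10, 10), c(9.5, 16), mode = "tsv")
  expect_equal(mixed$frac_gt_5pct, 0.5)
  expect_equal(mixed$frac_lt_1pct, 0.5)

  expect_error(validation_metrics(1:3, 1:2), class = "nirlib_validation_error")
})

test_that("metric identities hold on random reports", {
  set.seed(45)
  for (i in 1:10) {
    true <- runif(12, 5, 60); pred <- true + rnorm(12, 0, 3)
    rep_ <- validation_metrics(true, pred, mode = "tsv")
    expect_equal(rep_$rmsep^2 * rep_$n, rep_$press, tolerance = 1e-10)
    tss <- sum((true - mean(true))^2)
    expect_equal(rep_$r_squared, 100 * (1 - rep_$press / tss),
                 tolerance = 1e-10)
    expect_true(rep_$r_squared <= 100)
  }
})

test_that("LOOCV equals a literal hold-one-out loop", {
  set.seed(46)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(12, 0, 0.5) + 25
  fast <- loocv_pls1(X, y, max_rank = 4)
  slow <- loocv_literal(X, y, max_rank = 4)
  expect_equal(fast$predictions, slow$predictions, tolerance = 1e-10)
  expect_equal(fast$press, slow$press, tolerance = 1e-10)
  expect_equal(fast$rmsecv, sqrt(fast$press / 12), tolerance = 1e-12)
  # every sample predicted exactly once per rank
  expect_true(all(is.finite(fast$predictions)))
})

test_that("LOOCV generalizes exactly on noiseless linear data", {
  set.seed(47)
  X <- matrix(rnorm(14 * 3), 14, 3)
  y <- drop(X %*% c(1, 2, 3)) + 10
  cv <- loocv_pls1(X, y, max_rank = 3)
  expect_lt(cv$rmsecv[3], 1e-6)
  expect_error(loocv_pls1(X, y, max_rank = 13), class = "nirlib_rank_error")
})

test_that("F-test rank selection picks the most parsimonious adequate rank", {
  expect_identical(select_rank_ftest(3.7, n = 10), 1L)

  # frozen oracle: PRESS (100, 10, 9.99, 9.98) at n = 100; threshold =
  # 9.98 * qf(0.75, 100, 100) ~ 11.28, so ranks 2-4 pass and 2 wins
  expect_identical(select_rank_ftest(c(100, 10, 9.99, 9.98), n = 100), 2L)
  expect_true(100 > 9.98 * qf(0.75, 100, 100))

  # an isolated 10x drop at the last rank leaves only the minimum passing
  press <- c(100, 50, 30, 2.9)
  expect_identical(select_rank_ftest(press, n = 50), 4L)

  expect_error(select_rank_ftest(c(1, -2), n = 10),
               class = "nirlib_validation_error")
})

test_that("PCA scores diagonalize the covariance and fix signs", {
  set.seed(48)
  X <- matrix(rnorm(30 * 5), 30, 5) %*% diag(c(5, 3, 1, 0.5, 0.1))
  sc <- pca_scores(X, 3)
  cv <- crossprod(sc) / (nrow(X) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_true(all(diff(diag(cv)) <= 1e-10))
  # oracle: eigendecomposition of the covariance matrix
  ev <- eigen(stats::cov(X))$values[1:3]
  expect_equal(unname(diag(cv)), ev, tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  L <- attr(sc, "loadings")
  for (a in 1:3) expect_gt(L[which.max(abs(L[, a])), a], 0)

  # collinear points have no second-component variance
  line <- cbind(1:10, 2 * (1:10))
  sc2 <- pca_scores(line, 2)
  expect_lt(max(abs(sc2[, 2])), 1e-10)
  expect_error(pca_scores(line, 3), class = "nirlib_rank_error")
})
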