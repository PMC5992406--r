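# Shared fixtures and independent oracles, built in code at test time.

# Simple spectrum on a uniform grid.
make_spectrum <- function(absorbance, wavenumbers = NULL, sample_id = "s1",
                          ...) {
  if (is.null(wavenumbers))
    wavenumbers <- seq(4000, by = 4, length.out = length(absorbance))
  nir_spectrum(wavenumbers, absorbance, sample_id = sample_id, ...)
}

# Indexed library entry with a given r_t (%) without running the pipeline;
# used for selection-logic tests where only (r_t, sample_id) matter.
make_rt_entry <- function(rt_pct, sample_id, amox = 20) {
  e <- library_entry(
    make_spectrum(seq(0.1, 1, length.out = 24), sample_id = sample_id),
    reference_assay(amoxicillin_pct = amox))
  e$r_t <- rt_pct / 100
  e
}

# Small default synthetic library (cached per session: generation is
# deterministic, so sharing is safe).
.lib_cache <- new.env(parent = emptyenv())
small_library <- function(seed = 1, n_per_form = c(tablet = 30,
                                                   dispersible_tablet = 31,
                                                   chewable_tablet = 4,
                                                   granule = 38,
                                                   oral_suspension = 47),
                          ...) {
  key <- paste0("lib_", seed, "_", paste(n_per_form, collapse = "."),
                paste(c(...), collapse = "."))
  if (is.null(.lib_cache[[key]]))
    .lib_cache[[key]] <- generate_library(
      generator_spec(n_per_form = n_per_form, seed = seed, ...))
  .lib_cache[[key]]
}

entry_forms <- function(lib)
  vapply(lib$entries, function(e) e$spectrum$meta$dosage_form, character(1))

# ---- independent oracles ------------------------------------------------

# Brute-force Ward agglomeration: repeatedly merge the pair of clusters with
# the smallest increase in total within-cluster sum of squares.
ward_bruteforce <- function(X, k) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  sse_inc <- function(a, b) {
    na <- length(a); nb <- length(b)
    ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
    (na * nb) / (na + nb) * sum((ca - cb)^2)
  }
  while (length(clusters) > k) {
    best <- c(NA, NA); best_inc <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        inc <- sse_inc(clusters[[i]], clusters[[j]])
        if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(X))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# TRUE iff two label vectors describe the same partition.
same_partition <- function(a, b) {
  ta <- outer(a, a, `==`); tb <- outer(b, b, `==`)
  all(ta == tb)
}

# Literal leave-one-out loop: an independent re-implementation that refits
# via fit_pls1 for every (held-out sample, rank) pair and predicts through
# the regression vector.
loocv_literal <- function(X, y, max_rank) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, max_rank)
  for (i in seq_len(n)) {
    for (r in seq_len(max_rank)) {
      m <- fit_pls1(X[-i, , drop = FALSE], y[-i], r)
      preds[i, r] <- predict(m, X[i, , drop = FALSE])
    }
  }
  press <- colSums((y - preds)^2)
  list(press = press, rmsecv = sqrt(press / n), predictions = preds)
}
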