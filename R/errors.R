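# Classed error helper. Every user-facing failure mode raises a condition of
# class nirlib_<class>_error so callers can branch without matching messages.
nir_stop <- function(msg, class = "validation", call. = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("nirlib_", class, "_error"), "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness routes here.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit string hash (polynomial rolling hash mod 2^31 - 1); used to
# derive per-sample RNG substreams from sample ids.
string_hash31 <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

# FNV-1a style hash of a deparsed object, for config provenance stamps.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  codes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483648
  for (c in codes) h <- (bitwXor(as.integer(h), c) * 31 + 17) %% 2147483648
  sprintf("%08x", h)
}
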