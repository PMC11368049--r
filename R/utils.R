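# Internal caches and small helpers shared across modules.

.ad_cache <- new.env(parent = emptyenv())

cache_fetch <- function(key, compute) {
  if (!is.null(.ad_cache[[key]])) return(.ad_cache[[key]])
  val <- compute()
  .ad_cache[[key]] <- val
  val
}

#' Clear the in-process molecule cache
#'
#' Canonical SMILES, molecular graphs and fingerprints are memoized per
#' process. Call this to drop the cache (e.g. between benchmarks when
#' measuring wall time).
#'
#' @return Invisibly, the number of entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(.ad_cache))
  rm(list = ls(.ad_cache), envir = .ad_cache)
  invisible(n)
}

# Deterministic integer hashing over integer vectors; arithmetic stays within
# the exact-double range so results are identical across platforms/sessions.
.HASH_MOD <- 2147483647
hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% .HASH_MOD)) %% .HASH_MOD
  h
}

# Derive a child seed from a base seed and stream index, kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 1009 * as.numeric(stream)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) stop(..., call. = FALSE)
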