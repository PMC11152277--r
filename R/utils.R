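# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# Derive a reproducible substream seed from a root seed. Keeps results
# below 2^31 so they remain valid R integers.
substream_seed <- function(root, k) {
  as.integer((as.numeric(root) * 1103L + as.numeric(k) * 7919) %% 2147483647)
}

# Deterministic key for a set of identifiers (order-free).
set_key <- function(ids) paste0("s|", paste(sort(ids), collapse = "\x1f"))

fl_stop <- function(...) stop(..., call. = FALSE)

fl_assert <- function(cond, ...) if (!isTRUE(cond)) fl_stop(...)
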