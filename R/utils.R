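# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Counter-mode derivation of per-unit seeds (columns, bootstrap replicates):
# results depend only on (seed, index), never on iteration order. Kept below
# 2^31 - 1 so the value is a legal set.seed() argument.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 +
                1103515245 * (as.numeric(index) %% 2048) +
                12345 * as.numeric(index)) %% 2147483646 + 1)
}

is_count <- function(x) {
  is.numeric(x) && length(x) >= 1L && all(is.finite(x)) &&
    all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_note <- function(notes, tag) unique(c(notes, tag))
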