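# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic 31-bit string hash (double arithmetic stays exact: values
# never exceed 2^53).  Used for sub-stream seed derivation and config digests.
string_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483629
  h
}

# Derive a per-stage sub-seed from the run seed so that adding a stage never
# perturbs another stage's random stream.  Always < 2^31.
derive_seed <- function(seed, label) {
  as.integer((as.double(seed) %% 2147483629 + 1000003 * string_hash(label)) %%
               2147483629)
}

hash_file <- function(path) {
  sprintf("%08x", string_hash(paste(readLines(path, warn = FALSE), collapse = "\n")))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
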