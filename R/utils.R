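# Internal helpers: argument checking, typed errors, shared kernels.

abort_targetodds <- function(message, class) {
  rlang::abort(message, class = c(class, "targetodds_error"))
}

check_probability <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_targetodds(sprintf("`%s` must be numeric with no missing values.", name),
                     "targetodds_invalid_argument")
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!all(lo_ok & hi_ok)) {
    abort_targetodds(sprintf("`%s` must be a probability in %s0, 1%s.", name,
                             if (allow_zero) "[" else "(",
                             if (allow_one) "]" else ")"),
                     "targetodds_invalid_argument")
  }
  x
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    abort_targetodds(sprintf("`%s` must be a single integer-valued number.", name),
                     "targetodds_invalid_argument")
  }
  if (positive && x <= 0) {
    abort_targetodds(sprintf("`%s` must be strictly positive.", name),
                     "targetodds_invalid_argument")
  }
  if (!positive && x < 0) {
    abort_targetodds(sprintf("`%s` must be non-negative.", name),
                     "targetodds_invalid_argument")
  }
  as.double(x)
}

# Smallest integer N with 1 - (1 - p)^N >= confidence. The `nearest` rounding
# reproduces quoted counts derived from the real-valued solution, where the
# stated confidence is attained only approximately.
n_for_at_least_one <- function(p, confidence, rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  check_probability(confidence, "confidence", allow_zero = FALSE, allow_one = FALSE)
  check_probability(p, "p")
  if (any(p == 0)) {
    abort_targetodds(
      "Per-trial success probability is 0: no number of trials attains the confidence.",
      "targetodds_unattainable")
  }
  exact <- log1p(-confidence) / log1p(-p)
  n <- switch(rounding,
    ceiling = ceiling(exact - 1e-9),
    nearest = round(exact)
  )
  as.integer(pmax(n, 1))
}

# Evaluate `code` under a temporary RNG state when `seed` is given; restores
# (or removes) .Random.seed afterwards so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

new_pmf_tbl <- function(df) {
  class(df) <- c("pmf_tbl", class(df))
  df
}

`%||%` <- rlang::`%||%`
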