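#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers are unaffected. All stochastic routines in
#' the package thread seeds through this helper.
#'
#' @param seed integer seed (< 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# draw k reproducible sub-seeds from a parent seed (kept below 2^31)
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(2147483646L, k))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# linear interpolation of a signal at arbitrary times, erroring when the
# nearest sample is farther than `max_gap` seconds away
interp_at <- function(time, values, t, max_gap = Inf) {
  if (any(t < time[1] - max_gap) || any(t > time[length(time)] + max_gap)) {
    stopf("time %g outside the recording", t[which(t < time[1] | t > time[length(time)])][1])
  }
  stats::approx(time, values, xout = t, rule = 2)$y
}
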