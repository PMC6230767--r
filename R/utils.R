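# Shared internal helpers and constants.

# The 20 standard amino acids, in the fixed column order used by every
# emission vector in the package.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson amino-acid background frequencies (the standard
# null model used by profile-HMM software), normalised to sum to 1.
AA_BACKGROUND <- local({
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f <- f[AA20]
  f / sum(f)
})

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the R random-number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded package operations do not
#' perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stop unless all conditions hold; `...` are named logical scalars whose
# names double as error messages.
stopifnot_named <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(conds[[nm]])) stop(nm, call. = FALSE)
  }
  invisible(TRUE)
}

# log(sum(exp(x))) guarded against -Inf underflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
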