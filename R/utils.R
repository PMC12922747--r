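#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's
#' random-number state afterwards, so generators are pure functions of their
#' configuration and do not disturb the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# stopifnot() with a readable message
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

#' Round a percentage half away from zero to one decimal
#'
#' Reporting convention used throughout: \code{percent(752, 922)} is
#' \code{81.6}. Base \code{round()} rounds half to even, so the half-away
#' rule is implemented explicitly.
#'
#' @param numerator,denominator non-negative counts, \code{numerator <=
#'   denominator}, \code{denominator > 0}.
#' @return Percentage rounded to one decimal place.
#' @examples
#' percent(752, 922)   # 81.6
#' percent(2517, 3136) # 80.3
#' @export
percent <- function(numerator, denominator) {
  assert_that(all(denominator > 0), "percent(): zero denominator")
  assert_that(all(numerator >= 0 & numerator <= denominator),
              "percent(): need 0 <= numerator <= denominator")
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}
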