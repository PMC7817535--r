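## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's
#' `.Random.seed` afterwards, so seeded operations never disturb the global
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.integer(seed) * 101L + as.integer(stream) * 7919L) %% 2147483647L
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive whole number", name), call. = FALSE)
  invisible(as.integer(x))
}

## Standardize to mean 0, sample SD 1 (n - 1 denominator).
#' Standardize a numeric vector
#'
#' Centres by the mean and scales by the sample standard deviation
#' (denominator `n - 1`), the convention used for competition covariates
#' before they enter a mixed model.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector with mean 0 and sample SD 1.
#' @examples
#' standardize(c(2, 4, 6)) # -1 0 1
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || sum(is.finite(x)) < 2)
    stop("`x` must contain at least two finite values", call. = FALSE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant vector (zero standard deviation)",
         call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}
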