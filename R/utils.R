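#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif plogis qlogis pnorm pchisq predict
#'   binomial coef quantile
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

assert_binary <- function(x, name) {
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must contain only 0/1 values", name), call. = FALSE)
  invisible(x)
}

assert_both_classes <- function(outcome) {
  if (length(unique(outcome)) < 2L)
    stop("outcome has a single class; both cases and controls are required",
         call. = FALSE)
  invisible(outcome)
}
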