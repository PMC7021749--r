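#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd aov t.test cor.test optimize approx
#'   median quantile setNames
#' @importFrom grDevices contourLines
#' @importFrom utils write.csv read.csv modifyList combn packageVersion
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be positive", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
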