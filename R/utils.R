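#' @importFrom stats aggregate anova aov coef cor.test dist kmeans lm
#'   pchisq pf pnorm poly qnorm quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
#' @importFrom tools md5sum
NULL

stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("laminardev_invalid_parameter", "laminardev_error")))
}

stop_lookup <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("laminardev_lookup_error", "laminardev_error")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded helpers do not perturb outer simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a single finite number, got %s", deparse(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-task sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629)
}
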