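#' @keywords internal
"_PACKAGE"

## Small shared helpers.

stop_invalid <- function(...) {
  stop(structure(class = c("longage_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Beta-binomial log-density (mean/concentration parametrization)
#'
#' Density of `y` successes out of `n` draws where the success probability is
#' Beta-distributed with mean `p` and concentration `c` (shape1 = p*c,
#' shape2 = (1-p)*c).  As `c` grows the distribution approaches Binomial(n, p).
#'
#' @param y,n integer counts, `0 <= y <= n`.
#' @param p mean in (0,1).
#' @param c concentration, positive.
#' @return log-density, vectorized over its arguments.
#' @export
dbetabinom_log <- function(y, n, p, c) {
  a <- p * c
  b <- (1 - p) * c
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

rbetabinom <- function(nobs, size, p, c) {
  pr <- stats::rbeta(nobs, p * c, (1 - p) * c)
  stats::rbinom(nobs, size, pr)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

## Derive a bounded child seed for a pipeline stage from a master seed.
## Documented counter scheme: child = (master * 101 + index) mod (2^31 - 1).
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 101 + index) %% (2^31 - 1))
}
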