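#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Percentile by linear interpolation between order statistics
#'
#' Thin wrapper over [stats::quantile()] type 7 used everywhere a percentile
#' threshold is needed, so the estimator is stated once: sort the values and
#' linearly interpolate between adjacent order statistics.
#'
#' @param x numeric values.
#' @param percentile percentile in (0, 100].
#' @return the percentile as a single number.
#' @export
percentile <- function(x, percentile) {
  stopifnot(is.numeric(x), length(x) > 0L, percentile > 0, percentile <= 100)
  stats::quantile(x, percentile / 100, type = 7, names = FALSE)
}

#' Wilcoxon rank-sum z statistic
#'
#' Standardized rank-sum statistic (normal approximation, tie correction by
#' midranks) for the second sample versus the first: positive z means `y`
#' tends to be larger than `x`.
#'
#' @param x,y numeric samples.
#' @return list with `z`, the rank sum `w` of `y`, and the null mean/sd.
#' @export
rank_sum_z <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))               # midranks
  w <- sum(r[(n1 + 1L):n])
  mu <- n2 * (n + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_corr)
  sigma <- sqrt(sigma2)
  z <- if (sigma > 0) (w - mu) / sigma else 0
  list(z = z, w = w, mu = mu, sigma = sigma)
}

#' Resource-equation minimum sample size
#'
#' Minimum number of subjects for a repeated-sessions design by the resource
#' equation: `ceiling(10 / (sessions - 1) + 1)`.
#'
#' @param sessions number of sessions per subject (> 1).
#' @return integer minimum number of subjects.
#' @export
resource_equation_n <- function(sessions) {
  stopifnot(is.numeric(sessions), length(sessions) == 1L, sessions > 1)
  as.integer(ceiling(10 / (sessions - 1) + 1))
}
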