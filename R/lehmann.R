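#' Supremum distance between F0^theta and F0
#'
#' For a Lehmann alternative \eqn{F = F_0^\theta} the maximal vertical
#' distance from the model does not depend on \eqn{F_0}:
#' \deqn{\|F_0^\theta - F_0\| = |\theta^{1/(1-\theta)} -
#'       \theta^{\theta/(1-\theta)}|.}
#' The apparent singularity at \eqn{\theta = 1} is removable (the distance
#' is 0 there); for \eqn{|\theta - 1| < 10^{-8}} the first-order expansion
#' \eqn{e^{-1}|\theta - 1|} is used.
#'
#' @param theta positive numeric (vectorized), the Lehmann parameter.
#' @return The sup-distance, in \[0, 1).
#' @examples
#' sup_distance(2)       # 0.25
#' sup_distance(1)       # 0
#' @export
sup_distance <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta <= 0))
    stop("'theta' must be positive and finite", call. = FALSE)
  out <- numeric(length(theta))
  near <- abs(theta - 1) < 1e-8
  out[near] <- exp(-1) * abs(theta[near] - 1)
  th <- theta[!near]
  if (length(th)) {
    l <- log(th)
    out[!near] <- abs(exp(l / (1 - th)) - exp(th * l / (1 - th)))
  }
  out
}

#' Sample from a Lehmann alternative
#'
#' Draws `n` i.i.d. observations with cdf \eqn{F_0^\theta} by the
#' probability-integral transform: if \eqn{U \sim U(0,1)} then
#' \eqn{F_0^{-1}(U^{1/\theta})} has cdf \eqn{F_0^\theta}. Uniform draws that
#' hit 0 or 1 exactly (possible at machine level) are rejected and redrawn so
#' that every observation lies strictly inside the support.
#'
#' @param n sample size.
#' @param model a [gof_model()].
#' @param theta positive Lehmann parameter; `theta = 1` samples from the
#'   model itself.
#' @param seed optional integer; if given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
rlehmann <- function(n, model, theta = 1, seed = NULL) {
  stopifnot(inherits(model, "gof_model"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("'theta' must be a positive number", call. = FALSE)
  n <- as.integer(n)
  runner <- function() {
    u <- stats::runif(n)
    bad <- u <= 0 | u >= 1
    while (any(bad)) {
      u[bad] <- stats::runif(sum(bad))
      bad <- u <= 0 | u >= 1
    }
    model$quantile(u^(1 / theta))
  }
  if (is.null(seed)) return(runner())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runner()
}

#' Maximum likelihood estimator of the Lehmann parameter
#'
#' \deqn{\hat\theta_n(F_0) = -n / \sum_{i=1}^n \log F_0(X_i).}
#' This is both the ML estimator of \eqn{\theta} in the Lehmann family
#' \eqn{F_0^\theta} and (a monotone transform of) the sufficient statistic,
#' so the exact test is based on it. Observations with \eqn{F_0(x) \in
#' \{0, 1\}} make the statistic degenerate; they raise an error naming the
#' offending index rather than being silently clamped, since clamping would
#' destroy the exactness of the procedure (the usual remedy is a mismatched
#' data/model pairing).
#'
#' @param x numeric sample.
#' @param model a [gof_model()].
#' @return The estimate \eqn{\hat\theta_n > 0}.
#' @examples
#' theta_mle(0, gof_model("normal"))  # single median observation: 1/log(2)
#' @export
theta_mle <- function(x, model) {
  stopifnot(inherits(model, "gof_model"))
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x)))
    stop("'x' must be a non-empty finite numeric sample", call. = FALSE)
  u <- model$cdf(x)
  bad <- which(u <= 0 | u >= 1)
  if (length(bad))
    stop("observation(s) at index ", paste(bad, collapse = ", "),
         " fall on or outside the support of the model (F0(x) is 0 or 1); ",
         "check that the data match the hypothesized distribution",
         call. = FALSE)
  -length(x) / sum(log(u))
}

#' Exact cdf of the Lehmann parameter estimator
#'
#' Under \eqn{F = F_0^\theta}, \eqn{-2\theta\sum\log F_0(X_i) \sim
#' \chi^2_{2n}} regardless of \eqn{F_0}, so the estimator
#' \eqn{\hat\theta_n} has exact cdf
#' \deqn{t \mapsto 1 - F_{\chi^2_{2n}}(2\theta n / t), \quad t > 0,}
#' the basis of the exact test, its power function and the critical
#' constants.
#'
#' @param t evaluation points (vectorized); non-positive values give 0.
#' @param theta positive true Lehmann parameter.
#' @param n sample size.
#' @return Probabilities \eqn{P_\theta[\hat\theta_n \le t]}.
#' @export
theta_mle_cdf <- function(t, theta, n) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("'theta' must be a positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  out[pos] <- 1 - stats::pchisq(2 * theta * n / t[pos], df = 2 * n)
  out[is.infinite(t) & t > 0] <- 1
  out
}
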