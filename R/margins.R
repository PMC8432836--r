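#' Convert a Lehmann margin to a Kolmogorov-distance margin
#'
#' Under the Lehmann alternative \eqn{F = F_0^\theta}, the supremum distance
#' \eqn{\|F - F_0\|} attained at the boundary \eqn{\theta = 1+\varepsilon} of
#' the multiplicative equivalence interval \eqn{(1/(1+\varepsilon),
#' 1+\varepsilon)} is
#' \deqn{\delta = (1+\varepsilon)^{-1/\varepsilon} -
#'       (1+\varepsilon)^{-(1+\varepsilon)/\varepsilon}.}
#' This function evaluates that map; [epsilon_from_delta()] inverts it.
#' Powers are computed as `exp(-a * log1p(epsilon))` for numerical stability
#' at extreme margins.
#'
#' @param epsilon positive numeric (vectorized), the Lehmann margin.
#' @return The corresponding maximal sup-distance, in (0, 1).
#' @examples
#' delta_from_epsilon(1)       # exactly 0.25
#' delta_from_epsilon(0.5077)  # 0.15 to printed precision
#' @seealso [epsilon_from_delta()], [equivalence_margin()], [sup_distance()]
#' @export
delta_from_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("'epsilon' must be positive and finite", call. = FALSE)
  l <- log1p(epsilon)
  exp(-l / epsilon) - exp(-(1 + epsilon) / epsilon * l)
}

#' Convert a Kolmogorov-distance margin to a Lehmann margin
#'
#' Solves \eqn{(1+\varepsilon)^{-1/\varepsilon} -
#' (1+\varepsilon)^{-(1+\varepsilon)/\varepsilon} = \delta} for
#' \eqn{\varepsilon}. The left-hand side is strictly increasing in
#' \eqn{\varepsilon}, so the root is unique; it is found by bracketed search
#' (upper bracket doubled until it encloses the root) followed by
#' [stats::uniroot()] at tolerance `1e-14`, ensuring the round trip through
#' [delta_from_epsilon()] holds to about 1e-12.
#'
#' @param delta numeric in (0, 1) (vectorized), the sup-distance margin.
#' @return The corresponding Lehmann margin \eqn{\varepsilon > 0}.
#' @examples
#' epsilon_from_delta(0.15)  # 0.5077
#' epsilon_from_delta(0.25)  # exactly 1
#' @export
epsilon_from_delta <- function(delta) {
  if (!is.numeric(delta) || any(!is.finite(delta)) ||
      any(delta <= 0) || any(delta >= 1))
    stop("'delta' must lie strictly between 0 and 1", call. = FALSE)
  vapply(delta, function(d) {
    hi <- 1
    while (delta_from_epsilon(hi) < d) hi <- hi * 2
    stats::uniroot(function(e) delta_from_epsilon(e) - d,
                   lower = 1e-12, upper = hi, tol = 1e-14)$root
  }, numeric(1))
}

#' Paired equivalence margins
#'
#' Builds the margin pair \eqn{(\delta, \varepsilon)} from either component,
#' deriving the other through the one-to-one correspondence of
#' [delta_from_epsilon()]. `log_upper = log(1 + epsilon)` is the right-hand
#' equivalence limit for \eqn{\log\theta}, the scale on which the Lehmann
#' parameter is usually reported in proportional-hazards work.
#'
#' @param delta,epsilon exactly one must be supplied.
#' @return An object of class `eqgof_margin`: list with `delta`, `epsilon`,
#'   `log_upper`.
#' @examples
#' equivalence_margin(delta = 0.15)
#' @export
equivalence_margin <- function(delta = NULL, epsilon = NULL) {
  if (is.null(delta) == is.null(epsilon))
    stop("supply exactly one of 'delta' or 'epsilon'", call. = FALSE)
  if (is.null(delta)) {
    delta <- delta_from_epsilon(epsilon)
  } else {
    epsilon <- epsilon_from_delta(delta)
  }
  structure(list(delta = delta, epsilon = epsilon,
                 log_upper = log1p(epsilon)),
            class = "eqgof_margin")
}

#' @export
print.eqgof_margin <- function(x, ...) {
  cat("Equivalence margins for goodness-of-fit\n")
  cat(sprintf("  delta (max ||F - F0||)    : %.4f\n", x$delta))
  cat(sprintf("  epsilon (Lehmann margin)  : %.4f\n", x$epsilon))
  cat(sprintf("  log(1 + epsilon)          : %.4f\n", x$log_upper))
  cat(sprintf("  theta equivalence interval: (%.4f, %.4f)\n",
              1 / (1 + x$epsilon), 1 + x$epsilon))
  invisible(x)
}
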