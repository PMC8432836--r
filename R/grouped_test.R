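#' Equal-probability partition of the model support
#'
#' Cuts the real line at the \eqn{F_0}-quantiles \eqn{j/k}, \eqn{j = 1,
#' \dots, k-1}, so each of the `k` classes carries mass \eqn{1/k} under the
#' model — the classical recommendation for grouped goodness-of-fit work.
#' Classes are left-open/right-closed, \eqn{(b_{j-1}, b_j]}.
#'
#' @param model a [gof_model()].
#' @param k number of classes (>= 2).
#' @return Object of class `grouped_partition`: list with `k`, `boundaries`
#'   (the k-1 interior cut points), `pi0` (the target vector, all `1/k`) and
#'   `model_name`.
#' @examples
#' equal_prob_partition(gof_model("normal"), 5)
#' @export
equal_prob_partition <- function(model, k) {
  stopifnot(inherits(model, "gof_model"))
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k))
    stop("'k' must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  b <- model$quantile(seq_len(k - 1) / k)
  structure(list(k = k, boundaries = b, pi0 = rep(1 / k, k),
                 model_name = model$name),
            class = "grouped_partition")
}

#' @export
print.grouped_partition <- function(x, ...) {
  cat(sprintf("Equal-probability partition (%s model, k = %d classes)\n",
              x$model_name, x$k))
  cat("  interior boundaries:", paste(sprintf("%.4f", x$boundaries),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Class masses under a Lehmann alternative
#'
#' Probability of each partition class under \eqn{F = F_0^\theta}:
#' \eqn{\pi_j(\theta) = F_0(b_j)^\theta - F_0(b_{j-1})^\theta} with
#' \eqn{b_0 = -\infty}, \eqn{b_k = +\infty}. At \eqn{\theta = 1} this is the
#' uniform vector \eqn{(1/k, \dots, 1/k)} by construction. Because the
#' boundaries sit at fixed \eqn{F_0}-quantiles, the masses depend on
#' \eqn{F_0} only through \eqn{u_j = j/k} and are distribution-free.
#'
#' @param partition an [equal_prob_partition()].
#' @param model the [gof_model()] used to build the partition.
#' @param theta positive Lehmann parameter.
#' @return Numeric vector of `k` masses summing to 1.
#' @export
class_masses <- function(partition, model, theta) {
  stopifnot(inherits(partition, "grouped_partition"),
            inherits(model, "gof_model"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("'theta' must be a positive number", call. = FALSE)
  u <- c(0, model$cdf(partition$boundaries), 1)
  diff(u^theta)
}

#' Grouped-data equivalence margin
#'
#' The Euclidean distance between the class-mass vector induced by the
#' boundary alternative \eqn{\theta = 1+\varepsilon} and the target vector
#' \eqn{\pi^\circ = (1/k, \dots, 1/k)}:
#' \deqn{\varepsilon_* = \| \pi^{(1+\varepsilon)} - \pi^\circ \|_2.}
#' This is the margin at which the multinomial equivalence test matches the
#' continuous-data problem with Lehmann margin \eqn{\varepsilon}. Like the
#' masses themselves it is distribution-free.
#'
#' @param partition an [equal_prob_partition()].
#' @param model the matching [gof_model()].
#' @param epsilon positive Lehmann margin.
#' @return The grouped margin \eqn{\varepsilon_* > 0}.
#' @examples
#' m <- gof_model("normal")
#' grouped_margin(equal_prob_partition(m, 5), m, 0.5077)  # 0.1548
#' @export
grouped_margin <- function(partition, model, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("'epsilon' must be a positive number", call. = FALSE)
  pm <- class_masses(partition, model, 1 + epsilon)
  sqrt(sum((pm - partition$pi0)^2))
}

# Core decision arithmetic, vectorized over columns of a k x m count matrix.
# v_n^2 is computed in the moment form
#   4 * [ sum_j a_j^2 pihat_j - (sum_j a_j pihat_j)^2 ],  a_j = pihat_j - pi0_j,
# which is algebraically identical to the published double-sum expression
# after multiplying through, but never divides by a zero class frequency.
grouped_decide <- function(counts, pi0, eps_star, alpha) {
  counts <- as.matrix(counts)
  n <- colSums(counts)
  pihat <- sweep(counts, 2, n, "/")
  a <- pihat - pi0
  d2 <- colSums(a^2)
  vn2 <- 4 * (colSums(a^2 * pihat) - colSums(a * pihat)^2)
  vn2 <- pmax(vn2, 0)
  degenerate <- vn2 < 1e-14
  bound <- eps_star^2 - stats::qnorm(1 - alpha) * sqrt(vn2) / sqrt(n)
  # Degenerate variance (e.g. pihat exactly on target): the asymptotic bound
  # collapses to comparing d^2 with eps*^2; honored only from n >= 30, below
  # which the large-sample argument backing the rule has no force.
  reject <- ifelse(degenerate, d2 < eps_star^2 & n >= 30, d2 < bound)
  list(n = n, pihat = pihat, d2 = d2, vn2 = vn2, bound = bound,
       reject = reject, degenerate = degenerate)
}

#' Grouped multinomial equivalence goodness-of-fit test
#'
#' Asymptotic test of \eqn{H_*: d(\pi, \pi^\circ) \ge \varepsilon_*} against
#' \eqn{K_*: d(\pi, \pi^\circ) < \varepsilon_*} for the class-probability
#' vector \eqn{\pi} of grouped observations, where \eqn{d} is Euclidean
#' distance. The decision rule rejects \eqn{H_*} (establishing fit of the
#' grouped model) when
#' \deqn{d^2(\hat\pi, \pi^\circ) < \varepsilon_*^2 - z_{1-\alpha}
#'       v_n(\hat\pi, \pi^\circ) / \sqrt{n},}
#' with \eqn{v_n^2 = 4[\sum_j \hat\pi_j a_j^2 - (\sum_j \hat\pi_j a_j)^2]},
#' \eqn{a_j = \hat\pi_j - \pi^\circ_j}, and \eqn{z_{1-\alpha}} the standard
#' normal quantile. When the variance estimate degenerates to zero (e.g.
#' \eqn{\hat\pi = \pi^\circ} exactly) the rule reduces to comparing
#' \eqn{d^2} with \eqn{\varepsilon_*^2}, applied only for \eqn{n \ge 30}
#' (the rule is asymptotic); such results carry a `degenerate` flag.
#'
#' Either raw observations `x` (grouped internally over the partition) or
#' pre-tabulated `counts` may be supplied. The margin is given directly as
#' `eps_star`, or derived from a continuous-data Lehmann margin `epsilon`
#' via [grouped_margin()].
#'
#' @param counts vector of `k` class counts, or `NULL`.
#' @param x raw numeric sample, grouped over `(b_{j-1}, b_j]`, or `NULL`.
#' @param partition an [equal_prob_partition()].
#' @param model the matching [gof_model()] (required with `x` or `epsilon`).
#' @param alpha level, in (0, 0.5).
#' @param epsilon,eps_star the margin: supply exactly one.
#' @return Object of class `grouped_gof_test` with `counts`, `pi_hat`, `d2`,
#'   `vn2`, `bound`, `reject`, `degenerate`, `n`, `k`, `alpha`, `eps_star`.
#' @export
grouped_gof_test <- function(counts = NULL, x = NULL, partition, model = NULL,
                             alpha = 0.05, epsilon = NULL, eps_star = NULL) {
  stopifnot(inherits(partition, "grouped_partition"))
  check_alpha(alpha)
  if (is.null(counts) == is.null(x))
    stop("supply exactly one of 'counts' or 'x'", call. = FALSE)
  if (is.null(epsilon) == is.null(eps_star))
    stop("supply exactly one of 'epsilon' or 'eps_star'", call. = FALSE)
  if (is.null(eps_star)) {
    if (is.null(model))
      stop("'model' is needed to derive eps_star from epsilon", call. = FALSE)
    eps_star <- grouped_margin(partition, model, epsilon)
  }
  if (is.null(counts)) {
    breaks <- c(-Inf, partition$boundaries, Inf)
    counts <- as.integer(table(cut(x, breaks, right = TRUE)))
  }
  if (length(counts) != partition$k || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be ", partition$k, " nonnegative integers",
         call. = FALSE)
  if (sum(counts) < 1) stop("empty sample", call. = FALSE)
  d <- grouped_decide(matrix(counts, ncol = 1), partition$pi0, eps_star,
                      alpha)
  structure(list(counts = as.integer(counts), pi_hat = drop(d$pihat),
                 d2 = d$d2, vn2 = d$vn2, bound = d$bound,
                 reject = as.logical(d$reject),
                 degenerate = as.logical(d$degenerate),
                 n = d$n, k = partition$k, alpha = alpha,
                 eps_star = eps_star),
            class = "grouped_gof_test")
}

#' @export
print.grouped_gof_test <- function(x, ...) {
  cat("Grouped multinomial equivalence goodness-of-fit test\n")
  cat(sprintf("  k = %d classes, n = %d, alpha = %g, eps* = %.4f\n",
              x$k, x$n, x$alpha, x$eps_star))
  cat("  counts:", paste(x$counts, collapse = ", "), "\n")
  cat(sprintf("  d^2(pi_hat, pi0) = %.6f, v_n^2 = %.6f, bound = %.6f\n",
              x$d2, x$vn2, x$bound))
  if (x$degenerate)
    cat("  note: variance estimate degenerate; rule reduced to d^2 < eps*^2\n")
  cat("  decision:",
      if (x$reject)
        "REJECT lack-of-fit null => goodness-of-fit ESTABLISHED\n"
      else
        "do not reject => goodness-of-fit NOT established\n")
  invisible(x)
}

# All compositions of n into k nonnegative parts, as a matrix with
# choose(n+k-1, k-1) rows.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  parts <- lapply(0:n, function(j)
    cbind(j, compositions(n - j, k - 1L), deparse.level = 0))
  do.call(rbind, parts)
}

#' Power of the grouped equivalence test
#'
#' Rejection probability of [grouped_gof_test()] when the true class
#' probabilities are `pi_true`. The exact mode enumerates all
#' \eqn{\binom{n+k-1}{k-1}} count vectors (chunked over the first class to
#' bound memory), evaluates the rejection rule on each through the same
#' internal decision function the test itself uses, and sums multinomial
#' probabilities; it is guarded to at most 2e7 compositions. The Monte Carlo
#' mode simulates count vectors with [stats::rmultinom()].
#'
#' @param n sample size.
#' @param pi_true probability vector of length `k` (the truth).
#' @param eps_star grouped equivalence margin.
#' @param alpha level, in (0, 0.5).
#' @param mode `"exact"`, `"montecarlo"`, or `"auto"` (exact when the
#'   enumeration is at most 2e5 compositions).
#' @param reps Monte Carlo replicates.
#' @param seed optional seed for the Monte Carlo mode.
#' @return Rejection probability. In exact mode the total enumerated
#'   probability mass (which must be 1) is attached as attribute
#'   `"total_mass"`.
#' @export
grouped_power <- function(n, pi_true, eps_star, alpha = 0.05,
                          mode = c("auto", "exact", "montecarlo"),
                          reps = 1e4, seed = NULL) {
  mode <- match.arg(mode)
  check_alpha(alpha)
  k <- length(pi_true)
  if (k < 2 || any(pi_true < 0) || abs(sum(pi_true) - 1) > 1e-10)
    stop("'pi_true' must be a probability vector of length >= 2",
         call. = FALSE)
  pi0 <- rep(1 / k, k)
  n_comp <- choose(n + k - 1, k - 1)
  if (mode == "auto") mode <- if (n_comp <= 2e5) "exact" else "montecarlo"
  if (mode == "exact") {
    if (n_comp > 2e7)
      stop("exact enumeration would need ", format(n_comp),
           " compositions; use mode = 'montecarlo'", call. = FALSE)
    lgn <- lgamma(n + 1)
    logp <- log(ifelse(pi_true > 0, pi_true, 1))  # guarded; zero classes below
    power <- 0
    total <- 0
    for (j in 0:n) {
      rest <- compositions(n - j, k - 1L)
      cnt <- cbind(j, rest, deparse.level = 0)
      # multinomial log-pmf; classes with pi = 0 contribute -Inf unless count 0
      lp <- lgn - rowSums(lgamma(cnt + 1)) +
        as.vector(cnt %*% logp)
      zero_cl <- which(pi_true == 0)
      if (length(zero_cl))
        lp[rowSums(cnt[, zero_cl, drop = FALSE]) > 0] <- -Inf
      p <- exp(lp)
      dec <- grouped_decide(t(cnt), pi0, eps_star, alpha)
      power <- power + sum(p[dec$reject])
      total <- total + sum(p)
    }
    return(structure(power, total_mass = total))
  }
  # Monte Carlo
  runner <- function() {
    got <- 0
    chunk <- 5e4
    left <- reps
    while (left > 0) {
      m <- min(chunk, left)
      cnt <- stats::rmultinom(m, n, pi_true)
      got <- got + sum(grouped_decide(cnt, pi0, eps_star, alpha)$reject)
      left <- left - m
    }
    got / reps
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
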