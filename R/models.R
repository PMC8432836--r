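#' Hypothesized distribution models
#'
#' A `gof_model` bundles everything the goodness-of-fit machinery needs to
#' know about the hypothesized continuous distribution \eqn{F_0}: cdf,
#' quantile function, density, log-density, log-cdf, the log-density
#' derivative \eqn{f_0'/f_0} (used by the score test), and the support
#' interval. A small catalogue of standard models is built in; arbitrary
#' continuous models can be supplied through [gof_model_custom()].
#'
#' For the location-scale score test the model must be the *standard* member
#' of its family (e.g. the standard normal for testing normality); location
#' and scale are handled by the test itself.
#'
#' @param name one of `"normal"`, `"exponential"`, `"uniform"`, `"logistic"`.
#' @param mean,sd normal parameters (defaults 0, 1).
#' @param rate exponential rate (default 1).
#' @param min,max uniform endpoints (defaults 0, 1).
#' @param location,scale logistic parameters (defaults 0, 1).
#'
#' @return An object of class `gof_model`: a list with components `name`,
#'   `cdf`, `quantile`, `density`, `log_density`, `log_cdf`, `dlog_density`,
#'   `support` (length-2 numeric, possibly infinite) and `params`.
#' @examples
#' m <- gof_model("normal")
#' m$cdf(0)          # 0.5
#' m$quantile(0.975) # 1.96
#' @export
gof_model <- function(name = c("normal", "exponential", "uniform", "logistic"),
                      mean = 0, sd = 1, rate = 1, min = 0, max = 1,
                      location = 0, scale = 1) {
  name <- match.arg(name)
  m <- switch(name,
    normal = {
      stopifnot(sd > 0)
      new_gof_model(
        name = "normal",
        cdf = function(x) stats::pnorm(x, mean, sd),
        quantile = function(p) stats::qnorm(p, mean, sd),
        density = function(x) stats::dnorm(x, mean, sd),
        log_density = function(x) stats::dnorm(x, mean, sd, log = TRUE),
        log_cdf = function(x) stats::pnorm(x, mean, sd, log.p = TRUE),
        dlog_density = function(x) -(x - mean) / sd^2,
        support = c(-Inf, Inf),
        params = c(mean = mean, sd = sd)
      )
    },
    exponential = {
      stopifnot(rate > 0)
      new_gof_model(
        name = "exponential",
        cdf = function(x) stats::pexp(x, rate),
        quantile = function(p) stats::qexp(p, rate),
        density = function(x) stats::dexp(x, rate),
        log_density = function(x) stats::dexp(x, rate, log = TRUE),
        log_cdf = function(x) stats::pexp(x, rate, log.p = TRUE),
        dlog_density = function(x) rep(-rate, length(x)),
        support = c(0, Inf),
        params = c(rate = rate)
      )
    },
    uniform = {
      stopifnot(max > min)
      new_gof_model(
        name = "uniform",
        cdf = function(x) stats::punif(x, min, max),
        quantile = function(p) stats::qunif(p, min, max),
        density = function(x) stats::dunif(x, min, max),
        log_density = function(x) stats::dunif(x, min, max, log = TRUE),
        log_cdf = function(x) stats::punif(x, min, max, log.p = TRUE),
        dlog_density = function(x) rep(0, length(x)),
        support = c(min, max),
        params = c(min = min, max = max)
      )
    },
    logistic = {
      stopifnot(scale > 0)
      new_gof_model(
        name = "logistic",
        cdf = function(x) stats::plogis(x, location, scale),
        quantile = function(p) stats::qlogis(p, location, scale),
        density = function(x) stats::dlogis(x, location, scale),
        log_density = function(x) stats::dlogis(x, location, scale, log = TRUE),
        log_cdf = function(x) stats::plogis(x, location, scale, log.p = TRUE),
        # d/dx log f = -tanh(z/2)/scale with z = (x - location)/scale
        dlog_density = function(x) {
          z <- (x - location) / scale
          -tanh(z / 2) / scale
        },
        support = c(-Inf, Inf),
        params = c(location = location, scale = scale)
      )
    }
  )
  m
}

#' User-supplied distribution model
#'
#' Wraps arbitrary cdf/quantile/density callables as a [gof_model()].
#' Missing auxiliary functions are derived numerically: `log_density` and
#' `log_cdf` as logs of the primitives, `dlog_density` by central
#' differences of `log_density`.
#'
#' @param cdf,quantile,density vectorized functions defining the model.
#' @param log_density,log_cdf,dlog_density optional analytic versions.
#' @param support numeric length 2, the open support interval.
#' @param name identifier used in printed reports.
#' @return A `gof_model` object.
#' @export
gof_model_custom <- function(cdf, quantile, density, support,
                             log_density = NULL, log_cdf = NULL,
                             dlog_density = NULL, name = "custom") {
  stopifnot(is.function(cdf), is.function(quantile), is.function(density),
            length(support) == 2, support[1] < support[2])
  if (is.null(log_density)) log_density <- function(x) log(density(x))
  if (is.null(log_cdf)) log_cdf <- function(x) log(cdf(x))
  if (is.null(dlog_density)) {
    dlog_density <- function(x) {
      h <- 1e-6 * pmax(1, abs(x))
      (log_density(x + h) - log_density(x - h)) / (2 * h)
    }
  }
  new_gof_model(name = name, cdf = cdf, quantile = quantile, density = density,
                log_density = log_density, log_cdf = log_cdf,
                dlog_density = dlog_density, support = as.numeric(support),
                params = NULL)
}

new_gof_model <- function(name, cdf, quantile, density, log_density, log_cdf,
                          dlog_density, support, params) {
  structure(
    list(name = name, cdf = cdf, quantile = quantile, density = density,
         log_density = log_density, log_cdf = log_cdf,
         dlog_density = dlog_density, support = support, params = params),
    class = "gof_model"
  )
}

#' @export
print.gof_model <- function(x, ...) {
  cat("Hypothesized model F0:", x$name, "\n")
  if (length(x$params))
    cat("  parameters:", paste(names(x$params), signif(x$params, 6),
                               sep = " = ", collapse = ", "), "\n")
  cat("  support: (", x$support[1], ", ", x$support[2], ")\n", sep = "")
  invisible(x)
}

# Consistency checks used by tests and by gof_model_custom users; not run in
# constructors to keep them cheap.
validate_gof_model <- function(model, tol = 1e-9) {
  u <- seq(0.01, 0.99, by = 0.01)
  err <- max(abs(model$cdf(model$quantile(u)) - u))
  if (err > tol)
    stop("cdf(quantile(u)) differs from u by ", format(err), call. = FALSE)
  lo <- model$quantile(1e-10); hi <- model$quantile(1 - 1e-10)
  mass <- stats::integrate(model$density, lo, hi, rel.tol = 1e-9)$value
  if (abs(mass - 1) > 1e-6)
    stop("density does not integrate to 1 (got ", format(mass), ")",
         call. = FALSE)
  invisible(TRUE)
}
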