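test_that("log-likelihood reduces and shifts as theory demands", {
  set.seed(111)
  x <- rnorm(30, 1, 2)
  # theta = 1: plain location-scale log-likelihood
  expect_equal(ls_loglik(x, 1, 0.5, 1.5, norm_model),
               sum(dnorm(x, 0.5, 1.5, log = TRUE)), tolerance = 1e-12)
  # location equivariance
  expect_equal(ls_loglik(x + 3, 1.3, 0.5 + 3, 1.5, norm_model),
               ls_loglik(x, 1.3, 0.5, 1.5, norm_model), tolerance = 1e-10)
})

test_that("analytic scores match finite differences of the log-likelihood", {
  set.seed(112)
  for (model in list(norm_model, gof_model("logistic"))) {
    x <- model$quantile(runif(25, 0.05, 0.95))
    for (theta in c(0.6633, 1, 1.5077)) {
      mu <- 0.2; sigma <- 1.1
      s <- ls_scores(x, theta, mu, sigma, model)
      h <- 1e-6
      fd <- c(
        (ls_loglik(x, theta + h, mu, sigma, model) -
           ls_loglik(x, theta - h, mu, sigma, model)) / (2 * h),
        (ls_loglik(x, theta, mu + h, sigma, model) -
           ls_loglik(x, theta, mu - h, sigma, model)) / (2 * h),
        (ls_loglik(x, theta, mu, sigma + h, model) -
           ls_loglik(x, theta, mu, sigma - h, model)) / (2 * h))
      expect_equal(unname(s), fd, tolerance = 1e-6)
    }
  }
  # the theta score is exactly n/theta + sum log F0(z)
  x <- rnorm(10)
  s <- ls_scores(x, 1.4, 0, 1, norm_model)
  expect_equal(unname(s["theta"]),
               10 / 1.4 + sum(pnorm(x, log.p = TRUE)), tolerance = 1e-12)
})

test_that("score vector has mean zero at the truth", {
  set.seed(113)
  theta <- 1.2; n <- 50; reps <- 2000
  S <- vapply(seq_len(reps), function(i) {
    x <- rlehmann(n, norm_model, theta)
    ls_scores(x, theta, 0, 1, norm_model)
  }, numeric(3))
  m <- rowMeans(S)
  se <- apply(S, 1, sd) / sqrt(reps)
  expect_true(all(abs(m) < 3 * se))
})

test_that("restricted fits solve the nuisance score equations", {
  set.seed(114)
  x <- rnorm(80, 0.4, 1.3)
  # theta = 1 in the normal family: closed-form Gaussian MLE
  f1 <- restricted_mle(x, 1, norm_model)
  expect_equal(f1$mu, mean(x), tolerance = 1e-10)
  expect_equal(f1$sigma, sd(x) * sqrt(79 / 80), tolerance = 1e-10)
  # boundary thetas: nuisance scores vanish at the solution
  for (th in c(1 / 1.5077, 1.5077)) {
    f <- restricted_mle(x, th, norm_model)
    s <- ls_scores(x, th, f$mu, f$sigma, norm_model)
    expect_lt(max(abs(s[c("mu", "sigma")])), 1e-8 * 80)
    expect_equal(f$score_theta, unname(s["theta"]))
    # it is a maximum over the nuisance parameters
    expect_gt(f$loglik, ls_loglik(x, th, f$mu + 0.05, f$sigma, norm_model))
    expect_gt(f$loglik, ls_loglik(x, th, f$mu, f$sigma * 1.05, norm_model))
  }
  expect_error(restricted_mle(c(1, 2), 1, norm_model), "at least 3")
})

test_that("expected information recovers Gaussian closed forms at theta 1", {
  V <- expected_information(1, 0, 1, norm_model)
  expect_equal(V["mu", "mu"], 1, tolerance = 1e-9)
  expect_equal(V["sigma", "sigma"], 2, tolerance = 1e-9)
  expect_equal(V["mu", "sigma"], 0, tolerance = 1e-9)
  expect_lt(attr(V, "self_check"), 1e-10)
  # sigma enters as the exact diagonal scaling
  V3 <- expected_information(1.4, 0, 3, norm_model)
  V1 <- expected_information(1.4, 0, 1, norm_model)
  S <- diag(c(1, 1 / 3, 1 / 3))
  expect_equal(unclass(V3), unclass(S %*% V1 %*% S), tolerance = 1e-12,
               ignore_attr = TRUE)
  # mu does not enter at all
  V_mu <- expected_information(1.4, 5, 1, norm_model)
  expect_equal(unclass(V_mu), unclass(V1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("quadrature information matches Monte Carlo score covariance", {
  set.seed(115)
  N <- 2e5
  for (theta in c(1 / 1.5077, 1.51)) {
    V <- expected_information(theta, 0, 1, norm_model)
    u <- runif(N)^(1 / theta)
    z <- qnorm(u)
    r <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    S <- cbind(1 / theta + pnorm(z, log.p = TRUE),
               -((theta - 1) * r - z),
               -((theta - 1) * r * z - z * z + 1))
    C <- cov(S)
    # entrywise 3-SE bands for a sample covariance
    for (i in 1:3) for (j in 1:3) {
      se <- sd(scale(S[, i], scale = FALSE) *
                 scale(S[, j], scale = FALSE)) / sqrt(N)
      expect_lt(abs(C[i, j] - V[i, j]), 3 * se)
    }
  }
})

test_that("TOST score test is equivariant and monotone in the margin", {
  x <- rlehmann(120, norm_model, 1, seed = 116)
  t0 <- score_gof_test(x, norm_model, epsilon = 0.5077)
  # affine transformation of the data leaves the standardized test invariant
  t1 <- score_gof_test(3 + 2 * x, norm_model, epsilon = 0.5077)
  expect_equal(t1$fit_lower$mu, 3 + 2 * t0$fit_lower$mu, tolerance = 1e-6)
  expect_equal(t1$fit_lower$sigma, 2 * t0$fit_lower$sigma, tolerance = 1e-6)
  expect_equal(t1$U_lower, t0$U_lower, tolerance = 1e-6)
  expect_equal(t1$z_lower, t0$z_lower, tolerance = 1e-6)
  expect_equal(t1$z_upper, t0$z_upper, tolerance = 1e-6)
  expect_equal(t1$v2_lower, t0$v2_lower, tolerance = 1e-10)
  # rejection is monotone in epsilon on the same data
  eps_grid <- c(0.3, 0.5077, 0.9, 1.5, 2.5)
  rej <- vapply(eps_grid, function(e)
    score_gof_test(x, norm_model, epsilon = e)$reject, logical(1))
  expect_true(all(diff(as.integer(rej)) >= 0))
  # decision structure: combined rejection is the conjunction
  expect_equal(t0$reject, t0$reject_lower && t0$reject_upper)
  expect_error(score_gof_test(x[1:5], norm_model, epsilon = 0.5),
               "n >= 10")
  expect_warning(score_gof_test(x[1:30], norm_model, epsilon = 0.5077),
                 "n < 50")
})
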