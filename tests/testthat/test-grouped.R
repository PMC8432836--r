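test_that("equal-probability partitions sit at the model quantiles", {
  p5 <- equal_prob_partition(norm_model, 5)
  expect_equal(round(p5$boundaries, 4), c(-0.8416, -0.2533, 0.2533, 0.8416))
  expect_equal(norm_model$cdf(p5$boundaries), (1:4) / 5, tolerance = 1e-9)
  expect_equal(p5$pi0, rep(0.2, 5))

  expect_equal(equal_prob_partition(norm_model, 2)$boundaries, 0)
  expect_equal(equal_prob_partition(unif_model, 4)$boundaries,
               c(0.25, 0.5, 0.75))
  expect_error(equal_prob_partition(norm_model, 1), "integer >= 2")
})

test_that("class masses are a valid distribution and recover the target", {
  p5 <- equal_prob_partition(norm_model, 5)
  expect_equal(class_masses(p5, norm_model, 1), rep(0.2, 5),
               tolerance = 1e-12)
  for (th in c(0.4, 1.5077, 3)) {
    pm <- class_masses(p5, norm_model, th)
    expect_true(all(pm >= 0))
    expect_equal(sum(pm), 1, tolerance = 1e-12)
  }
  # distance of the boundary-alternative masses from the uniform target
  pm <- class_masses(p5, norm_model, 1.5077)
  expect_equal(round(sqrt(sum((pm - 0.2)^2)), 4), 0.1548)
})

test_that("grouped margin is distribution-free and vanishes with epsilon", {
  p5n <- equal_prob_partition(norm_model, 5)
  p5e <- equal_prob_partition(exp_model, 5)
  for (eps in c(0.1, 0.5077, 1.5)) {
    en <- grouped_margin(p5n, norm_model, eps)
    ee <- grouped_margin(p5e, exp_model, eps)
    expect_equal(en, ee, tolerance = 1e-9)
  }
  expect_equal(round(grouped_margin(p5n, norm_model, 0.5077), 4), 0.1548)
  expect_lt(grouped_margin(p5n, norm_model, 1e-6), 1e-5)
})

test_that("the variance moment form equals the published double sum", {
  set.seed(81)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    pihat <- as.vector(rmultinom(1, 200, rep(1 / k, k))) / 200
    pi0 <- rep(1 / k, k)
    a <- pihat - pi0
    moment <- 4 * (sum(a^2 * pihat) - sum(a * pihat)^2)
    dbl <- 4 * (sum(a^2 * pihat) -
                  sum(outer(a * pihat, a * pihat)))
    expect_equal(moment, dbl, tolerance = 1e-12)
  }
})

test_that("grouped test computes the statistic and decision correctly", {
  p5 <- equal_prob_partition(norm_model, 5)
  es <- grouped_margin(p5, norm_model, 0.5077)

  # all mass in one class: d^2 by direct arithmetic, no rejection
  r <- grouped_gof_test(counts = c(100, 0, 0, 0, 0), partition = p5,
                        alpha = 0.05, eps_star = es)
  expect_equal(r$d2, (1 - 0.2)^2 + 4 * 0.2^2, tolerance = 1e-12)
  expect_false(r$reject)

  # perfect agreement with the target: degenerate variance path
  r0 <- grouped_gof_test(counts = rep(100, 5), partition = p5,
                         alpha = 0.05, eps_star = es)
  expect_true(r0$degenerate)
  expect_equal(r0$d2, 0)
  expect_true(r0$reject)
  # the same configuration below the asymptotic minimum does not reject
  r_small <- grouped_gof_test(counts = rep(1, 5), partition = p5,
                              alpha = 0.05, eps_star = es)
  expect_true(r_small$degenerate)
  expect_false(r_small$reject)

  # raw data are grouped over left-open right-closed classes
  x <- c(-2, -0.8416, -0.5, 0, 0.2533, 0.9, 2)
  rx <- grouped_gof_test(x = x, partition = p5, model = norm_model,
                         alpha = 0.05, epsilon = 0.5077)
  # -0.8416 sits just above the exact quantile -0.84162..., hence class 2
  expect_equal(rx$counts, c(1, 2, 2, 0, 2))
  expect_equal(sum(rx$counts), length(x))

  expect_error(grouped_gof_test(counts = c(1, 2), partition = p5,
                                eps_star = es), "5 nonnegative")
  expect_error(grouped_gof_test(counts = rep(10, 5), x = x, partition = p5,
                                eps_star = es), "exactly one")
})

test_that("exact power enumeration is a proper distribution and matches MC", {
  es <- 0.1548
  pe <- grouped_power(30, rep(0.2, 5), es, mode = "exact")
  expect_equal(attr(pe, "total_mass"), 1, tolerance = 1e-10)
  pm <- grouped_power(30, rep(0.2, 5), es, mode = "montecarlo",
                      reps = 4e4, seed = 91)
  se <- sqrt(pe * (1 - pe) / 4e4)
  expect_lt(abs(pm - pe), 3 * se + 1e-12)

  # a zero-mass class: exact and MC still agree
  pi_z <- c(0.4, 0.3, 0.2, 0.1, 0)
  pz <- grouped_power(25, pi_z, es, mode = "exact")
  expect_equal(attr(pz, "total_mass"), 1, tolerance = 1e-10)
  pzm <- grouped_power(25, pi_z, es, mode = "montecarlo",
                       reps = 4e4, seed = 92)
  expect_lt(abs(pzm - pz), 3 * sqrt(max(pz * (1 - pz), 1e-6) / 4e4) + 1e-3)

  # tiny samples cannot establish equivalence at these margins
  expect_equal(as.numeric(grouped_power(5, rep(0.2, 5), es, mode = "exact")),
               0, tolerance = 1e-12)

  expect_error(grouped_power(5000, rep(0.2, 5), es, mode = "exact"),
               "montecarlo")
})

test_that("grouped power grows with n and respects the boundary size", {
  es <- 0.1548
  pw <- vapply(c(50, 100, 200, 400), function(n)
    grouped_power(n, rep(0.2, 5), es, mode = "montecarlo", reps = 1e4,
                  seed = 100 + n), numeric(1))
  expect_true(all(diff(pw) > 0))

  # size at a boundary vector with d(pi, pi0) = eps*
  p5 <- equal_prob_partition(norm_model, 5)
  pi_b <- class_masses(p5, norm_model, 1.5077)
  expect_equal(sqrt(sum((pi_b - 0.2)^2)), es, tolerance = 1e-4)
  sz <- grouped_power(500, pi_b, sqrt(sum((pi_b - 0.2)^2)),
                      mode = "montecarlo", reps = 1e5, seed = 101)
  expect_lte(sz, 0.05 + 3 * sqrt(0.05 * 0.95 / 1e5))
})
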