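# Shared fixtures for the test suite. Everything is generated in code;
# the only stored file is the packaged synthetic worked-example sample.

norm_model <- gof_model("normal")
exp_model <- gof_model("exponential")
unif_model <- gof_model("uniform")

# Table of margin correspondences (printed to 4 decimals)
margin_table <- data.frame(
  delta = c(0.05, 0.075, 0.10, 0.15, 0.20, 0.25),
  epsilon = c(0.1457, 0.2266, 0.3135, 0.5077, 0.7341, 1.0000),
  log_upper = c(0.1360, 0.2042, 0.2727, 0.4106, 0.5505, 0.6931)
)

# Reference grid of exact-test constants and power at theta = 1, alpha 0.05
# (printed to 4 decimals)
constants_table <- data.frame(
  epsilon = rep(c(0.3135, 0.5077, 0.7341), each = 5),
  n = rep(c(10, 20, 50, 100, 200), 3),
  c1 = c(0.9836, 0.9830, 0.9593, 0.9047, 0.8587,
         0.9821, 0.9560, 0.8510, 0.7883, 0.7481,
         0.9629, 0.8670, 0.7400, 0.6854, 0.6504),
  c2 = c(1.0423, 1.0427, 1.0671, 1.1227, 1.1737,
         1.0767, 1.1039, 1.2125, 1.2887, 1.3473,
         1.1450, 1.2444, 1.3946, 1.4822, 1.5496),
  power = c(0.0723, 0.1043, 0.2919, 0.7183, 0.9727,
            0.1142, 0.2496, 0.7869, 0.9857, 1.0000,
            0.2118, 0.5738, 0.9743, 0.9998, 1.0000)
)

fixture_path <- function() {
  system.file("extdata", "synthetic_norm100.txt", package = "eqgof",
              mustWork = TRUE)
}

# Monte Carlo draws of the Lehmann-parameter estimator by actually sampling
# data and evaluating the statistic (the honest pipeline, not the chi-square
# shortcut the estimator's distribution theory provides).
simulate_theta_mle <- function(reps, n, theta, model) {
  vapply(seq_len(reps), function(i)
    theta_mle(rlehmann(n, model, theta), model), numeric(1))
}
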