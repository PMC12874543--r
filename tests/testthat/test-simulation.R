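test_that("the generator is seed-deterministic and honors the noiseless limit", {
  d1 <- simulate_replicates(50, 0.4, 0.1, 0.05, seed = 14)
  d2 <- simulate_replicates(50, 0.4, 0.1, 0.05, seed = 14)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # with zero error rates, every replicate equals the true status
  d0 <- simulate_replicates(200, 0.3, p = 0, q = 0, seed = 2)
  expect_equal(d0$s, d0$n * d0$t_true)
  expect_s3_class(d0, "replicate_data")
})

test_that("simulated score means match the closed-form expectation", {
  set.seed(15)
  d <- simulate_replicates(1e5, 0.4, 0.1, 0.05)
  ya <- score_average(d$n, d$s)
  se <- sd(ya) / sqrt(length(ya))
  expect_lt(abs(mean(ya) - (0.1 + 0.4 * (1 - 0.1 - 0.05))), 3 * se)
})

test_that("single-measurement fraction forces n = 1 and degrades to the base model at 0", {
  d <- simulate_replicates(100, 0.4, 0.1, 0.05, f_single = 0.3, seed = 4)
  expect_equal(sum(d$n == 1), 30)
  d2 <- simulate_replicates(100, 0.4, 0.1, 0.05, f_single = 0, seed = 4)
  expect_true(all(d2$n >= 2))
  # mean and median scores coincide for everyone when all n = 1
  d3 <- simulate_replicates(60, 0.4, 0.1, 0.05, f_single = 1, seed = 5)
  expect_equal(score_dataset(d3, "A"), score_dataset(d3, "M"),
               ignore_attr = TRUE)
})

test_that("heterogeneous error rates follow the logistic-normal map", {
  d <- simulate_replicates(500, 0.4, sigma = 1, seed = 7)
  rates <- attr(d, "rates")
  expect_true(all(rates$p > 0 & rates$p < 0.5))
  expect_true(all(rates$q > 0 & rates$q < 0.5))
  # sigma -> 0: all rates collapse to 0.5 * logistic(0) = 0.25
  d0 <- simulate_replicates(20, 0.4, sigma = 1e-8, seed = 7)
  expect_equal(attr(d0, "rates")$p, rep(0.25, 20), tolerance = 1e-6)
  # sample mean of p_i at sigma = 1 vs a large Monte-Carlo reference
  set.seed(99)
  ref <- mean(0.5 * plogis(rnorm(1e6)))
  se <- sd(rates$p) / sqrt(nrow(rates))
  expect_lt(abs(mean(rates$p) - ref), 3 * se)
})

test_that("exact bias curves are corroborated by direct simulation", {
  # median-score bias oracle: binomial tails, checked by brute simulation
  set.seed(16)
  d <- simulate_replicates(2e5, 0.35, 0.1, 0.05, n_values = 2:6)
  ym <- score_dataset(d, "M")
  se <- sd(ym) / sqrt(length(ym))
  expect_lt(abs(mean(ym) - 0.35 - bias_median(0.35, 0.1, 0.05, 2:6)), 3 * se)
  # the average bias vanishes exactly at theta = p / (p + q)
  expect_equal(bias_average(2 / 3, 0.1, 0.05), 0)
})

test_that("bias sweep tracks the closed-form average bias and orders methods", {
  sw <- suppressWarnings(
    bias_sweep(theta_grid = c(0.2, 0.4), N = 150, n_datasets = 8,
               em_args = lean_em, bayes_args = lean_bayes, seed = 2))
  expect_setequal(unique(sw$errors$method), c("A", "M", "MAP", "B"))
  for (th in c(0.2, 0.4)) {
    med_a <- sw$summary$median[sw$summary$method == "A" &
                                 sw$summary$theta_T == th]
    expect_lt(abs(med_a - bias_average(th, 0.1, 0.05)), 0.03)
  }
  expect_equal(sw$theory$bias_A, bias_average(c(0.2, 0.4), 0.1, 0.05))
})

test_that("median-score prevalence bias vanishes as replicate counts grow", {
  b <- vapply(seq(0.05, 0.95, by = 0.01), bias_median, 0,
              p = 0.1, q = 0.05, n_values = 25)
  expect_lt(max(abs(b)), 0.01)
})

test_that("single-measurement sweep favors model-based methods at high f_single", {
  # with 90% singletons all methods commit identically on the singletons,
  # so classification risks can only differ through the replicated 10%:
  # model-based methods must be no worse in risk, and are strictly
  # better on prevalence bias
  sm <- single_measurement_sweep(f_grid = 0.9, N = 150, n_datasets = 50,
                                 em_args = lean_em, bayes_args = lean_bayes,
                                 seed = 3)
  med_risk <- tapply(sm$risk, sm$method, median)
  mc_slack <- 2 * sd(sm$risk[sm$method == "A"]) / sqrt(50)
  expect_lte(med_risk["B"], med_risk["A"] + mc_slack)
  expect_lte(med_risk["MAP"], med_risk["A"] + mc_slack)
  med_bias <- tapply(abs(sm$error), sm$method, median)
  expect_lt(med_bias["B"], med_bias["A"])
  expect_lt(med_bias["MAP"], med_bias["A"])
})

test_that("heterogeneity sweep runs and reports all methods", {
  hs <- suppressWarnings(heterogeneity_sweep(sigma_grid = 0.5, N = 80, n_datasets = 3,
                            em_args = lean_em, bayes_args = lean_bayes,
                            seed = 4))
  expect_setequal(unique(hs$method), c("A", "M", "MAP", "B"))
  expect_true(all(is.finite(hs$risk)) && all(is.finite(hs$error)))
})
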