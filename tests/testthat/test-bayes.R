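test_that("prior specifications validate and defaults are as documented", {
  pr <- default_prior()
  expect_equal(unlist(pr),
               c(a_T = 0.5, b_T = 0.5, a_FP = 2, b_FP = 2, a_FN = 2,
                 b_FN = 2))
  # a deliberately misinformed prior is still a valid specification
  expect_s3_class(prior_spec(50, 50, 50, 50, 0.5, 0.5), "prior_spec")
  expect_error(prior_spec(0, 1, 1, 1, 1, 1), "positive")
})

test_that("truncated-Beta draws stay below 1/2 and match the truncated CDF", {
  set.seed(2)
  x <- rbeta_trunc_half(5000, 2, 2)
  expect_true(all(x > 0 & x < 0.5))
  # oracle: truncated CDF is F(x) / F(1/2); compare at a few quantiles
  for (q in c(0.1, 0.25, 0.4)) {
    expect_lt(abs(mean(x <= q) - pbeta(q, 2, 2) / pbeta(0.5, 2, 2)), 0.02)
  }
})

test_that("with no data the sampler recovers the prior", {
  d <- replicate_data(character(0), integer(0), integer(0))
  fit <- fit_bayes(d, prior_spec(2, 3, 2, 2, 2, 2), n_iter = 4000,
                   burn_in = 500, chains = 2, seed = 4)
  expect_lt(abs(mean(fit$draws$theta_T) - 2 / 5), 0.02)
  # prior-only credible interval matches closed-form Beta quantiles
  ci <- credible_interval(fit, "theta_T", level = 0.9)
  expect_lt(max(abs(unname(ci) - qbeta(c(0.05, 0.95), 2, 3))), 0.03)
})

test_that("the sampler is seed-deterministic and respects the truncation", {
  d <- simulate_replicates(20, 0.4, 0.1, 0.05, seed = 9)
  f1 <- suppressWarnings(
    fit_bayes(d, n_iter = 400, burn_in = 100, chains = 2, seed = 31))
  f2 <- suppressWarnings(
    fit_bayes(d, n_iter = 400, burn_in = 100, chains = 2, seed = 31))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$latent, f2$latent)
  expect_true(all(f1$draws$p < 0.5 & f1$draws$q < 0.5))
  expect_true(all(f1$latent %in% c(0L, 1L)))
})

test_that("Gibbs posterior agrees with the deterministic grid oracle", {
  d <- simulate_replicates(15, 0.4, 0.1, 0.05, seed = 3)
  g <- grid_posterior(d)
  f <- fit_bayes(d, n_iter = 4000, burn_in = 1000, chains = 2, seed = 1)
  expect_lt(max(abs(posterior_mean(f) - g$params)), 0.02)
  expect_lt(max(abs(bayes_scores(f) - g$scores)), 0.02)
})

test_that("Rao-Blackwellized and latent-frequency Bayesian scores agree", {
  d <- simulate_replicates(25, 0.3, 0.15, 0.1, seed = 6)
  f <- fit_bayes(d, n_iter = 3000, burn_in = 500, chains = 2, seed = 2)
  rb <- bayes_scores(f)
  raw <- bayes_scores(f, rao_blackwell = FALSE)
  expect_lt(max(abs(rb - raw)), 0.05)
  expect_true(all(rb >= 0 & rb <= 1))
  expect_error(bayes_scores(f, data = toy_data()), "does not match")
})

test_that("grid quadrature is converged at the default resolution", {
  d <- replicate_data(letters[1:6], c(3, 4, 5, 2, 6, 3), c(3, 1, 4, 0, 5, 2))
  # smooth prior: midpoint quadrature converges cleanly, so halving the
  # step must move nothing by more than 1e-3
  pr <- prior_spec(2, 2, 2, 2, 2, 2)
  coarse <- grid_posterior(d, pr, grid_step = 0.02)
  fine <- grid_posterior(d, pr, grid_step = 0.01)
  expect_lt(max(abs(coarse$params - fine$params)), 1e-3)
  expect_lt(max(abs(coarse$scores - fine$scores)), 1e-3)
  # the default prior has integrable endpoint singularities in theta_T;
  # convergence is slower but still well inside the sampler-comparison
  # tolerance
  c2 <- grid_posterior(d, grid_step = 0.02)
  f2 <- grid_posterior(d, grid_step = 0.01)
  expect_lt(max(abs(c2$params - f2$params)), 0.01)
  expect_error(grid_posterior(d, grid_step = 0.001), "grid too fine")
  # single positive singleton under a flat-ish prior: positive evidence
  d1 <- replicate_data("A", 1, 1)
  g1 <- grid_posterior(d1, prior_spec(1, 1, 1, 1, 1, 1))
  expect_gt(g1$scores, 0.5)
  expect_lt(g1$scores, 1)
})

test_that("credible intervals are nested and contain the posterior median", {
  d <- simulate_replicates(30, 0.4, 0.1, 0.05, seed = 12)
  f <- fit_bayes(d, n_iter = 2000, burn_in = 500, chains = 2, seed = 3)
  ci50 <- credible_interval(f, "theta_T", 0.5)
  ci90 <- credible_interval(f, "theta_T", 0.9)
  med <- median(f$draws$theta_T)
  expect_true(ci50["lower"] <= med && med <= ci50["upper"])
  expect_true(ci90["lower"] <= ci50["lower"] && ci50["upper"] <= ci90["upper"])
  short <- suppressWarnings(
    fit_bayes(d, n_iter = 60, burn_in = 10, chains = 1, seed = 1))
  expect_warning(credible_interval(short, "theta_T"), "100")
})

test_that("reordering individuals leaves per-individual scores unchanged", {
  d <- simulate_replicates(12, 0.4, 0.1, 0.05, seed = 8)
  perm <- sample(nrow(d))
  d2 <- replicate_data(d$id[perm], d$n[perm], d$s[perm])
  f1 <- fit_bayes(d, n_iter = 3000, burn_in = 500, chains = 2, seed = 5)
  f2 <- fit_bayes(d2, n_iter = 3000, burn_in = 500, chains = 2, seed = 5)
  y1 <- bayes_scores(f1)[perm]
  y2 <- bayes_scores(f2)
  expect_lt(max(abs(y1 - y2)), 0.03)
})

test_that("posterior draws export round-trips through CSV", {
  d <- simulate_replicates(10, 0.4, 0.1, 0.05, seed = 2)
  f <- suppressWarnings(
    fit_bayes(d, n_iter = 200, burn_in = 50, chains = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(f, path)
  back <- read.csv(path)
  expect_equal(names(back), c("chain", "iter", "theta_T", "p", "q"))
  expect_equal(nrow(back), nrow(f$draws))
  expect_equal(back$theta_T, f$draws$theta_T)
})
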