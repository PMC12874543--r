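#' Simulate binary replicate datasets
#'
#' Draws datasets from the generative model: latent statuses
#' T_i ~ Bernoulli(theta_T), replicate counts n_i from `n_values`
#' (discrete uniform by default), and positive counts
#' S_i | T_i ~ Binomial(n_i, (1 - q) if T_i = 1 else p). Two departures
#' from the homogeneous model can be switched on: `f_single` forces a
#' fraction of individuals to a single replicate (the poorly replicated
#' regime), and `sigma > 0` replaces the common error rates by
#' per-individual rates p_i = 0.5 / (1 + exp(-v_i)) with
#' v_i ~ Normal(0, sigma^2), independently for p and q — a logistic-normal
#' heterogeneity that keeps every rate inside (0, 1/2). With sigma > 0
#' the `p`, `q` arguments are ignored and the attribute `rates` on the
#' result records the individual (p_i, q_i).
#'
#' @param N number of individuals.
#' @param theta_T prevalence in (0, 1).
#' @param p,q common false-positivity and false-negativity rates
#'   (homogeneous case, sigma = 0).
#' @param n_values support of the replicate-count distribution (sampled
#'   uniformly); default 2:6.
#' @param f_single fraction of individuals forced to n_i = 1 (the first
#'   `round(f_single * N)` individuals).
#' @param sigma heterogeneity scale (0 = homogeneous).
#' @param seed optional integer seed.
#' @return A [replicate_data] object with `t_true` attached; when
#'   sigma > 0, attribute `rates` is a data frame of the per-individual
#'   (p_i, q_i).
#' @examples
#' simulate_replicates(5, theta_T = 0.4, p = 0.1, q = 0.05, seed = 1)
#' @export
simulate_replicates <- function(N, theta_T, p = 0.1, q = 0.05,
                                n_values = 2:6, f_single = 0, sigma = 0,
                                seed = NULL) {
  if (f_single < 0 || f_single > 1) stop("f_single must be in [0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  if (theta_T <= 0 || theta_T >= 1) stop("theta_T must be in (0, 1)")
  old_rng <- push_seed(seed)
  on.exit(pop_seed(old_rng))
  t_true <- stats::rbinom(N, 1L, theta_T)
  n <- sample(n_values, N, replace = TRUE)
  k_single <- round(f_single * N)
  if (k_single > 0) n[seq_len(k_single)] <- 1L
  if (sigma > 0) {
    p_i <- 0.5 * stats::plogis(stats::rnorm(N, 0, sigma))
    q_i <- 0.5 * stats::plogis(stats::rnorm(N, 0, sigma))
  } else {
    # boundary rates 0 are allowed here (noiseless limit), unlike in
    # model_params(), since generation needs no identifiability
    if (p < 0 || p >= 0.5 || q < 0 || q >= 0.5) {
      stop("error rates p and q must lie in [0, 1/2)")
    }
    p_i <- rep(p, N); q_i <- rep(q, N)
  }
  prob <- ifelse(t_true == 1L, 1 - q_i, p_i)
  s <- stats::rbinom(N, n, prob)
  out <- replicate_data(id = paste0("ind", seq_len(N)), n = n, s = s,
                        t_true = t_true)
  if (sigma > 0) attr(out, "rates") <- data.frame(p = p_i, q = q_i)
  out
}

#' Exact bias of the average- and median-based prevalence estimators
#'
#' Closed forms under the generative model. The mean of the average
#' score is p + theta_T (1 - p - q), so its bias p - theta_T (p + q)
#' does not depend on the replicate counts and vanishes only at
#' theta_T = p / (p + q). The mean of the median score follows from
#' binomial tail probabilities in each mixture component,
#' E(Y_M | n) = P(S > n/2) + P(S = n/2) / 2, averaged over the
#' replicate-count distribution; it shrinks to 0 as the replicate counts
#' grow.
#'
#' @param theta_T prevalence (vectorized).
#' @param p,q error rates in (0, 1/2).
#' @param n_values support of the replicate-count distribution (uniform
#'   weights), for the median-score bias.
#' @return Numeric bias E(estimator) - theta_T.
#' @export
bias_average <- function(theta_T, p, q) {
  p - theta_T * (p + q)
}

#' @rdname bias_average
#' @export
bias_median <- function(theta_T, p, q, n_values = 2:6) {
  em1 <- mean(vapply(n_values, median_score_mean, 0, prob = 1 - q))
  em0 <- mean(vapply(n_values, median_score_mean, 0, prob = p))
  theta_T * em1 + (1 - theta_T) * em0 - theta_T
}

# E[median score] for S ~ Binomial(n, prob): P(S > n/2) + 0.5 P(S = n/2)
median_score_mean <- function(n, prob) {
  k <- floor(n / 2)
  tail <- 1 - stats::pbinom(k, n, prob)
  tie <- if (n %% 2 == 0) 0.5 * stats::dbinom(k, n, prob) else 0
  tail + tie
}

fit_all_methods <- function(data, prior, em_args, bayes_args) {
  em <- do.call(fit_map, c(list(data = data), em_args))
  gb <- do.call(fit_bayes, c(list(data = data, prior = prior), bayes_args))
  list(em = em, gibbs = gb)
}

method_scores <- function(data, fits) {
  list(A = score_dataset(data, "A"),
       M = score_dataset(data, "M"),
       MAP = score_dataset(data, "MAP", fits$em),
       B = score_dataset(data, "B", fits$gibbs))
}

method_theta <- function(data, fits) {
  sc <- method_scores(data, fits)
  c(A = mean(sc$A), M = mean(sc$M), MAP = mean(sc$MAP),
    B = prevalence_estimate(fits$gibbs))
}

#' Prevalence-bias sweep over the true prevalence
#'
#' For each value on `theta_grid`, simulates `n_datasets` datasets and
#' estimates the prevalence with all four methods, summarizing the
#' estimation error theta_hat - theta_T by its median and a central
#' quantile band. The exact bias curves of the average- and median-based
#' estimators are attached for reference.
#'
#' @param theta_grid prevalence values to sweep.
#' @param N individuals per dataset.
#' @param p,q generating error rates.
#' @param n_values replicate-count support.
#' @param n_datasets replicate datasets per grid point.
#' @param prior prior for the Bayesian fits.
#' @param em_args,bayes_args argument lists passed on to [fit_map()] and
#'   [fit_bayes()] (e.g. leaner iteration counts for large sweeps).
#' @param quantiles band levels (default the central 0.4-0.6 band).
#' @param seed integer seed.
#' @return A list with `errors` (long data frame: theta_T, method,
#'   replicate, error), `summary` (median and band per theta_T x method),
#'   and `theory` (exact A and M bias curves).
#' @export
bias_sweep <- function(theta_grid, N = 200, p = 0.1, q = 0.05,
                       n_values = 2:6, n_datasets = 50,
                       prior = default_prior(),
                       em_args = list(), bayes_args = list(),
                       quantiles = c(0.4, 0.6), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (th in theta_grid) {
    for (r in seq_len(n_datasets)) {
      d <- simulate_replicates(N, th, p, q, n_values = n_values)
      fits <- fit_all_methods(d, prior, em_args, bayes_args)
      est <- method_theta(d, fits)
      rows[[length(rows) + 1L]] <-
        data.frame(theta_T = th, method = names(est), replicate = r,
                   error = unname(est) - th)
    }
  }
  errors <- do.call(rbind, rows)
  summary <- stats::aggregate(
    error ~ theta_T + method, data = errors,
    FUN = function(e) c(median = stats::median(e),
                        lo = stats::quantile(e, quantiles[1], names = FALSE),
                        hi = stats::quantile(e, quantiles[2], names = FALSE)))
  summary <- cbind(summary[c("theta_T", "method")],
                   as.data.frame(summary$error))
  theory <- data.frame(
    theta_T = theta_grid,
    bias_A = bias_average(theta_grid, p, q),
    bias_M = vapply(theta_grid, bias_median, 0, p = p, q = q,
                    n_values = n_values))
  list(errors = errors, summary = summary, theory = theory)
}

#' Classification-risk sweep over the indecision cost
#'
#' For each indecision cost a on `a_grid`, simulates datasets, scores
#' them with all four methods, classifies with the risk-optimal
#' thresholds (v_L = a, v_U = 1 - a), and records the empirical
#' symmetric-loss risk against the simulated truths. The average-score
#' risk is piecewise linear in a with jumps only where a crosses an
#' attainable score s/n below 1/2; the median-score risk is linear and
#' increasing.
#'
#' @param a_grid indecision costs in (0, 1/2).
#' @param theta_T,N,p,q,n_values,n_datasets,prior,em_args,bayes_args,seed
#'   as in [bias_sweep()].
#' @param quantiles band levels.
#' @return A list with `risks` (long data frame: a, method, replicate,
#'   risk) and `summary` (median and band per a x method).
#' @export
risk_sweep <- function(a_grid, theta_T = 0.4, N = 200, p = 0.1, q = 0.05,
                       n_values = 2:6, n_datasets = 50,
                       prior = default_prior(),
                       em_args = list(), bayes_args = list(),
                       quantiles = c(0.4, 0.6), seed = 1) {
  if (any(a_grid <= 0 | a_grid >= 0.5)) stop("a_grid must lie in (0, 1/2)")
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n_datasets)) {
    d <- simulate_replicates(N, theta_T, p, q, n_values = n_values)
    fits <- fit_all_methods(d, prior, em_args, bayes_args)
    sc <- method_scores(d, fits)
    for (a in a_grid) {
      thr <- optimal_thresholds(loss_symmetric(a))
      loss <- loss_symmetric(a)
      for (m in names(sc)) {
        dec <- classify_scores(sc[[m]], thr)
        rows[[length(rows) + 1L]] <-
          data.frame(a = a, method = m, replicate = r,
                     risk = empirical_risk(dec, d$t_true, loss))
      }
    }
  }
  risks <- do.call(rbind, rows)
  summary <- stats::aggregate(
    risk ~ a + method, data = risks,
    FUN = function(e) c(median = stats::median(e),
                        lo = stats::quantile(e, quantiles[1], names = FALSE),
                        hi = stats::quantile(e, quantiles[2], names = FALSE)))
  summary <- cbind(summary[c("a", "method")], as.data.frame(summary$risk))
  list(risks = risks, summary = summary)
}

#' Sweep over the fraction of single-measurement individuals
#'
#' Evaluates robustness when many individuals carry a single replicate:
#' for each fraction on `f_grid`, simulates datasets with that share of
#' n_i = 1 individuals (the rest drawn from `n_values`), and records
#' both the symmetric-loss classification risk (indecision cost `a`) and
#' the prevalence-estimation error for every method.
#'
#' @param f_grid fractions in [0, 1].
#' @param a indecision cost for the risk evaluation.
#' @param theta_T,N,p,q,n_values,n_datasets,prior,em_args,bayes_args,seed
#'   as in [bias_sweep()].
#' @return A long data frame: f_single, method, replicate, risk, error.
#' @export
single_measurement_sweep <- function(f_grid, a = 0.45, theta_T = 0.4,
                                     N = 200, p = 0.1, q = 0.05,
                                     n_values = 2:6, n_datasets = 50,
                                     prior = default_prior(),
                                     em_args = list(), bayes_args = list(),
                                     seed = 1) {
  set.seed(seed)
  thr <- optimal_thresholds(loss_symmetric(a))
  loss <- loss_symmetric(a)
  rows <- list()
  for (f in f_grid) {
    for (r in seq_len(n_datasets)) {
      d <- simulate_replicates(N, theta_T, p, q, n_values = n_values,
                               f_single = f)
      fits <- suppressWarnings(fit_all_methods(d, prior, em_args, bayes_args))
      sc <- method_scores(d, fits)
      th <- method_theta(d, fits)
      for (m in names(sc)) {
        dec <- classify_scores(sc[[m]], thr)
        rows[[length(rows) + 1L]] <-
          data.frame(f_single = f, method = m, replicate = r,
                     risk = empirical_risk(dec, d$t_true, loss),
                     error = unname(th[m]) - theta_T)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep over the heterogeneity scale of the error rates
#'
#' Evaluates robustness when the false-positivity and false-negativity
#' rates vary across individuals on a logistic-normal scale sigma (see
#' [simulate_replicates()]). The fitted model remains the homogeneous
#' one; the sweep measures how gracefully each method degrades.
#'
#' @param sigma_grid heterogeneity scales > 0 (default 10 log-spaced
#'   points from 0.01 to 1).
#' @param a indecision cost for the risk evaluation.
#' @param theta_T,N,n_values,n_datasets,prior,em_args,bayes_args,seed as
#'   in [bias_sweep()].
#' @return A long data frame: sigma, method, replicate, risk, error.
#' @export
heterogeneity_sweep <- function(sigma_grid = exp(seq(log(0.01), log(1),
                                                     length.out = 10)),
                                a = 0.45, theta_T = 0.4, N = 200,
                                n_values = 2:6, n_datasets = 50,
                                prior = default_prior(),
                                em_args = list(), bayes_args = list(),
                                seed = 1) {
  if (any(sigma_grid <= 0)) stop("sigma_grid must be positive")
  set.seed(seed)
  thr <- optimal_thresholds(loss_symmetric(a))
  loss <- loss_symmetric(a)
  rows <- list()
  for (sg in sigma_grid) {
    for (r in seq_len(n_datasets)) {
      d <- simulate_replicates(N, theta_T, n_values = n_values, sigma = sg)
      fits <- fit_all_methods(d, prior, em_args, bayes_args)
      sc <- method_scores(d, fits)
      th <- method_theta(d, fits)
      for (m in names(sc)) {
        dec <- classify_scores(sc[[m]], thr)
        rows[[length(rows) + 1L]] <-
          data.frame(sigma = sg, method = m, replicate = r,
                     risk = empirical_risk(dec, d$t_true, loss),
                     error = unname(th[m]) - theta_T)
      }
    }
  }
  do.call(rbind, rows)
}
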