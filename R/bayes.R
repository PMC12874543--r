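#' Prior specification for the Bayesian model
#'
#' The Bayesian model places a Beta(a_T, b_T) prior on the prevalence
#' theta_T, and Beta priors on the false-positivity rate p and the
#' false-negativity rate q truncated to (0, 1/2) — error rates above 1/2
#' would make a replicate more often wrong than right. The default
#' hyperparameters are the Jeffreys-style Beta(1/2, 1/2) for the
#' prevalence and Beta(2, 2) for both error rates: replicates exist
#' because measurements are noisy, so mass near p = 0 or q = 0 (where
#' likelihood-based scoring degenerates) is deliberately down-weighted.
#'
#' @param a_T,b_T Beta hyperparameters for the prevalence prior.
#' @param a_FP,b_FP Beta hyperparameters for the false-positivity prior.
#' @param a_FN,b_FN Beta hyperparameters for the false-negativity prior.
#' @return An object of class `prior_spec`.
#' @examples
#' default_prior() # a_T = b_T = 1/2, all error-rate hyperparameters 2
#' @export
prior_spec <- function(a_T, b_T, a_FP, b_FP, a_FN, b_FN) {
  h <- c(a_T = a_T, b_T = b_T, a_FP = a_FP, b_FP = b_FP,
         a_FN = a_FN, b_FN = b_FN)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("all six hyperparameters must be strictly positive")
  }
  structure(as.list(h), class = "prior_spec")
}

#' @rdname prior_spec
#' @export
default_prior <- function() {
  prior_spec(a_T = 0.5, b_T = 0.5, a_FP = 2, b_FP = 2, a_FN = 2, b_FN = 2)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(paste0("Prior: theta_T ~ Beta(%g, %g); ",
                     "p ~ Beta(%g, %g), q ~ Beta(%g, %g), ",
                     "both truncated to (0, 1/2)\n"),
              x$a_T, x$b_T, x$a_FP, x$b_FP, x$a_FN, x$b_FN))
  invisible(x)
}

#' Sample a Beta distribution truncated to (0, 1/2)
#'
#' Exact inverse-CDF sampling on the restricted interval: draw
#' u ~ Uniform(0, F(1/2)) and return the Beta quantile at u. No
#' rejection loop, so the draw count per call is deterministic.
#'
#' @param m number of draws.
#' @param shape1,shape2 Beta shape parameters.
#' @return Numeric draws strictly inside (0, 1/2).
#' @export
rbeta_trunc_half <- function(m, shape1, shape2) {
  hi <- stats::pbeta(0.5, shape1, shape2)
  u <- stats::runif(m, 0, hi)
  q <- stats::qbeta(u, shape1, shape2)
  pmin(pmax(q, .Machine$double.xmin), 0.5 - 1e-12)
}

#' Gibbs sampler for the Bayesian replicate model
#'
#' Samples the joint posterior of (theta_T, p, q, T_1..T_N) by data
#' augmentation. All full conditionals are conjugate:
#' T_i | rest is Bernoulli with the likelihood-based score as success
#' probability; theta_T | T is Beta; p | rest and q | rest are Beta
#' truncated to (0, 1/2), drawn exactly by inverse-CDF. With a fixed
#' seed the draw sequence is reproducible bit-for-bit.
#'
#' @param data a [replicate_data] object (may have zero rows, in which
#'   case the sampler draws from the prior).
#' @param prior a [prior_spec]; defaults to [default_prior()].
#' @param n_iter iterations per chain (including burn-in).
#' @param burn_in iterations discarded at the start of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param chains number of independent chains.
#' @param seed optional integer seed.
#' @return An object of class `binreps_gibbs` with elements `draws` (a
#'   data frame with columns `chain`, `iter`, `theta_T`, `p`, `q`),
#'   `latent` (kept-draws x N binary matrix of T), `scores_rb`
#'   (Rao-Blackwellized per-individual posterior probabilities of T = 1),
#'   `rhat` (split-chain potential scale reduction per parameter, NA for
#'   a single short run), the sampler settings, and `data_n`, `data_s`.
#' @examples
#' d <- simulate_replicates(30, theta_T = 0.4, p = 0.1, q = 0.05, seed = 1)
#' fit <- fit_bayes(d, n_iter = 500, burn_in = 100, chains = 2, seed = 1)
#' posterior_mean(fit)
#' @export
fit_bayes <- function(data, prior = default_prior(), n_iter = 6000L,
                      burn_in = 1000L, thin = 1L, chains = 4L, seed = NULL) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (!inherits(prior, "prior_spec")) stop("prior must be a prior_spec")
  old_rng <- push_seed(seed)
  on.exit(pop_seed(old_rng))
  N <- nrow(data)
  n <- data$n; s <- data$s
  keep_idx <- seq(burn_in + 1L, n_iter, by = thin)
  H <- length(keep_idx)
  draws <- vector("list", chains)
  latent <- matrix(0L, nrow = chains * H, ncol = N)
  scores_rb <- numeric(N)
  row0 <- 0L
  for (ch in seq_len(chains)) {
    theta <- stats::rbeta(1, prior$a_T, prior$b_T)
    theta <- min(max(theta, 1e-12), 1 - 1e-12)
    p <- rbeta_trunc_half(1, prior$a_FP, prior$b_FP)
    q <- rbeta_trunc_half(1, prior$a_FN, prior$b_FN)
    t_cur <- if (N) as.integer(score_median(n, s) > 0.5) else integer(0)
    out <- matrix(NA_real_, nrow = H, ncol = 3L)
    k <- 0L
    for (it in seq_len(n_iter)) {
      if (N) {
        g <- score_likelihood(n, s, theta, p, q)
        t_cur <- as.integer(stats::runif(N) < g)
        pos <- t_cur == 1L
        sum_t <- sum(t_cur)
        s1 <- sum(s[pos]); n1 <- sum(n[pos])
        s0 <- sum(s[!pos]); n0 <- sum(n[!pos])
      } else {
        g <- numeric(0); sum_t <- 0L; s1 <- n1 <- s0 <- n0 <- 0L
      }
      theta <- stats::rbeta(1, prior$a_T + sum_t, prior$b_T + N - sum_t)
      theta <- min(max(theta, 1e-12), 1 - 1e-12)
      p <- rbeta_trunc_half(1, prior$a_FP + s0, prior$b_FP + n0 - s0)
      q <- rbeta_trunc_half(1, prior$a_FN + n1 - s1, prior$b_FN + s1)
      if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
        k <- k + 1L
        out[k, ] <- c(theta, p, q)
        if (N) {
          latent[row0 + k, ] <- t_cur
          # Rao-Blackwellized: average P(T_i = 1 | S_i, params) over draws
          scores_rb <- scores_rb + score_likelihood(n, s, theta, p, q)
        }
      }
    }
    draws[[ch]] <- data.frame(chain = ch, iter = keep_idx,
                              theta_T = out[, 1], p = out[, 2], q = out[, 3])
    row0 <- row0 + H
  }
  draws <- do.call(rbind, draws)
  scores_rb <- if (N) scores_rb / (chains * H) else numeric(0)
  rhat <- c(theta_T = split_rhat(draws$theta_T, chains),
            p = split_rhat(draws$p, chains),
            q = split_rhat(draws$q, chains))
  if (any(is.finite(rhat) & rhat > 1.01)) {
    warning("split-chain potential scale reduction exceeds 1.01 for: ",
            paste(names(rhat)[is.finite(rhat) & rhat > 1.01], collapse = ", "),
            "; consider more iterations")
  }
  structure(list(draws = draws, latent = latent, scores_rb = scores_rb,
                 rhat = rhat, prior = prior, n_iter = n_iter,
                 burn_in = burn_in, thin = thin, chains = chains,
                 seed = seed, data_n = n, data_s = s, data_id = data$id),
            class = "binreps_gibbs")
}

# split-chain potential scale reduction (Gelman-Rubin on split halves)
split_rhat <- function(x, chains) {
  H <- length(x) / chains
  if (H < 4) return(NA_real_)
  half <- floor(H / 2)
  segs <- lapply(seq_len(chains), function(ch) {
    xc <- x[((ch - 1) * H + 1):(ch * H)]
    list(xc[seq_len(half)], xc[(half + 1):(2 * half)])
  })
  segs <- unlist(segs, recursive = FALSE)
  m <- length(segs)
  means <- vapply(segs, mean, 0)
  vars <- vapply(segs, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.binreps_gibbs <- function(x, ...) {
  cat(sprintf(paste0("Gibbs posterior sample: %d chain(s) x %d kept draws",
                     " (n_iter = %d, burn_in = %d, thin = %d)\n"),
              x$chains, nrow(x$draws) / x$chains, x$n_iter, x$burn_in,
              x$thin))
  pm <- posterior_mean(x)
  cat(sprintf("Posterior means: theta_T = %.4f, p = %.4f, q = %.4f\n",
              pm["theta_T"], pm["p"], pm["q"]))
  if (any(is.finite(x$rhat))) {
    cat(sprintf("Split-chain Rhat: %s\n",
                paste(sprintf("%s = %.3f", names(x$rhat), x$rhat),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Posterior summaries of the fixed parameters
#'
#' `posterior_mean()` averages the kept draws. `credible_interval()`
#' returns the equal-tailed interval from the empirical quantiles of the
#' kept draws of one parameter.
#'
#' @param fit a `binreps_gibbs` object.
#' @param parameter one of "theta_T", "p", "q".
#' @param level interval level in (0, 1).
#' @return `posterior_mean()`: named numeric vector of the three
#'   posterior means. `credible_interval()`: numeric vector
#'   `c(lower, upper)`.
#' @export
posterior_mean <- function(fit) {
  c(theta_T = mean(fit$draws$theta_T), p = mean(fit$draws$p),
    q = mean(fit$draws$q))
}

#' @rdname posterior_mean
#' @export
credible_interval <- function(fit, parameter = c("theta_T", "p", "q"),
                              level = 0.95) {
  parameter <- match.arg(parameter)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x <- fit$draws[[parameter]]
  if (length(x) < 100) {
    warning("fewer than 100 posterior draws; interval is unstable")
  }
  alpha <- (1 - level) / 2
  out <- unname(stats::quantile(x, c(alpha, 1 - alpha)))
  names(out) <- c("lower", "upper")
  out
}

#' Bayesian per-individual scores
#'
#' The Bayesian score of individual i is the posterior probability that
#' its latent status is 1, integrating over the posterior uncertainty of
#' (theta_T, p, q). The Rao-Blackwellized form — the average over kept
#' draws of the likelihood-based score at each drawn parameter triple —
#' is returned by default; it has lower Monte-Carlo variance than the
#' raw frequency of T_i = 1 among the latent draws, which is available
#' with `rao_blackwell = FALSE`.
#'
#' @param fit a `binreps_gibbs` object.
#' @param data optional [replicate_data]; defaults to the data the
#'   sampler was run on (must match its record order if supplied).
#' @param rao_blackwell logical; see above.
#' @return Numeric score vector in [0, 1], one per individual.
#' @export
bayes_scores <- function(fit, data = NULL, rao_blackwell = TRUE) {
  if (!inherits(fit, "binreps_gibbs")) stop("fit must come from fit_bayes()")
  if (!is.null(data)) {
    if (!identical(as.integer(data$n), as.integer(fit$data_n)) ||
        !identical(as.integer(data$s), as.integer(fit$data_s))) {
      stop("data does not match the dataset the sampler was run on")
    }
  }
  if (rao_blackwell) fit$scores_rb else colMeans(fit$latent)
}

#' Deterministic grid approximation of the posterior
#'
#' Integrates the posterior of (theta_T, p, q) by midpoint quadrature on
#' a regular three-dimensional grid, with the latent statuses summed out
#' analytically through the two-component mixture likelihood. Serves as
#' an independent, Monte-Carlo-free check on the Gibbs sampler; feasible
#' only for moderate grid resolutions (the node count (1/step)^3 / 2 is
#' capped at 1e7).
#'
#' @param data a [replicate_data] object.
#' @param prior a [prior_spec].
#' @param grid_step grid spacing (default 0.01).
#' @return A list with `params` (posterior means of theta_T, p, q),
#'   `scores` (posterior mean of each T_i, the Bayesian scores), and
#'   `log_evidence` (log marginal likelihood up to the quadrature cell
#'   volume and dropped binomial constants).
#' @export
grid_posterior <- function(data, prior = default_prior(), grid_step = 0.01) {
  n_theta <- round(1 / grid_step)
  n_pq <- round(0.5 / grid_step)
  if (n_theta * n_pq^2 > 1e7) stop("grid too fine: more than 1e7 nodes")
  theta_g <- (seq_len(n_theta) - 0.5) * grid_step
  pq_g <- (seq_len(n_pq) - 0.5) * grid_step
  N <- nrow(data)
  n <- data$n; s <- data$s
  lp_theta <- stats::dbeta(theta_g, prior$a_T, prior$b_T, log = TRUE)
  lp_p <- stats::dbeta(pq_g, prior$a_FP, prior$b_FP, log = TRUE)
  lp_q <- stats::dbeta(pq_g, prior$a_FN, prior$b_FN, log = TRUE)
  # per-record mixture-component likelihood factors on the error-rate grids
  # A[i, j] = (1-q_j)^{s_i} q_j^{n_i - s_i};  B[i, k] = p_k^{s_i} (1-p_k)^{n_i-s_i}
  logA <- outer(s, pq_g, function(si, qq) si * log1p(-qq)) +
    outer(n - s, pq_g, function(mi, qq) mi * log(qq))
  logB <- outer(s, pq_g, function(si, pp) si * log(pp)) +
    outer(n - s, pq_g, function(mi, pp) mi * log1p(-pp))
  npq <- length(pq_g)
  logpost <- array(NA_real_, dim = c(n_theta, npq, npq))  # theta x p x q
  for (k in seq_len(npq)) {      # p index
    for (j in seq_len(npq)) {    # q index
      if (N) {
        a <- logA[, j]; b <- logB[, k]
        # loglik(theta) = sum_i log(theta e^{a_i} + (1-theta) e^{b_i})
        m <- pmax(a, b)
        ea <- exp(a - m); eb <- exp(b - m)
        ll <- colSums(log(outer(ea, theta_g) +
                          outer(eb, 1 - theta_g)) + m)
      } else {
        ll <- numeric(n_theta)
      }
      logpost[, k, j] <- ll + lp_theta + lp_p[k] + lp_q[j]
    }
  }
  mx <- max(logpost)
  w <- exp(logpost - mx)
  Z <- sum(w)
  w <- w / Z
  mean_theta <- sum(apply(w, 1, sum) * theta_g)
  mean_p <- sum(apply(w, 2, sum) * pq_g)
  mean_q <- sum(apply(w, 3, sum) * pq_g)
  scores <- numeric(N)
  if (N) {
    for (k in seq_len(npq)) {
      for (j in seq_len(npq)) {
        a <- logA[, j]; b <- logB[, k]
        # P(T_i = 1 | S_i, theta, p, q) across the theta grid: N x n_theta
        y <- stats::plogis(outer(a - b, rep(1, n_theta)) +
                           rep(log(theta_g) - log1p(-theta_g),
                               each = N))
        scores <- scores + y %*% w[, k, j]
      }
    }
    scores <- as.numeric(scores)
  }
  list(params = c(theta_T = mean_theta, p = mean_p, q = mean_q),
       scores = scores,
       log_evidence = mx + log(Z) + log(grid_step^3))
}

#' Export posterior draws
#'
#' Writes the kept parameter draws as CSV (columns chain, iter, theta_T,
#' p, q) for external convergence diagnostics.
#'
#' @param fit a `binreps_gibbs` object.
#' @param path output file path.
#' @return Invisibly, the draws data frame.
#' @export
write_draws <- function(fit, path) {
  utils::write.csv(fit$draws, path, row.names = FALSE)
  invisible(fit$draws)
}
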