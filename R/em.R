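#' Penalized log-likelihood of the binomial mixture
#'
#' The observed-data log-likelihood of (theta_T, p, q) given the
#' sufficient statistics,
#' \deqn{\sum_i \log\{\theta_T (1-q)^{s_i} q^{n_i - s_i}
#'   + (1-\theta_T) p^{s_i} (1-p)^{n_i - s_i}\},}
#' plus Beta(2, 2) log-penalties on p and q. The penalty keeps the
#' optimizer away from the degenerate boundary solutions p = 0 or q = 0
#' that the raw likelihood admits. Binomial coefficients (constant in the
#' parameters) are dropped.
#'
#' @param theta_T,p,q parameters satisfying 0 < theta_T < 1 and
#'   0 < p, q < 1/2; alternatively a [model_params] object as `theta_T`.
#' @param data a [replicate_data] object.
#' @return The penalized log-likelihood (a single number).
#' @export
penalized_loglik <- function(theta_T, p, q, data) {
  if (inherits(theta_T, "model_params")) {
    par <- theta_T
    theta_T <- par$theta_T; p <- par$p; q <- par$q
  } else {
    model_params(theta_T, p, q)
  }
  sum(mixture_loglik_terms(theta_T, p, q, data$n, data$s)) +
    stats::dbeta(p, 2, 2, log = TRUE) + stats::dbeta(q, 2, 2, log = TRUE)
}

# per-record log of theta*(1-q)^s q^(n-s) + (1-theta) p^s (1-p)^(n-s),
# via log-sum-exp
mixture_loglik_terms <- function(theta_T, p, q, n, s) {
  l1 <- log(theta_T) + (n - s) * log(q) + s * log1p(-q)
  l0 <- log1p(-theta_T) + s * log(p) + (n - s) * log1p(-p)
  m <- pmax(l1, l0)
  m + log(exp(l1 - m) + exp(l0 - m))
}

#' EM steps for the penalized-likelihood fit
#'
#' `em_e_step()` computes the responsibilities gamma_i = P(T_i = 1 | S_i)
#' at the current parameters (identical to [score_likelihood()]).
#' `em_m_step()` maximizes the expected complete-data penalized
#' log-likelihood given responsibilities: theta_T is the mean
#' responsibility, while the Beta(2, 2) penalties add one pseudo-success
#' and one pseudo-failure to each error-rate update,
#' \deqn{q = \frac{\sum_i \gamma_i (n_i - s_i) + 1}{\sum_i \gamma_i n_i + 2},
#'   \qquad
#'   p = \frac{\sum_i (1-\gamma_i) s_i + 1}{\sum_i (1-\gamma_i) n_i + 2},}
#' with p and q then clipped into (0, 1/2) (clip margin `eps`) to respect
#' the reliability constraint.
#'
#' @param params a [model_params] object.
#' @param data a [replicate_data] object.
#' @param gamma responsibilities in [0, 1], one per individual.
#' @param eps clip margin for the (0, 1/2) constraint.
#' @return `em_e_step()`: a numeric vector of responsibilities.
#'   `em_m_step()`: a [model_params] object.
#' @export
em_e_step <- function(params, data) {
  score_likelihood(data$n, data$s, params)
}

#' @rdname em_e_step
#' @export
em_m_step <- function(gamma, data, eps = 1e-6) {
  if (any(gamma < 0 | gamma > 1)) stop("responsibilities must be in [0, 1]")
  theta_T <- mean(gamma)
  q <- (sum(gamma * (data$n - data$s)) + 1) / (sum(gamma * data$n) + 2)
  p <- (sum((1 - gamma) * data$s) + 1) / (sum((1 - gamma) * data$n) + 2)
  model_params(theta_T = min(max(theta_T, eps), 1 - eps),
               p = min(max(p, eps), 0.5 - eps),
               q = min(max(q, eps), 0.5 - eps))
}

#' Penalized maximum-likelihood (MAP) fit by EM
#'
#' Fits (theta_T, p, q) by maximizing the Beta(2, 2)-penalized mixture
#' likelihood with the expectation-maximization algorithm, restarted from
#' several initial points to guard against local optima. The default
#' initialization uses one moment-based start (prevalence from the mean
#' median score, error rates from the ratio estimators evaluated at the
#' median scores) plus `n_starts - 1` random draws; the best final
#' penalized log-likelihood wins.
#'
#' @param data a [replicate_data] object (nonempty). When every
#'   individual has at most two replicates the mixture is weakly
#'   identified and a warning is issued.
#' @param tol convergence tolerance on the change in penalized
#'   log-likelihood between successive iterations.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of initializations (>= 1).
#' @param seed optional integer seed controlling the random restarts.
#' @param eps clip margin for the (0, 1/2) constraint on p and q.
#' @return An object of class `binreps_em` with elements `params`
#'   (a [model_params]), `gamma` (responsibilities at the optimum),
#'   `loglik` (final penalized log-likelihood), `trajectory` (per-iteration
#'   objective values of the winning start), `n_iter`, `converged`,
#'   and `n_starts`.
#' @examples
#' d <- simulate_replicates(50, theta_T = 0.4, p = 0.1, q = 0.05, seed = 1)
#' fit <- fit_map(d, seed = 1)
#' fit$params
#' @export
fit_map <- function(data, tol = 1e-8, max_iter = 500L, n_starts = 8L,
                    seed = NULL, eps = 1e-6) {
  if (nrow(data) == 0L) stop("dataset is empty")
  if (all(data$n <= 2L)) {
    warning("all individuals have n <= 2 replicates; ",
            "the mixture parameters are weakly identified")
  }
  starts <- em_starts(data, n_starts, seed, eps)
  best <- NULL
  for (par0 in starts) {
    res <- em_single(par0, data, tol, max_iter, eps)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  best$n_starts <- length(starts)
  class(best) <- "binreps_em"
  best
}

em_starts <- function(data, n_starts, seed, eps) {
  ym <- score_median(data$n, data$s)
  th0 <- min(max(mean(ym), 0.05), 0.95)
  # ratio estimators at the median scores; fall back to 0.1 if degenerate
  denom_p <- sum(data$n * (1 - ym)); denom_q <- sum(data$n * ym)
  p0 <- if (denom_p > 0) sum(data$s * (1 - ym)) / denom_p else 0.1
  q0 <- if (denom_q > 0) sum((data$n - data$s) * ym) / denom_q else 0.1
  clip <- function(x) min(max(x, 0.01), 0.49)
  starts <- list(model_params(th0, clip(p0), clip(q0)))
  if (n_starts > 1L) {
    old_rng <- push_seed(seed)
    on.exit(pop_seed(old_rng))
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- model_params(stats::runif(1, 0.05, 0.95),
                                       stats::runif(1, 0.01, 0.49),
                                       stats::runif(1, 0.01, 0.49))
    }
  }
  starts
}

em_single <- function(params, data, tol, max_iter, eps) {
  traj <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  gamma <- em_e_step(params, data)
  repeat {
    iter <- iter + 1L
    params <- em_m_step(gamma, data, eps)
    gamma <- em_e_step(params, data)
    ll <- penalized_loglik(params, data = data)
    traj <- c(traj, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(params = params, gamma = gamma, loglik = traj[length(traj)],
       trajectory = traj, n_iter = iter, converged = converged)
}

#' @export
print.binreps_em <- function(x, ...) {
  cat(sprintf(paste0("Penalized-likelihood (MAP) fit by EM: %d iterations",
                     " (%s), %d start(s)\n"),
              x$n_iter, if (x$converged) "converged" else "not converged",
              x$n_starts))
  print(x$params)
  cat(sprintf("Penalized log-likelihood: %.6f\n", x$loglik))
  invisible(x)
}
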