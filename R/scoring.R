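#' Model parameters for the binomial mixture of binary replicates
#'
#' The generative model assumes a latent binary status T ~ Bernoulli(theta_T)
#' per individual, and, given T, the number of positive replicates
#' S | T ~ Binomial(n, T (1 - q) + (1 - T) p), where p is the
#' false-positivity rate and q the false-negativity rate. Reliable
#' replicates require p, q in (0, 1/2) (otherwise a replicate is more
#' likely wrong than right); this constraint is enforced here and is what
#' makes the two mixture components identifiable without label switching.
#'
#' @param theta_T prevalence, in (0, 1).
#' @param p false-positivity rate, in (0, 1/2).
#' @param q false-negativity rate, in (0, 1/2).
#' @return An object of class `model_params` (a named list).
#' @export
model_params <- function(theta_T, p, q) {
  if (!is.finite(theta_T) || theta_T <= 0 || theta_T >= 1) {
    stop("theta_T must lie strictly inside (0, 1)")
  }
  if (!is.finite(p) || p <= 0 || p >= 0.5) {
    stop("false-positivity rate p must lie strictly inside (0, 1/2)")
  }
  if (!is.finite(q) || q <= 0 || q >= 0.5) {
    stop("false-negativity rate q must lie strictly inside (0, 1/2)")
  }
  structure(list(theta_T = theta_T, p = p, q = q), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model parameters: theta_T = %.4f, p = %.4f, q = %.4f\n",
              x$theta_T, x$p, x$q))
  invisible(x)
}

#' Average-based score
#'
#' The proportion of positive replicates, s / n.
#'
#' @param n,s replicate counts and positive counts (vectorized).
#' @return Numeric scores in [0, 1].
#' @export
score_average <- function(n, s) {
  s / n
}

#' Median-based score
#'
#' The median of the binary replicates: 1 when more than half are
#' positive, 0 when fewer than half are, and 1/2 at an exact tie (even n
#' with s = n/2).
#'
#' @param n,s replicate counts and positive counts (vectorized).
#' @return Numeric scores in \{0, 1/2, 1\}.
#' @export
score_median <- function(n, s) {
  as.numeric(s > n / 2) + 0.5 * as.numeric(s == n / 2)
}

#' Likelihood-based score P(T = 1 | S = s)
#'
#' The posterior probability of the positive latent status given the
#' replicate counts, at fixed model parameters:
#' \deqn{Y_L = \frac{\theta_T q^{n-s} (1-q)^s}
#'   {\theta_T q^{n-s} (1-q)^s + (1-\theta_T) p^s (1-p)^{n-s}}.}
#' Computed in log space for numerical stability; strictly increasing in
#' s at fixed n.
#'
#' @param n,s replicate counts and positive counts (vectorized).
#' @param theta_T,p,q model parameters satisfying 0 < theta_T < 1 and
#'   0 < p, q < 1/2 (vectorized, e.g. over posterior draws);
#'   alternatively pass a [model_params] object as `theta_T`.
#' @return Numeric scores in (0, 1).
#' @examples
#' score_likelihood(3, 2, theta_T = 0.4, p = 0.1, q = 0.05)
#' @export
score_likelihood <- function(n, s, theta_T, p, q) {
  if (inherits(theta_T, "model_params")) {
    par <- theta_T
    theta_T <- par$theta_T; p <- par$p; q <- par$q
  } else {
    if (any(!is.finite(theta_T)) || any(theta_T <= 0) || any(theta_T >= 1)) {
      stop("theta_T must lie strictly inside (0, 1)")
    }
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 0.5) ||
        any(!is.finite(q)) || any(q <= 0) || any(q >= 0.5)) {
      stop("error rates p and q must lie strictly inside (0, 1/2)")
    }
  }
  # log odds of component T=1 vs T=0
  l1 <- log(theta_T) + (n - s) * log(q) + s * log1p(-q)
  l0 <- log1p(-theta_T) + s * log(p) + (n - s) * log1p(-p)
  stats::plogis(l1 - l0)
}

#' Score every individual in a dataset
#'
#' Computes one of the four per-individual scores for the whole dataset:
#' `"A"` (average), `"M"` (median), `"MAP"` (likelihood-based score at
#' the penalized-likelihood optimum from [fit_map()]), or `"B"` (Bayesian
#' posterior probability of the positive status from [fit_bayes()]).
#' Method `"L"` evaluates the likelihood-based score at user-supplied
#' fixed parameters.
#'
#' @param data a [replicate_data] object.
#' @param method one of "A", "M", "MAP", "B", "L".
#' @param fit for "MAP" a [fit_map()] result; for "B" a [fit_bayes()]
#'   result; for "L" a [model_params] object. Ignored otherwise.
#' @return A numeric score vector aligned with the rows of `data`, with
#'   attribute `method`.
#' @export
score_dataset <- function(data, method = c("A", "M", "MAP", "B", "L"),
                          fit = NULL) {
  method <- match.arg(method)
  y <- switch(method,
    A = score_average(data$n, data$s),
    M = score_median(data$n, data$s),
    MAP = {
      if (!inherits(fit, "binreps_em")) {
        stop("method 'MAP' requires a fitted EM result from fit_map()")
      }
      score_likelihood(data$n, data$s, fit$params)
    },
    B = {
      if (!inherits(fit, "binreps_gibbs")) {
        stop("method 'B' requires a posterior sample from fit_bayes()")
      }
      bayes_scores(fit, data)
    },
    L = {
      if (!inherits(fit, "model_params")) {
        stop("method 'L' requires a model_params object")
      }
      score_likelihood(data$n, data$s, fit)
    })
  attr(y, "method") <- method
  y
}
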