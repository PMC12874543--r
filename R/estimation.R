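#' Prevalence estimators
#'
#' For the average-, median-, and MAP-based methods the prevalence is
#' estimated by the sample mean of the corresponding per-individual
#' scores. For the Bayesian method it is the posterior mean of theta_T.
#'
#' @param x either a numeric score vector (for score-based methods) or a
#'   `binreps_gibbs` posterior sample.
#' @return The prevalence estimate (a single number).
#' @export
prevalence_estimate <- function(x) {
  if (inherits(x, "binreps_gibbs")) {
    unname(posterior_mean(x)["theta_T"])
  } else {
    if (length(x) == 0L) stop("empty score vector")
    mean(x)
  }
}

#' Score-based error-rate estimators
#'
#' Treating the scores Y as soft labels for the latent statuses, the
#' false-positivity and false-negativity rates are estimated by
#' \deqn{\hat p = \frac{\sum_i S_i (1 - Y_i)}{\sum_i n_i (1 - Y_i)},
#'   \qquad
#'   \hat q = \frac{\sum_i (n_i - S_i) Y_i}{\sum_i n_i Y_i}.}
#' When the scores all equal the true statuses these reduce exactly to
#' the gold-standard estimators of [latent_estimates()].
#'
#' @param scores numeric scores in [0, 1], aligned with the dataset.
#' @param data a [replicate_data] object.
#' @return A list with `p_hat` and `q_hat`; either is NA (with a
#'   `degenerate` flag naming it) when its denominator vanishes, i.e.
#'   when every score is 1 (p inestimable) or every score is 0
#'   (q inestimable).
#' @export
error_rate_estimates <- function(scores, data) {
  if (length(scores) != nrow(data)) {
    stop("scores and dataset have different lengths")
  }
  denom_p <- sum(data$n * (1 - scores))
  denom_q <- sum(data$n * scores)
  degenerate <- character(0)
  p_hat <- if (denom_p > 0) sum(data$s * (1 - scores)) / denom_p else {
    degenerate <- c(degenerate, "p_hat"); NA_real_
  }
  q_hat <- if (denom_q > 0) sum((data$n - data$s) * scores) / denom_q else {
    degenerate <- c(degenerate, "q_hat"); NA_real_
  }
  list(p_hat = p_hat, q_hat = q_hat, degenerate = degenerate)
}

#' Gold-standard (latent-status) estimators
#'
#' When the true status of every individual is known, the model
#' parameters have direct empirical counterparts: the prevalence is the
#' fraction of true positives, the false-positivity rate the fraction of
#' positive replicates among truly negative individuals, and the
#' false-negativity rate the fraction of negative replicates among truly
#' positive individuals.
#'
#' @param data a [replicate_data] object carrying `t_true` for every
#'   record.
#' @return A list with `theta_hat`, `p_hat`, `q_hat` (NA when a truth
#'   class is empty).
#' @export
latent_estimates <- function(data) {
  if (!has_truth(data)) stop("dataset carries no true statuses (t_true)")
  t <- data$t_true
  denom_p <- sum(data$n * (1 - t))
  denom_q <- sum(data$n * t)
  list(theta_hat = mean(t),
       p_hat = if (denom_p > 0) sum(data$s * (1 - t)) / denom_p else NA_real_,
       q_hat = if (denom_q > 0) sum((data$n - data$s) * t) / denom_q
               else NA_real_)
}

#' Predictive score for a new individual
#'
#' `predict_plugin()` evaluates the likelihood-based score at point
#' estimates of the parameters (for the average-, median-, or MAP-based
#' pipelines). `predict_bayes()` averages the likelihood-based score over
#' the posterior draws, propagating parameter uncertainty into the
#' prediction; point-estimate plug-ins ignore that uncertainty and can be
#' over-confident.
#'
#' @param params a [model_params] object (plug-in estimates).
#' @param fit a `binreps_gibbs` posterior sample.
#' @param n,s replicate count and positive count of the new individual
#'   (vectorized).
#' @return Predictive scores in (0, 1).
#' @export
predict_plugin <- function(params, n, s) {
  score_likelihood(n, s, params)
}

#' @rdname predict_plugin
#' @export
predict_bayes <- function(fit, n, s) {
  if (!inherits(fit, "binreps_gibbs")) stop("fit must come from fit_bayes()")
  d <- fit$draws
  vapply(seq_along(n), function(i) {
    mean(score_likelihood(n[i], s[i], d$theta_T, d$p, d$q))
  }, 0)
}

#' Predictive decision table for new individuals
#'
#' For each number of replicates n in `n_range` and each attainable
#' positive count s = 0..n, tabulates the three-way decision each fitted
#' method would make for a new individual observed with (n, s). This is
#' the practitioner-facing lookup table: given how many replicates were
#' run and how many came back positive, read off the diagnosis (or the
#' indecision advising more replicates).
#'
#' @param fits named list of fitted methods; each element is either a
#'   [model_params] object (plug-in prediction) or a `binreps_gibbs`
#'   posterior sample (Bayesian prediction).
#' @param thr a [thresholds] object.
#' @param n_range integer vector of replicate counts to tabulate.
#' @return A data frame with columns `n`, `s`, then one decision column
#'   per method (values 0, 1/2, 1).
#' @export
prediction_table <- function(fits, thr, n_range) {
  grid <- do.call(rbind, lapply(n_range, function(nn) {
    data.frame(n = nn, s = 0:nn)
  }))
  for (m in names(fits)) {
    f <- fits[[m]]
    y <- if (inherits(f, "binreps_gibbs")) {
      predict_bayes(f, grid$n, grid$s)
    } else if (inherits(f, "model_params")) {
      predict_plugin(f, grid$n, grid$s)
    } else {
      stop("fits[['", m, "']] is neither model_params nor a posterior sample")
    }
    grid[[m]] <- classify_scores(y, thr)
  }
  grid
}
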