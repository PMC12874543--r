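#' Loss specification for three-way classification
#'
#' Classifying a binary truth t with decisions in \{0, 1/2, 1\} (1/2 is
#' the indecision response) uses the loss table
#' \tabular{lccc}{
#'    \tab decide 0 \tab decide 1/2 \tab decide 1 \cr
#'   truth 0 \tab 0 \tab a \tab b \cr
#'   truth 1 \tab c \tab d \tab 0
#' }
#' with positive constants a, b, c, d. `loss_symmetric(a)` builds the
#' symmetric form with unit misclassification costs (b = c = 1) and
#' equal indecision costs (d = a), 0 < a < 1.
#'
#' @param a cost of indecision when the truth is 0.
#' @param b cost of deciding 1 when the truth is 0 (false positive).
#' @param c cost of deciding 0 when the truth is 1 (false negative).
#' @param d cost of indecision when the truth is 1.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("loss constants a, b, c, d must all be strictly positive")
  }
  structure(as.list(v), class = "loss_spec")
}

#' @rdname loss_spec
#' @export
loss_symmetric <- function(a) {
  if (a <= 0 || a >= 1) stop("indecision cost a must be in (0, 1)")
  loss_spec(a = a, b = 1, c = 1, d = a)
}

#' @export
print.loss_spec <- function(x, ...) {
  cat(sprintf("Loss: indecision a = %g (truth 0), d = %g (truth 1); ",
              x$a, x$d))
  cat(sprintf("false positive b = %g, false negative c = %g\n", x$b, x$c))
  invisible(x)
}

#' Can the indecision response ever be optimal?
#'
#' The risk-minimizing decision uses the indecision response 1/2 on a
#' nonempty range of P(T = 1) exactly when
#' bc/(b + c) > a + (d - a) b/(b + c) and -b < d - a < c.
#' For the symmetric loss this reduces to a < 1/2: indecision must cost
#' less than half a misclassification to ever be worth returning.
#'
#' @param loss a [loss_spec].
#' @return Logical.
#' @export
indecision_condition <- function(loss) {
  with(loss, b * c / (b + c) > a + (d - a) * b / (b + c) &&
         -b < (d - a) && (d - a) < c)
}

#' Decision thresholds
#'
#' `thresholds()` validates an explicit pair 0 < v_L <= 1/2 <= v_U < 1.
#' `optimal_thresholds()` derives the risk-optimal pair from a loss
#' specification: v_L = a / (c - (d - a)) and
#' v_U = (b - a) / ((d - a) + b), which for the symmetric loss gives
#' (a, 1 - a). The three-way rule with these cuts minimizes the expected
#' loss among all decisions in \{0, 1/2, 1\} at every value of P(T = 1).
#'
#' @param v_L,v_U lower and upper cut points.
#' @param loss a [loss_spec] satisfying [indecision_condition()].
#' @return An object of class `thresholds` with fields `v_L`, `v_U`.
#' @examples
#' optimal_thresholds(loss_symmetric(0.45)) # (0.45, 0.55)
#' @export
thresholds <- function(v_L, v_U) {
  if (!(v_L > 0 && v_L <= 0.5 && v_U >= 0.5 && v_U < 1)) {
    stop("need 0 < v_L <= 1/2 <= v_U < 1")
  }
  structure(list(v_L = v_L, v_U = v_U), class = "thresholds")
}

#' @rdname thresholds
#' @export
optimal_thresholds <- function(loss) {
  if (!indecision_condition(loss)) {
    stop("this loss never favors the indecision response; ",
         "use a binary classifier (single threshold) instead")
  }
  thresholds(v_L = loss$a / (loss$c - (loss$d - loss$a)),
             v_U = (loss$b - loss$a) / ((loss$d - loss$a) + loss$b))
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("Decision thresholds: v_L = %g, v_U = %g\n", x$v_L, x$v_U))
  invisible(x)
}

#' Three-way classification of scores
#'
#' Applies the double-threshold rule: decide 0 when the score is below
#' v_L, 1 when above v_U, and the indecision response 1/2 in between.
#' Scores exactly at a threshold fall in the indecision band (the band
#' is closed). Median scores are their own decisions whenever the
#' thresholds straddle 1/2, since they only take values 0, 1/2, 1.
#'
#' @param scores numeric scores in [0, 1].
#' @param thr a [thresholds] object.
#' @return Numeric decisions in \{0, 1/2, 1\}.
#' @export
classify_scores <- function(scores, thr) {
  if (!inherits(thr, "thresholds")) stop("thr must be a thresholds object")
  ifelse(scores < thr$v_L, 0, ifelse(scores > thr$v_U, 1, 0.5))
}

loss_value <- function(truth, decision, loss) {
  # vectorized lookup of the 2 x 3 loss table
  ifelse(truth == 0,
         ifelse(decision == 0, 0, ifelse(decision == 0.5, loss$a, loss$b)),
         ifelse(decision == 1, 0, ifelse(decision == 0.5, loss$d, loss$c)))
}

#' Empirical risk of a decision vector
#'
#' The average (default) or total loss incurred over individuals with
#' known truth. The mean scale matches the per-individual risk
#' definition; the sum scale (mean times N) is sometimes more natural
#' when comparing counts of errors on a fixed dataset.
#'
#' @param decisions decisions in \{0, 1/2, 1\}.
#' @param truth binary truths, same length.
#' @param loss a [loss_spec].
#' @param scale `"mean"` or `"sum"`.
#' @return A single number.
#' @export
empirical_risk <- function(decisions, truth, loss, scale = c("mean", "sum")) {
  scale <- match.arg(scale)
  if (length(decisions) != length(truth)) {
    stop("decisions and truth must have equal lengths")
  }
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  if (!all(decisions %in% c(0, 0.5, 1))) {
    stop("decisions must be in {0, 1/2, 1}")
  }
  losses <- loss_value(truth, decisions, loss)
  if (scale == "mean") mean(losses) else sum(losses)
}

#' Diagnostic metrics under the indecision response
#'
#' Sensitivity and specificity count only committed correct decisions:
#' an indecision is an error whichever the truth, so it enters neither
#' numerator. The confusion table has truth in rows and the three
#' decisions in columns.
#'
#' @param decisions decisions in \{0, 1/2, 1\}.
#' @param truth binary truths, same length, required for every record.
#' @return A list with `sensitivity`, `specificity` (NA when the
#'   corresponding truth class is empty), `misclassification` (fraction
#'   of individuals without a committed correct decision), `informedness`
#'   (sensitivity + specificity - 1), and `confusion` (2 x 3 table).
#' @export
diagnostic_metrics <- function(decisions, truth) {
  if (length(decisions) != length(truth)) {
    stop("decisions and truth must have equal lengths")
  }
  if (anyNA(truth) || !all(truth %in% c(0, 1))) {
    stop("truth must be 0/1 for every record")
  }
  conf <- table(factor(truth, levels = c(0, 1)),
                factor(decisions, levels = c(0, 0.5, 1)),
                dnn = c("truth", "decision"))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  sens <- if (n1 > 0) conf["1", "1"] / n1 else NA_real_
  spec <- if (n0 > 0) conf["0", "0"] / n0 else NA_real_
  miscl <- mean(decisions != truth)
  list(sensitivity = unname(sens), specificity = unname(spec),
       misclassification = miscl,
       informedness = unname(sens + spec - 1),
       confusion = conf)
}

#' Agreement band between average- and median-based classifiers
#'
#' With n0 the largest number of replicates in the dataset, define
#' delta0 = 1/(2 n0) when n0 is odd and 1/(2 (n0 - 1)) when n0 is even.
#' Whenever v_L lies in (1/2 - delta0, 1/2] and v_U in [1/2, 1/2 + delta0),
#' no attainable average score s/n can separate the two rules, so the
#' average- and median-based classifications are identical on every
#' dataset with maximum replicate count n0.
#'
#' @param n0 maximum replicate count (positive integer).
#' @param thr optional [thresholds]; when given, the returned list
#'   reports whether the pair falls inside the band.
#' @return A list with `delta0`, `lower` (1/2 - delta0), `upper`
#'   (1/2 + delta0) and, if `thr` was supplied, `identical_classifiers`.
#' @examples
#' agreement_band(6) # delta0 = 0.1, band (0.4, 0.6)
#' @export
agreement_band <- function(n0, thr = NULL) {
  if (n0 < 1) stop("n0 must be at least 1")
  delta0 <- if (n0 %% 2 == 1) 1 / (2 * n0) else 1 / (2 * (n0 - 1))
  out <- list(delta0 = delta0, lower = 0.5 - delta0, upper = 0.5 + delta0)
  if (!is.null(thr)) {
    out$identical_classifiers <-
      thr$v_L > out$lower && thr$v_U < out$upper
  }
  out
}
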