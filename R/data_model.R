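#' Replicate datasets
#'
#' A `replicate_data` object holds, for each individual, the sufficient
#' statistics of its binary technical replicates: the number of replicates
#' `n` and the number of positive replicates `s`. Because replicates within
#' an individual are exchangeable, the pair (n, s) carries all the
#' statistical information in the raw replicate vector, so raw vectors are
#' collapsed on ingestion and never stored. An optional true status
#' `t_true` (0/1) may be attached when a gold-standard diagnosis exists.
#'
#' @param id character vector of individual labels (unique).
#' @param n integer vector of replicate counts (all >= 1).
#' @param s integer vector of positive-replicate counts, 0 <= s <= n.
#' @param t_true optional integer vector of true statuses in \{0, 1\};
#'   `NULL` (default) when no gold standard is available.
#'
#' @return An object of class `replicate_data`: a data frame with columns
#'   `id`, `n`, `s` and, when supplied, `t_true`, one row per individual,
#'   in the order given.
#' @examples
#' replicate_data(id = c("A", "B"), n = c(4, 3), s = c(3, 0))
#' @export
replicate_data <- function(id, n, s, t_true = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicated individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  n <- as.integer(n)
  s <- as.integer(s)
  if (length(n) != length(id) || length(s) != length(id)) {
    stop("id, n and s must have equal lengths")
  }
  if (length(id) > 0L) {
    if (anyNA(n) || anyNA(s)) stop("n and s must not contain missing values")
    if (any(n < 1L)) stop("replicate counts n must be >= 1")
    bad <- which(s < 0L | s > n)
    if (length(bad)) {
      stop("invalid counts (need 0 <= s <= n) for id(s): ",
           paste(id[bad], collapse = ", "))
    }
  }
  out <- data.frame(id = id, n = n, s = s, stringsAsFactors = FALSE)
  if (!is.null(t_true)) {
    t_true <- as.integer(t_true)
    if (length(t_true) != length(id)) stop("t_true has wrong length")
    if (length(id) > 0L && (anyNA(t_true) || !all(t_true %in% c(0L, 1L)))) {
      stop("t_true must be 0 or 1 for every individual")
    }
    out$t_true <- t_true
  }
  class(out) <- c("replicate_data", "data.frame")
  out
}

#' @export
print.replicate_data <- function(x, ...) {
  cat(sprintf("Binary replicate data: %d individuals, n in [%s, %s]%s\n",
              nrow(x),
              if (nrow(x)) min(x$n) else "-",
              if (nrow(x)) max(x$n) else "-",
              if (has_truth(x)) ", true status available" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

has_truth <- function(data) {
  !is.null(data$t_true)
}

#' Largest and smallest replicate count in a dataset
#'
#' Both extremes of the per-individual replicate counts are used by
#' theoretical quantities: the agreement band between average- and
#' median-based classifiers depends on the maximum, while asymptotic bias
#' statements about the median-based prevalence estimator involve the
#' minimum.
#'
#' @param data a `replicate_data` object.
#' @return The maximum (`n0_max`) or minimum (`n0_min`) of `n`.
#' @export
n0_max <- function(data) max(data$n)

#' @rdname n0_max
#' @export
n0_min <- function(data) min(data$n)

#' Collapse a raw replicate vector to its sufficient statistics
#'
#' @param values vector of binary replicate values (each 0 or 1).
#' @return A list with elements `n` (number of replicates) and `s`
#'   (number of positive replicates).
#' @examples
#' sufficient_stats(c(1, 0, 1)) # n = 3, s = 2
#' @export
sufficient_stats <- function(values) {
  if (length(values) == 0L) stop("replicate vector is empty")
  v <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(v) | !(v %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("non-binary replicate value %s at position %d",
                 deparse(values[bad[1L]]), bad[1L]))
  }
  list(n = length(v), s = as.integer(sum(v)))
}

#' Read replicate data in long format
#'
#' Long format is one row per replicate: an individual id column and a
#' binary value column, with an optional per-individual status column
#' (the gold-standard truth, constant within an individual). Rows are
#' collapsed per individual into (n, s); record order is the order of
#' first appearance in the file.
#'
#' @param path path to a delimited text file with a header.
#' @param id_col,value_col,status_col column names; `status_col` is used
#'   only if present in the file.
#' @param sep field delimiter (default comma).
#' @return A [replicate_data] object.
#' @export
read_replicates_long <- function(path, id_col = "id", value_col = "value",
                                 status_col = "status", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  for (col in c(id_col, value_col)) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  v <- df[[value_col]]
  bad <- which(is.na(v) | !(v %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("non-binary value %s at data row %d of %s",
                 deparse(v[bad[1L]]), bad[1L], path))
  }
  ids <- as.character(df[[id_col]])
  uid <- unique(ids)  # order of first appearance
  n <- tabulate(factor(ids, levels = uid))
  s <- as.integer(rowsum(as.numeric(v), factor(ids, levels = uid),
                         reorder = FALSE))
  t_true <- NULL
  if (status_col %in% names(df)) {
    st <- df[[status_col]]
    per_id <- tapply(st, factor(ids, levels = uid),
                     function(z) unique(z), simplify = FALSE)
    if (any(lengths(per_id) != 1L)) {
      stop("status column is not constant within an individual")
    }
    t_true <- as.integer(unlist(per_id))
  }
  replicate_data(id = uid, n = n, s = s, t_true = t_true)
}

#' Read replicate data in count format
#'
#' Count format is one row per individual with columns `id`, `n`, `s`
#' and an optional `t_true` column.
#'
#' @param path path to a delimited text file with a header.
#' @param sep field delimiter (default comma).
#' @return A [replicate_data] object.
#' @export
read_replicates_counts <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("id", "n", "s")) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  replicate_data(id = df$id, n = df$n, s = df$s,
                 t_true = if ("t_true" %in% names(df)) df$t_true else NULL)
}

#' Write per-individual scores and decisions
#'
#' Writes a delimited file with one row per individual: the sufficient
#' statistics followed by one score column and one decision column per
#' method. The indecision decision 1/2 is serialized as the token
#' `"indecisive"` so that it cannot be confused with a numeric score.
#'
#' @param data a `replicate_data` object.
#' @param scores named list of numeric score vectors (one per method),
#'   each aligned with the rows of `data`.
#' @param decisions named list of decision vectors with values in
#'   \{0, 1/2, 1\}, aligned likewise.
#' @param path output file path.
#' @param sep field delimiter.
#' @return Invisibly, the data frame that was written.
#' @export
write_results <- function(data, scores, decisions, path, sep = ",") {
  out <- data.frame(id = data$id, n = data$n, s = data$s,
                    stringsAsFactors = FALSE)
  for (m in names(scores)) {
    if (length(scores[[m]]) != nrow(data)) {
      stop("score vector '", m, "' has length ", length(scores[[m]]),
           ", expected ", nrow(data))
    }
    out[[paste0("score_", m)]] <- as.numeric(scores[[m]])
  }
  for (m in names(decisions)) {
    d <- decisions[[m]]
    if (length(d) != nrow(data)) {
      stop("decision vector '", m, "' has length ", length(d),
           ", expected ", nrow(data))
    }
    out[[paste0("decision_", m)]] <- decision_token(d)
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(out)
}

decision_token <- function(d) {
  if (!all(d %in% c(0, 0.5, 1))) stop("decisions must be in {0, 1/2, 1}")
  ifelse(d == 0.5, "indecisive", as.character(as.integer(d)))
}
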