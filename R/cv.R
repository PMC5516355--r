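#' Seeded (stratified) k-fold assignment
#'
#' Produces fold ids 1..k such that overall fold sizes differ by at most
#' one and, when stratified, per-class fold counts also differ by at most
#' one. Class remainders are placed on the folds with the smallest running
#' totals so both balance constraints hold simultaneously (116 patients,
#' k = 10 gives six folds of 12 and four of 11).
#'
#' @param labels class labels (any number of classes when
#'   `stratified = TRUE`; ignored except for length otherwise).
#' @param k fold count, `2 <= k <= length(labels)`.
#' @param seed RNG seed; same seed, same assignment.
#' @param stratified balance folds within each class.
#' @return integer vector of fold ids.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  check_number(k, "k", lower = 2, integer = TRUE)
  if (k > n) stop("k must not exceed the cohort size", call. = FALSE)
  with_seed(seed, {
    fold <- integer(n)
    if (!stratified) {
      base <- n %/% k; rem <- n %% k
      sizes <- rep(base, k) + (seq_len(k) <= rem)
      fold <- sample(rep(seq_len(k), sizes))
    } else {
      totals <- integer(k)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        m <- length(idx)
        base <- m %/% k; rem <- m %% k
        sizes <- rep(base, k)
        if (rem > 0) {
          # extras on the folds with the smallest running totals,
          # random order among ties
          pref <- order(totals + stats::runif(k))
          extra <- pref[seq_len(rem)]
          sizes[extra] <- sizes[extra] + 1L
        }
        fold[idx] <- sample(rep(seq_len(k), sizes))
        totals <- totals + sizes
      }
    }
    fold
  })
}

#' Accuracy, sensitivity and specificity of predicted classes
#'
#' Accuracy is the proportion of correctly classified patients,
#' sensitivity the proportion of correctly classified positive-class
#' patients, specificity the proportion of correctly classified
#' negative-class patients. Unclassified predictions (discriminant zero)
#' are counted as misclassifications under the default policy, or dropped
#' from all three denominators under `"exclude"`; their count is reported
#' either way.
#'
#' @param predicted predicted labels (may contain `"unclassified"`).
#' @param labels true labels.
#' @param positive positive-class level.
#' @param unclassified `"error"` (count against the metrics; default) or
#'   `"exclude"`.
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `n_unclassified`, `n`.
#' @export
classification_metrics <- function(predicted, labels, positive = NULL,
                                   unclassified = c("error", "exclude")) {
  unclassified <- match.arg(unclassified)
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(labels)) {
    stop("predicted and labels must be aligned", call. = FALSE)
  }
  is_pos <- as_binary_labels(labels, positive, allow_single = TRUE)
  positive <- attr(is_pos, "positive")
  uncls <- predicted == "unclassified"
  if (unclassified == "exclude") {
    keep <- !uncls
    predicted <- predicted[keep]; labels <- labels[keep]
    is_pos <- is_pos[keep]
  }
  correct <- predicted == as.character(labels)
  list(accuracy = mean(correct),
       sensitivity = if (any(is_pos)) mean(correct[is_pos]) else NA_real_,
       specificity = if (any(!is_pos)) mean(correct[!is_pos]) else NA_real_,
       n_unclassified = sum(uncls),
       n = length(correct))
}

#' Repeated stratified k-fold cross-validation of the LAD pipeline
#'
#' For each of `repeats` rerandomizations the cohort is partitioned into
#' `k` folds; for each fold the *entire* train pipeline — cutpoints,
#' degree-1 screen, support set, pattern enumeration and model selection —
#' is refit on the training folds only and applied to the held-out fold,
#' so there is no information leakage from test patients into any training
#' stage. A training split on which the pipeline fails (e.g. an absent
#' class) is recorded as a failed test, not silently dropped; the report
#' always contains `k * repeats` records.
#'
#' Dispersion is reported two ways: the standard deviation across all
#' `k * repeats` per-fold records, and the standard deviation of the
#' per-repeat means (the two conventions found in CV write-ups).
#'
#' @param x labeled [feature_matrix()] or numeric matrix.
#' @param y labels when `x` is a bare matrix.
#' @param k,repeats fold count and number of rerandomizations.
#' @param seed master seed; repeat `r` uses a seed derived from it.
#' @param stratified stratify folds by class.
#' @param unclassified metric policy, see [classification_metrics()].
#' @param positive positive-class level.
#' @param ... passed to [lad()].
#' @return an object of class `"lad_cv"`: list with `records` (one row
#'   per fold x repeat: accuracy, sensitivity, specificity, unclassified
#'   and test counts, failure flag), `summary` (mean and both dispersion
#'   conventions per metric), and `config`.
#' @export
lad_cv <- function(x, y = NULL, k = 10L, repeats = 10L, seed = 1L,
                   stratified = TRUE, unclassified = "error",
                   positive = NULL, ...) {
  vals <- get_values(x)
  if (is.null(colnames(vals))) colnames(vals) <- as.character(seq_len(ncol(vals)))
  if (is.null(y) && inherits(x, "feature_matrix")) y <- x$labels
  y <- as.character(y)
  check_number(repeats, "repeats", lower = 1, integer = TRUE)
  is_pos <- as_binary_labels(y, positive)
  positive <- attr(is_pos, "positive")

  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, k = k, seed = derive_seed(seed, r),
                       stratified = stratified)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      res <- tryCatch({
        fit <- lad(vals[train, , drop = FALSE], y[train],
                   positive = positive, ...)
        pred <- predict(fit, vals[test, , drop = FALSE], type = "class")
        m <- classification_metrics(pred, y[test], positive = positive,
                                    unclassified = unclassified)
        data.frame(repeat_ = r, fold = f, n_test = length(test),
                   accuracy = m$accuracy, sensitivity = m$sensitivity,
                   specificity = m$specificity,
                   n_unclassified = m$n_unclassified,
                   failed = FALSE, error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(repeat_ = r, fold = f, n_test = length(test),
                   accuracy = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, n_unclassified = NA_integer_,
                   failed = TRUE, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  records <- do.call(rbind, rows)

  agg <- function(metric) {
    v <- records[[metric]]
    per_repeat <- tapply(v, records$repeat_, mean, na.rm = TRUE)
    c(mean = mean(v, na.rm = TRUE),
      sd_folds = stats::sd(v[!is.na(v)]),
      sd_repeat_means = stats::sd(per_repeat))
  }
  summary <- rbind(accuracy = agg("accuracy"),
                   sensitivity = agg("sensitivity"),
                   specificity = agg("specificity"))
  structure(list(records = records, summary = summary,
                 config = list(k = k, repeats = repeats, seed = seed,
                               stratified = stratified,
                               unclassified = unclassified,
                               positive = positive),
                 n_tests = nrow(records),
                 n_failed = sum(records$failed)),
            class = "lad_cv")
}

#' @export
print.lad_cv <- function(x, ...) {
  cat(sprintf("LAD cross-validation: %d x %d-fold = %d tests (%d failed)\n",
              x$config$repeats, x$config$k, x$n_tests, x$n_failed))
  s <- x$summary
  for (m in rownames(s)) {
    cat(sprintf("  %-12s %.3f (sd over folds %.3f; sd of repeat means %.3f)\n",
                m, s[m, "mean"], s[m, "sd_folds"], s[m, "sd_repeat_means"]))
  }
  invisible(x)
}

#' Serialize a CV report as JSON (summary + per-test records)
#' @param cv a `"lad_cv"`; `file` a path.
#' @return `file`, invisibly.
#' @export
write_cv_report <- function(cv, file) {
  stopifnot(inherits(cv, "lad_cv"))
  jsonlite::write_json(list(config = cv$config,
                            summary = as.data.frame(cv$summary),
                            records = cv$records),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
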