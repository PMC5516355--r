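#' Quantile risk stratification of scored patients
#'
#' Patients are sorted by ascending (risk score, patient id) — the id
#' breaks ties so the partition is a total order — and split into `g`
#' contiguous groups of near-equal size; when the cohort size is not a
#' multiple of `g`, the remainder patients go to the highest-score groups
#' (116 patients in quintiles gives sizes 23, 23, 23, 23, 24). Per group,
#' the table reports the patient count, the percentage of positive-class
#' patients, the mean risk score and the score boundaries.
#'
#' @param risk numeric risk scores (e.g. [predict.lad()] with
#'   `type = "response"`, or any numeric severity score such as a
#'   proteinuria ratio).
#' @param labels class labels aligned with `risk`.
#' @param g number of groups (default 5, i.e. quintiles).
#' @param ids patient identifiers for tie-breaking (default: index order).
#' @param positive positive-class level.
#' @return a data frame of class `"risk_group_table"` with columns
#'   `group`, `n`, `pct_positive`, `mean_risk`, `min_risk`, `max_risk`,
#'   and attribute `"assignment"` (group per patient, original order).
#' @export
risk_groups <- function(risk, labels, g = 5L, ids = NULL, positive = NULL) {
  check_number(g, "g", lower = 2, integer = TRUE)
  n <- length(risk)
  if (n < g) stop("cohort smaller than the number of groups", call. = FALSE)
  is_pos <- as_binary_labels(labels, positive)
  if (is.null(ids)) ids <- sprintf("%06d", seq_len(n))
  ord <- order(risk, ids)
  base <- n %/% g; rem <- n %% g
  sizes <- c(rep(base, g - rem), rep(base + 1L, rem))
  grp_sorted <- rep(seq_len(g), sizes)
  grp <- integer(n); grp[ord] <- grp_sorted
  tab <- do.call(rbind, lapply(seq_len(g), function(k) {
    in_k <- grp == k
    data.frame(group = k, n = sum(in_k),
               pct_positive = 100 * mean(is_pos[in_k]),
               mean_risk = mean(risk[in_k]),
               min_risk = min(risk[in_k]), max_risk = max(risk[in_k]))
  }))
  attr(tab, "assignment") <- grp
  class(tab) <- c("risk_group_table", "data.frame")
  tab
}

#' @export
print.risk_group_table <- function(x, ...) {
  cat("Risk groups (ascending score)\n")
  df <- as.data.frame(x)
  df$pct_positive <- sprintf("%.2f", df$pct_positive)
  df$mean_risk <- sprintf("%.3f", df$mean_risk)
  print(df[c("group", "n", "pct_positive", "mean_risk")], row.names = FALSE)
  invisible(x)
}

#' Area under the ROC curve with a confidence interval
#'
#' AUC computed as the Mann-Whitney probability that a random
#' positive-class score exceeds a random negative-class score, with ties
#' counted one half. The default confidence interval uses the
#' Hanley-McNeil normal approximation of the AUC standard error; a seeded
#' nonparametric bootstrap (patients resampled with replacement,
#' percentile interval) is available for comparison. The interval method
#' is recorded in the output.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels class labels; both classes must be present.
#' @param positive positive-class level.
#' @param ci `"hanley"` or `"bootstrap"`.
#' @param conf confidence level.
#' @param boot bootstrap replicate count.
#' @param seed bootstrap seed.
#' @return an object of class `"lad_auc"`: list with `auc`, `ci`
#'   (length 2), `se` (Hanley-McNeil), `ci_method`, `n_positive`,
#'   `n_negative`.
#' @export
lad_auc <- function(scores, labels, positive = NULL,
                    ci = c("hanley", "bootstrap"), conf = 0.95,
                    boot = 2000L, seed = 1L) {
  ci <- match.arg(ci)
  is_pos <- as_binary_labels(labels, positive, allow_single = TRUE)
  if (all(is_pos) || !any(is_pos)) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  auc <- auc_rank(scores, is_pos)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  interval <- if (ci == "hanley") {
    c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    with_seed(seed, {
      reps <- vapply(seq_len(boot), function(b) {
        idx <- sample.int(length(scores), replace = TRUE)
        if (all(is_pos[idx]) || !any(is_pos[idx])) return(NA_real_)
        auc_rank(scores[idx], is_pos[idx])
      }, numeric(1))
      stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                      na.rm = TRUE, names = FALSE)
    })
  }
  structure(list(auc = auc, ci = interval, se = se, ci_method = ci,
                 conf = conf, n_positive = n1, n_negative = n0),
            class = "lad_auc")
}

# Mann-Whitney AUC via midranks (ties counted 1/2)
auc_rank <- function(scores, is_pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.lad_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f, %s; %d positive vs %d negative)\n",
              x$auc, round(100 * x$conf), x$ci[1], x$ci[2],
              if (x$ci_method == "hanley") "Hanley-McNeil" else "bootstrap",
              x$n_positive, x$n_negative))
  invisible(x)
}
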