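#' Fit a logical-analysis-of-data (LAD) classification model
#'
#' Runs the full LAD train pipeline on a labeled feature matrix:
#' \enumerate{
#'   \item essential-cutpoint discretization of every feature;
#'   \item a degree-1 pattern screen that retains features carrying at
#'     least one single-literal pattern with homogeneity and prevalence at
#'     or above `filter_homogeneity` / `filter_prevalence`;
#'   \item greedy minimal support-set selection over the binary (threshold)
#'     features of the retained features, yielding a small set of source
#'     masses that jointly distinguish every positive-negative patient
#'     pair;
#'   \item exhaustive enumeration of degree-`max_degree` candidate
#'     patterns over the support-set features at the (laxer) candidate
#'     thresholds;
#'   \item greedy selection of a small pattern model covering every
#'     training patient of each class.
#' }
#'
#' When the screen retains fewer than `min_filter_features` features (as
#' happens on weakly structured or label-permuted data), both screen
#' thresholds are relaxed deterministically in multiplicative steps of 0.9
#' until enough features pass; if the floor is reached the best
#' `max_filter_features` features by degree-1 screening margin are used.
#' The thresholds actually applied are recorded on the fit. Similarly, if
#' the candidate pool leaves some own-class training patient uncovered,
#' the single best pattern covering that patient (highest homogeneity,
#' then prevalence) over the support-set features is added to the pool
#' before model selection, so the assembled model always attains full
#' training coverage unless a positive and a negative patient share an
#' identical feature vector.
#'
#' @param x a [feature_matrix()], or a numeric matrix (patients x
#'   features) with column names.
#' @param y class labels (ignored when `x` is a feature matrix that
#'   carries labels and `y` is missing).
#' @param positive label of the positive class (default: first factor
#'   level).
#' @param filter_homogeneity,filter_prevalence degree-1 screen thresholds.
#' @param pattern_homogeneity,pattern_prevalence candidate-pattern
#'   thresholds for the model stage.
#' @param max_degree maximum literals per pattern (1 or 2).
#' @param min_filter_features minimum features the screen must retain
#'   before the relaxation ladder stops.
#' @param max_filter_features cap used by the final ranking fallback.
#' @param support `"greedy"` (default) or `"exhaustive"` (small instances
#'   only).
#' @return an object of class `"lad"` with components `positive_patterns`,
#'   `negative_patterns`, `P`, `N`, `support_set`, `cutpoints`,
#'   `filter` (thresholds used and features retained), `levels`,
#'   `positive` and `call`. Methods: [predict.lad()], `print`, `summary`,
#'   [coef.lad()], [plot.lad()].
#' @examples
#' set.seed(1)
#' x <- cbind(a = c(rnorm(10, 0), rnorm(10, 3)), b = rnorm(20))
#' fit <- lad(x, rep(c("slow", "rapid"), each = 10), positive = "rapid")
#' fit
#' predict(fit, x)
#' @export
lad <- function(x, y = NULL, positive = NULL,
                filter_homogeneity = 0.8, filter_prevalence = 0.8,
                pattern_homogeneity = 0.75, pattern_prevalence = 0.3,
                max_degree = 2L, min_filter_features = 2L,
                max_filter_features = 30L, support = c("greedy", "exhaustive")) {
  support <- match.arg(support)
  vals <- get_values(x)
  if (is.null(colnames(vals))) {
    colnames(vals) <- as.character(seq_len(ncol(vals)))
  }
  if (is.null(y) && inherits(x, "feature_matrix")) y <- x$labels
  is_pos <- as_binary_labels(y, positive)
  positive <- attr(is_pos, "positive")
  negative <- attr(is_pos, "negative")
  labels <- ifelse(is_pos, positive, negative)

  cuts <- feature_cutpoints(vals, labels, positive)

  # degree-1 screen with deterministic relaxation ladder; literal stats are
  # computed once, the ladder only re-applies thresholds
  st <- literal_screen_stats(vals, cuts, is_pos)
  h <- filter_homogeneity; p <- filter_prevalence
  retained <- screen_features(st, h, p)
  scores <- attr(retained, "scores")
  relaxed <- FALSE
  while (length(retained) < min_filter_features && (h > 0.5 || p > 0.1)) {
    h <- max(0.5, h * 0.9); p <- max(0.1, p * 0.9)
    relaxed <- TRUE
    retained <- screen_features(st, h, p)
  }
  if (length(retained) < min_filter_features) {
    # floor reached: rank all discretizable features by screening margin
    retained <- names(sort(scores, decreasing = TRUE))
    retained <- utils::head(retained, max_filter_features)
    relaxed <- TRUE
  } else if (length(retained) > max_filter_features) {
    keep <- names(sort(scores[retained], decreasing = TRUE))
    retained <- retained[retained %in% utils::head(keep, max_filter_features)]
  }
  if (length(retained) == 0L) {
    stop("no discretizable feature available; cannot fit", call. = FALSE)
  }

  cuts_ret <- structure(list(cutpoints = cuts$cutpoints[retained],
                             features = retained), class = "cutpoint_set")
  bin <- binarize(vals[, retained, drop = FALSE], cuts_ret, labels)
  ss <- if (support == "greedy") greedy_support_set(bin, positive) else
    exhaustive_support_set(bin, positive = positive)

  cand_pos <- enumerate_patterns(vals, cuts_ret, "positive",
                                 features = ss$features,
                                 max_degree = max_degree,
                                 min_homogeneity = pattern_homogeneity,
                                 min_prevalence = pattern_prevalence,
                                 labels = labels, positive = positive)
  cand_neg <- enumerate_patterns(vals, cuts_ret, "negative",
                                 features = ss$features,
                                 max_degree = max_degree,
                                 min_homogeneity = pattern_homogeneity,
                                 min_prevalence = pattern_prevalence,
                                 labels = labels, positive = positive)
  cand_pos <- repair_coverage(cand_pos, "positive", vals, cuts_ret,
                              ss$features, max_degree, labels, positive)
  cand_neg <- repair_coverage(cand_neg, "negative", vals, cuts_ret,
                              ss$features, max_degree, labels, positive)

  model <- select_model(c(cand_pos, cand_neg), vals, labels, positive)
  model$cutpoints <- cuts_ret
  model$support_set <- ss
  model$filter <- list(homogeneity = h, prevalence = p, relaxed = relaxed,
                       retained = retained,
                       requested = c(homogeneity = filter_homogeneity,
                                     prevalence = filter_prevalence))
  model$thresholds <- c(pattern_homogeneity = pattern_homogeneity,
                        pattern_prevalence = pattern_prevalence)
  model$n_candidates <- c(positive = length(cand_pos),
                          negative = length(cand_neg))
  model$call <- match.call()
  model
}

# for each own-class patient not covered by any candidate, add the best
# degree <= max_degree pattern over `features` that covers it
repair_coverage <- function(cands, sign, vals, cuts, features, max_degree,
                            labels, positive) {
  is_pos <- as_binary_labels(labels, positive)
  own <- if (sign == "positive") which(is_pos) else which(!is_pos)
  covered <- unique(unlist(lapply(cands, `[[`, "covered")))
  missing <- setdiff(own, covered)
  for (i in missing) {
    best <- best_pattern_covering(i, sign, vals, cuts, features, max_degree,
                                  labels, positive)
    if (!is.null(best)) cands[[length(cands) + 1L]] <- best
  }
  cands
}

best_pattern_covering <- function(i, sign, vals, cuts, features, max_degree,
                                  labels, positive) {
  is_pos <- as_binary_labels(labels, positive)
  own <- if (sign == "positive") is_pos else !is_pos
  lits <- literal_space(cuts, features)
  if (nrow(lits) == 0L) return(NULL)
  L <- literal_truth(lits, vals)
  sat <- which(L[i, ])  # literals the target patient satisfies
  if (length(sat) == 0L) return(NULL)
  if (length(sat) > 40L) {
    # bound the pair search: keep the literals with the purest own-class
    # coverage (then broadest), which is where the best conjunctions live
    own_cnt <- colSums(L[own, sat, drop = FALSE])
    tot_cnt <- colSums(L[, sat, drop = FALSE])
    ord <- order(-own_cnt / pmax(tot_cnt, 1L), -own_cnt)
    sat <- sat[ord[seq_len(40L)]]
  }
  best <- NULL
  consider <- function(idx) {
    cov <- if (length(idx) == 1L) L[, idx] else L[, idx[1]] & L[, idx[2]]
    n_own <- sum(own[cov])
    if (n_own == 0L) return()
    hom <- n_own / sum(cov)
    prev <- n_own / sum(own)
    if (is.null(best) || hom > best$homogeneity ||
        (hom == best$homogeneity && prev > best$prevalence)) {
      best <<- new_pattern(sign, lits[idx, , drop = FALSE], prev, hom,
                           which(cov))
    }
  }
  for (a in sat) consider(a)
  if (max_degree >= 2L && length(sat) >= 2L) {
    for (ai in seq_len(length(sat) - 1L)) {
      for (bi in (ai + 1L):length(sat)) {
        a <- sat[ai]; b <- sat[bi]
        if (lits$feature[a] != lits$feature[b]) consider(c(a, b))
      }
    }
  }
  best
}

#' Assemble a pattern model by greedy cover of the training patients
#'
#' Per sign, repeatedly selects the candidate pattern covering the most
#' still-uncovered own-class patients (ties broken by higher homogeneity,
#' then higher prevalence, then lexicographic literal order), then prunes,
#' in reverse selection order, any pattern whose own-class patients are
#' all covered by the remaining ones. The assembled model satisfies
#' coverage completeness: every training patient is covered by at least
#' one pattern of their own sign.
#'
#' @param candidates list of `"lad_pattern"` of both signs (with covered
#'   sets, i.e. produced by [enumerate_patterns()] or [pattern_stats()]).
#' @param x training matrix (used only for patient count and ids).
#' @param labels,positive training class labels.
#' @return an object of class `"lad"` (without the fit metadata that
#'   [lad()] adds).
#' @export
select_model <- function(candidates, x, labels = NULL, positive = NULL) {
  vals <- get_values(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  is_pos <- as_binary_labels(labels, positive)
  positive <- attr(is_pos, "positive")
  negative <- attr(is_pos, "negative")
  ids <- rownames(vals) %||% as.character(seq_len(nrow(vals)))

  pick_side <- function(sign) {
    own <- if (sign == "positive") which(is_pos) else which(!is_pos)
    side <- Filter(function(p) p$sign == sign, candidates)
    cov_union <- unique(unlist(lapply(side, `[[`, "covered")))
    not_cov <- setdiff(own, cov_union)
    if (length(not_cov)) {
      stop(sprintf("model infeasible: %s-class patient(s) %s covered by no candidate pattern",
                   sign, paste(ids[not_cov], collapse = ", ")),
           call. = FALSE)
    }
    key <- vapply(side, function(p) {
      paste(sprintf("%s|%020.10f|%s", p$literals$feature,
                    p$literals$cutpoint, p$literals$direction),
            collapse = "&")
    }, "")
    uncovered <- own
    sel <- integer(0)
    while (length(uncovered)) {
      gain <- vapply(side, function(p) length(intersect(p$covered, uncovered)),
                     integer(1))
      if (length(sel)) gain[sel] <- -1L
      best <- which(gain == max(gain))
      if (length(best) > 1L) {
        hm <- vapply(side[best], `[[`, 0, "homogeneity")
        best <- best[hm == max(hm)]
      }
      if (length(best) > 1L) {
        pv <- vapply(side[best], `[[`, 0, "prevalence")
        best <- best[pv == max(pv)]
      }
      if (length(best) > 1L) best <- best[order(key[best])[1L]]
      sel <- c(sel, best)
      uncovered <- setdiff(uncovered, side[[best]]$covered)
    }
    # reverse prune
    keep <- rep(TRUE, length(sel))
    for (i in rev(seq_along(sel))) {
      keep[i] <- FALSE
      cov <- unique(unlist(lapply(side[sel[keep]], `[[`, "covered")))
      if (!all(own %in% cov)) keep[i] <- TRUE
    }
    side[sel[keep]]
  }

  pos_pat <- pick_side("positive")
  neg_pat <- pick_side("negative")
  structure(list(positive_patterns = pos_pat,
                 negative_patterns = neg_pat,
                 P = length(pos_pat), N = length(neg_pat),
                 positive = positive, negative = negative,
                 levels = c(positive, negative),
                 train_ids = ids, train_labels = as.character(labels)),
            class = "lad")
}

#' Discriminant, risk score and predicted class for patient vectors
#'
#' For a model with `P` positive and `N` negative patterns, a patient
#' covered by `p` positive and `n` negative patterns has discriminant
#' `delta = p/P - n/N` in `[-1, 1]`; the predicted class follows the sign
#' of `delta`, with `delta = 0` reported as unclassified (never silently
#' coerced). The risk score `(delta + 1)/2` rescales the discriminant to
#' `[0, 1]`.
#'
#' @param model a `"lad"` model.
#' @param newdata matrix / feature matrix / named numeric vector.
#' @return data frame with columns `p`, `n`, `delta`, `risk`, `class`
#'   (one row per patient).
#' @export
discriminant <- function(model, newdata) {
  stopifnot(inherits(model, "lad"))
  vals <- get_values_vec(newdata)
  p <- rowSums(do.call(cbind, c(lapply(model$positive_patterns,
                                       pattern_covers, values = vals),
                                list(matrix(FALSE, nrow(vals), 0)))))
  n <- rowSums(do.call(cbind, c(lapply(model$negative_patterns,
                                       pattern_covers, values = vals),
                                list(matrix(FALSE, nrow(vals), 0)))))
  delta <- p / model$P - n / model$N
  cls <- ifelse(delta > 0, model$positive,
                ifelse(delta < 0, model$negative, "unclassified"))
  data.frame(p = as.integer(p), n = as.integer(n), delta = delta,
             risk = (delta + 1) / 2, class = cls,
             row.names = rownames(vals), stringsAsFactors = FALSE)
}

get_values_vec <- function(newdata) {
  if (inherits(newdata, "feature_matrix")) return(newdata$values)
  if (is.null(dim(newdata))) {
    return(matrix(newdata, 1L, dimnames = list(NULL, names(newdata))))
  }
  as.matrix(newdata)
}

#' Predict method for LAD models
#'
#' @param object a `"lad"` fit.
#' @param newdata patients x features matrix (or feature matrix, or a
#'   single named vector).
#' @param type `"class"` (predicted label, `"unclassified"` at
#'   discriminant zero), `"response"` (risk score in `[0, 1]`),
#'   `"discriminant"` (`delta` in `[-1, 1]`) or `"detail"` (full data
#'   frame from [discriminant()]).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.lad <- function(object, newdata,
                        type = c("class", "response", "discriminant",
                                 "detail"), ...) {
  type <- match.arg(type)
  d <- discriminant(object, newdata)
  switch(type,
         class = d$class,
         response = d$risk,
         discriminant = d$delta,
         detail = d)
}

#' @export
print.lad <- function(x, ...) {
  cat(sprintf("LAD classification model: %d positive + %d negative patterns\n",
              x$P, x$N))
  cat(sprintf("  positive class: %s; negative class: %s\n",
              x$positive, x$negative))
  if (!is.null(x$support_set)) {
    cat(sprintf("  support set: %d masses (%s)\n",
                length(x$support_set$features),
                paste(x$support_set$features, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.lad <- function(object, ...) {
  pats <- c(object$positive_patterns, object$negative_patterns)
  df <- data.frame(
    pattern = c(sprintf("P%d", seq_len(object$P)),
                sprintf("N%d", seq_len(object$N))),
    sign = vapply(pats, `[[`, "", "sign"),
    degree = vapply(pats, `[[`, 0L, "degree"),
    definition = vapply(pats, format_pattern, ""),
    prevalence = vapply(pats, `[[`, 0, "prevalence"),
    homogeneity = vapply(pats, `[[`, 0, "homogeneity"),
    stringsAsFactors = FALSE)
  structure(list(patterns = df, P = object$P, N = object$N,
                 positive = object$positive, negative = object$negative,
                 filter = object$filter,
                 support = object$support_set$features),
            class = "summary.lad")
}

#' @export
print.summary.lad <- function(x, ...) {
  cat(sprintf("LAD model: %d positive + %d negative patterns\n", x$P, x$N))
  if (!is.null(x$support)) {
    cat("Support-set masses:", paste(x$support, collapse = ", "), "\n")
  }
  if (!is.null(x$filter)) {
    cat(sprintf("Degree-1 screen: homogeneity >= %.2f, prevalence >= %.2f%s; %d features retained\n",
                x$filter$homogeneity, x$filter$prevalence,
                if (x$filter$relaxed) " (relaxed)" else "",
                length(x$filter$retained)))
  }
  df <- x$patterns
  df$prevalence <- sprintf("%.3f", df$prevalence)
  df$homogeneity <- sprintf("%.3f", df$homogeneity)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Patterns of a LAD model as a data frame
#'
#' One row per literal, with the pattern id, sign and quality statistics
#' repeated along its literals.
#' @param object a `"lad"` fit.
#' @param ... unused.
#' @return data frame.
#' @export
coef.lad <- function(object, ...) {
  pats <- c(object$positive_patterns, object$negative_patterns)
  ids <- c(sprintf("P%d", seq_len(object$P)), sprintf("N%d", seq_len(object$N)))
  do.call(rbind, lapply(seq_along(pats), function(i) {
    p <- pats[[i]]
    data.frame(pattern = ids[i], sign = p$sign, p$literals,
               prevalence = p$prevalence, homogeneity = p$homogeneity,
               stringsAsFactors = FALSE)
  }))
}

#' Coverage heatmap of a LAD model on its training data
#'
#' Patients (columns, ordered by class then discriminant) against model
#' patterns (rows); filled cells mark coverage. Mirrors the usual way LAD
#' models are displayed.
#' @param x a `"lad"` fit.
#' @param newdata matrix to display (defaults require training data to be
#'   re-supplied since the fit stores no intensities).
#' @param labels class labels for column ordering.
#' @param ... passed to [graphics::image()].
#' @export
plot.lad <- function(x, newdata, labels = NULL, ...) {
  vals <- get_values_vec(newdata)
  if (is.null(labels) && inherits(newdata, "feature_matrix")) {
    labels <- newdata$labels
  }
  pats <- c(x$positive_patterns, x$negative_patterns)
  cov <- vapply(pats, pattern_covers, logical(nrow(vals)), values = vals)
  d <- discriminant(x, vals)
  ord <- order(labels %||% rep("", nrow(vals)), -d$delta)
  graphics::image(x = seq_len(nrow(vals)), y = seq_along(pats),
                  z = cov[ord, , drop = FALSE] + 0,
                  col = c("white", "black"), xlab = "patients (sorted)",
                  ylab = "", axes = FALSE, ...)
  graphics::axis(2, at = seq_along(pats),
                 labels = c(sprintf("P%d", seq_len(x$P)),
                            sprintf("N%d", seq_len(x$N))), las = 1)
  graphics::box()
  invisible(x)
}

#' Serialize / parse a LAD model as JSON
#'
#' Canonical form: fixed key order, 10-significant-digit numbers, so
#' serialize-parse-serialize is byte-identical.
#' @param model a `"lad"` fit; `file` a path.
#' @return `file` (writer) or a `"lad"` model (reader; training metadata
#'   and covered sets are not stored).
#' @export
write_model <- function(model, file) {
  stopifnot(inherits(model, "lad"))
  pat_obj <- function(p) {
    list(sign = p$sign,
         literals = lapply(seq_len(nrow(p$literals)), function(l) {
           list(mz = p$literals$feature[l],
                cutpoint = signif(p$literals$cutpoint[l], 10),
                direction = p$literals$direction[l])
         }),
         prevalence = signif(p$prevalence, 10),
         homogeneity = signif(p$homogeneity, 10))
  }
  obj <- list(positive = model$positive, negative = model$negative,
              P = model$P, N = model$N,
              positive_patterns = lapply(model$positive_patterns, pat_obj),
              negative_patterns = lapply(model$negative_patterns, pat_obj))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  parse_pat <- function(p) {
    lits <- new_literals(
      vapply(p$literals, function(l) as.character(l$mz), ""),
      vapply(p$literals, function(l) as.numeric(l$cutpoint), 0),
      vapply(p$literals, function(l) as.character(l$direction), ""))
    new_pattern(p$sign, lits, as.numeric(p$prevalence),
                as.numeric(p$homogeneity), covered = NULL)
  }
  structure(list(
    positive_patterns = lapply(obj$positive_patterns, parse_pat),
    negative_patterns = lapply(obj$negative_patterns, parse_pat),
    P = as.integer(obj$P), N = as.integer(obj$N),
    positive = obj$positive, negative = obj$negative,
    levels = c(obj$positive, obj$negative)), class = "lad")
}
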