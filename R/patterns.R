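# Conjunctive patterns over threshold literals. A literal is
# (feature, cutpoint, direction) with direction ">=" or "<"; a pattern is a
# signed conjunction of literals scored by prevalence (fraction of own-class
# patients covered) and homogeneity (fraction of covered patients that are
# own-class).

new_literals <- function(feature, cutpoint, direction) {
  if (!all(direction %in% c(">=", "<"))) {
    stop("literal direction must be '>=' or '<'", call. = FALSE)
  }
  data.frame(feature = as.character(feature),
             cutpoint = as.numeric(cutpoint),
             direction = as.character(direction),
             stringsAsFactors = FALSE)
}

new_pattern <- function(sign, literals, prevalence, homogeneity, covered) {
  if (nrow(literals) < 1L) {
    stop("a pattern must have degree >= 1", call. = FALSE)
  }
  if (anyDuplicated(literals[c("feature", "cutpoint")])) {
    stop("a pattern may not repeat a (feature, cutpoint) literal",
         call. = FALSE)
  }
  if (!sign %in% c("positive", "negative")) {
    stop("pattern sign must be 'positive' or 'negative'", call. = FALSE)
  }
  structure(list(sign = sign, literals = literals,
                 degree = nrow(literals),
                 prevalence = prevalence, homogeneity = homogeneity,
                 covered = covered),
            class = "lad_pattern")
}

#' Render a pattern as text
#'
#' Produces the conventional reading, e.g.
#' `"m/z 9940 < 0.575 AND m/z 11274 >= 0.055"`.
#' @param x a `"lad_pattern"` (or its literal data frame).
#' @return a single string.
#' @export
format_pattern <- function(x) {
  lits <- if (inherits(x, "lad_pattern")) x$literals else x
  paste(sprintf("m/z %s %s %g", lits$feature, lits$direction, lits$cutpoint),
        collapse = " AND ")
}

#' Parse a rendered pattern back into literals
#'
#' Inverse of [format_pattern()]; accepts `>=`, `<` and (as a synonym used
#' in informal write-ups) `>` which is mapped to `>=` — on midpoint
#' cutpoints the two never differ on training data.
#' @param text rendered pattern string.
#' @param sign `"positive"` or `"negative"`.
#' @param x optional labeled matrix; when given, the parsed literals are
#'   scored with [pattern_stats()] and a full pattern is returned.
#' @param labels,positive class labels when `x` is a bare matrix.
#' @return a literal data frame, or a `"lad_pattern"` when `x` is supplied.
#' @export
parse_pattern <- function(text, sign = "positive", x = NULL, labels = NULL,
                          positive = NULL) {
  parts <- strsplit(text, "\\s+AND\\s+")[[1]]
  m <- regmatches(parts,
                  regexec("^m/z\\s+(\\S+)\\s+(>=|<|>)\\s+(\\S+)$", parts))
  if (any(lengths(m) != 4L)) {
    stop(sprintf("cannot parse pattern text: '%s'", text), call. = FALSE)
  }
  dir <- vapply(m, `[`, "", 3L)
  dir[dir == ">"] <- ">="
  lits <- new_literals(vapply(m, `[`, "", 2L), as.numeric(vapply(m, `[`, "", 4L)),
                       dir)
  if (is.null(x)) return(lits)
  pattern_stats(lits, sign, x, labels = labels, positive = positive)
}

#' @export
print.lad_pattern <- function(x, ...) {
  cat(sprintf("%s pattern (degree %d): %s\n", x$sign, x$degree,
              format_pattern(x)))
  cat(sprintf("  prevalence %.3f, homogeneity %.3f, covers %d patient(s)\n",
              x$prevalence, x$homogeneity, length(x$covered)))
  invisible(x)
}

get_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

literal_truth <- function(lits, vals) {
  missing <- setdiff(unique(lits$feature), colnames(vals))
  if (length(missing)) {
    stop(sprintf("pattern references missing feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- matrix(TRUE, nrow(vals), nrow(lits))
  col_of <- match(lits$feature, colnames(vals))
  ge <- lits$direction == ">="
  for (l in seq_len(nrow(lits))) {
    v <- vals[, col_of[l]]
    out[, l] <- if (ge[l]) v >= lits$cutpoint[l] else v < lits$cutpoint[l]
  }
  out
}

#' Does a pattern cover a patient?
#'
#' TRUE iff every literal of the pattern holds on the patient's feature
#' vector.
#' @param pattern a `"lad_pattern"` (or literal data frame).
#' @param values a named numeric vector, or a matrix with feature column
#'   names (then a logical vector per row is returned).
#' @return logical scalar or vector.
#' @export
pattern_covers <- function(pattern, values) {
  lits <- if (inherits(pattern, "lad_pattern")) pattern$literals else pattern
  if (is.null(dim(values))) {
    values <- matrix(values, 1L, dimnames = list(NULL, names(values)))
  }
  truth <- literal_truth(lits, values)
  as.vector(rowSums(truth) == ncol(truth))
}

#' Score a conjunction of literals on a labeled matrix
#'
#' Computes the exact covered set and the two pattern-quality statistics:
#' prevalence, the proportion of own-class patients the pattern covers, and
#' homogeneity, the proportion of own-class patients among all patients
#' covered. Counting is integer-exact. A conjunction covering no own-class
#' patient is not a valid pattern and yields `NULL` (a rejection signal,
#' not an error).
#'
#' @param literals a literal data frame (see [format_pattern()]) or a
#'   `"lad_pattern"`.
#' @param sign `"positive"` or `"negative"` (the own class).
#' @param x a [feature_matrix()] or numeric matrix with named columns.
#' @param labels,positive class labels when `x` is a bare matrix.
#' @return a `"lad_pattern"`, or `NULL` when no own-class patient is
#'   covered.
#' @export
pattern_stats <- function(literals, sign, x, labels = NULL, positive = NULL) {
  lits <- if (inherits(literals, "lad_pattern")) literals$literals else literals
  vals <- get_values(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  is_pos <- as_binary_labels(labels, positive)
  own <- if (sign == "positive") is_pos else !is_pos
  covered <- which(pattern_covers(lits, vals))
  n_own_cov <- sum(own[covered])
  if (n_own_cov == 0L) return(NULL)
  new_pattern(sign, lits,
              prevalence = n_own_cov / sum(own),
              homogeneity = n_own_cov / length(covered),
              covered = covered)
}

# All single literals over the allowed features: both directions per
# cutpoint, ordered by feature (matrix column order), cutpoint, then
# direction (">=" before "<")
literal_space <- function(cuts, features) {
  feats <- intersect(features, names(cuts$cutpoints))
  lit <- do.call(rbind, lapply(feats, function(f) {
    cp <- cuts$cutpoints[[f]]
    if (length(cp) == 0L) return(NULL)
    new_literals(rep(f, 2L * length(cp)), rep(cp, each = 2L),
                 rep(c(">=", "<"), length(cp)))
  }))
  if (is.null(lit)) new_literals(character(0), numeric(0), character(0))
  else lit
}

#' Enumerate bounded-degree patterns meeting quality thresholds
#'
#' Exhaustively enumerates conjunctions of threshold literals of degree up
#' to `max_degree` (degree 2 pairs literals on two *distinct* features)
#' over the allowed features, scores each with [pattern_stats()], and
#' returns every pattern whose prevalence and homogeneity meet the
#' thresholds. The literal space is induced by the supplied cutpoints (both
#' directions of every cutpoint). Output order is deterministic: by degree,
#' then literal order (feature, cutpoint, direction).
#'
#' @param x a [feature_matrix()] or numeric matrix with named columns.
#' @param cuts a [feature_cutpoints()] result.
#' @param sign `"positive"` or `"negative"`.
#' @param features allowed source features (default: all with cutpoints).
#' @param max_degree 1 or 2 (higher values are not enumerated).
#' @param min_homogeneity,min_prevalence thresholds in `[0, 1]`. The
#'   degree-1 screening stage conventionally uses 0.8/0.8; degree-2 model
#'   candidates need a lower prevalence floor since final models average
#'   well under 80% prevalence per pattern.
#' @param labels,positive class labels when `x` is a bare matrix.
#' @return list of `"lad_pattern"` objects (possibly empty).
#' @export
enumerate_patterns <- function(x, cuts, sign = "positive", features = NULL,
                               max_degree = 2L, min_homogeneity = 0.75,
                               min_prevalence = 0.3, labels = NULL,
                               positive = NULL) {
  stopifnot(max_degree >= 1L)
  if (max_degree > 2L) max_degree <- 2L
  check_number(min_homogeneity, "min_homogeneity", lower = 0, upper = 1)
  check_number(min_prevalence, "min_prevalence", lower = 0, upper = 1)
  vals <- get_values(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  is_pos <- as_binary_labels(labels, positive)
  own <- if (sign == "positive") is_pos else !is_pos
  if (is.null(features)) features <- names(cuts$cutpoints)
  lits <- literal_space(cuts, features)
  if (nrow(lits) == 0L) return(list())

  L <- literal_truth(lits, vals)  # patients x literals
  n_own <- sum(own)
  own_cnt <- colSums(L[own, , drop = FALSE])
  tot_cnt <- colSums(L)

  out <- list()
  keep1 <- own_cnt >= 1 & own_cnt / n_own >= min_prevalence &
    own_cnt / pmax(tot_cnt, 1L) >= min_homogeneity
  for (i in which(keep1)) {
    out[[length(out) + 1L]] <- new_pattern(
      sign, lits[i, , drop = FALSE],
      prevalence = own_cnt[i] / n_own,
      homogeneity = own_cnt[i] / tot_cnt[i],
      covered = which(L[, i]))
  }

  if (max_degree >= 2L && nrow(lits) >= 2L) {
    Ld <- L + 0
    own2 <- crossprod(Ld[own, , drop = FALSE])   # own-class joint counts
    tot2 <- crossprod(Ld)                        # total joint counts
    same_feat <- outer(lits$feature, lits$feature, `==`)
    cand <- which(upper.tri(own2) & !same_feat & own2 >= 1 &
                    own2 / n_own >= min_prevalence &
                    own2 / pmax(tot2, 1) >= min_homogeneity,
                  arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        out[[length(out) + 1L]] <- new_pattern(
          sign, rbind(lits[i, ], lits[j, ]),
          prevalence = own2[i, j] / n_own,
          homogeneity = own2[i, j] / tot2[i, j],
          covered = which(L[, i] & L[, j]))
      }
    }
  }
  out
}

# per-literal degree-1 coverage counts over the full literal space; computed
# once so threshold sweeps are cheap
literal_screen_stats <- function(vals, cuts, is_pos) {
  lits <- literal_space(cuts, names(cuts$cutpoints))
  if (nrow(lits) == 0L) {
    return(list(lits = lits, pos_cnt = integer(0), neg_cnt = integer(0),
                n_pos = sum(is_pos), n_neg = sum(!is_pos)))
  }
  L <- literal_truth(lits, vals)
  pos_cnt <- colSums(L[is_pos, , drop = FALSE])
  neg_cnt <- colSums(L[!is_pos, , drop = FALSE])
  list(lits = lits, pos_cnt = pos_cnt, neg_cnt = neg_cnt,
       n_pos = sum(is_pos), n_neg = sum(!is_pos))
}

# apply the two-threshold screen to precomputed stats
screen_features <- function(st, min_homogeneity, min_prevalence) {
  if (nrow(st$lits) == 0L) {
    return(structure(character(0),
                     scores = stats::setNames(numeric(0), character(0))))
  }
  tot_cnt <- st$pos_cnt + st$neg_cnt
  q_pos <- ifelse(st$pos_cnt >= 1,
                  pmin(st$pos_cnt / st$n_pos, st$pos_cnt / pmax(tot_cnt, 1)),
                  0)
  q_neg <- ifelse(st$neg_cnt >= 1,
                  pmin(st$neg_cnt / st$n_neg, st$neg_cnt / pmax(tot_cnt, 1)),
                  0)
  pass <- (st$pos_cnt >= 1 & st$pos_cnt / st$n_pos >= min_prevalence &
             st$pos_cnt / pmax(tot_cnt, 1) >= min_homogeneity) |
    (st$neg_cnt >= 1 & st$neg_cnt / st$n_neg >= min_prevalence &
       st$neg_cnt / pmax(tot_cnt, 1) >= min_homogeneity)
  feat_order <- unique(st$lits$feature)
  q_best <- pmax(q_pos, q_neg)
  scores <- vapply(split(q_best, factor(st$lits$feature, levels = feat_order)),
                   max, numeric(1))
  retained <- feat_order[feat_order %in% unique(st$lits$feature[pass])]
  structure(retained, scores = scores)
}

#' Degree-1 pattern screen for relevant features
#'
#' Retains the features that participate in at least one degree-1 pattern
#' of either sign meeting the homogeneity and prevalence thresholds (the
#' conventional screen uses 0.8/0.8). Order follows the matrix column
#' order (ascending bin center for binned spectra). The returned vector
#' carries, as the `"scores"` attribute, each feature's best degree-1
#' pattern quality `min(prevalence, homogeneity)` — the screening margin,
#' used for diagnostics and for ranking under relaxed thresholds.
#'
#' @inheritParams enumerate_patterns
#' @param min_homogeneity,min_prevalence screen thresholds.
#' @return character vector of retained feature names, with attribute
#'   `"scores"` (named numeric, all features with >= 1 cutpoint).
#' @export
degree1_feature_filter <- function(x, cuts = NULL, min_homogeneity = 0.8,
                                   min_prevalence = 0.8, labels = NULL,
                                   positive = NULL) {
  vals <- get_values(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  if (is.null(cuts)) cuts <- feature_cutpoints(vals, labels, positive)
  is_pos <- as_binary_labels(labels, positive)
  st <- literal_screen_stats(vals, cuts, is_pos)
  screen_features(st, min_homogeneity, min_prevalence)
}

#' Serialize / parse patterns as JSON
#'
#' Each pattern is written as
#' `{sign, literals: [{mz, cutpoint, direction}], prevalence, homogeneity}`.
#' Values are rounded to 10 significant digits so that
#' serialize-parse-serialize is byte-identical.
#'
#' @param patterns list of `"lad_pattern"`; `file` a path.
#' @return `file` (writer) or a list of `"lad_pattern"` (reader; covered
#'   sets are not stored and come back `NULL` until re-scored).
#' @export
write_patterns <- function(patterns, file) {
  obj <- lapply(patterns, function(p) {
    list(sign = p$sign,
         literals = lapply(seq_len(nrow(p$literals)), function(l) {
           list(mz = p$literals$feature[l],
                cutpoint = signif(p$literals$cutpoint[l], 10),
                direction = p$literals$direction[l])
         }),
         prevalence = signif(p$prevalence, 10),
         homogeneity = signif(p$homogeneity, 10))
  })
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(obj, function(p) {
    lits <- new_literals(
      vapply(p$literals, function(l) as.character(l$mz), ""),
      vapply(p$literals, function(l) as.numeric(l$cutpoint), 0),
      vapply(p$literals, function(l) as.character(l$direction), ""))
    new_pattern(p$sign, lits, as.numeric(p$prevalence),
                as.numeric(p$homogeneity), covered = NULL)
  })
}
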