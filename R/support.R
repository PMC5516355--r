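# Support-set selection: find a small subset of binary (threshold) features
# that distinguishes every positive-negative patient pair. The universe of a
# set-cover instance is the set of opposite-class pairs; a column covers a
# pair when the two patients take different values on it.

# pairs x columns logical matrix: D[p, j] is TRUE when column j separates
# opposite-class pair p; also returns the pair index table
pair_separation <- function(bin, positive = NULL) {
  stopifnot(inherits(bin, "binary_matrix"))
  is_pos <- as_binary_labels(bin$labels, positive)
  pos <- which(is_pos); neg <- which(!is_pos)
  pairs <- expand.grid(pos = pos, neg = neg, KEEP.OUT.ATTRS = FALSE)
  D <- bin$B[pairs$pos, , drop = FALSE] != bin$B[pairs$neg, , drop = FALSE]
  list(D = D, pairs = pairs)
}

infeasible_pairs_error <- function(bin, pairs, bad) {
  ids <- rownames(bin$B) %||% as.character(seq_len(nrow(bin$B)))
  shown <- utils::head(bad, 5L)
  msg <- paste(sprintf("(%s, %s)", ids[pairs$pos[shown]],
                       ids[pairs$neg[shown]]), collapse = ", ")
  stop(sprintf(paste0("support set infeasible: %d opposite-class pair(s) ",
                      "identical on every binary feature, e.g. %s"),
               length(bad), msg), call. = FALSE)
}

new_support_set <- function(bin, sel, method, trace = NULL) {
  structure(list(
    columns = unname(sel),
    literals = bin$literals[sel, , drop = FALSE],
    features = unique(bin$literals$feature[sel]),
    method = method,
    trace = trace,
    n_binary_features = ncol(bin$B)
  ), class = "support_set")
}

#' @export
print.support_set <- function(x, ...) {
  cat(sprintf("Support set (%s): %d binary features over %d source features\n",
              x$method, length(x$columns), length(x$features)))
  if (nrow(x$literals)) {
    cat(paste0("  ", sprintf("%s >= %g", x$literals$feature,
                             x$literals$cutpoint), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Greedy minimal support set
#'
#' Greedy set cover over the universe of opposite-class patient pairs: at
#' each step the column separating the most still-uncovered pairs is
#' selected (ties broken by the lowest column index), followed by a
#' reverse-order prune that removes any selected column whose pairs are all
#' covered by the others. The result is feasible (every pair separated) and
#' irredundant (no column can be dropped), though not necessarily of
#' minimum cardinality; see [exhaustive_support_set()] for the exact
#' reference solver.
#'
#' @param bin a [binarize()] result.
#' @param positive positive-class level.
#' @return an object of class `"support_set"`.
#' @export
greedy_support_set <- function(bin, positive = NULL) {
  ps <- pair_separation(bin, positive)
  D <- ps$D
  if (ncol(D) == 0L || nrow(D) == 0L) {
    if (nrow(D) > 0L) infeasible_pairs_error(bin, ps$pairs, seq_len(nrow(D)))
    return(new_support_set(bin, integer(0), "greedy"))
  }
  sep_count <- rowSums(D)
  if (any(sep_count == 0)) {
    infeasible_pairs_error(bin, ps$pairs, which(sep_count == 0))
  }
  uncovered <- rep(TRUE, nrow(D))
  sel <- integer(0)
  while (any(uncovered)) {
    cnt <- colSums(D[uncovered, , drop = FALSE])
    j <- which.max(cnt)  # first maximum = lowest column index
    sel <- c(sel, j)
    uncovered <- uncovered & !D[, j]
  }
  # reverse-order prune to irredundancy
  keep <- rep(TRUE, length(sel))
  for (i in rev(seq_along(sel))) {
    keep[i] <- FALSE
    others <- sel[keep]
    if (length(others) == 0L ||
        !all(rowSums(D[, others, drop = FALSE]) > 0)) {
      keep[i] <- TRUE
    }
  }
  sel <- sel[keep]
  new_support_set(bin, sel, "greedy")
}

#' Exhaustive minimum support set (reference solver)
#'
#' Enumerates column subsets by increasing cardinality and returns the
#' first feasible one (lexicographically smallest at the minimum size), so
#' the result is a certified minimum-cardinality support set. Intended as a
#' test oracle on small instances only; refuses instances with more than
#' `max_columns` binary features.
#'
#' @param bin a [binarize()] result.
#' @param max_columns enumeration guard.
#' @param positive positive-class level.
#' @return an object of class `"support_set"`.
#' @export
exhaustive_support_set <- function(bin, max_columns = 25L, positive = NULL) {
  ps <- pair_separation(bin, positive)
  D <- ps$D
  m <- ncol(D)
  if (m > max_columns) {
    stop(sprintf(paste0("instance has %d binary features, above the ",
                        "enumeration guard of %d; use greedy_support_set()"),
                 m, max_columns), call. = FALSE)
  }
  if (nrow(D) == 0L) return(new_support_set(bin, integer(0), "exhaustive"))
  if (m == 0L || any(rowSums(D) == 0)) {
    bad <- if (m == 0L) seq_len(nrow(D)) else which(rowSums(D) == 0)
    infeasible_pairs_error(bin, ps$pairs, bad)
  }
  np <- nrow(D)
  for (s in seq_len(m)) {
    subsets <- utils::combn(m, s)
    for (c_i in seq_len(ncol(subsets))) {
      S <- subsets[, c_i]
      if (all(.rowSums(D[, S, drop = FALSE], np, s) > 0)) {
        return(new_support_set(bin, S, "exhaustive"))
      }
    }
  }
  stop("unreachable: feasible instance with no cover", call. = FALSE)
}

#' Verify support-set invariants against its binary matrix
#'
#' Checks feasibility (every opposite-class pair separated) and
#' irredundancy (dropping any selected column breaks some pair).
#'
#' @param ss a `"support_set"`.
#' @param bin the [binarize()] result it was computed from.
#' @param positive positive-class level.
#' @return list with logical elements `feasible` and `irredundant`.
#' @export
verify_support_set <- function(ss, bin, positive = NULL) {
  ps <- pair_separation(bin, positive)
  D <- ps$D[, ss$columns, drop = FALSE]
  feasible <- nrow(D) == 0L || all(rowSums(D) > 0)
  irredundant <- all(vapply(seq_along(ss$columns), function(i) {
    rest <- D[, -i, drop = FALSE]
    ncol(rest) == 0L && nrow(D) > 0L || any(rowSums(rest) == 0)
  }, logical(1)))
  if (length(ss$columns) == 0L) irredundant <- TRUE
  list(feasible = feasible, irredundant = irredundant)
}

#' Serialize / parse a support set as JSON
#' @param ss a `"support_set"`; `file` a path.
#' @return `file` (writer) or the parsed list (reader).
#' @export
write_support_set <- function(ss, file) {
  stopifnot(inherits(ss, "support_set"))
  jsonlite::write_json(list(method = ss$method,
                            columns = ss$columns,
                            features = ss$features,
                            literals = ss$literals),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_support_set
#' @export
read_support_set <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(columns = as.integer(obj$columns),
                 literals = as.data.frame(obj$literals),
                 features = as.character(obj$features),
                 method = obj$method, trace = NULL,
                 n_binary_features = NA_integer_),
            class = "support_set")
}
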