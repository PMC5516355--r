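#' Essential cutpoints for one numeric feature
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values; a midpoint is kept ("essential") only when a class change
#' occurs across the gap — i.e. unless the observations at both bracketing
#' values belong to one and the same class. A value carried by both classes
#' therefore generates cutpoints on both of its sides. Features observed in
#' a single class yield no cutpoints.
#'
#' @param values numeric vector (one feature across patients).
#' @param labels class labels aligned with `values`.
#' @param positive level treated as the positive class (affects nothing
#'   here beyond validation; both classes are symmetric).
#' @return numeric vector of cutpoints, sorted ascending (possibly empty).
#' @examples
#' find_cutpoints(c(1, 2, 3, 4), c("a", "a", "b", "b"))  # 2.5
#' @export
find_cutpoints <- function(values, labels, positive = NULL) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  is_pos <- as_binary_labels(labels, positive, allow_single = TRUE)
  if (length(values) != length(is_pos)) {
    stop("values and labels must be aligned", call. = FALSE)
  }
  if (all(is_pos) || !any(is_pos)) return(numeric(0))
  ord <- order(values)
  v <- values[ord]; p <- is_pos[ord]
  new_val <- !duplicated(v)
  dv <- v[new_val]
  if (length(dv) < 2L) return(numeric(0))
  grp <- cumsum(new_val)
  cnt <- rowsum(cbind(p + 0L, 1L - p), grp)
  has_pos <- cnt[, 1L] > 0
  has_neg <- cnt[, 2L] > 0
  nl <- length(dv)
  a <- seq_len(nl - 1L); b <- a + 1L
  both_single <- xor(has_pos[a], has_neg[a]) & xor(has_pos[b], has_neg[b])
  same_class <- both_single & (has_pos[a] == has_pos[b])
  keep <- !same_class
  (dv[a][keep] + dv[b][keep]) / 2
}

#' Cutpoints for every feature of a labeled matrix
#'
#' @param x a [feature_matrix()] or numeric matrix.
#' @param labels class labels (taken from `x` when it is a feature matrix).
#' @param positive positive-class level.
#' @return an object of class `"cutpoint_set"`: a list with `cutpoints`
#'   (per-feature numeric vectors, named by feature) and `features`.
#' @export
feature_cutpoints <- function(x, labels = NULL, positive = NULL) {
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  if (is.null(colnames(vals))) colnames(vals) <- as.character(seq_len(ncol(vals)))
  is_pos <- as_binary_labels(labels, positive)
  cuts <- lapply(seq_len(ncol(vals)), function(j) {
    find_cutpoints(vals[, j], labels, positive = attr(is_pos, "positive"))
  })
  names(cuts) <- colnames(vals)
  structure(list(cutpoints = cuts, features = colnames(vals)),
            class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  n <- lengths(x$cutpoints)
  cat(sprintf("Cutpoint set: %d features, %d cutpoints (%d features with >= 1)\n",
              length(n), sum(n), sum(n > 0)))
  invisible(x)
}

#' Binarize a feature matrix at its cutpoints
#'
#' One binary column per (feature, cutpoint), with entry 1 iff
#' `value >= cutpoint` (the `>=` direction is the canonical stored form;
#' the `< cutpoint` literal is its complement). Because cutpoints are
#' midpoints between distinct observed values, ties cannot occur on the
#' data the cutpoints were derived from; the boundary rule matters only for
#' new data and is fixed for determinism.
#'
#' @param x a [feature_matrix()] or numeric matrix.
#' @param cuts a [feature_cutpoints()] result.
#' @param labels class labels (taken from `x` when available).
#' @return an object of class `"binary_matrix"`: a list with `B` (0/1
#'   integer matrix, patients x binary features), `literals` (data frame
#'   with columns `feature`, `cutpoint`), and `labels`.
#' @export
binarize <- function(x, cuts, labels = NULL) {
  vals <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  if (is.null(colnames(vals))) colnames(vals) <- as.character(seq_len(ncol(vals)))
  stopifnot(inherits(cuts, "cutpoint_set"))
  missing <- setdiff(names(cuts$cutpoints)[lengths(cuts$cutpoints) > 0],
                     colnames(vals))
  if (length(missing)) {
    stop(sprintf("cutpoints reference features absent from the matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  feats <- rep(names(cuts$cutpoints), lengths(cuts$cutpoints))
  cps <- unlist(cuts$cutpoints, use.names = FALSE)
  if (length(cps) == 0L) {
    B <- matrix(0L, nrow(vals), 0L)
  } else {
    B <- matrix(0L, nrow(vals), length(cps))
    for (l in seq_along(cps)) {
      B[, l] <- as.integer(vals[, feats[l]] >= cps[l])
    }
    colnames(B) <- sprintf("%s>=%g", feats, cps)
  }
  rownames(B) <- rownames(vals)
  structure(list(B = B,
                 literals = data.frame(feature = feats %||% character(0),
                                       cutpoint = cps %||% numeric(0),
                                       stringsAsFactors = FALSE),
                 labels = as.character(labels)),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("Binary matrix: %d patients x %d threshold features\n",
              nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Serialize / parse a cutpoint set as JSON
#' @param cuts a `"cutpoint_set"`; `file` a path.
#' @return `file` (writer) or a `"cutpoint_set"` (reader).
#' @export
write_cutpoints <- function(cuts, file) {
  stopifnot(inherits(cuts, "cutpoint_set"))
  jsonlite::write_json(list(features = cuts$features,
                            cutpoints = cuts$cutpoints),
                       file, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_cutpoints
#' @export
read_cutpoints <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  cuts <- lapply(obj$cutpoints, as.numeric)
  structure(list(cutpoints = cuts, features = as.character(obj$features)),
            class = "cutpoint_set")
}
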