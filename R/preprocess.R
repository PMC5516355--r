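#' Binning specification for mass spectra
#'
#' Bins are centered on the grid `low, low + width, ..., high` (inclusive),
#' each covering the half-open interval `[center - width/2, center +
#' width/2)`. The defaults — 2-Da bins over [500, 12000] Da — give
#' `floor((high - low)/width) + 1 = 5751` features, the working resolution
#' for SELDI serum profiling after discarding small peptides (m/z < 500) and
#' the poorly measured high-mass region (m/z > 12,000).
#'
#' @param low,high range of bin centers (Da).
#' @param width bin width (Da).
#' @return an object of class `"binning_spec"` with elements `low`, `high`,
#'   `width`, `n_features` and `centers`.
#' @examples
#' binning_spec()$n_features  # 5751
#' @export
binning_spec <- function(low = 500, high = 12000, width = 2) {
  check_number(low, "low")
  check_number(high, "high")
  if (low >= high) stop_field("low/high", "low must be < high")
  check_number(width, "width")
  if (width <= 0) stop_field("width", "must be > 0")
  n <- floor((high - low) / width) + 1L
  structure(list(low = low, high = high, width = width,
                 n_features = as.integer(n),
                 centers = low + width * (seq_len(n) - 1L)),
            class = "binning_spec")
}

#' @export
print.binning_spec <- function(x, ...) {
  cat(sprintf("Binning: [%g, %g] Da, width %g Da -> %d features\n",
              x$low, x$high, x$width, x$n_features))
  invisible(x)
}

#' Bin one spectrum record onto the feature grid
#'
#' Peaks falling outside `[low - width/2, high + width/2)` are discarded;
#' multiple peaks landing in the same bin are summed (total ion intensity in
#' the bin is preserved). The peak list must already be sorted by strictly
#' increasing m/z; an unsorted list signals upstream corruption and is an
#' error, never silently re-sorted.
#'
#' @param record a data frame with columns `mz` and `intensity` (one
#'   replicate run), or a numeric vector of m/z with `intensity` supplied
#'   separately.
#' @param spec a [binning_spec()].
#' @param intensity intensities when `record` is a bare m/z vector.
#' @return numeric vector of length `spec$n_features`.
#' @export
bin_spectrum <- function(record, spec = binning_spec(), intensity = NULL) {
  if (is.data.frame(record)) {
    mz <- record$mz
    intensity <- record$intensity
  } else {
    mz <- record
  }
  stopifnot(inherits(spec, "binning_spec"), length(mz) == length(intensity))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("peak m/z values are not strictly increasing; refusing to re-sort",
         call. = FALSE)
  }
  if (any(intensity < 0)) stop("negative peak intensity", call. = FALSE)
  v <- numeric(spec$n_features)
  idx <- floor((mz - (spec$low - spec$width / 2)) / spec$width) + 1
  keep <- idx >= 1 & idx <= spec$n_features
  if (any(keep)) {
    agg <- rowsum(intensity[keep], idx[keep])
    v[as.integer(rownames(agg))] <- agg[, 1L]
  }
  v
}

#' Normalize a binned spectrum to its internal standard
#'
#' The detected standard is the maximum-intensity bin whose center lies
#' within `window` Da of `standard_mz`; every value is divided by that
#' intensity. The detected (m/z, intensity) pair is returned for QC — the
#' relative mass error `100 * |detected - nominal| / nominal` is the usual
#' mass-accuracy check (serum SELDI runs are expected within 0.06% for
#' insulin).
#'
#' @param values binned intensity vector.
#' @param centers bin centers matching `values`.
#' @param standard_mz nominal standard mass (Da).
#' @param window half-width of the detection window (Da).
#' @param id optional record identifier used in error messages.
#' @return list with `values` (normalized), `standard_mz`,
#'   `standard_intensity` and `mass_error_pct`.
#' @export
normalize_to_standard <- function(values, centers, standard_mz = 5734.5,
                                  window = 10, id = NULL) {
  stopifnot(length(values) == length(centers))
  check_number(window, "window")
  if (window <= 0) stop_field("window", "must be > 0")
  in_win <- which(abs(centers - standard_mz) <= window)
  who <- if (is.null(id)) "" else sprintf(" (record %s)", id)
  if (length(in_win) == 0L) {
    stop(sprintf("no bin within %g Da of the standard at %g%s",
                 window, standard_mz, who), call. = FALSE)
  }
  i <- in_win[which.max(values[in_win])]
  s <- values[i]
  if (!is.finite(s) || s <= 0) {
    stop(sprintf("detected standard intensity %g is not positive%s", s, who),
         call. = FALSE)
  }
  list(values = values / s,
       standard_mz = centers[i],
       standard_intensity = s,
       mass_error_pct = 100 * abs(centers[i] - standard_mz) / standard_mz)
}

#' Relative mass error of a detected standard, in percent
#'
#' @param detected_mz,nominal_mz detected and nominal standard masses (Da).
#' @return `100 * |detected - nominal| / nominal`.
#' @export
mass_error_pct <- function(detected_mz, nominal_mz) {
  100 * abs(detected_mz - nominal_mz) / nominal_mz
}

#' Construct a labeled feature matrix
#'
#' Light container used by the discretization, pattern and validation
#' stages: an intensity matrix (patients x binned m/z features) with class
#' labels. All values must be finite and nonnegative.
#'
#' @param values numeric matrix, rows = patients.
#' @param labels class labels, one per row.
#' @param bin_centers numeric feature positions (defaults to column names).
#' @param patient_ids row identifiers (defaults to row names).
#' @param qc optional QC report carried along.
#' @return an object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(values, labels, bin_centers = NULL,
                           patient_ids = NULL, qc = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels)) {
    stop("row count must equal label count", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("feature values must be finite and nonnegative", call. = FALSE)
  }
  feature_names <- colnames(values)
  if (is.null(bin_centers)) {
    bin_centers <- suppressWarnings(as.numeric(feature_names))
    if (is.null(feature_names) || any(is.na(bin_centers))) {
      bin_centers <- seq_len(ncol(values))
    }
  }
  stopifnot(length(bin_centers) == ncol(values))
  if (is.null(feature_names)) feature_names <- as.character(bin_centers)
  if (is.null(patient_ids)) {
    patient_ids <- rownames(values) %||% sprintf("P%03d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(patient_ids, feature_names)
  structure(list(values = values, labels = as.character(labels),
                 bin_centers = as.numeric(bin_centers),
                 patient_ids = patient_ids, qc = qc),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d patients x %d features\n",
              nrow(x$values), ncol(x$values)))
  print(table(label = x$labels))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Bin, normalize and aggregate a cohort into a feature matrix
#'
#' Each replicate run is binned and normalized to the internal standard;
#' the normalized replicates of a patient are then averaged into one row.
#' The QC report holds, per patient, the between-replicate Pearson
#' correlation of the normalized binned vectors (computed before averaging)
#' and, per record, the detected standard mass, intensity and relative mass
#' error.
#'
#' @param cohort a `"seldi_cohort"` or long peaks data frame.
#' @param spec a [binning_spec()].
#' @param standard_mz,window passed to [normalize_to_standard()].
#' @return a [feature_matrix()] whose `qc` element has data frames
#'   `replicate_r` and `standard`.
#' @export
build_feature_matrix <- function(cohort, spec = binning_spec(),
                                 standard_mz = 5734.5, window = 10) {
  peaks <- if (inherits(cohort, "seldi_cohort")) cohort$peaks else cohort
  stopifnot(is.data.frame(peaks))
  by_pat <- split(peaks, peaks$patient_id)
  n_pat <- length(by_pat)
  values <- matrix(0, n_pat, spec$n_features)
  labels <- character(n_pat)
  qc_std <- list()
  qc_r <- data.frame(patient_id = names(by_pat), replicate_r = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_pat)) {
    p <- by_pat[[i]]
    lab <- unique(p$label)
    if (length(lab) != 1L) {
      stop(sprintf("conflicting labels for patient %s: %s", names(by_pat)[i],
                   paste(lab, collapse = ", ")), call. = FALSE)
    }
    labels[i] <- lab
    reps <- split(p, p$replicate_id)
    if (length(reps) < 1L) stop("patient without replicates", call. = FALSE)
    normed <- lapply(names(reps), function(rid) {
      r <- reps[[rid]]
      v <- bin_spectrum(r[order(r$mz), c("mz", "intensity")], spec)
      out <- normalize_to_standard(v, spec$centers, standard_mz, window,
                                   id = paste0(names(by_pat)[i], "/", rid))
      qc_std[[length(qc_std) + 1L]] <<- data.frame(
        patient_id = names(by_pat)[i], replicate_id = rid,
        standard_mz = out$standard_mz,
        standard_intensity = out$standard_intensity,
        mass_error_pct = out$mass_error_pct, stringsAsFactors = FALSE)
      out$values
    })
    if (length(normed) >= 2L) {
      combs <- utils::combn(length(normed), 2L)
      qc_r$replicate_r[i] <- mean(apply(combs, 2L, function(ij) {
        a <- normed[[ij[1]]]; b <- normed[[ij[2]]]
        if (stats::sd(a) == 0 && stats::sd(b) == 0) 1 else stats::cor(a, b)
      }))
    }
    values[i, ] <- Reduce(`+`, normed) / length(normed)
  }
  feature_matrix(values, labels, bin_centers = spec$centers,
                 patient_ids = names(by_pat),
                 qc = list(replicate_r = qc_r,
                           standard = do.call(rbind, qc_std)))
}

#' Write / read a feature matrix as CSV
#'
#' Dialect: comma-separated, UTF-8, mandatory header, `.` decimal
#' separator; first column `patient_id`, second `label`, remaining columns
#' headed by bin centers.
#'
#' @param fm a [feature_matrix()].
#' @param file path.
#' @return `file` (writer) or a `"feature_matrix"` (reader).
#' @export
write_feature_matrix <- function(fm, file) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(patient_id = fm$patient_ids, label = fm$labels,
                   fm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1] != "patient_id" ||
      names(df)[2] != "label") {
    stop("feature-matrix CSV must start with columns patient_id, label",
         call. = FALSE)
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid intensity at row %d, column '%s'",
                 bad[1], colnames(vals)[bad[2]]), call. = FALSE)
  }
  feature_matrix(vals, df$label,
                 bin_centers = suppressWarnings(as.numeric(colnames(vals))),
                 patient_ids = df$patient_id)
}
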