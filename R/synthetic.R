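#' Configuration for the synthetic SELDI-like cohort generator
#'
#' Describes a two-class serum-proteomic cohort emulating the statistical
#' signature of a SELDI-TOF biomarker study: duplicate runs per patient, an
#' insulin-like internal standard spiked into every run, a shared set of
#' background peaks with log-normally distributed base intensities, and a
#' small set of planted class-discriminative masses. The defaults emulate a
#' cohort of 57 rapid and 59 slow progressors of chronic kidney disease run
#' in duplicate, with a between-replicate Pearson correlation of about 0.82
#' and an internal standard at m/z 5,734.5 with intensity 28.96 +/- 2.02
#' (arbitrary units), as observed in hypertensive nephropathy serum panels.
#'
#' @param n_positive number of positive-class ("rapid") patients.
#' @param n_negative number of negative-class ("slow") patients.
#' @param replicates_per_patient replicate runs per patient.
#' @param mz_range numeric length-2, the raw emission m/z range in Da.
#' @param standard_mz m/z of the internal standard (Da).
#' @param standard_intensity_mean,standard_intensity_sd parameters of the
#'   (zero-truncated) normal from which the per-run standard intensity is
#'   drawn.
#' @param planted_masses data frame with columns `mz` (Da), `effect`
#'   (additive intensity shift on the natural scale) and `class`
#'   (`"positive"` or `"negative"`, the enriched class). The default plants
#'   seven discriminative masses, five of them higher in the negative/slow
#'   class, mirroring the empirical observation that most discriminative
#'   serum peaks are elevated in slow progressors.
#' @param background_peak_count number of non-discriminative peak positions
#'   shared across the cohort.
#' @param background_meanlog,background_sdlog log-normal parameters of the
#'   base intensities across peak positions.
#' @param replicate_correlation target between-replicate Pearson correlation
#'   (computed across peak positions within a patient), in (0, 1].
#' @param noise_sd standard deviation (intensity units) of the additive
#'   patient-level biological noise shared by all replicates of a patient.
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `"seldi_config"`.
#' @seealso [simulate_cohort()]
#' @export
seldi_config <- function(n_positive = 57L,
                         n_negative = 59L,
                         replicates_per_patient = 2L,
                         mz_range = c(0, 20000),
                         standard_mz = 5734.5,
                         standard_intensity_mean = 28.96,
                         standard_intensity_sd = 2.02,
                         planted_masses = default_planted_masses(),
                         background_peak_count = 193L,
                         background_meanlog = log(3),
                         background_sdlog = 0.7,
                         replicate_correlation = 0.82,
                         noise_sd = 0.6,
                         seed = 1L) {
  check_number(n_positive, "n_positive", lower = 1, integer = TRUE)
  check_number(n_negative, "n_negative", lower = 1, integer = TRUE)
  check_number(replicates_per_patient, "replicates_per_patient",
               lower = 1, integer = TRUE)
  if (!is.numeric(mz_range) || length(mz_range) != 2L ||
      !all(is.finite(mz_range)) || mz_range[1] >= mz_range[2]) {
    stop_field("mz_range", "must be (low, high) with low < high")
  }
  check_number(standard_mz, "standard_mz",
               lower = mz_range[1], upper = mz_range[2])
  check_number(standard_intensity_mean, "standard_intensity_mean", lower = 0)
  check_number(standard_intensity_sd, "standard_intensity_sd", lower = 0)
  check_number(background_peak_count, "background_peak_count",
               lower = 1, integer = TRUE)
  check_number(background_meanlog, "background_meanlog")
  check_number(background_sdlog, "background_sdlog", lower = 0)
  # r = 0 would require infinite replicate noise under the latent + noise
  # construction, so the open interval is enforced
  if (!is.numeric(replicate_correlation) ||
      length(replicate_correlation) != 1L ||
      !is.finite(replicate_correlation) ||
      replicate_correlation <= 0 || replicate_correlation > 1) {
    stop_field("replicate_correlation", "must lie in (0, 1]")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  planted_masses <- validate_planted(planted_masses, mz_range)

  structure(list(
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    replicates_per_patient = as.integer(replicates_per_patient),
    mz_range = as.numeric(mz_range),
    standard_mz = standard_mz,
    standard_intensity_mean = standard_intensity_mean,
    standard_intensity_sd = standard_intensity_sd,
    planted_masses = planted_masses,
    background_peak_count = as.integer(background_peak_count),
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    replicate_correlation = replicate_correlation,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "seldi_config")
}

#' Default planted discriminative masses
#'
#' Seven masses, five enriched in the negative (slow) class and two in the
#' positive (rapid) class; effects are additive intensity shifts.
#' @return data frame with columns `mz`, `effect`, `class`.
#' @export
default_planted_masses <- function() {
  data.frame(
    mz = c(1866, 2504, 3290, 4732, 7564, 9412, 11148),
    effect = c(3.0, 2.5, 3.0, 2.5, 3.0, 2.5, 3.0),
    class = c("negative", "positive", "negative", "negative",
              "positive", "negative", "negative"),
    stringsAsFactors = FALSE
  )
}

validate_planted <- function(pm, mz_range) {
  if (!is.data.frame(pm) || !all(c("mz", "effect", "class") %in% names(pm))) {
    stop_field("planted_masses",
               "must be a data frame with columns mz, effect, class")
  }
  if (nrow(pm) > 0) {
    if (!all(pm$class %in% c("positive", "negative"))) {
      stop_field("planted_masses", "class must be 'positive' or 'negative'")
    }
    if (any(pm$mz <= mz_range[1] | pm$mz >= mz_range[2])) {
      stop_field("planted_masses",
                 sprintf("all masses must lie inside mz_range (%g, %g)",
                         mz_range[1], mz_range[2]))
    }
    if (anyDuplicated(pm$mz)) {
      stop_field("planted_masses", "masses must be distinct")
    }
  }
  pm[c("mz", "effect", "class")]
}

#' @export
print.seldi_config <- function(x, ...) {
  cat("Synthetic SELDI cohort configuration\n")
  cat(sprintf("  patients: %d positive + %d negative, %d replicate(s) each\n",
              x$n_positive, x$n_negative, x$replicates_per_patient))
  cat(sprintf("  m/z range: [%g, %g] Da; %d background peaks\n",
              x$mz_range[1], x$mz_range[2], x$background_peak_count))
  cat(sprintf("  internal standard: m/z %g, intensity %g +/- %g\n",
              x$standard_mz, x$standard_intensity_mean,
              x$standard_intensity_sd))
  cat(sprintf("  planted masses: %d; replicate r target %.2f; noise sd %g\n",
              nrow(x$planted_masses), x$replicate_correlation, x$noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# zero-truncated normal draws by inverse CDF (exact, vectorized)
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean = mean, sd = sd)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}

#' Simulate a SELDI-like cohort of mass spectra
#'
#' Generates `(n_positive + n_negative) * replicates_per_patient` spectrum
#' records. Peak positions (background plus planted masses) are drawn once
#' and shared across the cohort; base intensities across positions are
#' log-normal; each planted mass adds its configured effect to the latent
#' intensity of patients in the enriched class; patient-level biological
#' noise (sd `noise_sd`) is shared by the replicates of a patient, while
#' replicate-level noise has its variance solved from the target
#' between-replicate correlation r as `var(latent) * (1 - r) / r`. Every
#' record carries the internal-standard peak with a zero-truncated normal
#' intensity. All intensities are truncated at zero.
#'
#' @param config a [seldi_config()].
#' @return an object of class `"seldi_cohort"`: a list with `peaks` (a long
#'   data frame with columns `patient_id`, `replicate_id`, `label`, `mz`,
#'   `intensity`, sorted by patient, replicate and m/z) and `config`.
#' @examples
#' cohort <- simulate_cohort(seldi_config(n_positive = 5, n_negative = 5,
#'                                        background_peak_count = 30))
#' cohort_summary(cohort)
#' @export
simulate_cohort <- function(config = seldi_config()) {
  stopifnot(inherits(config, "seldi_config"))
  with_seed(config$seed, {
    n_pat <- config$n_positive + config$n_negative
    labels <- rep(c("rapid", "slow"), c(config$n_positive, config$n_negative))
    patient_ids <- sprintf("P%03d", seq_len(n_pat))

    # shared peak positions; keep the standard's detection window clean
    low <- config$mz_range[1]; high <- config$mz_range[2]
    bg <- numeric(0)
    guard <- 0L
    while (length(bg) < config$background_peak_count) {
      cand <- stats::runif(config$background_peak_count - length(bg),
                           min = low, max = high)
      cand <- cand[abs(cand - config$standard_mz) > 10]
      bg <- unique(c(bg, cand))
      guard <- guard + 1L
      if (guard > 1000L) stop("could not place background peaks", call. = FALSE)
    }
    positions <- sort(c(bg, config$planted_masses$mz))
    n_peaks <- length(positions)
    planted_idx <- match(config$planted_masses$mz, positions)

    base <- stats::rlnorm(n_peaks, meanlog = config$background_meanlog,
                          sdlog = config$background_sdlog)

    shift_pos <- shift_neg <- numeric(n_peaks)
    if (nrow(config$planted_masses)) {
      pos_rows <- config$planted_masses$class == "positive"
      shift_pos[planted_idx[pos_rows]] <- config$planted_masses$effect[pos_rows]
      shift_neg[planted_idx[!pos_rows]] <-
        config$planted_masses$effect[!pos_rows]
    }

    r <- config$replicate_correlation
    rec_list <- vector("list", n_pat * config$replicates_per_patient)
    k <- 0L
    for (i in seq_len(n_pat)) {
      shift <- if (labels[i] == "rapid") shift_pos else shift_neg
      latent <- pmax(base + stats::rnorm(n_peaks, 0, config$noise_sd) + shift,
                     0)
      rep_sd <- if (r >= 1) 0 else sqrt(stats::var(latent) * (1 - r) / r)
      for (j in seq_len(config$replicates_per_patient)) {
        intens <- pmax(latent + stats::rnorm(n_peaks, 0, rep_sd), 0)
        std_int <- rtruncnorm0(1L, config$standard_intensity_mean,
                               config$standard_intensity_sd)
        mz_all <- c(positions, config$standard_mz)
        int_all <- c(intens, std_int)
        ord <- order(mz_all)
        k <- k + 1L
        rec_list[[k]] <- data.frame(
          patient_id = patient_ids[i], replicate_id = j, label = labels[i],
          mz = mz_all[ord], intensity = int_all[ord],
          stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, rec_list)
    rownames(peaks) <- NULL
    structure(list(peaks = peaks, config = config), class = "seldi_cohort")
  })
}

#' @export
print.seldi_cohort <- function(x, ...) {
  n_rec <- length(unique(paste(x$peaks$patient_id, x$peaks$replicate_id)))
  cat(sprintf("Synthetic SELDI cohort: %d patients, %d records, %d peaks/record\n",
              length(unique(x$peaks$patient_id)), n_rec,
              nrow(x$peaks) / n_rec))
  print(table(label = x$peaks$label[!duplicated(x$peaks$patient_id)]))
  invisible(x)
}

cohort_records <- function(x) {
  peaks <- if (inherits(x, "seldi_cohort")) x$peaks else x
  stopifnot(is.data.frame(peaks),
            all(c("patient_id", "replicate_id", "label", "mz",
                  "intensity") %in% names(peaks)))
  split(peaks, paste(peaks$patient_id, peaks$replicate_id, sep = "\r"))
}

#' Summarize a simulated or imported cohort
#'
#' Reports per-class patient counts, the per-patient between-replicate
#' Pearson correlation (computed across peak positions shared by the two
#' runs, excluding the internal-standard window), and the detected
#' internal-standard intensity per record. Records without a peak inside the
#' standard window are flagged, not dropped.
#'
#' @param x a `"seldi_cohort"` or a long peaks data frame (columns
#'   `patient_id`, `replicate_id`, `label`, `mz`, `intensity`).
#' @param standard_mz m/z of the internal standard (defaults to the cohort
#'   config, else 5734.5).
#' @param window half-width (Da) of the standard detection window.
#' @return an object of class `"cohort_summary"` with elements
#'   `class_counts`, `replicate_r` (per patient), `standard` (per record,
#'   with a `found` flag), `mean_replicate_r`, `standard_mean`, `standard_sd`.
#' @export
cohort_summary <- function(x, standard_mz = NULL, window = 10) {
  if (is.null(standard_mz)) {
    standard_mz <- if (inherits(x, "seldi_cohort")) {
      x$config$standard_mz
    } else 5734.5
  }
  peaks <- if (inherits(x, "seldi_cohort")) x$peaks else x
  if (is.null(peaks) || nrow(peaks) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  pat <- unique(peaks[c("patient_id", "label")])
  class_counts <- table(pat$label)

  recs <- split(peaks, list(peaks$patient_id, peaks$replicate_id),
                drop = TRUE)
  std <- do.call(rbind, lapply(recs, function(r) {
    in_win <- abs(r$mz - standard_mz) <= window
    if (!any(in_win)) {
      data.frame(patient_id = r$patient_id[1], replicate_id = r$replicate_id[1],
                 standard_mz = NA_real_, standard_intensity = NA_real_,
                 found = FALSE, stringsAsFactors = FALSE)
    } else {
      i <- which(in_win)[which.max(r$intensity[in_win])]
      data.frame(patient_id = r$patient_id[1], replicate_id = r$replicate_id[1],
                 standard_mz = r$mz[i], standard_intensity = r$intensity[i],
                 found = TRUE, stringsAsFactors = FALSE)
    }
  }))
  rownames(std) <- NULL
  std <- std[order(std$patient_id, std$replicate_id), ]

  rep_r <- vapply(split(peaks, peaks$patient_id), function(p) {
    p <- p[abs(p$mz - standard_mz) > window, ]
    reps <- split(p, p$replicate_id)
    if (length(reps) < 2L) return(NA_real_)
    combs <- utils::combn(length(reps), 2L)
    mean(apply(combs, 2L, function(ij) {
      a <- reps[[ij[1]]]; b <- reps[[ij[2]]]
      common <- intersect(a$mz, b$mz)
      ia <- a$intensity[match(common, a$mz)]
      ib <- b$intensity[match(common, b$mz)]
      if (stats::sd(ia) == 0 && stats::sd(ib) == 0) return(1)
      if (stats::sd(ia) == 0 || stats::sd(ib) == 0) return(NA_real_)
      stats::cor(ia, ib)
    }))
  }, numeric(1))

  structure(list(
    class_counts = class_counts,
    replicate_r = rep_r,
    standard = std,
    mean_replicate_r = mean(rep_r, na.rm = TRUE),
    standard_mean = mean(std$standard_intensity, na.rm = TRUE),
    standard_sd = stats::sd(std$standard_intensity)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n  class counts: ")
  cat(paste(names(x$class_counts), as.integer(x$class_counts),
            sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  mean replicate correlation: %.3f\n", x$mean_replicate_r))
  cat(sprintf("  internal standard intensity: %.2f +/- %.2f (%d/%d records)\n",
              x$standard_mean, x$standard_sd, sum(x$standard$found),
              nrow(x$standard)))
  invisible(x)
}

#' Write / read a cohort as TSV plus a JSON manifest
#'
#' The peak table is written as plain TSV (columns `patient_id`,
#' `replicate_id`, `label`, `mz`, `intensity`); the manifest echoes the
#' generating configuration, including the seed, when available.
#'
#' @param cohort a `"seldi_cohort"` or peaks data frame.
#' @param file path of the TSV to write.
#' @param manifest optional path of a JSON manifest.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file, manifest = NULL) {
  peaks <- if (inherits(cohort, "seldi_cohort")) cohort$peaks else cohort
  utils::write.table(peaks, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest) && inherits(cohort, "seldi_cohort")) {
    cfg <- cohort$config
    cfg$planted_masses <- as.list(cfg$planted_masses)
    jsonlite::write_json(unclass(cfg), manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  peaks <- utils::read.table(file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("patient_id", "replicate_id", "label", "mz", "intensity")
  if (!all(need %in% names(peaks))) {
    stop(sprintf("cohort TSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(peaks$intensity < 0)) {
    bad <- which(peaks$intensity < 0)[1]
    stop(sprintf("negative intensity at row %d", bad), call. = FALSE)
  }
  structure(list(peaks = peaks, config = NULL), class = "seldi_cohort")
}
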