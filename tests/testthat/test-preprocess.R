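# Binning, internal-standard normalization, feature-matrix assembly

test_that("feature count follows the floor law for arbitrary specs", {
  expect_equal(binning_spec(500, 12000, 2)$n_features, 5751L)
  set.seed(42)
  for (i in 1:25) {
    low <- runif(1, 0, 1000)
    high <- low + runif(1, 10, 5000)
    width <- runif(1, 0.5, 10)
    sp <- binning_spec(low, high, width)
    expect_equal(sp$n_features, floor((high - low) / width) + 1)
    expect_equal(length(sp$centers), sp$n_features)
  }
  expect_error(binning_spec(10, 5), "low")
  expect_error(binning_spec(0, 10, -1), "width")
})

test_that("bin assignment follows the half-open centered-interval rule", {
  sp <- binning_spec(500, 12000, 2)
  v <- bin_spectrum(data.frame(mz = c(500.9, 501.1), intensity = c(2, 3)), sp)
  expect_equal(v[sp$centers == 500], 2)
  expect_equal(v[sp$centers == 502], 3)
  # left edge inclusive, right edge exclusive
  v2 <- bin_spectrum(data.frame(mz = c(499.0, 501.0), intensity = c(1, 1)), sp)
  expect_equal(v2[sp$centers == 500], 1)
  expect_equal(v2[sp$centers == 502], 1)
  # out-of-range peaks are dropped; empty record gives all zeros
  v3 <- bin_spectrum(data.frame(mz = c(100, 13005), intensity = c(5, 5)), sp)
  expect_equal(sum(v3), 0)
  v4 <- bin_spectrum(data.frame(mz = numeric(0), intensity = numeric(0)), sp)
  expect_equal(length(v4), 5751L)
  expect_equal(sum(v4), 0)
})

test_that("multiple peaks in a bin are summed and in-range mass is conserved", {
  sp <- binning_spec(500, 520, 2)
  v <- bin_spectrum(data.frame(mz = c(503.2, 503.9), intensity = c(1, 2)), sp)
  expect_equal(v[sp$centers == 504], 3)
  set.seed(7)
  for (i in 1:20) {
    mz <- sort(runif(30, 490, 530))
    mz <- mz[!duplicated(mz)]
    intensity <- runif(length(mz), 0, 5)
    v <- bin_spectrum(data.frame(mz = mz, intensity = intensity), sp)
    in_range <- mz >= 499 & mz < 521
    expect_equal(sum(v), sum(intensity[in_range]))
  }
})

test_that("unsorted peak lists are rejected, never silently re-sorted", {
  sp <- binning_spec(500, 520, 2)
  expect_error(
    bin_spectrum(data.frame(mz = c(510, 505), intensity = c(1, 1)), sp),
    "strictly increasing")
  expect_error(
    bin_spectrum(data.frame(mz = c(505, 505), intensity = c(1, 1)), sp),
    "strictly increasing")
})

test_that("standard normalization divides by the detected peak and is idempotent", {
  centers <- seq(5700, 5760, 2)
  v <- rep(1, length(centers))
  v[centers == 5734] <- 2
  out <- normalize_to_standard(v, centers, 5734.5, window = 10)
  expect_equal(out$standard_intensity, 2)
  expect_equal(out$standard_mz, 5734)
  expect_equal(out$values[centers == 5700], 0.5)
  # already-normalized vector (standard = 1) is unchanged
  again <- normalize_to_standard(out$values, centers, 5734.5, window = 10)
  expect_equal(again$values, out$values)
  expect_equal(again$standard_intensity, 1)
})

test_that("normalization failures identify the record", {
  centers <- seq(5700, 5760, 2)
  expect_error(normalize_to_standard(rep(0, length(centers)), centers,
                                     5734.5, 10, id = "P9/2"),
               "not positive.*P9/2")
  expect_error(normalize_to_standard(c(1, 1), c(100, 102), 5734.5, 10),
               "no bin within")
})

test_that("mass-accuracy QC matches the hand calculation", {
  expect_equal(mass_error_pct(5737.3, 5734.5), 100 * 2.8 / 5734.5)
  expect_lt(mass_error_pct(5737.3, 5734.5), 0.06)
})

test_that("replicates are normalized, QC'd pre-averaging, then averaged", {
  # two replicates that are scalar multiples: identical after normalization
  peaks <- rbind(
    data.frame(patient_id = "A", replicate_id = 1, label = "rapid",
               mz = c(600.5, 5734.5, 8000.1), intensity = c(2, 4, 6)),
    data.frame(patient_id = "A", replicate_id = 2, label = "rapid",
               mz = c(600.5, 5734.5, 8000.1), intensity = c(4, 8, 12)),
    data.frame(patient_id = "B", replicate_id = 1, label = "slow",
               mz = c(600.5, 5734.5, 8000.1), intensity = c(1, 2, 1)))
  fm <- build_feature_matrix(peaks)
  expect_equal(dim(fm$values), c(2L, 5751L))
  expect_equal(fm$qc$replicate_r$replicate_r[fm$qc$replicate_r$patient_id == "A"], 1)
  expect_equal(unname(fm$values["A", "600"]), 0.5)
  expect_equal(unname(fm$values["A", "5734"]), 1)
  expect_equal(fm$labels, c("rapid", "slow"))
  expect_equal(fm$qc$standard$mass_error_pct,
               rep(100 * 0.5 / 5734.5, 3), tolerance = 1e-12)
})

test_that("conflicting replicate labels are an error", {
  peaks <- rbind(
    data.frame(patient_id = "A", replicate_id = 1, label = "rapid",
               mz = 5734.5, intensity = 4),
    data.frame(patient_id = "A", replicate_id = 2, label = "slow",
               mz = 5734.5, intensity = 4))
  expect_error(build_feature_matrix(peaks), "conflicting labels")
})

test_that("a duplicate-run cohort yields one row per patient", {
  co <- simulate_cohort(seldi_config(n_positive = 3, n_negative = 4,
                                     background_peak_count = 25, seed = 2))
  fm <- build_feature_matrix(co)
  expect_equal(dim(fm$values), c(7L, 5751L))
  expect_equal(sort(table(fm$labels), decreasing = TRUE),
               sort(table(c(rep("slow", 4), rep("rapid", 3))),
                    decreasing = TRUE))
  expect_true(all(fm$qc$standard$mass_error_pct < 0.06))
})

test_that("feature-matrix CSV round-trips and flags bad cells", {
  fm <- tiny_planted_matrix()
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$values, fm$values, ignore_attr = TRUE)
  expect_equal(back$labels, fm$labels)

  txt <- readLines(f)
  txt[3] <- sub("^(T02,[a-z]+,)[0-9.]+", "\\1-1", txt[3])
  writeLines(txt, f)
  expect_error(read_feature_matrix(f), "row 2")
})

test_that("feature_matrix validates its invariants", {
  expect_error(feature_matrix(matrix(1, 2, 2), c("a")), "row count")
  expect_error(feature_matrix(matrix(-1, 2, 2), c("a", "b")), "nonnegative")
  expect_error(feature_matrix(matrix(NA_real_, 2, 2), c("a", "b")),
               "finite")
})
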