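# Pattern coverage, prevalence/homogeneity, bounded-degree enumeration

p1 <- parse_pattern("m/z 9940 < 0.575 AND m/z 11274 > 0.055")

test_that("a patient is covered iff every literal holds", {
  pat <- c("9940" = 0.50, "11274" = 0.06)
  expect_true(pattern_covers(p1, pat))
  expect_false(pattern_covers(p1, c("9940" = 0.60, "11274" = 0.06)))
  expect_false(pattern_covers(p1, c("9940" = 0.50, "11274" = 0.02)))
  expect_error(pattern_covers(p1, c("9940" = 0.5)), "11274")
})

test_that("degree-0 patterns are rejected by construction", {
  expect_error(ladmass:::new_pattern("positive",
                                     data.frame(feature = character(0),
                                                cutpoint = numeric(0),
                                                direction = character(0)),
                                     1, 1, 1L),
               "degree >= 1")
  expect_error(
    ladmass:::new_pattern("positive",
                          data.frame(feature = c("a", "a"),
                                     cutpoint = c(1, 1),
                                     direction = c(">=", "<")),
                          1, 1, 1L),
    "repeat")
})

test_that("prevalence and homogeneity are exact counting ratios", {
  # 8 of 10 own-class covered plus 2 other-class: prevalence .8, homogeneity .8
  vals <- matrix(c(rep(1, 8), 0, 0, rep(1, 2), rep(0, 8)), ncol = 1,
                 dimnames = list(NULL, "f"))
  labels <- rep(c("pos", "neg"), each = 10)
  p <- pattern_stats(parse_pattern("m/z f >= 0.5"), "positive", vals,
                     labels = labels, positive = "pos")
  expect_equal(p$prevalence, 0.8)
  expect_equal(p$homogeneity, 0.8)
  expect_equal(sort(p$covered), c(1:8, 11:12))

  # covers all own-class, none other
  vals2 <- matrix(rep(c(1, 0), each = 5), ncol = 1,
                  dimnames = list(NULL, "f"))
  p2 <- pattern_stats(parse_pattern("m/z f >= 0.5"), "positive", vals2,
                      labels = rep(c("pos", "neg"), each = 5),
                      positive = "pos")
  expect_equal(p2$prevalence, 1)
  expect_equal(p2$homogeneity, 1)

  # zero own-class coverage is a rejection signal (NULL), not an error
  p3 <- pattern_stats(parse_pattern("m/z f < 0.5"), "positive", vals2,
                      labels = rep(c("pos", "neg"), each = 5),
                      positive = "pos")
  expect_null(p3)
})

test_that("hand-counted toy matrix matches brute-force cover enumeration", {
  vals <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  labels <- c("pos", "pos", "neg", "neg")
  p <- pattern_stats(parse_pattern("m/z a < 2.5 AND m/z b >= 2.5"),
                     "positive", vals, labels = labels, positive = "pos")
  covered_oracle <- which(vals[, "a"] < 2.5 & vals[, "b"] >= 2.5)
  expect_equal(p$covered, covered_oracle)
  expect_equal(p$prevalence, 1)
  expect_equal(p$homogeneity, 1)
})

test_that("enumeration equals brute force over the full literal space", {
  for (i in 1:12) {
    inst <- random_instance(i + 900, n_max = 10, f_max = 5)
    cuts <- feature_cutpoints(inst$vals, inst$labels, positive = "pos")
    is_pos <- inst$labels == "pos"
    for (sign in c("positive", "negative")) {
      min_h <- sample(c(0.5, 0.7, 0.9), 1)
      min_p <- sample(c(0.2, 0.4, 0.6), 1)
      got <- enumerate_patterns(inst$vals, cuts, sign = sign,
                                max_degree = 2, min_homogeneity = min_h,
                                min_prevalence = min_p,
                                labels = inst$labels, positive = "pos")
      got_sig <- sort(vapply(got, pattern_signature, ""))
      want_sig <- brute_force_patterns(inst$vals, is_pos, cuts, sign, 2,
                                       min_h, min_p)
      expect_equal(got_sig, want_sig)
    }
  }
})

test_that("impossible thresholds give an empty pattern list", {
  vals <- cbind(f = c(1, 2, 1, 2))  # classes overlap perfectly
  labels <- c("pos", "pos", "neg", "neg")
  cuts <- feature_cutpoints(vals, labels, positive = "pos")
  # both values are shared by both classes, so the gap is still essential
  expect_equal(cuts$cutpoints$f, 1.5)
  got <- enumerate_patterns(vals, cuts, "positive", max_degree = 2,
                            min_homogeneity = 1, min_prevalence = 1,
                            labels = labels, positive = "pos")
  expect_length(got, 0)
})

test_that("a perfectly separating planted feature yields a perfect degree-1 pattern", {
  fm <- tiny_planted_matrix()
  cuts <- feature_cutpoints(fm)
  got <- enumerate_patterns(fm, cuts, "positive", features = "sig",
                            max_degree = 1, min_homogeneity = 1,
                            min_prevalence = 1, positive = "pos")
  expect_gte(length(got), 1)
  expect_equal(got[[1]]$prevalence, 1)
  expect_equal(got[[1]]$homogeneity, 1)
})

test_that("raising thresholds never adds patterns; degree 2 contains degree 1", {
  inst <- random_instance(321, n_max = 10, f_max = 4)
  cuts <- feature_cutpoints(inst$vals, inst$labels, positive = "pos")
  lo <- enumerate_patterns(inst$vals, cuts, "positive", max_degree = 2,
                           min_homogeneity = 0.5, min_prevalence = 0.2,
                           labels = inst$labels, positive = "pos")
  hi <- enumerate_patterns(inst$vals, cuts, "positive", max_degree = 2,
                           min_homogeneity = 0.8, min_prevalence = 0.4,
                           labels = inst$labels, positive = "pos")
  expect_true(all(vapply(hi, pattern_signature, "") %in%
                    vapply(lo, pattern_signature, "")))
  d1 <- enumerate_patterns(inst$vals, cuts, "positive", max_degree = 1,
                           min_homogeneity = 0.5, min_prevalence = 0.2,
                           labels = inst$labels, positive = "pos")
  d2_deg1 <- Filter(function(p) p$degree == 1, lo)
  expect_equal(sort(vapply(d2_deg1, pattern_signature, "")),
               sort(vapply(d1, pattern_signature, "")))
})

test_that("pattern statistics are exact rationals of integer counts", {
  inst <- random_instance(55, n_max = 12, f_max = 4)
  cuts <- feature_cutpoints(inst$vals, inst$labels, positive = "pos")
  n_own <- sum(inst$labels == "pos")
  pats <- enumerate_patterns(inst$vals, cuts, "positive", max_degree = 2,
                             min_homogeneity = 0.3, min_prevalence = 0.1,
                             labels = inst$labels, positive = "pos")
  for (p in pats) {
    expect_equal(p$homogeneity * length(p$covered),
                 round(p$homogeneity * length(p$covered)))
    expect_equal(p$prevalence * n_own, round(p$prevalence * n_own))
  }
})

test_that("the degree-1 screen behaves at its threshold extremes", {
  fm <- tiny_planted_matrix(n_noise = 3)
  # vacuous thresholds retain every feature with a cutpoint
  cuts <- feature_cutpoints(fm)
  all_feats <- names(cuts$cutpoints)[lengths(cuts$cutpoints) > 0]
  expect_equal(degree1_feature_filter(fm, cuts, 0, 0), all_feats,
               ignore_attr = TRUE)
  # at 0.8/0.8 the perfect planted feature survives
  kept <- degree1_feature_filter(fm, cuts, 0.8, 0.8)
  expect_true("sig" %in% kept)
})

test_that("pure-noise features rarely pass the 0.8/0.8 screen", {
  set.seed(13)
  vals <- matrix(runif(60 * 150), 60, 150,
                 dimnames = list(NULL, paste0("f", 1:150)))
  labels <- rep(c("pos", "neg"), 30)
  kept <- degree1_feature_filter(vals, labels = labels, positive = "pos")
  expect_lt(length(kept), 2)  # < ~1% of 150 features
})

test_that("patterns render and parse losslessly", {
  txt <- format_pattern(p1)
  expect_equal(txt, "m/z 9940 < 0.575 AND m/z 11274 >= 0.055")
  back <- parse_pattern(txt)
  expect_equal(back, p1)
  f <- withr::local_tempfile(fileext = ".json")
  vals <- cbind(`9940` = c(0.5, 0.6), `11274` = c(0.06, 0.06))
  p <- pattern_stats(p1, "positive", vals, labels = c("pos", "neg"),
                     positive = "pos")
  write_patterns(list(p), f)
  back2 <- read_patterns(f)[[1]]
  expect_equal(back2$literals, p$literals)
  expect_equal(back2$prevalence, p$prevalence)
})
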