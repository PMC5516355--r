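# Model assembly, discriminant/risk algebra, risk groups, ROC/AUC

# assemble a lad model directly from rendered patterns scored on a matrix
manual_model <- function(pos_txt, neg_txt, vals, labels, positive = "pos") {
  score <- function(txt, sign) {
    pattern_stats(parse_pattern(txt), sign, vals, labels = labels,
                  positive = positive)
  }
  pos <- lapply(pos_txt, score, sign = "positive")
  neg <- lapply(neg_txt, score, sign = "negative")
  negative <- setdiff(unique(labels), positive)
  structure(list(positive_patterns = pos, negative_patterns = neg,
                 P = length(pos), N = length(neg), positive = positive,
                 negative = negative, levels = c(positive, negative)),
            class = "lad")
}

test_that("the discriminant follows delta = p/P - n/N with the sign rule", {
  # 3 positive + 4 negative single-literal patterns on 7 indicator columns
  vals <- matrix(0, 1, 7, dimnames = list(NULL, paste0("f", 1:7)))
  mk <- function(on) { v <- vals; v[1, on] <- 1; v }
  m <- manual_model(sprintf("m/z f%d >= 0.5", 1:3),
                    sprintf("m/z f%d >= 0.5", 4:7),
                    rbind(mk(1:3), mk(4:7)), c("pos", "neg"))
  # p = P, n = 0
  d <- discriminant(m, mk(1:3)[1, ])
  expect_equal(d$delta, 1); expect_equal(d$risk, 1)
  expect_equal(d$class, "pos")
  # p = 0, n = N
  d <- discriminant(m, mk(4:7)[1, ])
  expect_equal(d$delta, -1); expect_equal(d$risk, 0)
  expect_equal(d$class, "neg")
  # p = 2, n = 1: delta = 2/3 - 1/4 = 5/12, risk = 17/24
  d <- discriminant(m, mk(c(1, 2, 4))[1, ])
  expect_equal(d$delta, 5 / 12)
  expect_equal(d$risk, 17 / 24)
  expect_equal(d$p, 2L); expect_equal(d$n, 1L)
  expect_equal(d$class, "pos")
  # p/P = n/N: unclassified, surfaced not coerced
  vals0 <- matrix(0, 1, 7, dimnames = list(NULL, paste0("f", 1:7)))
  d <- discriminant(m, vals0[1, ])
  expect_equal(d$delta, 0)
  expect_equal(d$class, "unclassified")
})

test_that("delta bounds, risk bijection and sign rule hold for random models", {
  set.seed(202)
  for (i in 1:30) {
    P <- sample(1:5, 1); N <- sample(1:5, 1)
    nf <- P + N
    vals <- matrix(round(runif(10 * nf), 2), 10, nf,
                   dimnames = list(NULL, paste0("f", seq_len(nf))))
    train <- rbind(rep(1, nf), rep(0, nf))
    colnames(train) <- paste0("f", seq_len(nf))
    m <- manual_model(sprintf("m/z f%d >= 0.5", 1:P),
                      sprintf("m/z f%d < 0.5", P + 1:N),
                      train, c("pos", "neg"))
    d <- discriminant(m, vals)
    expect_true(all(abs(d$delta) <= 1))
    expect_true(all(d$risk >= 0 & d$risk <= 1))
    expect_equal(d$risk, (d$delta + 1) / 2)
    expect_equal(d$class[d$delta > 0], rep("pos", sum(d$delta > 0)))
    expect_equal(d$class[d$delta < 0], rep("neg", sum(d$delta < 0)))
    expect_equal(d$class[d$delta == 0],
                 rep("unclassified", sum(d$delta == 0)))
    expect_equal(d$p / m$P - d$n / m$N, d$delta)
  }
})

test_that("select_model keeps a trivial one-pattern-per-sign solution as is", {
  vals <- cbind(f = c(1, 1, 0, 0))
  rownames(vals) <- paste0("p", 1:4)
  labels <- c("pos", "pos", "neg", "neg")
  cands <- list(
    pattern_stats(parse_pattern("m/z f >= 0.5"), "positive", vals,
                  labels = labels, positive = "pos"),
    pattern_stats(parse_pattern("m/z f < 0.5"), "negative", vals,
                  labels = labels, positive = "pos"))
  m <- select_model(cands, vals, labels, positive = "pos")
  expect_equal(m$P, 1L); expect_equal(m$N, 1L)
  expect_equal(format_pattern(m$positive_patterns[[1]]), "m/z f >= 0.5")
})

test_that("greedy model selection matches exhaustive minimum cover on an engineered instance", {
  # positives need two patterns: each candidate covers half of them
  vals <- cbind(a = c(1, 1, 0, 0, 0, 0), b = c(0, 0, 1, 1, 0, 0),
                c = c(0, 0, 0, 0, 1, 1))
  labels <- c("pos", "pos", "pos", "pos", "neg", "neg")
  cands <- list(
    pattern_stats(parse_pattern("m/z a >= 0.5"), "positive", vals,
                  labels = labels, positive = "pos"),
    pattern_stats(parse_pattern("m/z b >= 0.5"), "positive", vals,
                  labels = labels, positive = "pos"),
    pattern_stats(parse_pattern("m/z c >= 0.5"), "negative", vals,
                  labels = labels, positive = "pos"))
  m <- select_model(cands, vals, labels, positive = "pos")
  expect_equal(m$P, 2L)
  expect_equal(m$N, 1L)
  # exhaustive check: no single positive candidate covers all positives
  pos_cands <- cands[1:2]
  expect_true(all(vapply(pos_cands,
                         function(p) length(p$covered) < 4, TRUE)))
  # coverage completeness invariant
  cov <- unique(unlist(lapply(m$positive_patterns, `[[`, "covered")))
  expect_true(all(1:4 %in% cov))
})

test_that("an uncoverable patient raises a model-infeasibility error naming it", {
  vals <- cbind(a = c(1, 0, 0))
  rownames(vals) <- c("p1", "p2", "p3")
  labels <- c("pos", "pos", "neg")
  cands <- list(
    pattern_stats(parse_pattern("m/z a >= 0.5"), "positive", vals,
                  labels = labels, positive = "pos"),
    pattern_stats(parse_pattern("m/z a < 0.5"), "negative", vals,
                  labels = labels, positive = "pos"))
  expect_error(select_model(cands, vals, labels, positive = "pos"),
               "p2")
})

test_that("quintile partition sizes and ordering follow the near-equal rule", {
  set.seed(5)
  risk <- runif(116)
  labels <- rep(c("pos", "neg"), c(57, 59))
  tab <- risk_groups(risk, labels, g = 5, positive = "pos")
  expect_equal(tab$n, c(23, 23, 23, 23, 24))
  expect_equal(sum(tab$n), 116)
  expect_true(all(diff(tab$mean_risk) > 0))
  # assignment respects score order
  grp <- attr(tab, "assignment")
  expect_true(all(tapply(risk, grp, max)[-5] <=
                    tapply(risk, grp, min)[-1]))
})

test_that("tied scores are partitioned deterministically by id", {
  risk <- rep(0.5, 10)
  labels <- rep(c("pos", "neg"), 5)
  ids <- sprintf("P%02d", 10:1)
  tab <- risk_groups(risk, labels, g = 5, ids = ids, positive = "pos")
  expect_equal(tab$n, rep(2, 5))
  grp <- attr(tab, "assignment")
  # ids sorted ascending: P01 (index 10) in group 1
  expect_equal(grp[10], 1L)
  expect_equal(grp[1], 5L)
  expect_true(all(is.finite(tab$pct_positive)))
})

test_that("a perfectly separated cohort stratifies 0% to 100%", {
  risk <- c(seq(0, 0.4, length.out = 10), seq(0.6, 1, length.out = 10))
  labels <- rep(c("neg", "pos"), each = 10)
  tab <- risk_groups(risk, labels, g = 5, positive = "pos")
  expect_equal(tab$pct_positive[1], 0)
  expect_equal(tab$pct_positive[5], 100)
})

test_that("AUC equals the pairwise-count oracle and its invariances hold", {
  expect_equal(lad_auc(c(1, 2, 3, 10, 11, 12), rep(c("n", "p"), each = 3),
                       positive = "p")$auc, 1)
  expect_equal(lad_auc(rep(1, 10), rep(c("p", "n"), 5),
                       positive = "p")$auc, 0.5)
  set.seed(404)
  for (i in 1:10) {
    scores <- round(runif(30), 2)  # rounding forces some ties
    labels <- sample(rep(c("p", "n"), 15))
    a <- lad_auc(scores, labels, positive = "p")$auc
    expect_equal(a, brute_force_auc(scores, labels == "p"))
    # strictly monotone transform leaves the AUC unchanged
    a2 <- lad_auc(exp(3 * scores), labels, positive = "p")$auc
    expect_equal(a2, a)
  }
  expect_error(lad_auc(1:5, rep("p", 5), positive = "p"), "both classes")
})

test_that("the Hanley-McNeil interval matches its closed form and pROC agrees", {
  set.seed(77)
  scores <- runif(40)
  labels <- rep(c("p", "n"), 20)
  a <- lad_auc(scores, labels, positive = "p")
  A <- a$auc; n1 <- 20; n0 <- 20
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
               (n1 * n0))
  expect_equal(a$se, se)
  expect_equal(a$ci, c(max(0, A - qnorm(0.975) * se),
                       min(1, A + qnorm(0.975) * se)))
  # independent implementation cross-check
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("n", "p"),
                                              direction = "<")))
  expect_equal(A, as.numeric(ref))
  # bootstrap interval is seeded and brackets the estimate
  b <- lad_auc(scores, labels, positive = "p", ci = "bootstrap",
               boot = 300, seed = 9)
  b2 <- lad_auc(scores, labels, positive = "p", ci = "bootstrap",
                boot = 300, seed = 9)
  expect_equal(b$ci, b2$ci)
  expect_true(b$ci[1] <= A && A <= b$ci[2])
})
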