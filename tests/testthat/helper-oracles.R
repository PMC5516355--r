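# Independent oracles and fixture generators used across the suite.
# Oracles are deliberately naive (enumeration / pairwise counting) and share
# no code with the package internals they check.

# O(n^2) pairwise-count AUC oracle, ties counted 1/2
brute_force_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# canonical signature of a pattern for set comparison
pattern_signature <- function(p) {
  lit <- sprintf("%s%s%.12g", p$literals$feature, p$literals$direction,
                 p$literals$cutpoint)
  paste(paste(sort(lit), collapse = "&"),
        sprintf("%.10f|%.10f", p$prevalence, p$homogeneity), sep = "@")
}

# brute-force enumeration of all degree <= 2 patterns meeting thresholds:
# explicit loops over every literal and literal pair (distinct features),
# cover evaluated directly on the matrix
brute_force_patterns <- function(vals, is_pos, cuts, sign, max_degree,
                                 min_h, min_p) {
  own <- if (sign == "positive") is_pos else !is_pos
  lits <- list()
  for (f in names(cuts$cutpoints)) {
    for (cp in cuts$cutpoints[[f]]) {
      lits[[length(lits) + 1L]] <- list(f = f, cp = cp, d = ">=")
      lits[[length(lits) + 1L]] <- list(f = f, cp = cp, d = "<")
    }
  }
  eval_lit <- function(l) {
    if (l$d == ">=") vals[, l$f] >= l$cp else vals[, l$f] < l$cp
  }
  out <- character(0)
  emit <- function(cov, lit_desc) {
    n_own <- sum(own & cov)
    if (n_own == 0) return()
    prev <- n_own / sum(own)
    hom <- n_own / sum(cov)
    if (prev >= min_p && hom >= min_h) {
      out[[length(out) + 1L]] <<- paste(
        paste(sort(lit_desc), collapse = "&"),
        sprintf("%.10f|%.10f", prev, hom), sep = "@")
    }
  }
  for (i in seq_along(lits)) {
    li <- lits[[i]]
    emit(eval_lit(li), sprintf("%s%s%.12g", li$f, li$d, li$cp))
  }
  if (max_degree >= 2 && length(lits) >= 2) {
    for (i in seq_len(length(lits) - 1L)) {
      for (j in (i + 1L):length(lits)) {
        li <- lits[[i]]; lj <- lits[[j]]
        if (li$f == lj$f) next
        emit(eval_lit(li) & eval_lit(lj),
             c(sprintf("%s%s%.12g", li$f, li$d, li$cp),
               sprintf("%s%s%.12g", lj$f, lj$d, lj$cp)))
      }
    }
  }
  sort(unlist(out))
}

# random small labeled matrix with continuous values (feasible support-set
# instances with probability 1)
random_instance <- function(seed, n_max = 12, f_max = 8) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  f <- sample(2:f_max, 1)
  vals <- matrix(round(runif(n * f), 3), n, f,
                 dimnames = list(NULL, paste0("f", seq_len(f))))
  labels <- c("pos", "neg", sample(c("pos", "neg"), n - 2, replace = TRUE))
  list(vals = vals, labels = labels)
}

# random discrete instance with a bounded binary-feature count (for the
# exhaustive support-set oracle); opposite-class duplicate rows are
# resampled away so the instance is feasible
random_discrete_instance <- function(seed, n_max = 12, f_max = 5,
                                     levels = 4) {
  set.seed(seed)
  repeat {
    n <- sample(4:n_max, 1)
    f <- sample(2:f_max, 1)
    vals <- matrix(sample(seq_len(levels), n * f, replace = TRUE), n, f,
                   dimnames = list(NULL, paste0("f", seq_len(f))))
    labels <- c("pos", "neg", sample(c("pos", "neg"), n - 2, replace = TRUE))
    pos <- which(labels == "pos"); neg <- which(labels == "neg")
    clash <- FALSE
    for (i in pos) for (j in neg) {
      if (all(vals[i, ] == vals[j, ])) clash <- TRUE
    }
    if (!clash) return(list(vals = vals, labels = labels))
  }
}

# verify a support set by first principles: every opposite-class pair
# differs on >= 1 selected binary column
oracle_feasible <- function(B, labels, cols) {
  pos <- which(labels == "pos"); neg <- which(labels == "neg")
  for (i in pos) for (j in neg) {
    if (length(cols) == 0L) return(FALSE)
    if (all(B[i, cols] == B[j, cols])) return(FALSE)
  }
  TRUE
}

# small deterministic planted two-class matrix: feature "sig" separates the
# classes perfectly, the rest are noise
tiny_planted_matrix <- function(n_pos = 6, n_neg = 6, n_noise = 4,
                                seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  vals <- matrix(round(runif(n * n_noise), 3), n, n_noise,
                 dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  sig <- c(runif(n_pos, 2, 3), runif(n_neg, 0, 1))
  vals <- cbind(sig = round(sig, 3), vals)
  labels <- rep(c("pos", "neg"), c(n_pos, n_neg))
  feature_matrix(vals, labels,
                 patient_ids = sprintf("T%02d", seq_len(n)))
}

# quick low-noise planted cohort feature matrix (bypasses spectrum binning:
# planted features plus uniform noise features, duplicates pre-averaged)
fast_planted_fm <- function(n_pos = 20, n_neg = 20, n_noise = 30,
                            effect = 3, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  vals <- matrix(abs(rnorm(n * n_noise, 3, 1)), n, n_noise)
  colnames(vals) <- paste0("b", seq_len(n_noise))
  planted <- matrix(abs(rnorm(n * 2, 3, noise_sd)), n, 2)
  planted[seq_len(n_pos), 1] <- planted[seq_len(n_pos), 1] + effect
  planted[n_pos + seq_len(n_neg), 2] <- planted[n_pos + seq_len(n_neg), 2] +
    effect
  colnames(planted) <- c("sigpos", "signeg")
  feature_matrix(cbind(planted, vals), rep(c("rapid", "slow"),
                                           c(n_pos, n_neg)))
}
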