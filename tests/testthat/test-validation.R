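test_that("tpr and fpr count set intersections as defined", {
  truth <- c(rep("c", 4), rep("h", 10), rep("o", 5))
  imp <- c("c", "c", "c", "h",            # 3 of 4 cancers recovered
           rep("h", 9), "c",              # 1 healthy false positive
           rep("c", 5))                   # all obesity imputed cancer
  expect_equal(tpr_cancer(truth, imp), 0.75)
  expect_equal(fpr_cancer(truth, imp, p_o = 0), 0.1)
  # worked example: x = 0.2 * 10 / 5 = 0.4;
  # FPR = (1 + 0.4 * 5) / (10 + 0.4 * 5) = 3/12 = 0.25
  expect_equal(fpr_cancer(truth, imp, p_o = 0.2), (1 + 0.4 * 5) / 12)
  # the spec-sheet variant with no healthy false positives -> 1/6
  imp2 <- imp
  imp2[14] <- "h"
  expect_equal(fpr_cancer(truth, imp2, p_o = 0.2), 1 / 6)
  # extremes
  expect_equal(tpr_cancer(truth, rep("c", 19)), 1)
  expect_equal(tpr_cancer(truth, rep("h", 19)), 0)
  expect_equal(fpr_cancer(truth, rep("h", 19), p_o = 0.2), 0)
})

test_that("undefined metrics signal NA instead of fabricating a value", {
  expect_true(is.na(tpr_cancer(rep("h", 3), rep("h", 3))))
  expect_true(is.na(fpr_cancer(rep("c", 3), rep("c", 3), p_o = 0)))
  # p_o > 0 with no obesity samples present is undefined
  truth <- c("h", "h", "c")
  expect_true(is.na(fpr_cancer(truth, c("h", "c", "c"), p_o = 0.2)))
  expect_false(is.na(fpr_cancer(truth, c("h", "c", "c"), p_o = 0)))
})

test_that("p_o = 0 reduces exactly to the healthy-only rate, exhaustively", {
  # all class/imputation count compositions on 2-10 sample validation sets
  for (n in 2:10) {
    for (n_h in 1:(n - 1)) {
      for (n_c in 0:(n - n_h)) {
        n_o <- n - n_h - n_c
        for (h_fp in 0:n_h) {
          for (o_fp in 0:n_o) {
            truth <- c(rep("h", n_h), rep("c", n_c), rep("o", n_o))
            imp <- c(rep("c", h_fp), rep("h", n_h - h_fp),
                     rep("h", n_c),
                     rep("c", o_fp), rep("o", n_o - o_fp))
            expect_identical(fpr_cancer(truth, imp, p_o = 0), h_fp / n_h)
          }
        }
      }
    }
  }
})

test_that("the prevalence weight matches physical dilution in expectation", {
  truth <- c(rep("h", 12), rep("o", 6), rep("c", 5))
  imp <- c(rep("c", 2), rep("h", 10),       # 2/12 healthy FPs
           rep("c", 4), rep("h", 2),        # 4/6 obesity FPs
           rep("c", 5))
  for (p_o in c(0.1, 0.2)) {
    analytic <- fpr_cancer(truth, imp, p_o = p_o)
    sim <- dilution_oracle_fpr(truth, imp, p_o, n_resample = 10000, seed = 4)
    # MC standard error of the pooled ratio, binomial-style bound
    se <- sqrt(analytic * (1 - analytic) / (10000 * 12))
    expect_lt(abs(sim - analytic), 3 * se + 1e-3)
  }
})

test_that("monotonicity: an extra healthy false positive never lowers FPR", {
  withr::local_seed(2)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    truth <- sample(c("h", "c", "o"), n, replace = TRUE)
    truth[1] <- "h"; truth[2] <- "c"; truth[3] <- "o"
    imp <- sample(c("h", "c", "o"), n, replace = TRUE)
    base <- fpr_cancer(truth, imp, p_o = 0.2)
    more <- fpr_cancer(c(truth, "h"), c(imp, "c"), p_o = 0.2)
    expect_gte(more, base)
  }
})

test_that("roc_curve_f spans (0,0) to (1,1) and separates separable data", {
  sep <- make_cohort(c("H", "H", "H", "BC", "BC", "LC"),
                     c(0.08, 0.09, 0.10, 0.02, 0.03, 0.04), rep(1e8, 6))
  roc <- roc_curve_f(sep)
  expect_true(any(roc$fpr == 0 & roc$tpr == 0))
  expect_true(any(roc$fpr == 1 & roc$tpr == 1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation
  expect_false(is.unsorted(roc$fpr))
  # single observed value -> exactly 3 points (sentinels + value)
  one <- make_cohort(c("H", "BC"), c(0.05, 0.05), c(1e8, 1e8))
  expect_equal(nrow(roc_curve_f(one)), 3)
})

test_that("a signal-free cohort yields a near-diagonal ROC curve", {
  withr::local_seed(14)
  cohort <- generate_cohort(default_cohort_spec(
    n = c(H = 100, BC = 100, LC = 0, ODminus = 0, ODplus = 0)), seed = 3)
  cohort$subtype <- sample(cohort$subtype)  # shuffle labels away
  roc <- roc_curve_f(cohort)
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("roc_region_gf agrees with brute-force enumeration on a toy", {
  cohort <- make_cohort(
    c("H", "H", "H", "BC", "BC", "LC", "ODminus", "ODplus", "ODminus"),
    formate = c(0.09, 0.05, 0.11, 0.02, 0.06, 0.03, 0.07, 0.04, 0.09),
    glucose = c(1.0e8, 1.2e8, 0.9e8, 1.0e8, 1.1e8, 0.95e8,
                1.9e8, 2.2e8, 1.4e8))
  region <- roc_region_gf(cohort, p_o = 0.2)
  brute <- purrr::pmap(region[, c("g_t", "f_t")], function(g_t, f_t) {
    imp <- impute_gf(cohort$glucose, cohort$formate, g_t, f_t)
    c(fpr = fpr_cancer(cohort$class, imp, p_o = 0.2),
      tpr = tpr_cancer(cohort$class, imp))
  })
  brute <- do.call(rbind, brute)
  expect_equal(region$fpr, unname(brute[, "fpr"]))
  expect_equal(region$tpr, unname(brute[, "tpr"]))
  # restricted to the max-glucose sentinel, the region contains the F-curve
  g_hi <- max(region$g_t)
  sub <- region[region$g_t == g_hi, c("f_t", "fpr", "tpr")]
  f_roc <- roc_curve_f(cohort, include_obesity = TRUE, p_o = 0.2)
  merged <- dplyr::inner_join(sub, f_roc, by = "f_t",
                              suffix = c("_gf", "_f"))
  expect_equal(merged$fpr_gf, merged$fpr_f)
  expect_equal(merged$tpr_gf, merged$tpr_f)
})

test_that("cross_validate is reproducible and nails separable cohorts", {
  sep <- make_cohort(
    rep(c("H", "BC", "ODminus"), each = 6),
    formate = c(seq(0.08, 0.13, by = 0.01), seq(0.02, 0.045, by = 0.005),
                seq(0.08, 0.13, by = 0.01)),
    glucose = c(rep(1e8, 12), seq(2e8, 2.5e8, by = 1e7)))
  for (kind in c("F", "GF")) {
    cv <- cross_validate(sep, classifier = kind, p_o = 0.2,
                         n_realisations = 300, seed = 6)
    est <- tidy(cv)
    expect_equal(est$median[est$metric == "TPR_C"], 1)
    expect_equal(est$median[est$metric == "FPR_C"], 0)
    cv2 <- cross_validate(sep, classifier = kind, p_o = 0.2,
                          n_realisations = 300, seed = 6)
    expect_identical(tidy(cv), tidy(cv2))
  }
})

test_that("per-realisation metrics match a straight-line reimplementation", {
  cohort <- generate_cohort(default_cohort_spec(
    n = c(H = 4, BC = 4, LC = 0, ODminus = 4, ODplus = 0)), seed = 9)
  n <- nrow(cohort)
  # replay the realisation stream exactly as cross_validate seeds it
  n_real <- 40
  seeds <- withr::with_seed(11L, sample.int(2147483646L, n_real,
                                            replace = TRUE))
  tpr <- rep(NA_real_, n_real)
  fpr <- rep(NA_real_, n_real)
  for (r in seq_len(n_real)) {
    set.seed(seeds[r])
    in_train <- runif(n) < 0.75
    train <- cohort[in_train, ]
    valid <- cohort[!in_train, ]
    fit <- tryCatch(optimize_f(train), error = function(e) NULL)
    if (is.null(fit) || nrow(valid) == 0) next
    m <- straightline_metrics(as.character(valid$class),
                              as.character(predict(fit, valid)), p_o = 0.2)
    tpr[r] <- m["tpr"]
    fpr[r] <- m["fpr"]
  }
  cv <- cross_validate(cohort, "F", p_o = 0.2, n_realisations = n_real,
                       seed = 11)
  est <- tidy(cv)
  expect_equal(est$n_valid[est$metric == "TPR_C"], sum(!is.na(tpr)))
  expect_equal(est$n_valid[est$metric == "FPR_C"], sum(!is.na(fpr)))
  expect_equal(est$median[est$metric == "TPR_C"],
               median(tpr, na.rm = TRUE))
  expect_equal(est$median[est$metric == "FPR_C"],
               median(fpr, na.rm = TRUE))
  expect_gt(sum(cv$skipped), 0)  # tiny cohort must produce skips
})

test_that("identical realisation values collapse the percentile summary", {
  s <- metabostrat:::summarise_metric(rep(0.4, 25))
  expect_equal(unlist(s[, c("median", "lo", "hi")]),
               c(median = 0.4, lo = 0.4, hi = 0.4))
})
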