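test_that("impute_f applies the strict-inequality branch definition", {
  expect_equal(as.character(impute_f(0.04, 0.054)), "c")
  expect_equal(as.character(impute_f(0.054, 0.054)), "h")  # boundary -> h
  expect_equal(as.character(impute_f(0.10, 0.054)), "h")
  expect_error(impute_f(-1, 0.05), "nonnegative")
  expect_error(impute_f(NaN, 0.05), "finite")
})

test_that("impute_gf applies the decision-tree branches with strict bounds", {
  expect_equal(as.character(impute_gf(2e8, 0.03, 1.3e8, 0.054)), "o")
  expect_equal(as.character(impute_gf(1e8, 0.03, 1.3e8, 0.054)), "c")
  expect_equal(as.character(impute_gf(1e8, 0.08, 1.3e8, 0.054)), "h")
  # equality on either threshold lands in the catch-all healthy branch
  expect_equal(as.character(impute_gf(1.3e8, 0.03, 1.3e8, 0.054)), "h")
  expect_equal(as.character(impute_gf(1e8, 0.054, 1.3e8, 0.054)), "h")
})

test_that("an unreachable glucose threshold degenerates GF into F", {
  cohort <- generate_cohort(default_cohort_spec(
    n = c(H = 15, BC = 10, LC = 10, ODminus = 8, ODplus = 7)), seed = 3)
  g_above <- max(cohort$glucose) + 1
  for (f_t in candidate_thresholds(cohort, "formate")) {
    gf <- impute_gf(cohort$glucose, cohort$formate, g_above, f_t)
    expect_false(any(gf == "o"))
    expect_equal(as.character(gf), as.character(impute_f(cohort$formate, f_t)))
  }
})

test_that("candidate grids are deduplicated observed values plus sentinels", {
  cohort <- make_cohort(c("H", "BC", "H"), c(0.05, 0.07, 0.05),
                        c(1e8, 1e8, 2e8))
  cand <- candidate_thresholds(cohort, "formate")
  expect_length(cand, 4)
  expect_lt(cand[1], 0.05)
  expect_equal(cand[2:3], c(0.05, 0.07))
  expect_gt(cand[4], 0.07)
  expect_length(candidate_thresholds(cohort[1, ], "formate"), 3)
  expect_error(candidate_thresholds(cohort[0, ], "formate"), "empty")
})

test_that("optimize_f separates a separable cohort and matches brute force", {
  # perfectly separated: all cancer formate below all healthy
  sep <- make_cohort(c("H", "H", "H", "BC", "BC", "LC"),
                     c(0.08, 0.09, 0.10, 0.02, 0.03, 0.04),
                     rep(1e8, 6))
  fit <- optimize_f(sep)
  expect_equal(fit$rmi, 1)
  expect_gt(fit$f_t, 0.04)
  expect_lte(fit$f_t, 0.08)

  # 6-sample set with an overlapping value: must equal exhaustive search
  ovl <- make_cohort(c("H", "H", "H", "BC", "BC", "BC"),
                     c(0.05, 0.08, 0.09, 0.02, 0.05, 0.03),
                     rep(1e8, 6))
  fit <- optimize_f(ovl)
  oracle <- brute_optimize_f(ovl)
  expect_equal(fit$f_t, oracle$f_t)
  expect_equal(fit$rmi, oracle$rmi, tolerance = 1e-12)

  expect_error(optimize_f(make_cohort(c("H", "H"), c(0.1, 0.2), c(1, 1))),
               "degenerate")
})

test_that("shuffled labels carry no recoverable formate signal", {
  withr::local_seed(31)
  cohort <- generate_cohort(default_cohort_spec(
    n = c(H = 30, BC = 30, LC = 0, ODminus = 0, ODplus = 0)), seed = 8)
  cohort$subtype <- sample(cohort$subtype)
  fit <- optimize_f(cohort)
  # achieved rmi no better than the permutation null's upper tail
  null_rmis <- vapply(1:99, function(k) {
    sh <- cohort
    sh$subtype <- sample(sh$subtype)
    optimize_f(sh)$rmi
  }, numeric(1))
  expect_lte(fit$rmi, quantile(null_rmis, 0.95) + 0.05)
})

test_that("optimize_gf matches full-grid brute force on toy cohorts", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- c(h = 3, c = 3, o = 3)
    cohort <- make_cohort(
      c("H", "H", "H", "BC", "BC", "LC", "ODminus", "ODplus", "ODminus"),
      formate = round(runif(9, 0.01, 0.12), 3),
      glucose = round(runif(9, 5e7, 2.5e8), -5))
    fit <- optimize_gf(cohort)
    oracle <- brute_optimize_gf(cohort)
    expect_equal(fit$f_t, oracle$f_t)
    expect_equal(fit$g_t, oracle$g_t)
    expect_equal(fit$rmi, oracle$rmi, tolerance = 1e-12)
    # optimum dominates every grid point (full enumeration)
    expect_true(all(fit$grid$rmi <= fit$rmi + 1e-12))
  }
})

test_that("perfect three-class separation reaches rmi = 1", {
  cohort <- make_cohort(
    c("H", "H", "BC", "BC", "ODminus", "ODplus"),
    formate = c(0.09, 0.10, 0.02, 0.03, 0.08, 0.09),
    glucose = c(1e8, 1.1e8, 0.9e8, 1e8, 2e8, 2.2e8))
  fit <- optimize_gf(cohort)
  expect_equal(fit$rmi, 1)
  imp <- predict(fit, cohort)
  expect_equal(as.character(imp), as.character(cohort$class))
})

test_that("fits are invariant to row order", {
  withr::local_seed(12)
  cohort <- generate_cohort(default_cohort_spec(
    n = c(H = 10, BC = 8, LC = 6, ODminus = 6, ODplus = 4)), seed = 21)
  shuffled <- cohort[sample(nrow(cohort)), ]
  for (f in list(optimize_f, optimize_gf)) {
    a <- f(cohort)
    b <- f(shuffled)
    expect_equal(glance(a), glance(b))
  }
})

test_that("threshold recovery lands between the group medians", {
  cohort <- generate_cohort(seed = 17)
  fit <- optimize_gf(cohort)
  med <- dplyr::summarise(dplyr::group_by(cohort, class),
                          f = median(formate), g = median(glucose))
  expect_gt(fit$f_t, med$f[med$class == "c"])
  expect_lt(fit$f_t, med$f[med$class == "h"])
  expect_gt(fit$g_t, max(med$g[med$class %in% c("h", "c")]))
  expect_lt(fit$g_t, med$g[med$class == "o"])
})
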