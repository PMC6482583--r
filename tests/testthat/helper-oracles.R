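# Independent oracles and small fixture builders used across the suite.
# Every oracle is a deliberately naive reimplementation (explicit sets,
# direct formulas, full enumeration) kept separate from the package's own
# computation paths.

make_cohort <- function(subtype, formate, glucose, ...) {
  validate_cohort(tibble::tibble(
    sample_id = sprintf("T%03d", seq_along(subtype)),
    subtype = subtype, formate = formate, glucose = glucose, ...
  ))
}

# entropy-identity oracle: I = H(S) + H(S*) - H(S, S*)
entropy_oracle_mi <- function(reference, imputed) {
  h <- function(x) {
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h(reference) + h(imputed) - h(paste(reference, imputed, sep = "\r"))
}

# brute-force F-threshold optimum: loop every candidate, recompute rmi from
# scratch via the exported label functions, smallest-threshold tie-break
brute_optimize_f <- function(cohort) {
  hc <- cohort[cohort$class %in% c("h", "c"), ]
  cand <- candidate_thresholds(hc, "formate")
  rmi <- vapply(cand, function(f_t) {
    relative_mutual_information(droplevels(hc$class),
                                impute_f(hc$formate, f_t))
  }, numeric(1))
  best <- min(which(rmi >= max(rmi) - 1e-12))
  list(f_t = cand[best], rmi = rmi[best])
}

# brute-force (g, f) optimum over the full Cartesian grid
brute_optimize_gf <- function(cohort) {
  g_cand <- candidate_thresholds(cohort, "glucose")
  f_cand <- candidate_thresholds(cohort, "formate")
  best <- list(rmi = -Inf)
  for (f_t in f_cand) {        # f outer, ascending: ties keep smallest f then g
    for (g_t in g_cand) {
      i <- relative_mutual_information(
        cohort$class, impute_gf(cohort$glucose, cohort$formate, g_t, f_t))
      if (i > best$rmi + 1e-12) {
        best <- list(g_t = g_t, f_t = f_t, rmi = i)
      }
    }
  }
  best
}

# straight-line per-realisation CV metrics from explicit set intersections
straightline_metrics <- function(truth, imputed, p_o) {
  V <- seq_along(truth)
  C <- V[truth == "c"]; H <- V[truth == "h"]; O <- V[truth == "o"]
  Cstar <- V[imputed == "c"]
  tpr <- if (length(C) == 0) NA_real_ else {
    length(intersect(C, Cstar)) / length(C)
  }
  fpr <- if (length(H) == 0 || (p_o > 0 && length(O) == 0)) NA_real_ else {
    x <- if (p_o > 0) p_o * length(H) / length(O) else 0
    (length(intersect(H, Cstar)) + x * length(intersect(O, Cstar))) /
      (length(H) + x * length(O))
  }
  c(tpr = tpr, fpr = fpr)
}

# physical-dilution oracle for the prevalence-corrected FPR: each healthy
# control recruits an obesity sample with probability p_o; the corrected rate
# is the ratio of pooled false-positive counts to pooled set sizes across
# resamples (ratio of expected counts).
dilution_oracle_fpr <- function(truth, imputed, p_o, n_resample, seed) {
  withr::with_seed(seed, {
    H <- which(truth == "h"); O <- which(truth == "o")
    fp_total <- 0
    n_total <- 0
    for (k in seq_len(n_resample)) {
      recruited <- O[sample.int(length(O), rbinom(1, length(H), p_o),
                                replace = TRUE)]
      set <- c(H, recruited)
      fp_total <- fp_total + sum(imputed[set] == "c")
      n_total <- n_total + length(set)
    }
    fp_total / n_total
  })
}

# direct Welch two-tailed p from the textbook formulas
welch_oracle_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t_stat), df)
}

# random label pair generator for property tests
random_labels <- function(n, k_ref = 2, k_imp = k_ref) {
  list(reference = sample(letters[seq_len(k_ref)], n, replace = TRUE),
       imputed = sample(letters[seq_len(k_imp)], n, replace = TRUE))
}
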