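# Prevalence-corrected classification metrics, ROC curves/regions, and
# repeated Monte-Carlo cross-validation.

#' Per-class true positive rate
#'
#' Fraction of validation samples of a given reference class imputed as that
#' class. Returns `NA` (an undefined-metric signal, not an error) when the
#' validation set contains no sample of the class.
#'
#' @param truth Factor/character vector of reference merged classes.
#' @param imputed Factor/character vector of imputed classes, same length.
#' @param class Target class label (e.g. `"c"`).
#' @return Scalar in `[0, 1]`, or `NA_real_` when undefined.
#' @export
class_tpr <- function(truth, imputed, class) {
  check_labels(truth, imputed)
  idx <- as.character(truth) == class
  if (!any(idx)) return(NA_real_)
  mean(as.character(imputed)[idx] == class)
}

#' Prevalence-corrected false positive rate for a target class
#'
#' Healthy controls always contribute with weight 1. Every other disease
#' class `d` with population prevalence `p_d` contributes with weight
#' `x_d = p_d * |V ∩ H| / |V ∩ D_d|`, which dilutes an oversampled
#' case-control group down to its population frequency per healthy control:
#'
#' `FPR = (|V∩H∩target*| + sum_d x_d |V∩D_d∩target*|) /
#'        (|V∩H| + sum_d x_d |V∩D_d|)`.
#'
#' With all prevalences zero this reduces exactly to the unweighted
#' healthy-only false positive rate. The weights are recomputed from the
#' supplied validation labels on every call.
#'
#' @inheritParams class_tpr
#' @param target The positive class (`"c"` or `"o"`).
#' @param prevalence Named numeric vector of population prevalences in
#'   `[0, 1)` for non-target disease classes, e.g. `c(o = 0.2)`.
#' @return Scalar in `[0, 1]`, or `NA_real_` when undefined (no healthy
#'   samples, or a positive prevalence for a class absent from `truth`).
#' @export
prevalence_fpr <- function(truth, imputed, target, prevalence = numeric()) {
  check_labels(truth, imputed)
  truth <- as.character(truth)
  imputed <- as.character(imputed)
  n_h <- sum(truth == "h")
  if (n_h == 0) return(NA_real_)
  num <- sum(truth == "h" & imputed == target)
  den <- n_h
  for (d in names(prevalence)) {
    p_d <- prevalence[[d]]
    if (p_d < 0 || p_d >= 1) {
      stop("prevalence must lie in [0, 1)", call. = FALSE)
    }
    if (d %in% c("h", target) || p_d == 0) next
    n_d <- sum(truth == d)
    if (n_d == 0) return(NA_real_)
    x_d <- p_d * n_h / n_d
    num <- num + x_d * sum(truth == d & imputed == target)
    den <- den + x_d * n_d
  }
  num / den
}

#' @rdname class_tpr
#' @export
tpr_cancer <- function(truth, imputed) class_tpr(truth, imputed, "c")

#' @rdname class_tpr
#' @export
tpr_obesity <- function(truth, imputed) class_tpr(truth, imputed, "o")

#' False positive rate for the cancer class, corrected for obesity prevalence
#'
#' @inheritParams class_tpr
#' @param p_o Obesity prevalence in the target population, in `[0, 1)`;
#'   `p_o = 0` gives the unweighted healthy-only rate.
#' @return Scalar in `[0, 1]`, or `NA_real_` when undefined.
#' @export
fpr_cancer <- function(truth, imputed, p_o = 0) {
  prevalence_fpr(truth, imputed, "c", c(o = p_o))
}

#' False positive rate for the obesity class, corrected for cancer prevalence
#'
#' @inheritParams fpr_cancer
#' @param p_c Cancer prevalence in the target population, in `[0, 1)`.
#' @export
fpr_obesity <- function(truth, imputed, p_c = 0) {
  prevalence_fpr(truth, imputed, "o", c(c = p_c))
}

#' ROC curve of the formate classifier
#'
#' Sweeps the formate threshold across all observed values (plus sentinels),
#' classifies every sample, and reports the cancer-class TPR and the
#' (optionally prevalence-corrected) FPR at each threshold. Training and
#' validation sets both equal the full cohort here. The sentinel thresholds
#' guarantee the endpoints (0, 0) and (1, 1).
#'
#' @param cohort A cohort tibble.
#' @param include_obesity If `FALSE`, obesity samples are dropped before the
#'   sweep (pure case-control setting); if `TRUE` they are classified too and
#'   enter the FPR with prevalence `p_o`.
#' @param p_o Obesity prevalence used in the corrected FPR.
#' @return Tibble with columns `f_t`, `fpr`, `tpr`, sorted by `fpr`.
#' @export
roc_curve_f <- function(cohort, include_obesity = FALSE, p_o = 0) {
  cohort <- validate_cohort(cohort)
  if (!include_obesity) {
    cohort <- dplyr::filter(cohort, .data$class != "o")
    p_o <- 0
  }
  cand <- candidate_thresholds(cohort, "formate")
  pts <- purrr::map(cand, function(f_t) {
    imp <- impute_f(cohort$formate, f_t)
    tibble::tibble(f_t = f_t,
                   fpr = fpr_cancer(cohort$class, imp, p_o),
                   tpr = tpr_cancer(cohort$class, imp))
  })
  dplyr::arrange(dplyr::bind_rows(pts), .data$fpr, .data$tpr)
}

#' ROC region of the (glucose, formate) classifier
#'
#' Evaluates the cancer-class TPR and prevalence-corrected FPR at every pair
#' of candidate glucose and formate thresholds. With two biomarkers the
#' attainable operating points form a region (not a curve) in the
#' (FPR, TPR) plane.
#'
#' @inheritParams roc_curve_f
#' @return Tibble with columns `g_t`, `f_t`, `fpr`, `tpr`.
#' @export
roc_region_gf <- function(cohort, p_o = 0) {
  cohort <- validate_cohort(cohort)
  cls <- class_codes(cohort$class)
  if (length(unique(cls)) < 3) {
    stop("cohort must contain all three classes (h, c, o)", call. = FALSE)
  }
  g_cand <- candidate_thresholds(cohort, "glucose")
  f_cand <- candidate_thresholds(cohort, "formate")
  pc <- gf_grid_counts(cohort$glucose, cohort$formate, cls, g_cand, f_cand)
  n_h <- pc$h$n
  n_c <- pc$c$n
  n_o <- pc$o$n
  tpr <- pc$c$c / n_c                       # [g, f] matrix
  x <- if (p_o > 0) p_o * n_h / n_o else 0
  fpr <- (pc$h$c + x * pc$o$c) / (n_h + x * n_o)
  grid <- tidyr::expand_grid(g_t = g_cand, f_t = f_cand)
  grid$fpr <- as.vector(t(fpr))
  grid$tpr <- as.vector(t(tpr))
  grid
}

# --- Monte-Carlo cross-validation ------------------------------------------

summarise_metric <- function(values) {
  ok <- values[!is.na(values)]
  if (length(ok) == 0) {
    return(tibble::tibble(median = NA_real_, lo = NA_real_, hi = NA_real_,
                          n_valid = 0L))
  }
  qs <- stats::quantile(ok, c(0.05, 0.5, 0.95), names = FALSE)
  tibble::tibble(median = qs[2], lo = qs[1], hi = qs[3],
                 n_valid = length(ok))
}

#' Repeated Monte-Carlo cross-validation of a threshold classifier
#'
#' For each realisation every sample is assigned to the training set with
#' probability `train_probability` (Bernoulli per sample, so split sizes
#' vary) and to the validation set otherwise. Thresholds are fitted on the
#' training set — on its healthy and cancer samples for the F-classifier, on
#' all three classes for the (G,F)-classifier — and the cancer-class TPR and
#' prevalence-corrected FPR are computed on the validation set. Realisations
#' with a degenerate training set or an undefined metric are skipped and
#' tallied, never imputed. Each metric is summarised as its median and
#' 5th/95th percentiles over the valid realisations.
#'
#' A single master seed draws one sub-seed per realisation up front, so
#' results do not depend on evaluation order.
#'
#' @param cohort A cohort tibble.
#' @param classifier `"F"` (formate only) or `"GF"` (glucose then formate).
#' @param p_o Obesity prevalence for the corrected FPR; `0` reproduces the
#'   pure case-control analysis.
#' @param train_probability Per-sample probability of assignment to the
#'   training set (default 0.75).
#' @param n_realisations Number of random splits (default 100000; use fewer
#'   for exploration).
#' @param seed Optional integer master seed.
#' @return A `cv_result`: list with an `estimates` tibble (metric, median,
#'   lo, hi, n_valid), a `skipped` tally, and the configuration.
#' @examples
#' cv <- cross_validate(generate_cohort(seed = 1), classifier = "F",
#'                      n_realisations = 200, seed = 7)
#' tidy(cv)
#' @export
cross_validate <- function(cohort, classifier = c("F", "GF"), p_o = 0,
                           train_probability = 0.75, n_realisations = 100000,
                           seed = NULL) {
  classifier <- match.arg(classifier)
  cohort <- validate_cohort(cohort)
  if (train_probability <= 0 || train_probability >= 1) {
    stop("train_probability must lie in (0, 1)", call. = FALSE)
  }
  if (n_realisations < 1) stop("n_realisations must be >= 1", call. = FALSE)
  n <- nrow(cohort)
  cls <- class_codes(cohort$class)
  formate <- cohort$formate
  glucose <- cohort$glucose
  truth_chr <- as.character(cohort$class)

  draw_seeds <- function() sample.int(2147483646L, n_realisations,
                                      replace = TRUE)
  sub_seeds <- if (is.null(seed)) draw_seeds() else {
    withr::with_seed(as.integer(seed), draw_seeds())
  }

  tpr_v <- rep(NA_real_, n_realisations)
  fpr_v <- rep(NA_real_, n_realisations)
  skipped <- c(degenerate_train = 0L, undefined_metric = 0L)

  for (r in seq_len(n_realisations)) {
    set.seed(sub_seeds[r])
    in_train <- stats::runif(n) < train_probability
    v <- which(!in_train)
    t_idx <- which(in_train)
    fit <- tryCatch(
      if (classifier == "F") {
        fit_f_core(formate[t_idx], cls[t_idx])
      } else {
        fit_gf_core(glucose[t_idx], formate[t_idx], cls[t_idx])
      },
      error = function(e) NULL
    )
    if (is.null(fit) || length(v) == 0) {
      skipped["degenerate_train"] <- skipped["degenerate_train"] + 1L
      next
    }
    imp <- if (classifier == "F") {
      ifelse(formate[v] < fit$f_t, "c", "h")
    } else {
      ifelse(glucose[v] > fit$g_t, "o",
             ifelse(glucose[v] < fit$g_t & formate[v] < fit$f_t, "c", "h"))
    }
    tpr <- class_tpr(truth_chr[v], imp, "c")
    fpr <- fpr_cancer(truth_chr[v], imp, p_o)
    if (is.na(tpr) || is.na(fpr)) {
      skipped["undefined_metric"] <- skipped["undefined_metric"] + 1L
    }
    tpr_v[r] <- tpr
    fpr_v[r] <- fpr
  }

  estimates <- dplyr::bind_rows(
    dplyr::mutate(summarise_metric(tpr_v), metric = "TPR_C", .before = 1),
    dplyr::mutate(summarise_metric(fpr_v), metric = "FPR_C", .before = 1)
  )
  if (all(estimates$n_valid == 0)) {
    stop("no valid cross-validation realisations (skipped: ",
         paste(names(skipped), skipped, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  structure(
    list(estimates = estimates, skipped = skipped,
         config = list(classifier = classifier, p_o = p_o,
                       train_probability = train_probability,
                       n_realisations = n_realisations, seed = seed,
                       n_samples = n)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cfg <- x$config
  cat("<cv_result> ", cfg$classifier, "-classifier, p_o = ", cfg$p_o,
      ", ", cfg$n_realisations, " realisations (train prob ",
      cfg$train_probability, ")\n", sep = "")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %s: %.3f (%.3f-%.3f), %d valid realisations\n",
                est$metric[i], est$median[i], est$lo[i], est$hi[i],
                est$n_valid[i]))
  }
  if (sum(x$skipped) > 0) {
    cat("  skipped:", paste(names(x$skipped), x$skipped, sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$estimates

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    classifier = x$config$classifier,
    p_o = x$config$p_o,
    n_realisations = x$config$n_realisations,
    tpr_median = est$median[est$metric == "TPR_C"],
    fpr_median = est$median[est$metric == "FPR_C"],
    n_skipped = sum(x$skipped)
  )
}
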