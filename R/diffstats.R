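# Differential screening statistics (volcano plots), correlation with a
# permutation p-value, and internal-standard formate quantification.

#' Volcano-plot statistics for one group comparison
#'
#' For every metabolite column shared by the two groups, computes the fold
#' change of the case group relative to the control group and a two-tailed
#' Welch (unequal-variance) t-test p-value. Metabolites with fewer than two
#' usable values in either group, or with zero variance in both, are emitted
#' with `p_value = NA` and flagged — never silently dropped. Significance is
#' flagged at the fixed tiers p < 1e-3 (`*`) and p < 1e-6 (`**`); a
#' Benjamini-Hochberg adjusted column is included as supplementary output but
#' does not drive the flags.
#'
#' @param cohort A cohort tibble; all numeric biomarker columns (formate,
#'   glucose, and any extra metabolites) are screened unless `metabolites`
#'   narrows the set.
#' @param case,control Subtypes to compare (e.g. `"BC"` vs `"H"`).
#' @param metabolites Optional character vector of metabolite columns.
#' @param estimator `"mean"` (default) or `"median"` for the fold-change
#'   group summary.
#' @return Tibble with one row per metabolite: `metabolite`, `fold_change`,
#'   `p_value`, `tier` (`""`, `"*"`, `"**"`, or `"undefined"`), `p_adj`,
#'   `n_case`, `n_control`.
#' @examples
#' welch_volcano(generate_cohort(seed = 1), case = "BC", control = "H")
#' @export
welch_volcano <- function(cohort, case, control, metabolites = NULL,
                          estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  cohort <- validate_cohort(cohort)
  if (!all(c(case, control) %in% cohort_subtypes())) {
    stop("case and control must be cohort subtypes", call. = FALSE)
  }
  if (is.null(metabolites)) {
    metabolites <- setdiff(names(cohort), c("sample_id", "subtype", "class"))
  }
  est <- if (estimator == "mean") mean else stats::median
  rows <- purrr::map(metabolites, function(m) {
    x <- cohort[[m]][cohort$subtype == case]
    y <- cohort[[m]][cohort$subtype == control]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    fc <- if (length(x) > 0 && length(y) > 0 && est(y) > 0) {
      est(x) / est(y)
    } else {
      NA_real_
    }
    p <- if (length(x) >= 2 && length(y) >= 2) {
      tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
               error = function(e) NA_real_)
    } else {
      NA_real_
    }
    tibble::tibble(metabolite = m, fold_change = fc, p_value = p,
                   n_case = length(x), n_control = length(y))
  })
  out <- dplyr::bind_rows(rows)
  out$tier <- dplyr::case_when(
    is.na(out$p_value) ~ "undefined",
    out$p_value < 1e-6 ~ "**",
    out$p_value < 1e-3 ~ "*",
    TRUE ~ ""
  )
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::select(out, "metabolite", "fold_change", "p_value", "tier",
                "p_adj", "n_case", "n_control")
}

#' Pearson correlation with a permutation p-value
#'
#' Plug-in Pearson correlation of two paired metabolite vectors, with a
#' two-sided permutation p-value: one vector is shuffled `n_perm` times and
#' the add-one rule `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm)` is
#' applied, so p is never exactly 0.
#'
#' @param x,y Paired finite numeric vectors, length >= 3.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return A one-row tibble with `estimate` (r), `p_value` and `n_perm`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' correlation_perm(cohort$sarcosine, cohort$formate, n_perm = 999, seed = 1)
#' @export
correlation_perm <- function(x, y, n_perm = 10000, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r_obs <- stats::cor(x, y)
  run <- function() {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      if (abs(stats::cor(x, sample(y))) >= abs(r_obs)) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  tibble::tibble(estimate = r_obs, p_value = (1 + hits) / (1 + n_perm),
                 n_perm = as.integer(n_perm))
}

#' Internal-standard quantification of formate from peak areas
#'
#' Converts a formate peak area to a concentration by ratio against the
#' isotope-labelled internal standard (d2-formate) after background
#' subtraction:
#'
#' `conc = standard_conc * (area_formate - blank_area_formate) /
#'         (area_d2 - blank_area_d2)`.
#'
#' `standard_conc` is the effective in-sample concentration of the internal
#' standard; with the reference protocol (50 uM d2-formate, 20 uL spiked into
#' a 40 uL sample) this is 25 uM, the default. The assay is validated in the
#' 0-100 uM range; results outside it are returned with a warning.
#'
#' @param area_formate Formate peak area(s) (m/z 136), nonnegative.
#' @param area_d2 Internal-standard peak area(s) (m/z 138), nonnegative.
#' @param blank_area_formate,blank_area_d2 Background peak areas from blank
#'   samples, subtracted before taking the ratio.
#' @param standard_conc Effective in-sample internal-standard concentration
#'   (uM).
#' @return Numeric vector of formate concentrations (uM).
#' @examples
#' quantify_formate(area_formate = 2e5, area_d2 = 1e5)  # 50 uM
#' @export
quantify_formate <- function(area_formate, area_d2, blank_area_formate = 0,
                             blank_area_d2 = 0, standard_conc = 25) {
  areas <- c(area_formate, area_d2, blank_area_formate, blank_area_d2)
  if (any(!is.finite(areas) | areas < 0)) {
    stop("peak areas must be finite and nonnegative", call. = FALSE)
  }
  if (standard_conc <= 0) {
    stop("standard_conc must be positive", call. = FALSE)
  }
  corr_d2 <- area_d2 - blank_area_d2
  if (any(corr_d2 <= 0)) {
    stop("corrected internal-standard area must be positive", call. = FALSE)
  }
  conc <- standard_conc * (area_formate - blank_area_formate) / corr_d2
  outside <- conc < 0 | conc > 100
  if (any(outside)) {
    warning("formate concentration(s) outside the validated 0-100 uM range",
            call. = FALSE)
  }
  conc
}
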