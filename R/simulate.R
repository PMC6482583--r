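#' Default synthetic-cohort specification
#'
#' Returns the specification the generator consumes: one row of lognormal
#' parameters per subtype plus the target correlation of the sarcosine-like
#' co-metabolite with formate. Group sizes default to the study-population
#' table (H = 50, BC = 68, LC = 56, OD- = 46, OD+ = 35). Formate is depressed
#' in cancer; in obesity it is a 50/50 mixture of the healthy-like and
#' cancer-like components, so obese formate spans healthy-like to cancer-like
#' values. Glucose is elevated in obesity regardless of diabetes status.
#'
#' The distribution parameters are synthetic modelling choices calibrated only
#' to these ordering constraints and to the published decision thresholds
#' (healthy formate centred above 0.054 mM, cancer below it; obese glucose
#' centred above 1.3e8 peak-area units, healthy and cancer below it); no
#' per-group means or SDs are published for the original measurements.
#'
#' @param n Named integer vector of group sizes, names among the five
#'   subtypes; omitted names keep the defaults.
#' @param co_metabolite_rho Target Pearson correlation between the
#'   sarcosine-like channel and formate, in (-1, 1).
#' @param seed Default integer seed stored in the spec.
#' @return A `cohort_spec` object (list with `groups` tibble,
#'   `co_metabolite_rho`, sarcosine scale parameters, and `seed`).
#' @examples
#' spec <- default_cohort_spec(n = c(H = 10, BC = 10))
#' @export
default_cohort_spec <- function(n = NULL, co_metabolite_rho = 0.6, seed = 1L) {
  sizes <- c(H = 50L, BC = 68L, LC = 56L, ODminus = 46L, ODplus = 35L)
  if (!is.null(n)) {
    bad <- setdiff(names(n), names(sizes))
    if (length(bad) > 0 || is.null(names(n))) {
      stop("group sizes must be named by subtype", call. = FALSE)
    }
    sizes[names(n)] <- as.integer(n)
  }
  groups <- tibble::tibble(
    subtype = cohort_subtypes(),
    n = unname(sizes[cohort_subtypes()]),
    # primary formate component (healthy-like for H and obesity)
    formate_logmean = log(c(0.080, 0.035, 0.035, 0.080, 0.080)),
    formate_logsd   = c(0.35, 0.40, 0.40, 0.35, 0.35),
    # second formate component (cancer-like); mix1 = weight of the primary
    formate_logmean2 = c(NA, NA, NA, log(0.035), log(0.035)),
    formate_logsd2   = c(NA, NA, NA, 0.40, 0.40),
    formate_mix1     = c(1, 1, 1, 0.5, 0.5),
    glucose_logmean = log(c(1.0e8, 1.0e8, 1.0e8, 1.7e8, 2.0e8)),
    glucose_logsd   = c(0.15, 0.15, 0.15, 0.20, 0.22)
  )
  structure(
    list(groups = groups,
         co_metabolite_rho = co_metabolite_rho,
         sarcosine_logmean = log(2),
         sarcosine_logsd = 0.5,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

validate_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("not a cohort_spec", call. = FALSE)
  g <- spec$groups
  stopifnot(is.data.frame(g), all(cohort_subtypes() %in% g$subtype))
  if (any(g$n < 0)) stop("group sizes must be nonnegative", call. = FALSE)
  if (any(g$formate_logsd <= 0) || any(g$glucose_logsd <= 0) ||
      any(!is.na(g$formate_logsd2) & g$formate_logsd2 <= 0)) {
    stop("log-sd parameters must be positive", call. = FALSE)
  }
  if (any(g$formate_mix1 < 0 | g$formate_mix1 > 1)) {
    stop("formate_mix1 must lie in [0, 1]", call. = FALSE)
  }
  if (abs(spec$co_metabolite_rho) >= 1) {
    stop("co_metabolite_rho must satisfy |rho| < 1", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic cohort
#'
#' Draws per-sample formate (mM) and glucose (peak-area) values from the
#' lognormal group distributions of a [default_cohort_spec()], and a
#' sarcosine-like co-metabolite coupled to formate through a latent Gaussian
#' on the log scale so that its pooled Pearson correlation with formate is
#' close to `spec$co_metabolite_rho`. The same seed always yields the
#' identical cohort.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed; defaults to the seed stored in `spec`.
#' @return A validated cohort tibble with a `sarcosine` column.
#' @examples
#' cohort <- generate_cohort(seed = 42)
#' dplyr::count(cohort, subtype)
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = spec$seed) {
  validate_spec(spec)
  g <- spec$groups
  total <- sum(g$n)
  withr::with_seed(as.integer(seed), {
    rows <- purrr::pmap(g, function(subtype, n, formate_logmean, formate_logsd,
                                    formate_logmean2, formate_logsd2,
                                    formate_mix1, glucose_logmean,
                                    glucose_logsd) {
      if (n == 0) {
        return(tibble::tibble(subtype = character(), formate = numeric(),
                              glucose = numeric()))
      }
      use1 <- stats::runif(n) < formate_mix1
      mu <- ifelse(use1, formate_logmean, formate_logmean2)
      sd <- ifelse(use1, formate_logsd, formate_logsd2)
      tibble::tibble(
        subtype = rep(subtype, n),
        formate = exp(mu + sd * stats::rnorm(n)),
        glucose = exp(glucose_logmean + glucose_logsd * stats::rnorm(n))
      )
    })
    out <- dplyr::bind_rows(rows)
    # sarcosine-like channel: latent-Gaussian coupling to pooled log-formate
    rho <- spec$co_metabolite_rho
    lf <- log(out$formate)
    z <- if (total > 1 && stats::sd(lf) > 0) {
      (lf - mean(lf)) / stats::sd(lf)
    } else {
      rep(0, total)
    }
    eps <- stats::rnorm(total)
    out$sarcosine <- exp(spec$sarcosine_logmean +
                           spec$sarcosine_logsd *
                             (rho * z + sqrt(1 - rho^2) * eps))
    out$sample_id <- sprintf("S%04d", seq_len(nrow(out)))
  })
  if (total == 0) {
    return(validate_cohort(tibble::tibble(sample_id = character(),
                                          subtype = character(),
                                          formate = numeric(),
                                          glucose = numeric(),
                                          sarcosine = numeric())))
  }
  validate_cohort(out)
}
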