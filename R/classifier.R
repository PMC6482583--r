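# Threshold classifiers and threshold selection by relative mutual
# information.
#
# Branch semantics follow the published case definitions literally: all
# comparisons are strict, and a sample equal to a threshold falls through to
# the catch-all healthy branch. Because candidate grids are built from
# observed values, threshold equality is common and this convention matters.

check_biomarker <- function(x, what) {
  if (any(!is.finite(x) | x < 0)) {
    stop(what, " values must be finite and nonnegative", call. = FALSE)
  }
  invisible(NULL)
}

#' Impute cancer/healthy status from formate alone
#'
#' The binomial formate classifier: a sample is imputed as cancer (`c`) when
#' its formate level lies strictly below the threshold `f_t`, and healthy
#' (`h`) otherwise (equality included).
#'
#' @param formate Numeric vector of formate concentrations (mM, nonnegative).
#' @param f_t Formate threshold (mM), finite scalar.
#' @return Factor with levels `h`, `c`.
#' @examples
#' impute_f(c(0.04, 0.054, 0.10), f_t = 0.054)
#' @export
impute_f <- function(formate, f_t) {
  check_biomarker(formate, "formate")
  if (length(f_t) != 1 || !is.finite(f_t)) {
    stop("f_t must be a finite scalar", call. = FALSE)
  }
  factor(ifelse(formate < f_t, "c", "h"), levels = c("h", "c"))
}

#' Impute obesity/cancer/healthy status from glucose and formate
#'
#' The multinomial decision tree: obesity (`o`) when glucose lies strictly
#' above `g_t`; otherwise cancer (`c`) when glucose lies strictly below `g_t`
#' and formate strictly below `f_t`; healthy (`h`) in all remaining cases.
#' Equality with either threshold lands in the catch-all `h` branch.
#'
#' @param glucose Numeric vector of glucose signals (peak area, nonnegative).
#' @param formate Numeric vector of formate concentrations (mM, nonnegative).
#' @param g_t Glucose threshold (peak area), finite scalar.
#' @param f_t Formate threshold (mM), finite scalar.
#' @return Factor with levels `h`, `c`, `o`.
#' @examples
#' impute_gf(glucose = c(2e8, 1e8, 1e8), formate = c(0.03, 0.03, 0.08),
#'           g_t = 1.3e8, f_t = 0.054)
#' @export
impute_gf <- function(glucose, formate, g_t, f_t) {
  check_biomarker(glucose, "glucose")
  check_biomarker(formate, "formate")
  if (length(glucose) != length(formate)) {
    stop("glucose and formate must have equal length", call. = FALSE)
  }
  if (length(g_t) != 1 || !is.finite(g_t) || length(f_t) != 1 ||
      !is.finite(f_t)) {
    stop("thresholds must be finite scalars", call. = FALSE)
  }
  out <- ifelse(glucose > g_t, "o",
                ifelse(glucose < g_t & formate < f_t, "c", "h"))
  factor(out, levels = cohort_classes())
}

#' Candidate threshold grid for a biomarker
#'
#' The sorted distinct observed values of the biomarker, augmented with one
#' sentinel below the minimum and one above the maximum so the all-negative
#' and all-positive classifications are reachable by the grid search.
#'
#' @param cohort A cohort tibble (see [validate_cohort()]).
#' @param biomarker `"formate"` or `"glucose"`.
#' @return Sorted numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(cohort, biomarker = c("formate", "glucose")) {
  biomarker <- match.arg(biomarker)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  threshold_grid(cohort[[biomarker]])
}

threshold_grid <- function(x) {
  v <- sort(unique(x))
  span <- v[length(v)] - v[1]
  delta <- if (span > 0) span / 2 else max(1, abs(v[1]))
  c(v[1] - delta, v, v[length(v)] + delta)
}

# --- vectorised relative mutual information over threshold grids -----------

# 2-class fit (h vs c) across an F-threshold grid.
# cls: integer codes (1 = h, 2 = c); returns rmi per candidate.
rmi_grid_f <- function(formate, cls, cand) {
  n <- length(cls)
  n_h <- sum(cls == 1L)
  n_c <- n - n_h
  # counts imputed c (formate < f_t) per candidate, split by reference class
  less <- outer(formate, cand, "<")
  c_h <- colSums(less[cls == 1L, , drop = FALSE])  # ref h imputed c
  c_c <- colSums(less[cls == 2L, , drop = FALSE])  # ref c imputed c
  counts <- list(hh = n_h - c_h, hc = c_h, ch = n_c - c_c, cc = c_c)
  q <- c(n_h, n_c) / n
  r_c <- (c_h + c_c) / n
  r_h <- 1 - r_c
  term <- function(cnt, qa, rb) {
    p <- cnt / n
    out <- numeric(length(p))
    pos <- p > 0
    out[pos] <- p[pos] * log(p[pos] / (qa * rb[pos]))
    out
  }
  i_abs <- term(counts$hh, q[1], r_h) + term(counts$hc, q[1], r_c) +
    term(counts$ch, q[2], r_h) + term(counts$cc, q[2], r_c)
  i_abs / entropy_from_fractions(q)
}

# Joint imputed-class counts per reference class over a (g, f) grid.
# Returns, for each reference class k, matrices [g, f] of counts imputed c
# and vectors of counts imputed o; h counts follow by complement.
gf_grid_counts <- function(glucose, formate, cls, g_cand, f_cand) {
  below_g <- outer(glucose, g_cand, "<")   # n x nG
  above_g <- outer(glucose, g_cand, ">")
  below_f <- outer(formate, f_cand, "<")   # n x nF
  per_class <- lapply(1:3, function(k) {
    idx <- cls == k
    list(
      n = sum(idx),
      # imputed c: glucose < g AND formate < f
      c = crossprod(below_g[idx, , drop = FALSE],
                    below_f[idx, , drop = FALSE]),
      # imputed o: glucose > g (independent of f)
      o = colSums(above_g[idx, , drop = FALSE])
    )
  })
  names(per_class) <- cohort_classes()
  per_class
}

# 3-class fit across the full (g, f) grid; returns rmi matrix [g, f].
rmi_grid_gf <- function(glucose, formate, cls, g_cand, f_cand) {
  pc <- gf_grid_counts(glucose, formate, cls, g_cand, f_cand)
  n <- length(cls)
  n_g <- length(g_cand)
  n_f <- length(f_cand)
  q <- vapply(pc, function(x) x$n, numeric(1)) / n

  cnt <- function(k, b) {
    x <- pc[[k]]
    switch(b,
           c = x$c,
           o = matrix(x$o, n_g, n_f),
           h = x$n - x$c - matrix(x$o, n_g, n_f))
  }
  r <- list(
    c = (cnt(1, "c") + cnt(2, "c") + cnt(3, "c")) / n,
    o = (cnt(1, "o") + cnt(2, "o") + cnt(3, "o")) / n
  )
  r$h <- 1 - r$c - r$o

  i_abs <- matrix(0, n_g, n_f)
  for (k in 1:3) {
    if (q[k] == 0) next
    for (b in c("h", "c", "o")) {
      p <- cnt(k, b) / n
      pos <- p > 0
      if (any(pos)) {
        i_abs[pos] <- i_abs[pos] + p[pos] * log(p[pos] / (q[k] * r[[b]][pos]))
      }
    }
  }
  i_abs / entropy_from_fractions(q)
}

# --- fitting ---------------------------------------------------------------

new_threshold_fit <- function(classifier, g_t, f_t, rmi, grid, n_train,
                              class_counts) {
  structure(
    list(classifier = classifier, g_t = g_t, f_t = f_t, rmi = rmi,
         grid = grid, n_train = n_train, class_counts = class_counts),
    class = "threshold_fit"
  )
}

# fast core: cls integer codes over h/c rows only
fit_f_core <- function(formate, cls) {
  keep <- cls <= 2L
  formate <- formate[keep]
  cls <- cls[keep]
  if (!any(cls == 1L) || !any(cls == 2L)) {
    stop("degenerate training set: need at least one healthy and one ",
         "cancer sample", call. = FALSE)
  }
  cand <- threshold_grid(formate)
  rmi <- rmi_grid_f(formate, cls, cand)
  # value-based tie-break with a float tolerance: equal-count grid points can
  # differ in the last ulp depending on summation order
  best <- which(rmi >= max(rmi) - 1e-12)[1]  # cand sorted: smallest f_t
  list(f_t = cand[best], rmi = rmi[best], cand = cand, rmi_all = rmi,
       n = length(cls), counts = c(h = sum(cls == 1L), c = sum(cls == 2L)))
}

fit_gf_core <- function(glucose, formate, cls) {
  if (length(unique(cls)) < 3) {
    stop("degenerate training set: need samples from all three classes ",
         "(h, c, o)", call. = FALSE)
  }
  g_cand <- threshold_grid(glucose)
  f_cand <- threshold_grid(formate)
  rmi <- rmi_grid_gf(glucose, formate, cls, g_cand, f_cand)
  mx <- max(rmi)
  hits <- which(rmi >= mx - 1e-12, arr.ind = TRUE)
  # tie-break: smallest f_t, then smallest g_t (grids are sorted ascending)
  ord <- order(hits[, 2], hits[, 1])
  pick <- hits[ord[1], ]
  list(g_t = g_cand[pick[1]], f_t = f_cand[pick[2]], rmi = mx,
       g_cand = g_cand, f_cand = f_cand, rmi_all = rmi, n = length(cls),
       counts = c(h = sum(cls == 1L), c = sum(cls == 2L), o = sum(cls == 3L)))
}

#' Fit the formate-only classifier by relative mutual information
#'
#' Exhaustively searches the candidate formate thresholds (observed values
#' plus sentinels) on the healthy and cancer samples of the training cohort,
#' and returns the threshold maximising the relative mutual information
#' between imputed and reference labels. Ties are broken toward the smallest
#' threshold, so the result is deterministic and invariant to row order.
#' Obesity samples in `train` are ignored during fitting.
#'
#' @param train A cohort tibble containing at least one healthy and one
#'   cancer sample.
#' @return A `threshold_fit` object with elements `f_t`, `rmi`, and a `grid`
#'   tibble of the full rmi profile; see also [tidy()] and [glance()].
#' @examples
#' fit <- optimize_f(generate_cohort(seed = 1))
#' glance(fit)
#' @export
optimize_f <- function(train) {
  train <- validate_cohort(train)
  core <- fit_f_core(train$formate, class_codes(train$class))
  new_threshold_fit(
    classifier = "F", g_t = NA_real_, f_t = core$f_t, rmi = core$rmi,
    grid = tibble::tibble(f_t = core$cand, rmi = core$rmi_all),
    n_train = core$n, class_counts = core$counts
  )
}

#' Fit the (glucose, formate) decision tree by relative mutual information
#'
#' Exhaustively searches the Cartesian grid of candidate glucose and formate
#' thresholds on a cohort containing all three merged classes, maximising the
#' relative mutual information between the decision-tree labels and the
#' reference labels. Among tied optima the pair with the smallest formate
#' threshold, then smallest glucose threshold, is returned.
#'
#' @param train A cohort tibble containing healthy, cancer and obesity
#'   samples.
#' @return A `threshold_fit` object with elements `g_t`, `f_t`, `rmi`, and a
#'   `grid` tibble (`g_t`, `f_t`, `rmi`) covering the full search surface.
#' @examples
#' fit <- optimize_gf(generate_cohort(seed = 1))
#' glance(fit)
#' @export
optimize_gf <- function(train) {
  train <- validate_cohort(train)
  core <- fit_gf_core(train$glucose, train$formate, class_codes(train$class))
  grid <- tidyr::expand_grid(g_t = core$g_cand, f_t = core$f_cand)
  grid$rmi <- as.vector(t(core$rmi_all))  # expand_grid varies f fastest
  new_threshold_fit(
    classifier = "GF", g_t = core$g_t, f_t = core$f_t, rmi = core$rmi,
    grid = grid, n_train = core$n, class_counts = core$counts
  )
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit> ", x$classifier, "-classifier\n", sep = "")
  if (x$classifier == "GF") {
    cat("  g_t:", format(x$g_t, digits = 6), "(peak area)\n")
  }
  cat("  f_t:", format(x$f_t, digits = 6), "mM\n")
  cat("  relative mutual information:", format(x$rmi, digits = 4), "\n")
  cat("  trained on", x$n_train, "samples (",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), ")\n")
  invisible(x)
}

#' Predict class labels for a cohort from a fitted threshold classifier
#'
#' @param object A `threshold_fit`.
#' @param new_data A cohort tibble.
#' @param ... Unused.
#' @return Factor of imputed labels: levels `h`, `c` for the F-classifier,
#'   `h`, `c`, `o` for the (G,F)-classifier.
#' @export
predict.threshold_fit <- function(object, new_data, ...) {
  new_data <- validate_cohort(new_data)
  if (object$classifier == "F") {
    impute_f(new_data$formate, object$f_t)
  } else {
    impute_gf(new_data$glucose, new_data$formate, object$g_t, object$f_t)
  }
}

#' @method tidy threshold_fit
#' @export
tidy.threshold_fit <- function(x, ...) x$grid

#' @method glance threshold_fit
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, g_t = x$g_t, f_t = x$f_t,
                 rmi = x$rmi, n_train = x$n_train)
}
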