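# Plug-in mutual information between two finite classifications, in nats.
# Internal fast path works on integer codes; the exported functions validate
# and delegate.

check_labels <- function(reference, imputed) {
  if (length(reference) != length(imputed)) {
    stop("reference and imputed labels must have equal length", call. = FALSE)
  }
  if (length(reference) == 0) stop("empty sample set", call. = FALSE)
  if (anyNA(reference) || anyNA(imputed)) {
    stop("labels must not contain missing values", call. = FALSE)
  }
  invisible(NULL)
}

# a, b: integer codes in 1..na / 1..nb
mi_codes <- function(a, b, na, nb) {
  n <- length(a)
  joint <- tabulate((a - 1L) * nb + b, nbins = na * nb) / n
  q <- tabulate(a, nbins = na) / n
  r <- tabulate(b, nbins = nb) / n
  qr <- rep(q, each = nb) * rep.int(r, na)
  pos <- joint > 0
  # the plug-in estimator is provably nonnegative; summation rounding can
  # leave a tiny negative residue near independence
  max(0, sum(joint[pos] * log(joint[pos] / qr[pos])))
}

entropy_from_fractions <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Mutual information between imputed and reference classifications
#'
#' Plug-in estimator `I = sum_ab p_ab ln(p_ab / (q_a r_b))` over the joint
#' class fractions, in nats (natural logarithm). Empty cells contribute zero
#' (the `0 ln 0 = 0` limit). The statistic is symmetric in its arguments and
#' always nonnegative.
#'
#' @param reference Vector (character or factor) of reference class labels.
#' @param imputed Vector of imputed class labels, same length.
#' @return Mutual information in nats (scalar, `>= 0`).
#' @examples
#' mutual_information(c("h", "h", "c", "c"), c("h", "h", "c", "c")) # ln 2
#' @export
mutual_information <- function(reference, imputed) {
  check_labels(reference, imputed)
  a <- as.integer(factor(as.character(reference)))
  b <- as.integer(factor(as.character(imputed)))
  mi_codes(a, b, max(a), max(b))
}

#' Relative mutual information of a classifier
#'
#' Mutual information normalised by the reference-label entropy
#' `H(S) = -sum_a q_a ln q_a`, its maximum attainable value (reached when the
#' imputed labels reproduce the reference exactly). Equals 1 for a perfect
#' match and 0 when imputed and reference labels are independent.
#'
#' @inheritParams mutual_information
#' @return Dimensionless value in `[0, 1]`.
#' @examples
#' relative_mutual_information(c("h", "c", "o"), c("h", "c", "o")) # 1
#' @export
relative_mutual_information <- function(reference, imputed) {
  check_labels(reference, imputed)
  a <- as.integer(factor(as.character(reference)))
  if (max(a) < 2) {
    stop("reference labels must take at least two distinct values ",
         "(normalisation undefined for a single class)", call. = FALSE)
  }
  b <- as.integer(factor(as.character(imputed)))
  h <- entropy_from_fractions(tabulate(a) / length(a))
  mi_codes(a, b, max(a), max(b)) / h
}

#' Permutation p-value for the relative mutual information
#'
#' Shuffles the reference labels uniformly at random `n_perm` times and
#' reports the add-one permutation p-value
#' `p = (1 + #\{i_perm >= i_obs\}) / (1 + n_perm)`, which is never exactly 0.
#' Shuffling preserves the label marginals, so permuting the reference or the
#' imputed labels is equivalent for this statistic.
#'
#' @inheritParams mutual_information
#' @param n_perm Number of permutations (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return Scalar p-value in `(0, 1]`.
#' @examples
#' s <- rep(c("h", "c"), each = 20)
#' permutation_pvalue(s, s, n_perm = 999, seed = 1)
#' @export
permutation_pvalue <- function(reference, imputed, n_perm = 10000,
                               seed = NULL) {
  check_labels(reference, imputed)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  a <- as.integer(factor(as.character(reference)))
  b <- as.integer(factor(as.character(imputed)))
  na <- max(a)
  nb <- max(b)
  i_obs <- mi_codes(a, b, na, nb)
  run <- function() {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      if (mi_codes(sample(a), b, na, nb) >= i_obs) hits <- hits + 1L
    }
    hits
  }
  hits <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  (1 + hits) / (1 + n_perm)
}
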