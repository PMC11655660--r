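#' One-sample group test of decoding performance against chance
#'
#' One-sample t test of per-subject AUC values against the chance level.
#' Decoding contrasts use a one-tailed test (greater than chance), since
#' below-chance decoding is uninterpretable; two-tailed is available for
#' other quantities.
#'
#' @param aucs per-subject values (>= 2).
#' @param chance chance level (0.5 for balanced binary AUC).
#' @param tail `"one"` (greater) or `"two"`.
#' @return list with `t`, `df`, `p`, `mean`, `n`, `tail`.
#' @export
group_auc_test <- function(aucs, chance = 0.5, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (length(aucs) < 2) stop_invalid("need >= 2 subjects")
  if (stats::sd(aucs) == 0) {
    # degenerate but possible at ceiling performance: all subjects equal
    d <- mean(aucs) - chance
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (tail == "one") {
      if (d > 0) 0 else if (d < 0) 1 else 0.5
    } else {
      if (d == 0) 1 else 0
    }
    return(list(t = t, df = length(aucs) - 1, p = p, mean = mean(aucs),
                n = length(aucs), tail = tail))
  }
  ht <- stats::t.test(aucs, mu = chance,
                      alternative = if (tail == "one") "greater" else "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(aucs), n = length(aucs), tail = tail)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment: adjusted values are monotone
#' in rank and capped at 1.
#'
#' @param p_values raw p values in `[0, 1]`.
#' @return adjusted p values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation between two spatial patterns
#'
#' @param a,b equally-sized pattern vectors; if both are named, names
#'   must match.
#' @return Pearson correlation across features.
#' @export
pattern_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("patterns have different lengths")
  if (length(a) < 3) stop_invalid("need >= 3 features")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop_invalid("patterns have mismatched feature ids")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_invalid("pattern correlation undefined for zero-variance input")
  }
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Permutation test for a mean within-subject pattern correlation
#'
#' The observed statistic is the mean over participants of the Pearson
#' correlation between each participant's two patterns. Under the null,
#' the feature order of the second pattern is shuffled independently
#' within each participant, the mean correlation recomputed, and this is
#' repeated `K` times to build the null distribution. The p value uses
#' the add-one estimator `p = (1 + #{|null| >= |observed|}) / (K + 1)`
#' (never exactly zero), two-tailed on the magnitude since correlations
#' of either sign are interpretable.
#'
#' @param pairs list with one element per participant, each a list (or
#'   2-element list) holding patterns `a` and `b`.
#' @param K number of permutations (>= 1); 1000 is conventional.
#' @param seed integer seed; participant x iteration shuffles all
#'   descend from it.
#' @return a `permutation_outcome` list: `observed_mean_r`,
#'   `null_values` (length `K`), `p`, `K`, `per_subject_r`, `seed`.
#' @export
permutation_corr_test <- function(pairs, K = 1000, seed = 1) {
  if (K < 1) stop_invalid("K must be >= 1")
  if (length(pairs) < 2) stop_invalid("need >= 2 participants")
  obs <- vapply(pairs, function(pr) pattern_correlation(pr[[1]], pr[[2]]),
                numeric(1))
  observed <- mean(obs)
  null_values <- with_seed(seed, {
    acc <- matrix(0, K, length(pairs))
    for (i in seq_along(pairs)) {
      a <- as.numeric(pairs[[i]][[1]])
      b <- as.numeric(pairs[[i]][[2]])
      nf <- length(b)
      perm <- vapply(seq_len(K), function(k) b[sample.int(nf)],
                     numeric(nf))
      acc[, i] <- drop(stats::cor(a, perm))
    }
    rowMeans(acc)
  })
  p <- (1 + sum(abs(null_values) >= abs(observed))) / (K + 1)
  structure(list(observed_mean_r = observed, null_values = null_values,
                 p = p, K = K, per_subject_r = obs, seed = seed),
            class = "permutation_outcome")
}

#' @export
print.permutation_outcome <- function(x, ...) {
  cat(sprintf(
    "<permutation_outcome> mean r = %.3f, p = %.4g (K = %d permutations)\n",
    x$observed_mean_r, x$p, x$K))
  invisible(x)
}
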