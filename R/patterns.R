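#' Fit a classifier on all pseudo-trials and back-project its weights
#'
#' Fits the full decoding stack (pseudo-trial averaging, train-set
#' standardization, PCA at `pca_variance`, linear SVM) on all available
#' data — no fold split, since the weights are wanted for
#' interpretation, not generalization scoring — and back-projects the
#' SVM weight vector through the PCA basis and the standardization
#' scaling into the original feature space. Weights are oriented so that
#' a larger decision value means the second factor level of `y` (the
#' "positive" class; by package convention `hard` or `colour`).
#'
#' @param x observations x features matrix or [signal_features].
#' @param y binary class labels.
#' @param config a [decode_config].
#' @return list with `weights` (original feature space), `weights_std`
#'   (standardized space), `z` (the standardized pseudo-trial matrix the
#'   classifier saw), `kept` (feature indices surviving standardization),
#'   `feature_ids`, and `positive`.
#' @export
fit_full_weights <- function(x, y, config = decode_config()) {
  ids <- NULL
  if (inherits(x, "signal_features")) {
    ids <- x$feature_ids
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(ids)) ids <- colnames(x)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop_invalid("need exactly 2 classes")
  positive <- levels(y)[2]
  ps <- make_pseudotrials(x, y, config$pseudo_size,
                          seed = derive_seed(config$seed, 303))
  st <- standardize(ps$x)
  pc <- pca_reduce(st$train, NULL, config$pca_variance)
  model <- fit_linear_svm(pc$train, ps$y, config$cost)
  w_pca <- drop(crossprod(model$coefs, model$SV))
  first <- model$levels[model$labels[1]]
  if (!identical(first, positive)) w_pca <- -w_pca
  w_std <- drop(pc$rotation %*% w_pca)
  w_orig <- w_std / st$scale
  if (!is.null(ids)) names(w_orig) <- names(w_std) <- ids[st$kept]
  list(weights = w_orig, weights_std = w_std, z = st$train, kept = st$kept,
       feature_ids = ids, positive = positive)
}

#' Haufe transform: classifier weights to activation patterns
#'
#' Linear classifier weights are extraction filters and cannot be read
#' as per-feature signal strength; multiplying them by the feature
#' covariance yields the corresponding activation pattern, which for a
#' linear model equals the univariate class contrast up to scale. The
#' pattern is normalized to unit Euclidean norm (it is defined only up
#' to positive scale). Signs are kept: positive entries mean greater
#' signal in the positive (second-level) class.
#'
#' @param weights feature-space weight vector.
#' @param features observations x features matrix from which the
#'   covariance is estimated (>= 2 rows); by convention the standardized
#'   pseudo-trial matrix the classifier was fitted on.
#' @return named numeric vector (class `activation_pattern`).
#' @export
haufe_transform <- function(weights, features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop_invalid("need >= 2 observations for covariance")
  if (ncol(features) != length(weights)) {
    stop_invalid("weights length (%d) must match feature count (%d)",
                 length(weights), ncol(features))
  }
  p <- drop(stats::cov(features) %*% as.numeric(weights))
  nrm <- sqrt(sum(p^2))
  if (nrm > 0) p <- p / nrm
  names(p) <- colnames(features)
  structure(p, class = c("activation_pattern", "numeric"))
}

#' One-call activation pattern for a binary contrast
#'
#' Convenience wrapper: [fit_full_weights()] followed by
#' [haufe_transform()] using the covariance of the standardized
#' pseudo-trial features the classifier was fitted on.
#'
#' @inheritParams fit_full_weights
#' @return named `activation_pattern` vector.
#' @export
activation_pattern <- function(x, y, config = decode_config()) {
  fw <- fit_full_weights(x, y, config)
  haufe_transform(fw$weights_std, fw$z)
}

#' Aggregate activation patterns across subjects and subtasks
#'
#' Each pattern is z-scored across its features (removing per-pattern
#' scale and offset), then the z-scored patterns are averaged
#' elementwise. All patterns must share the same feature identities.
#'
#' @param patterns list of equally-named numeric pattern vectors.
#' @return named numeric group pattern.
#' @export
aggregate_patterns <- function(patterns) {
  if (!length(patterns)) stop_invalid("no patterns supplied")
  ids <- names(patterns[[1]])
  for (p in patterns) {
    if (length(p) != length(patterns[[1]]) ||
        (!is.null(ids) && !identical(names(p), ids))) {
      stop_invalid("patterns have mismatched feature ids")
    }
  }
  zs <- vapply(patterns,
               function(p) as.numeric(scale(as.numeric(p))),
               numeric(length(patterns[[1]])))
  out <- rowMeans(zs)
  names(out) <- ids
  out
}

#' Threshold a pattern at a magnitude percentile
#'
#' Retains features whose absolute value ranks at or above the given
#' percentile of all absolute values (e.g. `lower_percentile = 60`
#' keeps the top 40% strongest features). Retained entries keep their
#' signs, so both increases and decreases survive thresholding; ties at
#' the cutoff are all retained.
#'
#' @param pattern numeric pattern vector.
#' @param lower_percentile in `[0, 100)`.
#' @return list with `mask` (logical) and `pattern` (thresholded values,
#'   zero where masked out).
#' @export
percentile_mask <- function(pattern, lower_percentile = 60) {
  if (!length(pattern)) stop_invalid("empty pattern")
  if (lower_percentile < 0 || lower_percentile >= 100) {
    stop_invalid("lower_percentile must lie in [0, 100)")
  }
  a <- abs(as.numeric(pattern))
  thr <- stats::quantile(a, lower_percentile / 100, names = FALSE, type = 7)
  mask <- a >= thr
  out <- as.numeric(pattern)
  out[!mask] <- 0
  names(mask) <- names(out) <- names(pattern)
  list(mask = mask, pattern = out)
}

#' Write pattern tables as tidy TSV
#'
#' @param patterns named list of pattern vectors (names = e.g.
#'   "signal/contrast" identifiers).
#' @param path output path.
#' @param lower_percentile threshold used for the `retained` flag.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(patterns, path, lower_percentile = 60) {
  rows <- lapply(names(patterns), function(nm) {
    p <- patterns[[nm]]
    pm <- percentile_mask(p, lower_percentile)
    data.frame(id = nm, feature_id = names(p), value = as.numeric(p),
               retained = pm$mask, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
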