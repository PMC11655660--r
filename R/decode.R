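#' Decoding configuration
#'
#' Settings for the MVPA stage: pseudo-trial averaging, repeated
#' stratified k-fold cross-validation, PCA dimensionality reduction and
#' a linear support-vector classifier.
#'
#' Defaults: pseudo-trials of 4 raw trials, 5 folds, 25 repetitions
#' (pseudo-trials are redrawn inside every repetition so results do not
#' depend on one particular set of trial averages), PCA components
#' retained up to 99% cumulative variance, SVM cost 1. Performance is
#' the area under the ROC curve computed from continuous decision
#' values, not hard labels.
#'
#' @param n_folds number of cross-validation folds (>= 2).
#' @param n_reps number of repetitions of the whole procedure.
#' @param pca_variance cumulative explained-variance fraction to retain
#'   (in (0, 1]; 1 disables reduction).
#' @param pseudo_size raw trials averaged per pseudo-trial (>= 1).
#' @param cost SVM regularization constant.
#' @param seed integer seed; all fold assignments and pseudo-trial draws
#'   descend from it via [derive_seed()].
#' @return an object of class `decode_config`.
#' @export
decode_config <- function(n_folds = 5, n_reps = 25, pca_variance = 0.99,
                          pseudo_size = 4, cost = 1, seed = 1) {
  if (n_folds < 2) stop_invalid("n_folds must be >= 2")
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  if (pca_variance <= 0 || pca_variance > 1) {
    stop_invalid("pca_variance must lie in (0, 1]")
  }
  if (pseudo_size < 1) stop_invalid("pseudo_size must be >= 1")
  if (cost <= 0) stop_invalid("cost must be positive")
  structure(list(n_folds = n_folds, n_reps = n_reps,
                 pca_variance = pca_variance, pseudo_size = pseudo_size,
                 cost = cost, seed = seed),
            class = "decode_config")
}

#' Average raw trials into pseudo-trials
#'
#' Within each class, observations are randomly partitioned into groups
#' of `pseudo_size` and averaged; remainder trials that do not fill a
#' group are excluded. Class counts are then equated by randomly
#' removing surplus pseudo-trials from the larger class, so downstream
#' AUC is computed on balanced data.
#'
#' @param x observations x features matrix, or a [signal_features].
#' @param y class labels (coerced to factor).
#' @param pseudo_size raw trials per pseudo-trial.
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return list with `x` (pseudo-trial matrix) and `y` (balanced factor).
#' @export
make_pseudotrials <- function(x, y, pseudo_size, seed = NULL) {
  if (inherits(x, "signal_features")) x <- x$x
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  run <- function() {
    parts <- lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      if (length(idx) < pseudo_size) {
        stop_invalid("class '%s' has %d observation(s), fewer than pseudo_size = %d",
                     lv, length(idx), pseudo_size)
      }
      idx <- sample(idx)
      ng <- length(idx) %/% pseudo_size
      idx <- idx[seq_len(ng * pseudo_size)]
      g <- rep(seq_len(ng), each = pseudo_size)
      rowsum(x[idx, , drop = FALSE], g, reorder = TRUE) / pseudo_size
    })
    nmin <- min(vapply(parts, nrow, 1L))
    parts <- lapply(parts, function(p) {
      if (nrow(p) > nmin) p[sort(sample.int(nrow(p), nmin)), , drop = FALSE]
      else p
    })
    list(x = do.call(rbind, parts),
         y = factor(rep(levels(y), each = nmin), levels = levels(y)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Standardize features using training-set statistics
#'
#' Per-feature mean and standard deviation are estimated on `train` and
#' applied to both `train` and `test`, so no test-set information leaks
#' into the scaling. Zero-variance features are dropped with a warning
#' naming them.
#'
#' @param train observations x features matrix with >= 2 rows.
#' @param test optional matrix with the same columns.
#' @return list with standardized `train`, `test` (or `NULL`), the
#'   applied `center` and `scale`, and `kept` (column indices retained).
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop_invalid("need >= 2 training rows to standardize")
  m <- colMeans(train)
  s <- sqrt(colSums(sweep(train, 2, m)^2) / (nrow(train) - 1))
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    nm <- colnames(train)
    ids <- if (is.null(nm)) as.character(which(zero)) else nm[zero]
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(ids, collapse = ", ")), call. = FALSE)
  }
  keep <- which(!zero)
  if (!length(keep)) stop_invalid("all features have zero variance")
  ztr <- sweep(sweep(train[, keep, drop = FALSE], 2, m[keep]), 2, s[keep], "/")
  zte <- NULL
  if (!is.null(test)) {
    zte <- sweep(sweep(as.matrix(test)[, keep, drop = FALSE], 2, m[keep]),
                 2, s[keep], "/")
  }
  list(train = ztr, test = zte, center = m[keep], scale = s[keep],
       kept = keep)
}

# PCA fitted on the training rows only; both sets projected onto the
# smallest number of leading components reaching `variance` cumulative
# explained variance.
pca_reduce <- function(train, test, variance) {
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ve) >= variance - 1e-12)[1]
  if (is.na(k)) k <- length(ve)
  list(train = pc$x[, seq_len(k), drop = FALSE],
       test = if (is.null(test)) NULL else
         sweep(test, 2, pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center, k = k, var_explained = ve)
}

fit_linear_svm <- function(x, y, cost) {
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
}

# Continuous decision values oriented so that larger means `positive`.
svm_scores <- function(model, x, positive) {
  w <- crossprod(model$coefs, model$SV)      # 1 x p
  s <- drop(as.matrix(x) %*% t(w)) - model$rho
  first <- model$levels[model$labels[1]]
  if (identical(first, positive)) s else -s
}

# Rank (Mann-Whitney) AUC of scores for the positive class.
auc_from_scores <- function(scores, y, positive) {
  pos <- y == positive
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0 || nn == 0) stop_invalid("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# Shuffled fold assignment stratified by class.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    if (length(idx) < k) {
      stop_invalid("class '%s' has %d pseudo-trial(s), fewer than %d folds",
                   lv, length(idx), k)
    }
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Within-condition decoding with repeated cross-validation
#'
#' For each repetition: pseudo-trials are rebuilt with a fresh seeded
#' draw, assigned to stratified folds, and each fold is scored by
#' standardizing on the training folds, fitting PCA there (retaining
#' `pca_variance` cumulative variance), projecting both sides, fitting a
#' linear SVM, and computing the test-fold AUC from continuous decision
#' values. The result is the mean AUC over folds and repetitions. The
#' positive class (larger decision values) is the second factor level.
#'
#' @param x observations x features matrix or [signal_features].
#' @param y binary class labels.
#' @param config a [decode_config].
#' @return a `decoding_result` list: `auc` (grand mean), `auc_reps`
#'   (per-repetition means), `n_pseudotrials`, `n_reps`, `positive`.
#' @export
decode_within <- function(x, y, config = decode_config()) {
  if (inherits(x, "signal_features")) x <- x$x
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop_invalid("decode_within needs exactly 2 classes")
  positive <- levels(y)[2]
  aucs <- numeric(config$n_reps)
  n_ps <- NA_integer_
  for (r in seq_len(config$n_reps)) {
    ps <- make_pseudotrials(x, y, config$pseudo_size,
                            seed = derive_seed(config$seed, 101, r))
    n_ps <- nrow(ps$x)
    folds <- with_seed(derive_seed(config$seed, 202, r),
                       stratified_folds(ps$y, config$n_folds))
    fold_auc <- numeric(config$n_folds)
    for (k in seq_len(config$n_folds)) {
      tr <- folds != k
      st <- standardize(ps$x[tr, , drop = FALSE], ps$x[!tr, , drop = FALSE])
      pc <- pca_reduce(st$train, st$test, config$pca_variance)
      model <- fit_linear_svm(pc$train, ps$y[tr], config$cost)
      sc <- svm_scores(model, pc$test, positive)
      fold_auc[k] <- auc_from_scores(sc, ps$y[!tr], positive)
    }
    aucs[r] <- mean(fold_auc)
  }
  structure(list(auc = mean(aucs), auc_reps = aucs, n_pseudotrials = n_ps,
                 n_reps = config$n_reps, positive = positive),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> AUC = %.3f (%d reps, %d pseudo-trials)\n",
              x$auc, x$n_reps, x$n_pseudotrials))
  invisible(x)
}

#' Cross-condition decoding (train on one subtask, test on another)
#'
#' Pseudo-trials are built in both sets; standardization and PCA are
#' fitted on the training subtask only (no test-set leakage); the
#' classifier is fitted on all training pseudo-trials (no fold split)
#' and scored by AUC on the test pseudo-trials. Repeated over
#' `config$n_reps` pseudo-trial draws and averaged.
#'
#' @param train_x,train_y training subtask features and binary labels.
#' @param test_x,test_y testing subtask features and binary labels
#'   (same classes and same features as training).
#' @param config a [decode_config].
#' @return mean AUC for this train-to-test direction.
#' @export
decode_cross <- function(train_x, train_y, test_x, test_y,
                         config = decode_config()) {
  if (inherits(train_x, "signal_features") && inherits(test_x, "signal_features")) {
    if (!identical(train_x$feature_ids, test_x$feature_ids)) {
      stop_invalid("train and test feature_ids differ")
    }
    if (!identical(train_x$signal, test_x$signal)) {
      stop_invalid("train (%s) and test (%s) signals differ",
                   train_x$signal, test_x$signal)
    }
    train_x <- train_x$x
    test_x <- test_x$x
  }
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) {
    stop_invalid("train (%d) and test (%d) feature counts differ",
                 ncol(train_x), ncol(test_x))
  }
  train_y <- droplevels(factor(train_y))
  test_y <- factor(test_y, levels = levels(train_y))
  if (nlevels(train_y) != 2 || anyNA(test_y)) {
    stop_invalid("train and test must share the same 2 classes")
  }
  positive <- levels(train_y)[2]
  aucs <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    ps_tr <- make_pseudotrials(train_x, train_y, config$pseudo_size,
                               seed = derive_seed(config$seed, 404, r))
    ps_te <- make_pseudotrials(test_x, test_y, config$pseudo_size,
                               seed = derive_seed(config$seed, 505, r))
    st <- standardize(ps_tr$x, ps_te$x)
    pc <- pca_reduce(st$train, st$test, config$pca_variance)
    model <- fit_linear_svm(pc$train, ps_tr$y, config$cost)
    sc <- svm_scores(model, pc$test, positive)
    aucs[r] <- auc_from_scores(sc, ps_te$y, positive)
  }
  mean(aucs)
}

#' Cross-task generalization matrix
#'
#' Square subtask x subtask table of decoding AUC for one signal:
#' diagonal entries are within-subtask cross-validated AUC
#' ([decode_within()]); each off-diagonal entry is the average of the
#' two train-test directions between the pair ([decode_cross()]), so
#' the matrix is symmetric by construction.
#'
#' @param xs named list of per-subtask feature matrices (or
#'   [signal_features]), one element per subtask.
#' @param ys list of binary label vectors aligned with `xs`.
#' @param config a [decode_config].
#' @return symmetric numeric matrix with subtask dimnames.
#' @export
generalization_matrix <- function(xs, ys, config = decode_config()) {
  if (length(xs) < 2) stop_invalid("need >= 2 subtasks")
  if (length(ys) != length(xs)) stop_invalid("xs and ys lengths differ")
  nm <- names(xs)
  if (is.null(nm)) nm <- paste0("subtask", seq_along(xs))
  n <- length(xs)
  M <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    M[i, i] <- decode_within(xs[[i]], ys[[i]], config)$auc
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ab <- decode_cross(xs[[i]], ys[[i]], xs[[j]], ys[[j]], config)
      ba <- decode_cross(xs[[j]], ys[[j]], xs[[i]], ys[[i]], config)
      M[i, j] <- M[j, i] <- (ab + ba) / 2
    }
  }
  M
}
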