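test_that("pseudo-trial counts follow the grouping and equalization rules", {
  set.seed(1)
  x <- matrix(rnorm(68 * 3), 68, 3)
  y <- factor(c(rep("easy", 38), rep("hard", 30)),
              levels = c("easy", "hard"))
  ps <- make_pseudotrials(x, y, 4, seed = 2)
  # 38 -> 9 groups (2 remainder dropped), 30 -> 7; equalized to 7 + 7
  expect_identical(as.vector(table(ps$y)), c(7L, 7L))
  expect_identical(nrow(ps$x), 14L)
  # without the smaller class the larger yields 9
  ps38 <- make_pseudotrials(x[y == "easy", ], factor(rep("easy", 38)), 4,
                            seed = 2)
  expect_identical(nrow(ps38$x), 9L)
  # averaging identical trials reproduces the common row
  xc <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  psc <- make_pseudotrials(xc, factor(rep("a", 4)), 4, seed = 1)
  expect_equal(unname(psc$x), matrix(c(1, 2, 3), 1, 3))
  expect_error(make_pseudotrials(x[1:3, ], factor(rep("a", 3)), 4),
               "fewer than pseudo_size")
})

test_that("standardization uses training statistics and drops constants", {
  set.seed(2)
  tr <- matrix(rnorm(40), 10, 4)
  colnames(tr) <- paste0("F", 1:4)
  st <- standardize(tr, tr)
  expect_lt(max(abs(colMeans(st$train))), 1e-10)
  expect_equal(unname(apply(st$train, 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_equal(st$train, st$test)
  # test-set statistics are never used
  te2 <- matrix(rnorm(40, mean = 100), 10, 4)
  st2 <- standardize(tr, te2)
  expect_identical(st2$center, st$center)
  expect_identical(st2$scale, st$scale)
  expect_identical(st2$train, st$train)
  # constant features are dropped with a warning naming them
  tr3 <- cbind(tr, F5 = 7)
  expect_warning(st3 <- standardize(tr3), "F5")
  expect_identical(ncol(st3$train), 4L)
  expect_error(standardize(tr[1, , drop = FALSE]), ">= 2")
})

test_that("oriented decision scores match e1071 predict()", {
  g <- gaussian_classes(30, 4, d = 1.5, seed = 3)
  model <- irasadecode:::fit_linear_svm(g$x, g$y, cost = 1)
  s <- irasadecode:::svm_scores(model, g$x, positive = "hard")
  dv <- attr(predict(model, g$x, decision.values = TRUE),
             "decision.values")
  expect_equal(abs(s), unname(abs(drop(dv))), tolerance = 1e-8)
  # orientation: hard trials score higher on average
  expect_gt(mean(s[g$y == "hard"]), mean(s[g$y == "easy"]))
})

test_that("rank-based AUC matches the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(30)
  y <- factor(rep(c("easy", "hard"), each = 50), levels = c("easy", "hard"))
  scores <- rnorm(100) + (y == "hard") * 0.8
  ours <- irasadecode:::auc_from_scores(scores, y, positive = "hard")
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, levels = c("easy", "hard"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("decoding is perfect for separated classes and calibrated for d = 1", {
  sep <- gaussian_classes(40, 3, d = 10, seed = 4)
  res <- decode_within(sep$x, sep$y,
                       decode_config(n_reps = 2, pseudo_size = 1, seed = 5))
  expect_equal(res$auc, 1.0)
  # closed-form Gaussian oracle: AUC = pnorm(d / sqrt(2)) ~ 0.760
  g <- gaussian_classes(2000, 1, d = 1, seed = 6)
  res2 <- decode_within(g$x, g$y,
                        decode_config(n_reps = 1, pseudo_size = 1, seed = 7))
  expect_equal(res2$auc, pnorm(1 / sqrt(2)), tolerance = 0.02)
})

test_that("decoding is deterministic given the config seed", {
  g <- gaussian_classes(40, 6, d = 0.5, seed = 8)
  cfg <- decode_config(n_reps = 3, seed = 9)
  r1 <- decode_within(g$x, g$y, cfg)
  r2 <- decode_within(g$x, g$y, cfg)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$auc_reps, r2$auc_reps)
})

test_that("label-shuffled decoding sits near chance", {
  set.seed(10)
  g <- gaussian_classes(100, 6, d = 2, seed = 10)
  y_shuf <- sample(g$y)
  res <- decode_within(g$x, y_shuf, decode_config(n_reps = 5, seed = 11))
  expect_gt(res$auc, 0.3)
  expect_lt(res$auc, 0.7)
})

test_that("AUC rises monotonically with simulated effect size", {
  aucs <- vapply(c(0, 0.7, 1.5, 3), function(d) {
    g <- gaussian_classes(60, 8, d = d, seed = 12)
    decode_within(g$x, g$y, decode_config(n_reps = 3, seed = 13))$auc
  }, numeric(1))
  expect_identical(order(aucs), 1:4)   # Spearman rho = 1 on the 4-point grid
})

test_that("cross-decoding transfers, anti-transfers, and nulls correctly", {
  cfg <- decode_config(n_reps = 5, seed = 14)
  make_set <- function(sign, seed) {
    set.seed(seed)
    x <- matrix(rnorm(80 * 6), 80, 6)
    y <- factor(rep(c("easy", "hard"), each = 40),
                levels = c("easy", "hard"))
    x[y == "hard", 1:3] <- x[y == "hard", 1:3] + sign * 1.5
    list(x = x, y = y)
  }
  a <- make_set(+1, 15)
  b <- make_set(+1, 16)   # independent draw, same effect map
  neg <- make_set(-1, 17) # negated effect map
  within_auc <- decode_within(a$x, a$y, cfg)$auc
  cross_ab <- decode_cross(a$x, a$y, b$x, b$y, cfg)
  expect_lt(abs(cross_ab - within_auc), 0.08)
  expect_lt(decode_cross(a$x, a$y, neg$x, neg$y, cfg), 0.5)
  # shuffled test labels -> chance on average over shuffles (any single
  # shuffle retains chance-level correlation with the true labels)
  set.seed(18)
  null_aucs <- vapply(1:6, function(i) {
    decode_cross(a$x, a$y, b$x, sample(b$y), cfg)
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)
  expect_error(decode_cross(a$x[, 1:4], a$y, b$x, b$y, cfg), "feature")
})

test_that("generalization matrices are symmetric with sensible entries", {
  cfg <- decode_config(n_reps = 3, seed = 19)
  mk <- function(seed, cols) {
    set.seed(seed)
    x <- matrix(rnorm(64 * 8), 64, 8)
    y <- factor(rep(c("easy", "hard"), each = 32),
                levels = c("easy", "hard"))
    x[y == "hard", cols] <- x[y == "hard", cols] + 1.5
    list(x = x, y = y)
  }
  a <- mk(20, 1:3)
  b <- mk(21, 1:3)
  ort <- mk(22, 6:8)  # orthogonal effect map
  M <- generalization_matrix(list(A = a$x, B = b$x, C = ort$x),
                             list(a$y, b$y, ort$y), cfg)
  expect_identical(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  # shared-map pair generalizes close to its diagonal
  expect_lt(abs(M["A", "B"] - mean(c(M["A", "A"], M["B", "B"]))), 0.1)
  # orthogonal subtask does not
  expect_lt(abs(M["A", "C"] - 0.5), 0.15)
  expect_error(generalization_matrix(list(a$x), list(a$y), cfg), ">= 2")
})
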