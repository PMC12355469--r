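# PCA, OPLS-DA, VIP, confusion metrics, cross-validation, permutation
# testing, ROC and Mann-Whitney.

test_that("PCA matches a direct eigendecomposition", {
  set.seed(20)
  # data on one line through the mean: PC1 explains everything
  t <- rnorm(30)
  d <- rnorm(50)
  X1 <- outer(t, d)
  p1 <- spectraPCA(X1)
  expect_equal(p1$explained[1], 100)
  # completeness and eigen oracle
  X <- matrix(rnorm(20 * 50), 20, 50)
  p <- spectraPCA(X)
  expect_equal(sum(p$explained), 100, tolerance = 1e-9)
  ev <- eigen(cov(X), symmetric = TRUE)
  r <- min(19, 50)
  expect_equal(p$explained[1:10],
               100 * ev$values[1:10] / sum(pmax(ev$values, 0)),
               tolerance = 1e-8)
  for (j in 1:5) {
    v <- ev$vectors[, j]
    expect_lt(min(max(abs(p$loadings[, j] - v)),
                  max(abs(p$loadings[, j] + v))), 1e-8)
  }
  expect_error(spectraPCA(matrix(1, 5, 4)), "constant")
})

test_that("OPLS-DA separates predictive and orthogonal structure", {
  pl <- plantedOPLS(seed = 42)
  fit <- oplsFit(pl$X, pl$y, nOrtho = 1)
  expect_gte(abs(sum(fit@weightsPred * pl$w)), 0.999)
  expect_gte(abs(sum(fit@weightsOrtho[, 1] * pl$q)), 0.999)
  expect_lt(abs(cor(fit@scoresOrtho[, 1], pl$y)), 1e-8)
  # no orthogonal structure: orthogonal score norms vanish with the noise
  set.seed(1)
  w <- rnorm(30); w <- w / sqrt(sum(w^2))
  y <- rep(c(1, -1), 10)
  for (eps in c(1e-3, 1e-5)) {
    Xn <- outer(y, w) + matrix(rnorm(600, 0, eps), 20)
    fn <- oplsFit(Xn, y, nOrtho = 1)
    expect_lt(sqrt(sum(fn@scoresOrtho[, 1]^2)) /
                sqrt(sum(fn@scoresPred^2)), 20 * eps)
  }
  expect_error(oplsFit(pl$X, rep("a", nrow(pl$X)), 1), "two classes")
  # orthogonality invariant over random fits
  set.seed(33)
  for (rep in 1:10) {
    X <- matrix(rnorm(24 * 40), 24)
    yy <- rep(c(1, -1), each = 12)
    f <- oplsFit(X, yy, nOrtho = 3)
    for (h in seq_len(f@nOrtho))
      expect_lt(abs(cor(f@scoresOrtho[, h], yy)), 1e-8)
    expect_lt(abs(mean(vipScores(f)^2) - 1), 1e-9)
  }
})

test_that("nOrtho = 0 reproduces an independent PLS1 oracle", {
  set.seed(77)
  X <- matrix(rnorm(30 * 80), 30)
  y <- rep(c(1, -1), each = 15)
  fit <- oplsFit(X, y, nOrtho = 0)
  Xnew <- matrix(rnorm(10 * 80), 10)
  expect_lt(max(abs(oplsPredict(fit, X)$yhat - pls1Oracle(X, y))), 1e-10)
  expect_lt(max(abs(oplsPredict(fit, Xnew)$yhat -
                      pls1Oracle(X, y, Xnew))), 1e-10)
})

test_that("prediction is exact projection arithmetic", {
  pl <- plantedOPLS(seed = 9)
  fit <- oplsFit(pl$X, pl$y, nOrtho = 1)
  pr <- oplsPredict(fit, pl$X)
  expect_true(all((pr$yhat > 0) == (pl$y > 0)))
  # duplicated sample gives the identical prediction
  pr2 <- oplsPredict(fit, pl$X[c(1, 1), ])
  expect_equal(pr2$yhat[1], pr2$yhat[2])
  # hand-rolled projection on a 3-sample toy
  X3 <- matrix(c(1, 0, 0,
                 0, 1, 0,
                 0, 0, 1), 3, byrow = TRUE)
  y3 <- c(1, -1, 1)
  f3 <- oplsFit(X3, y3, nOrtho = 0)
  Xc <- scale(X3, scale = FALSE)
  w <- crossprod(Xc, y3 - mean(y3)); w <- w / sqrt(sum(w^2))
  t3 <- Xc %*% w
  q3 <- sum((y3 - mean(y3)) * t3) / sum(t3^2)
  manual <- as.numeric(t3 * q3 + mean(y3))
  expect_lt(max(abs(oplsPredict(f3, X3)$yhat - manual)), 1e-12)
  expect_error(oplsPredict(oplsFit(pl$X, pl$y, 1,
                                   wavenumbers = seq_len(ncol(pl$X))),
                           pl$X, wavenumbers = seq_len(ncol(pl$X)) + 1),
               "axis")
})

test_that("VIP highlights informative channels", {
  set.seed(14)
  n <- 60; m <- 25
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(rnorm(n * m, 0, 0.05), n, m)
  X[, 7] <- X[, 7] + y           # single informative channel
  fit <- oplsFit(X, y, nOrtho = 0)
  v <- vipScores(fit)
  expect_equal(which.max(v), 7L)
  expect_gt(v[7], 1)
  expect_lt(abs(sum(v^2) - m), 1e-6)
  # all channels identically informative: all VIP exactly 1
  Xeq <- outer(y, rep(1, m))
  veq <- vipScores(oplsFit(Xeq, y, nOrtho = 0))
  expect_equal(veq, rep(1, m))
})

test_that("confusion metrics follow their definitions", {
  perfect <- confusionMetrics(50, 0, 50, 0)
  expect_equal(perfect, list(sensitivity = 1, specificity = 1, mcc = 1))
  expect_equal(confusionMetrics(25, 25, 25, 25)$mcc, 0)
  # MCC equals the Pearson correlation of the binary truth/prediction pairs
  m <- confusionMetrics(45, 10, 40, 5)
  truth <- c(rep(1, 45), rep(0, 10), rep(0, 40), rep(1, 5))
  pred  <- c(rep(1, 45), rep(1, 10), rep(0, 40), rep(0, 5))
  expect_equal(m$mcc, cor(truth, pred), tolerance = 1e-12)
  expect_equal(m$sensitivity, 45 / 50)
  expect_equal(m$specificity, 40 / 50)
  expect_error(confusionMetrics(-1, 0, 0, 1), "non-negative")
})

test_that("group-stratified cross-validation behaves at the extremes", {
  pl <- plantedOPLS(n = 28, m = 40, seed = 3)
  y <- ifelse(pl$y > 0, "precursor", "erythrocyte_like")
  cv <- crossValidate(pl$X, y, seq_len(28), nOrtho = 1, kFolds = 7,
                      seed = 1, classLevels = c("precursor",
                                                "erythrocyte_like"))
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$mcc, 1)
  expect_equal(cv$TP + cv$FN, sum(y == "precursor"))
  expect_equal(cv$TN + cv$FP, sum(y == "erythrocyte_like"))
  # groups never span folds
  byGroup <- tapply(cv$predictions$fold, cv$predictions$group,
                    function(f) length(unique(f)))
  expect_true(all(byGroup == 1))
  # null data: MCC near zero on average (hygienic pipeline, no leakage)
  set.seed(50)
  nullMCC <- vapply(1:20, function(s) {
    X <- matrix(rnorm(24 * 30), 24)
    yy <- sample(rep(c("a", "b"), each = 12))
    crossValidate(X, yy, seq_len(24), nOrtho = 1, kFolds = 4, seed = s,
                  classLevels = c("a", "b"))$mcc
  }, 0)
  expect_lt(abs(mean(nullMCC)), 0.15)
})

test_that("permutation test applies the add-one smoothed formula", {
  pl <- plantedOPLS(n = 16, m = 10, seed = 8)
  y <- ifelse(pl$y > 0, "a", "b")
  # constant statistic: every null draw ties the observed value -> p = 1
  ptTie <- permutationTest(pl$X, y, seq_len(16), nPerm = 99, nOrtho = 0,
                           kFolds = 4, statistic = function(cv) 0, seed = 2)
  expect_equal(ptTie$p_value, 1)
  # separable data: observed above all 99 draws -> p = 1/100
  ptSep <- permutationTest(pl$X, y, seq_len(16), nPerm = 99, nOrtho = 0,
                           kFolds = 4, seed = 2)
  expect_equal(ptSep$p_value, 0.01)
  expect_equal(ptSep$observed, 1)
  expect_error(permutationTest(pl$X, y, seq_len(16), nPerm = 10), "99")
})

test_that("ROC analysis equals the all-pairs Mann-Whitney statistic", {
  # perfect separation
  r <- rocCurve(c(1, 2, 3, 11, 12, 13), rep(c("neg", "pos"), each = 3),
                positive = "pos")
  expect_equal(r$auc, 1)
  expect_true(r$threshold > 3 && r$threshold < 11)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # monotone sweep
  ordT <- order(r$thresholds)
  expect_true(all(diff(r$tpr[ordT]) <= 0) && all(diff(r$fpr[ordT]) <= 0))
  # AUC == all-pairs oracle, including ties
  set.seed(31)
  for (rep in 1:10) {
    v <- sample(round(rnorm(40), 1))       # coarse values force ties
    lab <- sample(rep(c("pos", "neg"), each = 20))
    rc <- rocCurve(v, lab, positive = "pos")
    expect_equal(rc$auc, aucOracle(v, lab, "pos"), tolerance = 1e-12)
  }
  # null: AUC near 0.5 for independent labels at large n
  set.seed(32)
  vNull <- rnorm(2000)
  lNull <- sample(rep(c("pos", "neg"), each = 1000))
  expect_lt(abs(rocCurve(vNull, lNull, positive = "pos")$auc - 0.5), 0.05)
  # constant values are flagged degenerate with AUC 0.5
  dg <- rocCurve(rep(1, 10), rep(c("pos", "neg"), 5), positive = "pos")
  expect_true(dg$degenerate)
  expect_equal(dg$auc, 0.5)
})

test_that("Mann-Whitney p-values match exact enumeration and wilcox.test", {
  mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)             # 2/20 rank assignments
  expect_identical(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # U_a + U_b = n1 * n2
  set.seed(40)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(9)
    expect_equal(mannWhitney(a, b)$U + mannWhitney(b, a)$U, 63)
  }
  # tie-free exact mode agrees with wilcox.test's exact p
  for (rep in 1:5) {
    a <- rnorm(8); b <- rnorm(6, 0.5)
    expect_equal(mannWhitney(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large samples fall back to the tie-corrected normal approximation
  a <- rnorm(40); b <- rnorm(30, 0.3)
  big <- mannWhitney(a, b)
  expect_equal(big$method, "normal-approximation")
  expect_equal(big$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})
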