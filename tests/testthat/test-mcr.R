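# MCR-ALS: NNLS solver, purest-variable initialization, ALS recovery,
# contrast step, signal fractions, high-intensity pixel statistics and
# component matching.

test_that("the multi-RHS NNLS solver agrees with lsqnonneg", {
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(runif(30 * 4), 30, 4)
    B <- matrix(rnorm(30 * 6), 30, 6)
    X <- RamanEry:::.nnlsMultiple(crossprod(A), crossprod(A, B))
    for (j in 1:6) {
      ref <- pracma::lsqnonneg(A, B[, j])$x
      expect_equal(X[, j], ref, tolerance = 1e-6)
    }
    expect_true(all(X >= 0))
  }
})

test_that("purest-variable initialization finds pure structure", {
  # two non-collinear components with abundant pure pixels
  mix <- pureMixCube(k = 2, shape = c(24L, 24L), nchan = 300,
                     pureFrac = 0.3, seed = 13)
  S0 <- initPurestVariables(mix$cube, 2)
  mt <- matchComponents(S0, mix$S)
  expect_true(all(mt$cosines >= 0.99))
  # k = 1 reduces to the brute-force purity criterion over channels
  D <- matrix(mix$cube, ncol = 300)
  mu <- colMeans(D)
  sg <- apply(D, 2, sd)
  alpha <- 0.03 * max(mu)
  S1 <- initPurestVariables(mix$cube, 1)
  expect_equal(attr(S1, "channels"), which.max(sg / (mu + alpha)))
  # duplicated channels: the second selection never repeats the first
  Ddup <- cbind(D[, 1:10], D[, 1:10])
  cube2 <- array(Ddup, c(24, 24, 20))
  S2 <- initPurestVariables(cube2, 2)
  ch <- attr(S2, "channels")
  expect_false(ch[2] == ch[1] || ch[2] == ch[1] + 10 || ch[2] == ch[1] - 10)
})

test_that("MCR-ALS recovers exact and noiseless factorizations", {
  # rank-1 non-negative cube: recovered spectrum equals truth up to scale
  set.seed(2)
  ax <- seq(600, by = 2, length.out = 120)
  s <- buildEndmember(endmemberSpec("p", bands(c(700, 760), c(1, 0.5))), ax)
  c1 <- rgamma(100, 2)
  cube1 <- array(outer(c1, s), c(10, 10, 120))
  cs1 <- mcrALS(cube1, k = 1, tolLOF = 1e-9)
  cosv <- sum(componentSpectra(cs1)[1, ] * s) /
    sqrt(sum(componentSpectra(cs1)[1, ]^2) * sum(s^2))
  expect_gte(cosv, 0.999)
  # noiseless 3-component cube with pure pixels
  mix <- pureMixCube(k = 3, shape = c(32L, 32L), nchan = 300, seed = 17)
  cs <- mcrALS(mix$cube, k = 3, tolLOF = 1e-8, maxIter = 300)
  expect_lt(lofPercent(cs), 1)
  mt <- matchComponents(componentSpectra(cs), mix$S)
  expect_true(all(mt$cosines >= 0.98))
  # non-negativity of the returned factors
  expect_gte(min(componentSpectra(cs)), 0)
  expect_gte(min(concentrationMatrix(cs)), 0)
  # huge tolerance: stops after the first iteration
  csFast <- mcrALS(mix$cube, k = 3, tolLOF = 1e9)
  expect_equal(csFast@iterations, 1L)
  expect_error(mcrALS(mix$cube, k = 2000), "pixels")
})

test_that("the contrast step is sum-preserving dominant-component shrinkage", {
  C <- matrix(c(0.6, 0.4), 1)
  expect_identical(contrastStep(C, 0), C)
  expect_equal(contrastStep(C, 1), matrix(c(1, 0), 1))
  set.seed(4)
  Cr <- matrix(rgamma(300, 1), 100, 3)
  for (w in c(0.2, 0.5, 0.9)) {
    Cw <- contrastStep(Cr, w)
    expect_lt(max(abs(rowSums(Cw) - rowSums(Cr))), 1e-12)
    expect_true(all(Cw >= 0))
  }
  expect_error(contrastStep(Cr, 1.5), "weight")
})

test_that("signal fractions partition the sum-squared signal", {
  set.seed(6)
  ax <- seq(600, by = 2, length.out = 80)
  s1 <- buildEndmember(endmemberSpec("a", bands(700, 1, 14)), ax)
  s2 <- buildEndmember(endmemberSpec("b", bands(740, 1, 14)), ax)
  # single component, exact factorization: fraction = 100%
  c1 <- rgamma(64, 2)
  cube1 <- array(outer(c1, s1), c(8, 8, 80))
  cs1 <- mcrALS(cube1, k = 1, tolLOF = 1e-10)
  fr1 <- signalFractions(cs1, cube1)
  expect_equal(fr1$fractions, 100, tolerance = 1e-6)
  # disjoint spatial support: fractions sum to 100 - residual; the identity
  # is checked on an exactly constructed factorization so it isolates the
  # fraction computation from ALS convergence
  C <- matrix(0, 64, 2)
  C[1:32, 1] <- rgamma(32, 2)
  C[33:64, 2] <- rgamma(32, 2)
  S12 <- rbind(s1, s2)
  D <- C %*% S12
  cube2 <- array(D, c(8, 8, 80))
  cs2 <- new("ComponentSet", S = S12, concentration = C,
             mapDim = c(8L, 8L), wavenumbers = ax,
             lofPercent = 0, lofHistory = 0,
             signalFractions = numeric(0), residualPercent = NA_real_,
             iterations = 1L, converged = TRUE)
  fr2 <- signalFractions(cs2, cube2)
  expect_lt(abs(sum(fr2$fractions) + fr2$residual - 100), 1e-9)
  # relabeling invariance
  perm <- new("ComponentSet", S = cs2@S[2:1, ],
              concentration = concentrationMatrix(cs2)[, 2:1],
              mapDim = cs2@mapDim, wavenumbers = cs2@wavenumbers,
              lofPercent = cs2@lofPercent, lofHistory = cs2@lofHistory,
              signalFractions = numeric(0), residualPercent = NA_real_,
              iterations = cs2@iterations, converged = cs2@converged)
  frp <- signalFractions(perm, cube2)
  expect_equal(frp$fractions, fr2$fractions[2:1])
  expect_error(signalFractions(cs2, array(0, c(8, 8, 80))), "zero-signal")
})

test_that("high-intensity pixel fractions follow the threshold rules", {
  m <- matrix(5, 10, 10)
  expect_equal(as.numeric(highIntensityFraction(m, rule = "absolute",
                                                value = 1)), 100)
  set.seed(3)
  pooled <- runif(4000)
  f <- highIntensityFraction(matrix(pooled[1:2000], 40, 50),
                             rule = "percentile", value = 0.6,
                             pooled = pooled)
  expect_equal(as.numeric(highIntensityFraction(matrix(pooled, 80, 50),
                                                rule = "percentile",
                                                value = 0.6,
                                                pooled = pooled)),
               40, tolerance = 0.1)
  expect_error(highIntensityFraction(matrix(1, 5, 5), rule = "otsu"),
               "constant")
  # hemoglobin direction: high-intensity percent larger in the class with
  # raised hemoglobin abundance, across 10 seeds (sign test)
  profs <- defaultClassProfiles()
  wins <- vapply(1:10, function(s) {
    phA <- makePhantom(3, c(128L, 128L), seed = s)
    phB <- makePhantom(3, c(128L, 128L),
                       list(radiusScale =
                              profs$erythrocyte_like$cell_radius_scale),
                       seed = s + 100)
    ax <- seq(600, 640, by = 10)
    iA <- simulateHSImage(phA, profs$precursor, axis = ax, seed = s)
    iB <- simulateHSImage(phB, profs$erythrocyte_like, axis = ax,
                          seed = s + 100)
    hA <- iA@metadata$ground_truth$C[, "hemoglobin"]
    hB <- iB@metadata$ground_truth$C[, "hemoglobin"]
    cellA <- hA > 0 | iA@metadata$ground_truth$C[, "protein_cytoplasm"] > 0
    cellB <- hB > 0 | iB@metadata$ground_truth$C[, "protein_cytoplasm"] > 0
    pooled <- c(hA[cellA], hB[cellB])
    fA <- highIntensityFraction(matrix(hA[cellA]), rule = "percentile",
                                value = 0.6, pooled = pooled)
    fB <- highIntensityFraction(matrix(hB[cellB]), rule = "percentile",
                                value = 0.6, pooled = pooled)
    fB > fA
  }, TRUE)
  # all 10 in the reported direction: one-sided sign test p = 2^-10 < 0.05
  expect_true(all(wins))
})

test_that("component matching is an optimal, scale-invariant assignment", {
  set.seed(12)
  S <- matrix(rgamma(5 * 40, 2), 5, 40)
  perm <- sample(5)
  mt <- matchComponents(S[perm, ], S)
  expect_equal(mt$permutation, perm)
  expect_equal(mt$cosines, rep(1, 5))
  # scale invariance
  Ssc <- S
  Ssc[3, ] <- 5 * Ssc[3, ]
  mts <- matchComponents(Ssc, S)
  expect_equal(mts$cosines, rep(1, 5))
  # brute-force assignment oracle on noisy copies
  for (rep in 1:5) {
    St <- matrix(rgamma(4 * 30, 2), 4, 30)
    Se <- St[sample(4), ] + matrix(rnorm(120, 0, 0.3), 4)
    Se <- abs(Se)
    sim <- matchComponents(Se, St)$similarity
    perms <- allPermutations(4)
    tot <- apply(perms, 1, function(p) sum(sim[cbind(1:4, p)]))
    best <- perms[which.max(tot), ]
    got <- matchComponents(Se, St)$permutation
    expect_equal(sum(sim[cbind(1:4, got)]), max(tot), tolerance = 1e-12)
  }
  # differing counts: unmatched estimated rows are NA
  mtp <- matchComponents(S, S[1:3, ])
  expect_equal(sum(is.na(mtp$permutation)), 2)
})
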