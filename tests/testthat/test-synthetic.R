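# Synthetic-data generator: band rendering, phantoms, image simulation,
# cohort spectra, and the linear-mixing / determinism / directionality
# contracts.

test_that("band rendering matches the closed-form peak shapes", {
  ax <- seq(900, 1100, by = 1)
  sp <- endmemberSpec("one", bands(center = 1006, amplitude = 1, fwhm = 10))
  y <- buildEndmember(sp, ax)
  expect_equal(y[ax == 1006], 1)                    # peak value = amplitude
  expect_equal(y[ax == 1006 + 5], 0.5)              # Lorentzian half height
  expect_equal(y[ax == 1006 - 5], 0.5)
  # pointwise numeric evaluation of the Lorentzian
  u <- (ax - 1006) / 5
  expect_equal(y, 1 / (1 + u^2))
  # Gaussian branch: half height at center +/- fwhm/2
  spg <- endmemberSpec("g", bands(1000, 2, 20, shape = "gaussian"))
  yg <- buildEndmember(spg, ax)
  expect_equal(yg[ax == 1000], 2)
  expect_equal(yg[ax == 1010], 1)
  expect_error(endmemberSpec("bad", bands(numeric(0))), "degenerate")
})

test_that("hemoglobin endmember peaks sit at the reported band positions", {
  ax <- seq(600, 1800, by = 2)
  hb <- buildEndmember(endmemberLibrary()$hemoglobin, ax)
  peaks <- ax[which(diff(sign(diff(hb))) == -2) + 1]
  expected <- c(753, 1130, 1310, 1340, 1377, 1400, 1555, 1585, 1610)
  for (b in expected)
    expect_true(min(abs(peaks - b)) <= 2,
                label = sprintf("peak near %d cm-1", b))
  expect_true(all(renderLibrary(axis = ramanAxis()) >= 0))
})

test_that("phantoms satisfy the mask invariants and are reproducible", {
  ph <- makePhantom(1, c(64L, 64L), seed = 4)
  expect_length(ph, 1)
  p <- ph[[1]]
  expect_true(any(p$mask_nucleus))
  expect_true(all(p$mask_nucleus <= p$mask_cell))        # nucleus in cell
  expect_true(all(p$mask_mito <= p$mask_cytoplasm))
  expect_true(all(p$mask_lipid_droplets <= p$mask_cytoplasm))
  expect_identical(p$mask_cytoplasm, p$mask_cell & !p$mask_nucleus)
  # one connected component
  lab <- EBImage::bwlabel(EBImage::Image(p$mask_cell * 1))
  expect_equal(max(lab), 1)
  # determinism
  ph2 <- makePhantom(1, c(64L, 64L), seed = 4)
  expect_identical(ph, ph2)
  # pairwise non-overlap, brute force
  many <- makePhantom(20, c(256L, 256L), seed = 9)
  for (i in seq_along(many)) {
    for (j in seq_len(i - 1)) {
      expect_false(any(many[[i]]$mask_cell & many[[j]]$mask_cell))
    }
  }
})

test_that("noiseless cubes are exact bilinear mixtures with ground truth", {
  ph <- makePhantom(2, c(48L, 48L), seed = 2)
  prof <- defaultClassProfiles()$precursor
  ax <- ramanAxis(from = 600, to = 1000)
  img <- simulateHSImage(ph, prof, axis = ax, noise = noiseParams(), seed = 5)
  gt <- img@metadata$ground_truth
  recon <- gt$C %*% gt$S
  expect_equal(max(abs(matrix(cubeData(img), ncol = length(ax)) - recon)), 0)
  # determinism: bit-identical repeat
  img2 <- simulateHSImage(ph, prof, axis = ax, noise = noiseParams(),
                          seed = 5)
  expect_identical(cubeData(img), cubeData(img2))
  expect_error(noiseParams(gain = -1), "non-negative")
})

test_that("probe_scale = 0 leaves only background in the probe window", {
  ph <- makePhantom(2, c(48L, 48L), seed = 2)
  profs <- defaultClassProfiles()
  p0 <- profs$precursor
  p0$probe_scale <- 0
  ax <- seq(1900, 2500, by = 6)
  img <- simulateHSImage(ph, p0, axis = ax, noise = noiseParams(), seed = 5)
  gt <- img@metadata$ground_truth
  win <- which(ax >= 2150 & ax <= 2300)
  noProbe <- setdiff(rownames(gt$S), "probe_MB")
  bgOnly <- gt$C[, noProbe] %*% gt$S[noProbe, win]
  flat <- matrix(cubeData(img), ncol = length(ax))[, win]
  expect_equal(mean(flat), mean(bgOnly))
  # with the probe on, the window carries strictly more signal
  img1 <- simulateHSImage(ph, profs$precursor, axis = ax,
                          noise = noiseParams(), seed = 5)
  expect_gt(mean(matrix(cubeData(img1), ncol = length(ax))[, win]),
            mean(flat))
})

test_that("Poisson-Gaussian noise matches its stated variance at high count", {
  lam <- 400
  gain <- 0.5
  readSD <- 3
  np <- noiseParams(gain = gain, readSD = readSD)
  set.seed(11)
  draws <- replicate(4000,
    RamanEry:::.applyNoise(matrix(lam, 1, 1), np)[1, 1])
  expected <- gain * lam + readSD^2
  expect_lt(abs(var(draws) - expected) / expected, 0.1)
  expect_lt(abs(mean(draws) - lam) / lam, 0.02)
})

test_that("cohort spectra mix linearly and respect the class contrast", {
  profs <- defaultClassProfiles()
  ax <- ramanAxis()
  # identical profiles, noise on: band-wise two-sample t-tests behave as null
  pNull <- profs$precursor
  pNull$class_label <- "erythrocyte_like"   # same abundances, other label
  se0 <- simulateCohortSpectra(30, list(profs$precursor, pNull),
                               axis = ax, noiseSD = 0.04, seed = 21)
  cm0 <- cohortMatrix(se0)
  pvals <- vapply(seq_along(ax), function(j)
    t.test(cm0$X[cm0$y == "precursor", j],
           cm0$X[cm0$y != "precursor", j])$p.value, 0)
  expect_gte(mean(pvals > 0.05), 0.94)
  # hemoglobin doubled, noiseless: 1610 cm-1 mean intensity exactly doubles
  hbOnly <- endmemberLibrary()["hemoglobin"]
  paH <- classProfile("precursor", c(hemoglobin = 1), abundanceCV = 0)
  pbH <- classProfile("erythrocyte_like", c(hemoglobin = 2), abundanceCV = 0)
  seH <- simulateCohortSpectra(3, list(paH, pbH), library = hbOnly,
                               axis = ax, noiseSD = 0, seed = 1)
  cmH <- cohortMatrix(seH)
  i1610 <- which(ax == 1610)
  m <- tapply(cmH$X[, i1610], cmH$y, mean)
  expect_equal(unname(m["erythrocyte_like"] / m["precursor"]), 2)
  # determinism
  seA <- simulateCohortSpectra(5, profs, axis = ax, seed = 33)
  seB <- simulateCohortSpectra(5, profs, axis = ax, seed = 33)
  expect_identical(SummarizedExperiment::assay(seA),
                   SummarizedExperiment::assay(seB))
})

test_that("default class profiles encode the reported marker directions", {
  profs <- defaultClassProfiles()
  pre <- profs$precursor$abundance_mean
  dox <- profs$erythrocyte_like$abundance_mean
  expect_gt(dox["hemoglobin"], pre["hemoglobin"])
  expect_lt(dox["cytochrome_c"], pre["cytochrome_c"])
  expect_gt(dox["glycogen"], pre["glycogen"])
  expect_lt(dox["nuclear"], pre["nuclear"])
  expect_gt(dox["lipid_saturated"] / dox["lipid_unsaturated"],
            pre["lipid_saturated"] / pre["lipid_unsaturated"])
  expect_lt(profs$erythrocyte_like$probe_scale, profs$precursor$probe_scale)
  expect_gt(profs$erythrocyte_like$background_scale,
            profs$precursor$background_scale)
  # the directions survive to noiseless class-mean spectra
  ax <- ramanAxis()
  p0 <- profs
  p0$precursor$abundance_cv <- 0
  p0$erythrocyte_like$abundance_cv <- 0
  se <- simulateCohortSpectra(2, p0, axis = ax, noiseSD = 0, seed = 1)
  cm <- cohortMatrix(se)
  mPre <- colMeans(cm$X[cm$y == "precursor", ])
  mDox <- colMeans(cm$X[cm$y == "erythrocyte_like", ])
  expect_gt(mDox[ax == 1610], mPre[ax == 1610])   # hemoglobin marker band up
  expect_lt(mDox[ax == 2222], mPre[ax == 2222])   # probe band down
})
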