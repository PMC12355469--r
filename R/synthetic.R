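## Synthetic Raman / SRS data generator: endmember spectra built from band
## tables, hyperspectral cell phantoms with ground truth, and labeled
## single-cell cohorts. The defaults encode the biology of drug-induced
## erythroid differentiation: hemoglobin and glycogen rise, cytochrome c and
## nuclear material fall, lipids shift toward saturated species, the
## mitochondrial alkyne probe signal weakens, the silent-region fluorescence
## background grows, and cells enlarge.

# Evaluate with and restore the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default wavenumber axes
#'
#' @param mode "raman" gives the fingerprint-to-CH full axis at 2 cm^-1
#'   steps; "hsSRS" the CH-stretch window sampled at 6 cm^-1 steps, the
#'   acquisition step of hyperspectral SRS stacks.
#' @param from,to optional axis limits (cm^-1).
#' @return numeric, strictly increasing wavenumber grid.
#' @export
ramanAxis <- function(mode = c("raman", "hsSRS"), from = NULL, to = NULL) {
  mode <- match.arg(mode)
  if (mode == "raman") {
    if (is.null(from)) from <- 600
    if (is.null(to)) to <- 3100
    seq(from, to, by = 2)
  } else {
    if (is.null(from)) from <- 2800
    if (is.null(to)) to <- 3050
    seq(from, to, by = 6)
  }
}

#' Band table constructor
#'
#' @param center band positions (cm^-1).
#' @param amplitude peak heights (>= 0); recycled.
#' @param fwhm full widths at half maximum (cm^-1, > 0); recycled.
#' @param shape "lorentzian" or "gaussian" per band; recycled.
#' @param eta pseudo-Voigt Lorentzian fraction in `[0, 1]`; only used when
#'   shape = "lorentzian"; eta = 1 is a pure Lorentzian.
#' @return data.frame with one row per band.
#' @export
bands <- function(center, amplitude = 1, fwhm = 12,
                  shape = "lorentzian", eta = 1) {
  n <- length(center)
  out <- data.frame(center = center, amplitude = rep_len(amplitude, n),
                    fwhm = rep_len(fwhm, n), shape = rep_len(shape, n),
                    eta = rep_len(eta, n), stringsAsFactors = FALSE)
  if (any(out$fwhm <= 0)) stop("band fwhm must be > 0")
  if (any(out$amplitude < 0)) stop("band amplitude must be >= 0")
  if (!all(out$shape %in% c("lorentzian", "gaussian")))
    stop("band shape must be 'lorentzian' or 'gaussian'")
  out
}

#' Endmember specification
#'
#' An endmember is a sum of vibrational bands plus an optional smooth
#' polynomial background bump confined to a wavenumber window (used to model
#' the silent-region fluorescence pedestal).
#'
#' @param name endmember label, unique within a library.
#' @param bandTable data.frame from [bands()]; may have zero rows only when
#'   a baseline term is present.
#' @param baselineOrder polynomial order of the background bump (0 = none).
#' @param baselineWindow length-2 wavenumber interval carrying the bump.
#' @param baselineAmplitude peak height of the bump.
#' @return list of class "EndmemberSpec".
#' @export
endmemberSpec <- function(name, bandTable = bands(numeric(0)),
                          baselineOrder = 0L,
                          baselineWindow = c(1800, 2800),
                          baselineAmplitude = 0) {
  if (nrow(bandTable) == 0L && (baselineOrder == 0L || baselineAmplitude <= 0))
    stop("degenerate endmember: no bands and no baseline term")
  structure(list(name = name, bands = bandTable,
                 baselineOrder = as.integer(baselineOrder),
                 baselineWindow = baselineWindow,
                 baselineAmplitude = baselineAmplitude),
            class = "EndmemberSpec")
}

# Smooth non-negative polynomial bump on [w1, w2], zero outside, peak ~ 1.
.baselineBump <- function(axis, window, order) {
  s <- (axis - window[1]) / diff(window)
  inside <- s >= 0 & s <= 1
  b <- numeric(length(axis))
  if (!any(inside)) return(b)
  # peak-normalize by the analytic maximum on [0, 1] so the rendered bump
  # does not depend on how the axis samples the window
  f <- if (order >= 3) {
    function(u) u * (1 - u) * (0.8 + 0.4 * u)  # cubic, red-edge tilt
  } else {
    function(u) u * (1 - u)
  }
  vmax <- max(f(seq(0, 1, length.out = 2001)))
  b[inside] <- f(s[inside]) / vmax
  b
}

#' Render one endmember spectrum on an axis
#'
#' Peak value of each band equals its amplitude; Lorentzian bands take value
#' amplitude/2 at center +/- fwhm/2.
#'
#' @param spec an [endmemberSpec()].
#' @param axis strictly increasing wavenumber grid.
#' @return non-negative numeric spectrum, length(axis).
#' @export
buildEndmember <- function(spec, axis) {
  stopifnot(inherits(spec, "EndmemberSpec"))
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  y <- numeric(length(axis))
  bt <- spec$bands
  for (i in seq_len(nrow(bt))) {
    u <- (axis - bt$center[i]) / (bt$fwhm[i] / 2)
    lor <- 1 / (1 + u^2)
    gau <- exp(-log(2) * u^2)
    y <- y + bt$amplitude[i] *
      if (bt$shape[i] == "gaussian") gau
      else bt$eta[i] * lor + (1 - bt$eta[i]) * gau
  }
  if (spec$baselineOrder > 0L && spec$baselineAmplitude > 0)
    y <- y + spec$baselineAmplitude *
      .baselineBump(axis, spec$baselineWindow, spec$baselineOrder)
  y
}

#' Built-in endmember library
#'
#' Nine endmembers covering the biochemical species resolved in
#' resonance-enhanced single-cell Raman images of erythroid cells:
#' hemoglobin and cytochrome c (overlapping haem bands at 753/1130/1310/1585
#' but distinct oxidation-marker bands), glycogen, saturated and unsaturated
#' lipids, nuclear material (DNA/RNA/nucleoprotein), cytoplasmic protein
#' (phenylalanine + amide bands + CH3 stretch), the alkyne mitochondrial
#' probe (2222 cm^-1), and a silent-region fluorescence pedestal.
#'
#' @return named list of [endmemberSpec()] objects.
#' @export
endmemberLibrary <- function() {
  lst <- list(
    hemoglobin = endmemberSpec("hemoglobin", bands(
      center    = c(753, 1130, 1310, 1340, 1377, 1400, 1555, 1585, 1610, 2930),
      amplitude = c(1.0, 0.55, 0.6, 0.7, 0.65, 0.5, 0.75, 0.8, 0.7, 0.35),
      fwhm      = c(12, 12, 14, 14, 12, 12, 14, 14, 12, 40))),
    cytochrome_c = endmemberSpec("cytochrome_c", bands(
      center    = c(611, 647, 753, 1130, 1175, 1315, 1450, 1585, 1653, 2930),
      amplitude = c(0.3, 0.25, 1.0, 0.8, 0.3, 0.85, 0.35, 0.9, 0.4, 0.3),
      fwhm      = c(12, 12, 12, 12, 12, 14, 16, 14, 20, 40))),
    glycogen = endmemberSpec("glycogen", bands(
      center    = c(483, 579, 856, 941, 1051, 1084, 1130, 1337, 1387, 1460,
                    2910),
      amplitude = c(0.9, 0.4, 0.6, 0.55, 0.5, 0.55, 0.45, 0.4, 0.45, 0.5,
                    0.8),
      fwhm      = c(14, 14, 14, 14, 14, 14, 14, 16, 16, 18, 50))),
    lipid_saturated = endmemberSpec("lipid_saturated", bands(
      center    = c(725, 1075, 1306, 1440, 1740, 2850, 2880),
      amplitude = c(0.3, 0.4, 0.6, 0.8, 0.45, 1.0, 0.7),
      fwhm      = c(14, 16, 16, 18, 16, 24, 26))),
    lipid_unsaturated = endmemberSpec("lipid_unsaturated", bands(
      center    = c(1260, 1660, 2850, 3009),
      amplitude = c(0.5, 0.7, 0.6, 0.55),
      fwhm      = c(16, 18, 24, 18))),
    nuclear = endmemberSpec("nuclear", bands(
      center    = c(789, 1098, 1195, 1290, 1340, 1380, 1490, 1585, 2876,
                    2940, 2980),
      amplitude = c(0.8, 0.5, 0.35, 0.4, 0.6, 0.5, 0.45, 0.5, 0.55, 0.8,
                    0.5),
      fwhm      = c(14, 16, 14, 14, 16, 16, 14, 14, 30, 34, 26))),
    protein_cytoplasm = endmemberSpec("protein_cytoplasm", bands(
      center    = c(1006, 1040, 1265, 1450, 1662, 2930),
      amplitude = c(1.0, 0.35, 0.5, 0.6, 0.8, 1.0),
      fwhm      = c(8, 10, 18, 18, 22, 38))),
    probe_MB = endmemberSpec("probe_MB", bands(
      center = 2222, amplitude = 1, fwhm = 16)),
    baseline_fluorescence = endmemberSpec("baseline_fluorescence",
      bands(numeric(0)), baselineOrder = 3L,
      baselineWindow = c(1800, 2800), baselineAmplitude = 1)
  )
  lst
}

#' Render a library of endmembers on an axis
#'
#' @param library named list of [endmemberSpec()]s (default
#'   [endmemberLibrary()]).
#' @param axis wavenumber grid.
#' @return k x length(axis) matrix, rownames = endmember names.
#' @export
renderLibrary <- function(library = endmemberLibrary(), axis = ramanAxis()) {
  nm <- vapply(library, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("endmember names must be unique")
  S <- t(vapply(library, buildEndmember, numeric(length(axis)), axis = axis))
  rownames(S) <- nm
  S
}

#' Class abundance profile
#'
#' @param classLabel "precursor" or "erythrocyte_like".
#' @param abundanceMean named non-negative vector of mean abundances, names
#'   matching the endmember library.
#' @param abundanceCV relative SD of per-cell abundances (scalar or named).
#' @param backgroundScale multiplier on the silent-region fluorescence
#'   endmember.
#' @param probeScale multiplier on the probe endmember abundance.
#' @param cellRadiusScale multiplier on phantom cell radii (differentiated
#'   cells are larger).
#' @return list of class "ClassProfile".
#' @export
classProfile <- function(classLabel, abundanceMean, abundanceCV = 0.18,
                         backgroundScale = 1, probeScale = 1,
                         cellRadiusScale = 1) {
  stopifnot(classLabel %in% c("precursor", "erythrocyte_like"),
            all(abundanceMean >= 0), backgroundScale >= 0, probeScale >= 0)
  structure(list(class_label = classLabel,
                 abundance_mean = abundanceMean,
                 abundance_cv = abundanceCV,
                 background_scale = backgroundScale,
                 probe_scale = probeScale,
                 cell_radius_scale = cellRadiusScale),
            class = "ClassProfile")
}

#' Default class profiles for the two-population model
#'
#' Encodes the reported direction of every differentiation marker:
#' erythrocyte-like cells have more hemoglobin and glycogen, less
#' cytochrome c and nuclear material, a saturated-lipid shift, a weaker
#' mitochondrial probe signal, a stronger silent-region background, and a
#' larger cell body.
#'
#' @return named list with elements `precursor` and `erythrocyte_like`.
#' @export
defaultClassProfiles <- function() {
  base <- c(hemoglobin = 0.35, cytochrome_c = 1.0, glycogen = 0.45,
            lipid_saturated = 0.7, lipid_unsaturated = 0.7, nuclear = 1.3,
            protein_cytoplasm = 1.0, probe_MB = 1.0,
            baseline_fluorescence = 0.3)
  dox <- c(hemoglobin = 1.9, cytochrome_c = 0.55, glycogen = 0.95,
           lipid_saturated = 1.0, lipid_unsaturated = 0.45, nuclear = 0.6,
           protein_cytoplasm = 0.9, probe_MB = 1.0,
           baseline_fluorescence = 0.3)
  list(
    precursor = classProfile("precursor", base, abundanceCV = 0.18,
                             backgroundScale = 1, probeScale = 1,
                             cellRadiusScale = 1),
    erythrocyte_like = classProfile("erythrocyte_like", dox,
                                    abundanceCV = 0.18,
                                    backgroundScale = 3, probeScale = 0.35,
                                    cellRadiusScale = 1.3)
  )
}

# Effective abundance means with probe/background multipliers folded in.
.effectiveMeans <- function(profile) {
  m <- profile$abundance_mean
  if ("probe_MB" %in% names(m))
    m["probe_MB"] <- m["probe_MB"] * profile$probe_scale
  if ("baseline_fluorescence" %in% names(m))
    m["baseline_fluorescence"] <-
      m["baseline_fluorescence"] * profile$background_scale
  m
}

# Gamma draw with given mean and cv (cv = 0 -> deterministic).
.drawAbundance <- function(mean, cv) {
  out <- mean
  pos <- mean > 0 & cv > 0
  if (any(pos)) {
    shape <- 1 / cv^2
    out[pos] <- stats::rgamma(sum(pos), shape = shape,
                              scale = mean[pos] / shape)
  }
  out
}

## ---- cell phantoms -------------------------------------------------------

.ellipseMask <- function(shape, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  u^2 + v^2 <= 1
}

#' Generate non-overlapping cell phantoms
#'
#' Each phantom is an elliptical cell with a nucleus, a perinuclear
#' mitochondrial ring, a few lipid droplets, and cytoplasm = cell minus
#' nucleus. Packing is by bounded rejection sampling; if fewer than
#' `nCells` fit, the achieved count is returned with a warning.
#'
#' @param nCells requested number of cells.
#' @param imageShape c(ny, nx) in pixels.
#' @param geometry list: radius (mean cell radius, px), radiusJitter
#'   (relative), nucleusFrac, nLipid, lipidRadius, margin (px between
#'   cells), radiusScale (global multiplier).
#' @param seed RNG seed.
#' @param pixelSizeUm micrometres per pixel.
#' @return list of phantoms; each has masks (cell, nucleus, cytoplasm,
#'   mito, lipid), center, radii and `pixel_size`.
#' @export
makePhantom <- function(nCells, imageShape = c(128L, 128L),
                        geometry = list(), seed = 1, pixelSizeUm = 0.3) {
  g <- modifyList(list(radius = 12, radiusJitter = 0.12, nucleusFrac = 0.5,
                       nLipid = 4, lipidRadius = 1.8, margin = 3,
                       radiusScale = 1), geometry)
  withSeed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    maxTries <- 300L * nCells
    while (nrow(centers) < nCells && tries < maxTries) {
      tries <- tries + 1L
      r <- g$radius * g$radiusScale * (1 + g$radiusJitter * rnorm(1))
      r <- max(4, r)
      cy <- runif(1, r + 2, imageShape[1] - r - 2)
      cx <- runif(1, r + 2, imageShape[2] - r - 2)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(d < radii + r + g$margin)) next
      }
      centers <- rbind(centers, c(cy, cx))
      radii <- c(radii, r)
    }
    if (nrow(centers) < nCells)
      warning(sprintf("placed %d of %d requested cells", nrow(centers),
                      nCells))
    phantoms <- vector("list", nrow(centers))
    for (i in seq_len(nrow(centers))) {
      r <- radii[i]
      ecc <- runif(1, 0.8, 1)      # mild ellipticity
      th <- runif(1, 0, pi)
      cell <- .ellipseMask(imageShape, centers[i, 1], centers[i, 2],
                           r, r * ecc, th)
      rn <- r * g$nucleusFrac
      off <- runif(2, -0.15 * r, 0.15 * r)
      nucleus <- .ellipseMask(imageShape, centers[i, 1] + off[1],
                              centers[i, 2] + off[2], rn, rn * ecc, th) & cell
      ring <- .ellipseMask(imageShape, centers[i, 1] + off[1],
                           centers[i, 2] + off[2],
                           rn * 1.45, rn * 1.45 * ecc, th)
      cytoplasm <- cell & !nucleus
      mito <- ring & cytoplasm
      lipid <- matrix(FALSE, imageShape[1], imageShape[2])
      for (j in seq_len(g$nLipid)) {
        a <- runif(1, 0, 2 * pi)
        rr <- runif(1, rn * 1.5, max(rn * 1.5, r * 0.85))
        lc <- centers[i, ] + rr * c(sin(a), cos(a))
        lipid <- lipid | .ellipseMask(imageShape, lc[1], lc[2],
                                      g$lipidRadius, g$lipidRadius)
      }
      lipid <- lipid & cytoplasm
      phantoms[[i]] <- list(
        mask_cell = cell, mask_nucleus = nucleus, mask_cytoplasm = cytoplasm,
        mask_mito = mito, mask_lipid_droplets = lipid,
        center = centers[i, ], radius = r, pixel_size = pixelSizeUm)
    }
    phantoms
  })
}

## ---- hyperspectral image simulation --------------------------------------

# Map endmember names to the phantom compartment carrying them.
.endmemberMask <- function(name, ph) {
  switch(name,
    hemoglobin = ph$mask_cytoplasm,
    cytochrome_c = ph$mask_mito,
    glycogen = ph$mask_cytoplasm,
    lipid_saturated = ph$mask_lipid_droplets | ph$mask_mito,
    lipid_unsaturated = ph$mask_lipid_droplets,
    nuclear = ph$mask_nucleus,
    protein_cytoplasm = ph$mask_cell,
    probe_MB = ph$mask_cytoplasm,
    baseline_fluorescence = ph$mask_cell,
    ph$mask_cell)
}

#' Noise parameter set
#'
#' The simulated detector applies shot noise (Poisson counts at an
#' electrons-per-intensity gain), additive Gaussian read noise, and rare
#' single-channel spike artifacts. All-zero parameters give the exact
#' noiseless cube.
#'
#' @param gain intensity units per detected count (0 disables shot noise).
#' @param readSD SD of additive Gaussian noise (intensity units).
#' @param spikeRate per-spectrum probability of a cosmic-ray spike.
#' @param spikeAmplitude spike height (intensity units).
#' @return named list.
#' @export
noiseParams <- function(gain = 0, readSD = 0, spikeRate = 0,
                        spikeAmplitude = 50) {
  if (gain < 0 || readSD < 0 || spikeRate < 0 || spikeAmplitude < 0)
    stop("noise parameters must be non-negative")
  list(gain = gain, read_sd = readSD, spike_rate = spikeRate,
       spike_amplitude = spikeAmplitude)
}

.applyNoise <- function(mat, np) {
  # mat: pixels x channels, non-negative
  if (np$gain > 0) {
    lam <- pmax(mat, 0) / np$gain
    mat <- matrix(rpois(length(lam), lam), nrow(mat)) * np$gain
  }
  if (np$read_sd > 0)
    mat <- mat + matrix(rnorm(length(mat), 0, np$read_sd), nrow(mat))
  if (np$spike_rate > 0) {
    hit <- which(runif(nrow(mat)) < np$spike_rate)
    if (length(hit)) {
      ch <- sample.int(ncol(mat), length(hit), replace = TRUE)
      mat[cbind(hit, ch)] <- mat[cbind(hit, ch)] + np$spike_amplitude
    }
  }
  mat
}

#' Simulate a hyperspectral image of phantom cells
#'
#' The noiseless cube is the exact bilinear product of per-endmember
#' concentration maps (compartment masks scaled by per-cell abundance
#' draws) with the rendered endmember spectra; Poisson-Gaussian noise and
#' spike artifacts are added on top. Ground truth (noiseless C, S, class)
#' is stored in the image metadata.
#'
#' @param phantoms list from [makePhantom()] (all on one image grid).
#' @param profile a [classProfile()].
#' @param library endmember spec list.
#' @param axis wavenumber grid.
#' @param noise a [noiseParams()] list.
#' @param seed RNG seed.
#' @return an [HSImage-class]; `metadata(...)$ground_truth` holds `C`
#'   (pixels x k, column-major pixel order), `S` (k x channels),
#'   `class`, `seed` and the abundance draws.
#' @export
simulateHSImage <- function(phantoms, profile, library = endmemberLibrary(),
                            axis = ramanAxis(), noise = noiseParams(),
                            seed = 1) {
  stopifnot(length(phantoms) >= 1)
  S <- renderLibrary(library, axis)
  mns <- .effectiveMeans(profile)
  if (!all(names(mns) %in% rownames(S)))
    stop("profile abundance names must match the endmember library")
  S <- S[names(mns), , drop = FALSE]
  shape <- dim(phantoms[[1]]$mask_cell)
  npx <- prod(shape)
  k <- length(mns)
  withSeed(seed, {
    C <- matrix(0, npx, k, dimnames = list(NULL, names(mns)))
    abund <- matrix(NA_real_, length(phantoms), k,
                    dimnames = list(NULL, names(mns)))
    for (i in seq_along(phantoms)) {
      a <- .drawAbundance(mns, profile$abundance_cv)
      abund[i, ] <- a
      for (e in names(mns)) {
        m <- .endmemberMask(e, phantoms[[i]])
        C[as.vector(m), e] <- C[as.vector(m), e] + a[e]
      }
    }
    clean <- C %*% S
    noisy <- .applyNoise(clean, noise)
    cube <- array(noisy, dim = c(shape, length(axis)))
    HSImage(cube, axis, pixelSize = phantoms[[1]]$pixel_size,
            modality = if (length(axis) < 100) "hsSRS" else "raman",
            metadata = list(
              class_label = profile$class_label, seed = seed,
              ground_truth = list(C = C, S = S, class = profile$class_label,
                                  seed = seed, abundances = abund)))
  })
}

## ---- single-cell cohort spectra ------------------------------------------

#' Simulate a labeled cohort of single-cell mean spectra
#'
#' Each synthetic cell contributes one mean spectrum: a gamma-distributed
#' abundance draw per endmember mixed linearly with the rendered library,
#' plus additive Gaussian noise (mean spectra over many pixels are
#' approximately Gaussian).
#'
#' @param nPerClass integer (recycled to both classes), >= 2.
#' @param profiles list of two [classProfile()]s (default
#'   [defaultClassProfiles()]).
#' @param library endmember spec list.
#' @param axis wavenumber grid.
#' @param noiseSD additive Gaussian noise SD (intensity units).
#' @param seed RNG seed.
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `intensity` (channels x cells), rowData `wavenumber_cm1`, colData
#'   `class` and `cell_id`.
#' @export
simulateCohortSpectra <- function(nPerClass = 50,
                                  profiles = defaultClassProfiles(),
                                  library = endmemberLibrary(),
                                  axis = ramanAxis(), noiseSD = 0.04,
                                  seed = 1) {
  nPerClass <- rep_len(nPerClass, length(profiles))
  if (any(nPerClass < 2)) stop("need at least 2 cells per class")
  S <- renderLibrary(library, axis)
  withSeed(seed, {
    Xs <- list(); cls <- character(0)
    for (j in seq_along(profiles)) {
      p <- profiles[[j]]
      mns <- .effectiveMeans(p)
      Sj <- S[names(mns), , drop = FALSE]
      A <- do.call(rbind, lapply(seq_len(nPerClass[j]), function(i)
        .drawAbundance(mns, p$abundance_cv)))
      Xj <- A %*% Sj
      if (noiseSD > 0)
        Xj <- Xj + matrix(rnorm(length(Xj), 0, noiseSD), nrow(Xj))
      Xs[[j]] <- Xj
      cls <- c(cls, rep(p$class_label, nPerClass[j]))
    }
    X <- do.call(rbind, Xs)
    ids <- sprintf("cell_%03d", seq_len(nrow(X)))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = t(X)),
      rowData = S4Vectors::DataFrame(wavenumber_cm1 = axis),
      colData = S4Vectors::DataFrame(class = cls, cell_id = ids,
                                     row.names = ids))
  })
}

#' Extract the spectra matrix and labels from a cohort
#'
#' @param se cohort `SummarizedExperiment` from [simulateCohortSpectra()] or
#'   [readSpectraCSV()].
#' @return list with `X` (cells x channels), `y` (character classes),
#'   `groups` (cell ids) and `axis`.
#' @export
cohortMatrix <- function(se) {
  list(X = t(SummarizedExperiment::assay(se, "intensity")),
       y = SummarizedExperiment::colData(se)$class,
       groups = SummarizedExperiment::colData(se)$cell_id,
       axis = SummarizedExperiment::rowData(se)$wavenumber_cm1)
}
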