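## Spectral phasor transform of hyperspectral SRS cubes and unsupervised
## segmentation of the phasor plane into cellular regions. The phasor of a
## pixel is the n-th discrete Fourier coefficient of its spectrum
## normalized by total intensity; it is scale-invariant and linear under
## spectral mixing, which makes it a natural 2-d embedding for clustering.

#' Spectral phasor transform
#'
#' For a pixel spectrum I_k over N channels (k = 0..N-1):
#' G = sum_k I_k cos(2 pi n k / N) / sum_k I_k,
#' S = sum_k I_k sin(2 pi n k / N) / sum_k I_k.
#' Non-negative spectra map inside the unit circle; a flat spectrum maps to
#' (0, 0) and a delta in the first channel to (1, 0). Pixels whose total
#' intensity is below `intensityFloor` x max total intensity are flagged
#' invalid and carry G = S = 0.
#'
#' @param cube [HSImage-class] or 3-d array with >= 3 channels.
#' @param harmonic harmonic number n (>= 1, < channels/2).
#' @param intensityFloor validity floor as a fraction of the maximum total
#'   pixel intensity (default 0.01).
#' @return a [PhasorMap-class].
#' @export
spectralPhasor <- function(cube, harmonic = 1L, intensityFloor = 0.01) {
  a <- if (is(cube, "HSImage")) cubeData(cube) else cube
  d <- dim(a)
  if (d[3] < 3L) stop("need at least 3 channels")
  if (harmonic < 1L || harmonic >= d[3] / 2)
    stop("harmonic must satisfy 1 <= n < channels/2")
  flat <- matrix(a, prod(d[1:2]), d[3])
  k <- seq_len(d[3]) - 1
  cosv <- cos(2 * pi * harmonic * k / d[3])
  sinv <- sin(2 * pi * harmonic * k / d[3])
  tot <- rowSums(flat)
  valid <- tot > intensityFloor * max(tot, 0) & tot > 0
  G <- S <- numeric(length(tot))
  G[valid] <- (flat[valid, , drop = FALSE] %*% cosv) / tot[valid]
  S[valid] <- (flat[valid, , drop = FALSE] %*% sinv) / tot[valid]
  new("PhasorMap",
      G = matrix(G, d[1], d[2]), S = matrix(S, d[1], d[2]),
      intensity = matrix(tot, d[1], d[2]), harmonic = as.integer(harmonic),
      validMask = matrix(valid, d[1], d[2]))
}

# Mean spectrum of the cube over a pixel subset (indices into the flattened
# spatial grid).
.meanSpectrumAt <- function(cube, idx) {
  a <- if (is(cube, "HSImage")) cubeData(cube) else cube
  d <- dim(a)
  flat <- matrix(a, prod(d[1:2]), d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Segment a cube through its phasor plane
#'
#' k-means clustering of the (G, S) coordinates of valid pixels (seeded,
#' with restarts), followed by naming of the clusters from the relative
#' CH-stretch character of their mean spectra: the cluster whose mean
#' spectrum has the highest protein/nucleic 2930-region share is the
#' nucleus, the highest lipid 2850-region share is the intermediate
#' (lipid-rich) region, and the remainder is cytoplasm. Background = pixels
#' below the phasor intensity floor.
#'
#' @param phasorMap a [PhasorMap-class].
#' @param cube the cube it came from (used for naming the clusters).
#' @param nClusters number of regions (default 3).
#' @param seed RNG seed for k-means.
#' @param nStart k-means restarts (default 10).
#' @return a [RegionSegmentation-class].
#' @export
phasorSegment <- function(phasorMap, cube, nClusters = 3L, seed = 1,
                          nStart = 10L) {
  valid <- which(phasorMap@validMask)
  if (length(valid) < nClusters) stop("fewer valid pixels than clusters")
  pts <- cbind(phasorMap@G[valid], phasorMap@S[valid])
  if (nrow(unique(pts)) < nClusters)
    stop("degenerate phasor distribution: fewer distinct phasors than clusters")
  km <- withSeed(seed, kmeans(pts, centers = nClusters, nstart = nStart,
                              iter.max = 100L))
  labels <- matrix(0L, nrow(phasorMap@G), ncol(phasorMap@G))
  labels[valid] <- km$cluster
  wn <- if (is(cube, "HSImage")) wavenumbers(cube) else
    seq_len(dim(if (is(cube, "HSImage")) cubeData(cube) else cube)[3])
  regionNames <- paste0("region_", seq_len(nClusters))
  rule <- "unnamed clusters (nClusters != 3)"
  if (nClusters == 3L) {
    # name clusters by cosine match of their mean spectra against rendered
    # reference signatures: nucleus ~ nucleic/nucleoprotein CH (2930-region
    # character), cytoplasm ~ protein CH3, intermediate ~ lipid CH2 (2850)
    refs <- renderLibrary(axis = wn)[
      c("nuclear", "protein_cytoplasm", "lipid_saturated"), , drop = FALSE]
    refNames <- c("nucleus", "cytoplasm", "intermediate")
    means <- t(vapply(seq_len(nClusters), function(cl)
      .meanSpectrumAt(cube, valid[km$cluster == cl]),
      numeric(length(wn))))
    nm <- sqrt(rowSums(means^2))
    nr <- sqrt(rowSums(refs^2))
    if (all(nm > 0) && all(nr > 0)) {
      sim <- (means / nm) %*% t(refs / nr)
      assign <- .hungarian(1 - sim)
      regionNames <- refNames[assign]
      rule <- paste("clusters named by optimal cosine assignment of",
                    "cluster-mean spectra to nuclear / protein / lipid",
                    "reference signatures; background = below intensity",
                    "floor")
    }
  }
  new("RegionSegmentation", labels = labels, regionNames = regionNames,
      centers = km$centers, rule = rule)
}
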