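# Shared fixture builders and independent oracles used across test files.

# Planted OPLS construction: X = y w' + o q' with w _|_ q and o _|_ y.
plantedOPLS <- function(n = 40, m = 60, seed = 42) {
  set.seed(seed)
  w <- rnorm(m); w <- w / sqrt(sum(w^2))
  q <- rnorm(m); q <- q - sum(q * w) * w; q <- q / sqrt(sum(q^2))
  y <- rep(c(1, -1), each = n / 2)
  o <- rnorm(n); o <- o - sum(o * y) / sum(y^2) * y
  list(X = outer(y, w) + outer(o, q), y = y, w = w, q = q, o = o)
}

# Minimal independent NIPALS PLS1 (1 latent variable) used as the oracle for
# the nOrtho = 0 equivalence; written from the textbook recursion, shares no
# code with the package.
pls1Oracle <- function(X, y, Xnew = X) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w <- crossprod(Xc, yc)
  w <- w / sqrt(sum(w^2))
  t <- Xc %*% w
  q <- sum(yc * t) / sum(t^2)
  En <- scale(Xnew, center = attr(Xc, "scaled:center"), scale = FALSE)
  as.numeric((En %*% w) * q + mean(y))
}

# Three spatially disjoint pure regions (nucleic-, protein-, lipid-like) on
# the CH-stretch axis; returns the cube plus a ground-truth label image
# (1 = nucleus, 2 = cytoplasm, 3 = intermediate/lipid).
pureRegionCube <- function(seed = 3, shape = c(64L, 64L), noiseSD = 0.002) {
  ax <- ramanAxis("hsSRS")
  S <- renderLibrary(axis = ax)[
    c("nuclear", "protein_cytoplasm", "lipid_saturated"), ]
  lab <- matrix(0L, shape[1], shape[2])
  lab[10:30, 10:30] <- 1L
  lab[40:60, 10:30] <- 2L
  lab[10:30, 40:60] <- 3L
  set.seed(seed)
  D <- matrix(0, prod(shape), length(ax))
  for (r in 1:3) {
    idx <- which(lab == r)
    D[idx, ] <- matrix(rep(S[r, ], each = length(idx)), length(idx)) *
      runif(length(idx), 0.8, 1.2)
  }
  D <- pmax(D + matrix(rnorm(length(D), 0, noiseSD), nrow(D)), 0)
  list(img = HSImage(array(D, c(shape, length(ax))), ax, modality = "hsSRS"),
       labels = lab, truthNames = c("nucleus", "cytoplasm", "intermediate"))
}

# Synthetic k-component cube with a share of near-pure pixels, known C and
# unit-norm S; optional additive Gaussian noise at a given amplitude SNR.
pureMixCube <- function(k = 3, shape = c(64L, 64L), nchan = 600, snr = Inf,
                        pureFrac = 0.15, seed = 7) {
  set.seed(seed)
  ax <- seq(600, by = 2, length.out = nchan)
  nm <- c("hemoglobin", "glycogen", "nuclear", "lipid_saturated",
          "protein_cytoplasm", "cytochrome_c")[seq_len(k)]
  S <- renderLibrary(axis = ax)[nm, , drop = FALSE]
  S <- S / sqrt(rowSums(S^2))
  n <- prod(shape)
  C <- matrix(rgamma(n * k, shape = 2, scale = 1), n, k)
  pure <- sample(n, round(pureFrac * n))
  for (i in seq_along(pure)) {
    j <- (i %% k) + 1L
    C[pure[i], ] <- 0
    C[pure[i], j] <- rgamma(1, 2, 1) + 1
  }
  D <- C %*% S
  if (is.finite(snr)) {
    D <- D + matrix(rnorm(length(D), 0, sqrt(mean(D^2)) / snr), n)
  }
  list(cube = array(D, c(shape, nchan)), C = C, S = S, axis = ax)
}

# All permutations of 1..n as rows (for brute-force assignment oracles).
allPermutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- allPermutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# All-pairs Mann-Whitney AUC oracle: concordant pairs + half ties.
aucOracle <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  cmp <- outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Build a labeled marker table without any imaging (for ROC-level tests).
syntheticMarkerTable <- function(n = 30, sep = 2, seed = 1) {
  set.seed(seed)
  data.frame(
    cell_id = seq_len(2 * n),
    cell_area_um2 = rep(1, 2 * n),
    cytoplasm_area_um2 = rep(1, 2 * n),
    lp_per_area = c(rnorm(n, sep), rnorm(n, 0)),
    mb_per_area = c(rnorm(n, sep), rnorm(n, 0)),
    class = rep(c("precursor", "erythrocyte_like"), each = n),
    stringsAsFactors = FALSE)
}
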