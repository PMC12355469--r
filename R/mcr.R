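## Multivariate curve resolution by alternating least squares on unfolded
## hyperspectral cubes: D (pixels x channels) ~ C (pixels x k) %*% S
## (k x channels), with non-negativity on both factors, an optional
## sum-preserving contribution-contrast step on C, SIMPLISMA-style purest
## variable initialization, and permutation/scale-invariant diagnostics.

# Single-RHS Lawson-Hanson NNLS on the normal equations.
.nnlsSingle <- function(AtA, Atb, tol) {
  k <- length(Atb)
  x <- numeric(k)
  P <- logical(k)
  w <- Atb
  for (outer in seq_len(10L * k + 10L)) {
    cand <- which(!P & w > tol)
    if (!length(cand)) break
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(k)
      np <- sum(P)
      s[P] <- solve(AtA[P, P, drop = FALSE] + diag(tol, np, np), Atb[P])
      if (all(s[P] > 0)) { x <- s; break }
      bad <- P & s <= 0
      alpha <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - AtA %*% x
  }
  x
}

# Fast combinatorial NNLS: min ||A X - B||, X >= 0, vectorized over the
# columns of B, given the normal-equation blocks AtA (k x k) and AtB
# (k x n). Columns sharing a passive set are solved in one call.
.nnlsMultiple <- function(AtA, AtB, maxOuter = 60L) {
  k <- nrow(AtA)
  n <- ncol(AtB)
  tol <- 1e-12 * max(diag(AtA), 1)
  cssls <- function(P) {
    X <- matrix(0, k, n)
    codes <- colSums(P * 2^(seq_len(k) - 1))
    for (code in unique(codes)) {
      cols <- which(codes == code)
      p <- P[, cols[1]]
      if (!any(p)) next
      np <- sum(p)
      X[p, cols] <- solve(AtA[p, p, drop = FALSE] + diag(tol, np, np),
                          AtB[p, cols, drop = FALSE])
    }
    X
  }
  P <- matrix(TRUE, k, n)
  X <- cssls(P)
  Fcols <- seq_len(n)
  iter <- 0L
  while (length(Fcols) && iter < maxOuter) {
    iter <- iter + 1L
    # feasibility: drop negative passive variables and re-solve
    inner <- 0L
    repeat {
      inner <- inner + 1L
      neg <- P[, Fcols, drop = FALSE] & X[, Fcols, drop = FALSE] < -tol
      if (!any(neg) || inner > 5L * k) break
      bad <- Fcols[colSums(neg) > 0]
      P[, bad][neg[, match(bad, Fcols), drop = FALSE]] <- FALSE
      X[, bad] <- cssls(P)[, bad, drop = FALSE]
    }
    X[X < 0] <- 0
    # optimality: Lagrange gradient on the active set
    W <- AtB[, Fcols, drop = FALSE] - AtA %*% X[, Fcols, drop = FALSE]
    W[P[, Fcols, drop = FALSE]] <- -Inf
    improvable <- apply(W, 2, max) > tol
    done <- Fcols[!improvable]
    Fcols <- Fcols[improvable]
    if (length(Fcols)) {
      add <- apply(W[, improvable, drop = FALSE], 2, which.max)
      P[cbind(add, Fcols)] <- TRUE
      X[, Fcols] <- cssls(P)[, Fcols, drop = FALSE]
    }
  }
  if (length(Fcols)) {
    # rare cycling: finish those columns with the single-RHS solver
    for (j in Fcols) X[, j] <- .nnlsSingle(AtA, AtB[, j], tol)
  }
  X
}

# Unfold an HSImage or array cube into pixels x channels (column-major
# pixel order) plus the spatial dims.
.unfoldCube <- function(cube) {
  a <- if (is(cube, "HSImage")) cubeData(cube) else cube
  d <- dim(a)
  if (length(d) != 3L) stop("cube must be a 3-d array or HSImage")
  list(D = matrix(a, prod(d[1:2]), d[3]), mapDim = as.integer(d[1:2]))
}

#' SIMPLISMA-style purest-variable initialization
#'
#' Selects `k` spectral channels by the iterative purity criterion
#' std/(mean + offset), weighted from the second selection on by the
#' determinant of the correlation-around-origin matrix of already selected
#' channels (so an already-selected or collinear channel has purity ~0).
#' The concentration profiles of the selected channels seed a non-negative
#' least-squares solve for the initial spectra.
#'
#' @param cube [HSImage-class] or 3-d array.
#' @param k number of components, <= channels.
#' @param noisePercent purity offset as percent of the maximum channel mean.
#' @return k x channels matrix of unit-norm initial spectra; attributes
#'   `channels` (selected channel indices) and `purity`.
#' @export
initPurestVariables <- function(cube, k, noisePercent = 3) {
  u <- .unfoldCube(cube)
  D <- u$D
  m <- ncol(D)
  if (k > m) stop("k exceeds the number of channels")
  mu <- colMeans(D)
  sg <- apply(D, 2, sd)
  alpha <- noisePercent / 100 * max(mu)
  lam <- sqrt(mu^2 + (sg + alpha)^2)
  Z <- sweep(D, 2, lam, "/")
  COO <- crossprod(Z) / nrow(D)
  basePurity <- sg / (mu + alpha)
  sel <- integer(0)
  purity <- numeric(0)
  for (r in seq_len(k)) {
    if (r == 1L) {
      w <- rep(1, m)
    } else {
      detSel <- det(COO[sel, sel, drop = FALSE])
      w <- vapply(seq_len(m), function(j) {
        idx <- c(j, sel)
        det(COO[idx, idx, drop = FALSE])
      }, 0)
      w <- pmax(w, 0) / max(detSel, .Machine$double.eps)
    }
    p <- w * basePurity
    j <- which.max(p)
    if (r > 1L && p[j] < 1e-10)
      warning("requested k likely exceeds the numerical rank of the cube")
    sel <- c(sel, j)
    purity <- c(purity, p[j])
  }
  C0 <- D[, sel, drop = FALSE]
  S0 <- .nnlsMultiple(crossprod(C0), crossprod(C0, D))
  nrm <- sqrt(rowSums(S0^2))
  nrm[nrm == 0] <- 1
  S0 <- S0 / nrm
  attr(S0, "channels") <- sel
  attr(S0, "purity") <- purity
  S0
}

#' Sum-preserving contribution-contrast step
#'
#' Shrinks each pixel's concentration vector toward its dominant component
#' while preserving the pixel's total concentration:
#' C'_i = (1 - w) C_i + w proj(C_i), where proj places the whole row sum on
#' the dominant component. w = 0 is the identity; w = 1 assigns every pixel
#' entirely to its dominant component. Ties go to the lowest component
#' index.
#'
#' @param C pixels x components matrix, non-negative.
#' @param weight contrast weight in `[0, 1]`.
#' @return adjusted concentration matrix.
#' @export
contrastStep <- function(C, weight) {
  if (weight < 0 || weight > 1) stop("contrast weight must lie in [0, 1]")
  if (weight == 0) return(C)
  dom <- max.col(C, ties.method = "first")
  tot <- rowSums(C)
  P <- matrix(0, nrow(C), ncol(C))
  P[cbind(seq_len(nrow(C)), dom)] <- tot
  (1 - weight) * C + weight * P
}

#' MCR-ALS decomposition
#'
#' Alternating (non-negative) least squares with unit-norm spectra, an
#' optional contribution-contrast step on the concentrations, and a relative
#' lack-of-fit stopping rule.
#'
#' @param cube [HSImage-class] or 3-d array (y, x, channel).
#' @param k number of components (default 10, the component count used for
#'   full fingerprint-range cell images).
#' @param init "purest", "random" or "provided".
#' @param S0 initial spectra (k x channels) when init = "provided".
#' @param maxIter maximum ALS iterations.
#' @param tolLOF relative change in LOF below which iteration stops.
#' @param nonnegC,nonnegS apply non-negativity to C / S.
#' @param contrastWeight contribution-contrast weight in `[0, 1]` (0 = off).
#' @param noisePercent purity offset for the purest-variable init.
#' @param seed RNG seed (random init only).
#' @return a [ComponentSet-class].
#' @export
mcrALS <- function(cube, k = 10L, init = c("purest", "random", "provided"),
                   S0 = NULL, maxIter = 200L, tolLOF = 1e-6,
                   nonnegC = TRUE, nonnegS = TRUE, contrastWeight = 0,
                   noisePercent = 3, seed = 1) {
  init <- match.arg(init)
  if (tolLOF <= 0) stop("tolLOF must be > 0")
  u <- .unfoldCube(cube)
  D <- u$D
  if (!all(is.finite(D))) stop("cube must be finite")
  if (k > nrow(D)) stop("k exceeds the number of pixels")
  wn <- if (is(cube, "HSImage")) wavenumbers(cube) else
    seq_len(ncol(D))
  m <- ncol(D)
  S <- switch(init,
    purest = initPurestVariables(cube, k, noisePercent),
    random = withSeed(seed, matrix(runif(k * m), k, m)),
    provided = {
      if (is.null(S0) || nrow(S0) != k || ncol(S0) != m)
        stop("S0 must be a k x channels matrix")
      S0
    })
  S <- S / sqrt(rowSums(S^2))
  sumD2 <- sum(D^2)
  if (sumD2 == 0) stop("zero-signal cube")
  lofPrev <- 100
  lofHist <- numeric(0)
  C <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    # C update: min ||D - C S||, rows of D against A = t(S)
    AtA <- tcrossprod(S)
    AtB <- S %*% t(D)
    C <- if (nonnegC) t(.nnlsMultiple(AtA, AtB)) else t(solve(AtA, AtB))
    if (contrastWeight > 0) C <- contrastStep(C, contrastWeight)
    # S update: min ||D - C S||
    CtC <- crossprod(C)
    CtD <- crossprod(C, D)
    S <- if (nonnegS) .nnlsMultiple(CtC, CtD) else solve(CtC, CtD)
    # scale convention: unit-norm spectra, magnitude absorbed into C
    nrm <- sqrt(rowSums(S^2))
    nrm[nrm == 0] <- 1
    S <- S / nrm
    C <- sweep(C, 2, nrm, "*")
    res2 <- sumD2 - 2 * sum(crossprod(C, D) * S) +
      sum(crossprod(C) * tcrossprod(S))
    lof <- 100 * sqrt(max(res2, 0) / sumD2)
    lofHist <- c(lofHist, lof)
    if (abs(lofPrev - lof) / max(lof, .Machine$double.eps) < tolLOF ||
        abs(lofPrev - lof) < tolLOF) {
      converged <- TRUE
      break
    }
    lofPrev <- lof
  }
  cs <- new("ComponentSet", S = S, concentration = C, mapDim = u$mapDim,
            wavenumbers = as.numeric(wn),
            lofPercent = lofHist[length(lofHist)], lofHistory = lofHist,
            signalFractions = numeric(0), residualPercent = NA_real_,
            iterations = it, converged = converged)
  fr <- signalFractions(cs, cube)
  cs@signalFractions <- fr$fractions
  cs@residualPercent <- fr$residual
  cs
}

#' Per-component sum-squared signal fractions
#'
#' fraction_k = 100 * sum((C_k S_k)^2) / sum(data^2): the percent of the
#' total sum-squared signal carried by each component's rank-one
#' reconstruction, plus the residual percentage.
#'
#' @param componentSet a fitted [ComponentSet-class].
#' @param cube the data it was fitted to.
#' @return list(fractions, residual) in percent.
#' @export
signalFractions <- function(componentSet, cube) {
  D <- .unfoldCube(cube)$D
  sumD2 <- sum(D^2)
  if (sumD2 == 0) stop("zero-signal cube")
  C <- componentSet@concentration
  S <- componentSet@S
  fr <- vapply(seq_len(ncol(C)), function(j)
    100 * sum(C[, j]^2) * sum(S[j, ]^2) / sumD2, 0)
  res2 <- sumD2 - 2 * sum(crossprod(C, D) * S) +
    sum(crossprod(C) * tcrossprod(S))
  list(fractions = fr, residual = 100 * max(res2, 0) / sumD2)
}

# Otsu threshold on a numeric vector (maximize between-class variance).
.otsuThreshold <- function(x, nbins = 256L) {
  if (diff(range(x)) == 0) stop("otsu threshold undefined for constant map")
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  bc <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)]
}

#' Percent of high-intensity pixels in a concentration map
#'
#' @param map numeric matrix (one component's concentration image).
#' @param mask logical matrix of pixels to consider (NULL = all).
#' @param rule "absolute", "percentile" (of the pooled distribution) or
#'   "otsu".
#' @param value threshold value (absolute rule) or percentile in `[0, 1]`
#'   (percentile rule).
#' @param pooled pooled concentration values defining the percentile
#'   threshold (e.g. both classes together); defaults to the in-mask values.
#' @return percent of in-mask pixels above the threshold, with attribute
#'   `threshold`.
#' @export
highIntensityFraction <- function(map, mask = NULL,
                                  rule = c("percentile", "absolute", "otsu"),
                                  value = 0.6, pooled = NULL) {
  rule <- match.arg(rule)
  vals <- if (is.null(mask)) as.numeric(map) else map[mask]
  if (!length(vals)) stop("empty mask")
  thr <- switch(rule,
    absolute = value,
    percentile = quantile(if (is.null(pooled)) vals else pooled,
                          probs = value, names = FALSE, type = 7),
    otsu = .otsuThreshold(if (is.null(pooled)) vals else pooled))
  out <- 100 * mean(vals > thr)
  attr(out, "threshold") <- thr
  out
}

# Hungarian assignment (shortest augmenting path, O(n^3)) minimizing total
# cost on a square matrix; returns the column assigned to each row.
.hungarian <- function(cost) {
  n <- nrow(cost)
  J0 <- n + 1L  # virtual column
  u <- numeric(n)
  v <- numeric(J0)
  p <- integer(J0)          # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[J0] <- i
    way <- integer(n)
    minv <- rep(Inf, n)
    used <- rep(FALSE, J0)
    j0 <- J0
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(J0)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == J0) i else p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assign[p[j]] <- j
  assign
}

#' Match estimated components to reference spectra
#'
#' Optimal one-to-one assignment maximizing total cosine similarity
#' (Hungarian algorithm); cosine similarity is invariant to the
#' scale/permutation ambiguity of bilinear decompositions.
#'
#' @param Sest,Strue matrices of spectra in rows on the same channel grid.
#' @return list: `permutation` (index into rows of Strue for each row of
#'   Sest; NA for unmatched rows when counts differ), `cosines` (matched
#'   similarities) and the full `similarity` matrix.
#' @export
matchComponents <- function(Sest, Strue) {
  if (ncol(Sest) != ncol(Strue)) stop("channel grids differ")
  cosMat <- function(A, B) {
    An <- A / sqrt(rowSums(A^2))
    Bn <- B / sqrt(rowSums(B^2))
    tcrossprod(An, Bn)
  }
  sim <- cosMat(Sest, Strue)
  ke <- nrow(Sest)
  kt <- nrow(Strue)
  n <- max(ke, kt)
  cost <- matrix(2, n, n)  # padded entries: worst possible (cos >= -1)
  cost[seq_len(ke), seq_len(kt)] <- 1 - sim
  assign <- .hungarian(cost)
  perm <- rep(NA_integer_, ke)
  for (i in seq_len(ke)) if (assign[i] <= kt) perm[i] <- assign[i]
  cosines <- ifelse(is.na(perm), NA_real_,
                    sim[cbind(seq_len(ke), perm)])
  list(permutation = perm, cosines = cosines, similarity = sim)
}
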