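## Spectrum conditioning: spike removal, baseline correction (asymmetric
## least squares or polynomial), normalization, cropping, per-cell
## averaging. The pipeline order is fixed: despike -> baseline -> crop ->
## normalize; the config constructor refuses any other order.

#' Preprocessing configuration
#'
#' @param despikeWindow odd rolling-median window (channels); 0 disables.
#' @param despikeZ studentized-deviation threshold.
#' @param baselineMethod "asls", "polynomial" or "none".
#' @param aslsLambda,aslsP AsLS smoothness and asymmetry (p in (0,1)).
#' @param polyOrder polynomial baseline order.
#' @param norm "vector", "area" or "none".
#' @param crop list of length-2 wavenumber intervals to keep (NULL = all).
#' @return list of class "PreprocessConfig".
#' @export
preprocessConfig <- function(despikeWindow = 7L, despikeZ = 8,
                             baselineMethod = c("asls", "polynomial", "none"),
                             aslsLambda = 1e5, aslsP = 0.01, polyOrder = 3L,
                             norm = c("vector", "area", "none"),
                             crop = NULL) {
  baselineMethod <- match.arg(baselineMethod)
  norm <- match.arg(norm)
  if (despikeWindow > 0 && (despikeWindow %% 2L == 0L || despikeWindow < 3L))
    stop("despikeWindow must be odd and >= 3 (or 0 to disable)")
  if (aslsP <= 0 || aslsP >= 1) stop("aslsP must lie in (0, 1)")
  if (polyOrder < 0) stop("polyOrder must be >= 0")
  if (!is.null(crop) && !all(vapply(crop, length, 0L) == 2L))
    stop("crop must be a list of length-2 intervals")
  structure(list(despike_window = as.integer(despikeWindow),
                 despike_z = despikeZ, baseline_method = baselineMethod,
                 asls_lambda = aslsLambda, asls_p = aslsP,
                 poly_order = as.integer(polyOrder), norm = norm,
                 crop = crop),
            class = "PreprocessConfig")
}

# Rolling median with edge replication.
.rollMedian <- function(x, window) {
  n <- length(x)
  h <- window %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) median(xp[i:(i + window - 1L)]), 0)
}

#' Remove single-channel spikes
#'
#' Channels whose deviation from a rolling median, studentized by the
#' robust (MAD) scale of all deviations, exceeds `z` are replaced by the
#' rolling median; every other channel is untouched.
#'
#' @param spectrum numeric vector.
#' @param window odd window length >= 3, < length(spectrum).
#' @param z threshold on the studentized deviation.
#' @return despiked spectrum, with attribute `spikes` (indices replaced).
#' @export
removeSpikes <- function(spectrum, window = 7L, z = 8) {
  n <- length(spectrum)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (window >= n) stop("window must be smaller than the spectrum")
  med <- .rollMedian(spectrum, window)
  resid <- spectrum - med
  scale <- mad(resid)
  if (scale == 0) scale <- sd(resid)
  if (is.na(scale) || scale == 0) {
    attr(spectrum, "spikes") <- integer(0)
    return(spectrum)
  }
  hit <- which(abs(resid) / scale > z)
  out <- spectrum
  out[hit] <- med[hit]
  attr(out, "spikes") <- hit
  out
}

# Asymmetric least squares baseline (Eilers & Boelens): penalized
# second-difference smoother with asymmetric weights.
.aslsBaseline <- function(y, lambda = 1e5, p = 0.01, maxIter = 20L,
                          tol = 1e-8) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  zv <- y
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    W <- Matrix::Diagonal(m, w)
    zv <- as.numeric(Matrix::solve(W + DtD, w * y))
    wNew <- ifelse(y > zv, p, 1 - p)
    if (max(abs(wNew - w)) < tol) { converged <- TRUE; break }
    w <- wNew
  }
  list(baseline = zv, converged = converged, iterations = it,
       residual = sqrt(mean((y - zv)^2)))
}

#' Baseline-correct a spectrum
#'
#' @param spectrum numeric vector.
#' @param axis matching wavenumber grid (needed for polynomial baselines).
#' @param config a [preprocessConfig()]; only the baseline fields are used.
#' @return list(corrected, baseline, converged); corrected + baseline
#'   reconstructs the input exactly.
#' @export
baselineCorrect <- function(spectrum, axis = seq_along(spectrum),
                            config = preprocessConfig()) {
  method <- config$baseline_method
  if (method == "none") {
    return(list(corrected = spectrum, baseline = numeric(length(spectrum)),
                converged = TRUE))
  }
  if (method == "polynomial") {
    fit <- lm(spectrum ~ poly(axis, config$poly_order))
    b <- as.numeric(fitted(fit))
    return(list(corrected = spectrum - b, baseline = b, converged = TRUE))
  }
  res <- .aslsBaseline(spectrum, config$asls_lambda, config$asls_p)
  if (!res$converged)
    warning(sprintf("AsLS did not converge (%d iterations, residual %.3g)",
                    res$iterations, res$residual))
  list(corrected = spectrum - res$baseline, baseline = res$baseline,
       converged = res$converged)
}

#' Normalize a spectrum
#'
#' @param spectrum numeric vector.
#' @param mode "vector" (unit Euclidean norm), "area" (unit trapezoid
#'   integral over `axis`) or "none".
#' @param axis wavenumber grid, used by area mode.
#' @return normalized spectrum.
#' @export
normalizeSpectrum <- function(spectrum, mode = c("vector", "area", "none"),
                              axis = seq_along(spectrum)) {
  mode <- match.arg(mode)
  if (mode == "none") return(spectrum)
  if (all(spectrum == 0)) stop("cannot normalize an all-zero spectrum")
  if (mode == "vector") return(spectrum / sqrt(sum(spectrum^2)))
  a <- pracma::trapz(axis, spectrum)
  if (a == 0) stop("area normalization undefined: zero integral")
  spectrum / a
}

#' Crop a spectrum to wavenumber intervals
#'
#' @param spectrum numeric vector.
#' @param axis wavenumber grid.
#' @param intervals list of length-2 intervals to keep.
#' @return list(spectrum, axis) restricted to the union of intervals.
#' @export
cropSpectrum <- function(spectrum, axis, intervals) {
  keep <- Reduce(`|`, lapply(intervals, function(iv)
    axis >= min(iv) & axis <= max(iv)))
  list(spectrum = spectrum[keep], axis = axis[keep])
}

#' Mean (and SD) spectrum over a cell mask
#'
#' @param cube an [HSImage-class] or 3-d array.
#' @param mask logical matrix matching the cube's spatial dimensions.
#' @return list(mean, sd, n) per-channel statistics over masked pixels.
#' @export
meanCellSpectrum <- function(cube, mask) {
  a <- if (is(cube, "HSImage")) cubeData(cube) else cube
  d <- dim(a)
  if (!all(dim(mask) == d[1:2])) stop("mask shape must match the cube")
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  flat <- matrix(a, prod(d[1:2]), d[3])
  sub <- flat[idx, , drop = FALSE]
  list(mean = colMeans(sub),
       sd = if (nrow(sub) > 1) apply(sub, 2, sd) else rep(NA_real_, d[3]),
       n = length(idx))
}

#' Run the full preprocessing chain on one spectrum
#'
#' Applies despike, baseline correction, cropping and normalization in that
#' fixed order.
#'
#' @param spectrum numeric vector.
#' @param axis wavenumber grid.
#' @param config a [preprocessConfig()].
#' @return list(spectrum, axis, baseline, spikes).
#' @export
preprocessSpectrum <- function(spectrum, axis, config = preprocessConfig()) {
  sp <- spectrum
  spikes <- integer(0)
  if (config$despike_window > 0) {
    sp <- removeSpikes(sp, config$despike_window, config$despike_z)
    spikes <- attr(sp, "spikes")
    attributes(sp) <- NULL
  }
  bc <- baselineCorrect(sp, axis, config)
  sp <- bc$corrected
  ax <- axis
  if (!is.null(config$crop)) {
    cr <- cropSpectrum(sp, ax, config$crop)
    sp <- cr$spectrum
    ax <- cr$axis
  }
  sp <- normalizeSpectrum(sp, config$norm, ax)
  list(spectrum = sp, axis = ax, baseline = bc$baseline, spikes = spikes)
}
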