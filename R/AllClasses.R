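#' @import methods
#' @importFrom stats approx coef cor dnorm fitted kmeans lm mad median
#'   pnorm poly prcomp predict pwilcox quantile rbinom rgamma rnorm rpois
#'   runif sd setNames var
#' @importFrom utils head modifyList read.csv tail
#' @importFrom data.table data.table fread fwrite as.data.table
NULL

#' Hyperspectral image cube
#'
#' Container for a single hyperspectral Raman or SRS field of view: a
#' three-dimensional array indexed (y, x, channel) together with its
#' wavenumber axis (cm^-1, strictly increasing), the pixel size in
#' micrometres and free-form metadata (acquisition modality, class label,
#' simulation ground truth, ...).
#'
#' @slot cube numeric array, dim = c(ny, nx, nchannel).
#' @slot wavenumbers numeric, strictly increasing, length = nchannel.
#' @slot pixelSize positive scalar, micrometres per pixel.
#' @slot modality one of "raman", "hsSRS", "srs_frames".
#' @slot metadata named list; simulated images carry a `ground_truth`
#'   element (see [simulateHSImage()]).
#'
#' @export
setClass("HSImage",
  representation(
    cube = "array",
    wavenumbers = "numeric",
    pixelSize = "numeric",
    modality = "character",
    metadata = "list"
  ),
  prototype(pixelSize = 0.3, modality = "raman", metadata = list())
)

setValidity("HSImage", function(object) {
  d <- dim(object@cube)
  if (length(d) != 3L)
    return("cube must be a 3-d array (y, x, channel)")
  if (length(object@wavenumbers) != d[3L])
    return("length(wavenumbers) must equal the channel dimension of cube")
  if (any(!is.finite(object@wavenumbers)) || any(diff(object@wavenumbers) <= 0))
    return("wavenumbers must be finite and strictly increasing")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  if (!object@modality %in% c("raman", "hsSRS", "srs_frames"))
    return("modality must be one of 'raman', 'hsSRS', 'srs_frames'")
  TRUE
})

#' MCR-ALS decomposition result
#'
#' Bilinear factorization D ~ C S of an unfolded hyperspectral cube into
#' non-negative concentration maps (pixels x components) and unit-norm
#' component spectra (components x channels), with fit diagnostics.
#'
#' @slot S components x channels matrix of endmember spectra, rows unit
#'   Euclidean norm.
#' @slot concentration pixels x components concentration matrix (pixel
#'   order is column-major over the (y, x) image grid).
#' @slot mapDim integer c(ny, nx) used to refold C into images.
#' @slot wavenumbers spectral axis of S.
#' @slot lofPercent lack of fit, 100 * sqrt(sum(resid^2) / sum(data^2)).
#' @slot lofHistory LOF after every ALS iteration.
#' @slot signalFractions percent of total sum-squared signal carried by each
#'   component (see [signalFractions()]).
#' @slot residualPercent percent of total sum-squared signal left in the
#'   residual.
#' @slot iterations number of ALS iterations run.
#' @slot converged logical; FALSE means max_iter was hit before the relative
#'   LOF change fell below tolerance.
#'
#' @export
setClass("ComponentSet",
  representation(
    S = "matrix",
    concentration = "matrix",
    mapDim = "integer",
    wavenumbers = "numeric",
    lofPercent = "numeric",
    lofHistory = "numeric",
    signalFractions = "numeric",
    residualPercent = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("ComponentSet", function(object) {
  k <- nrow(object@S)
  if (ncol(object@concentration) != k)
    return("ncol(concentration) must equal nrow(S)")
  if (ncol(object@S) != length(object@wavenumbers))
    return("ncol(S) must equal length(wavenumbers)")
  if (length(object@mapDim) == 2L &&
      prod(object@mapDim) != nrow(object@concentration))
    return("prod(mapDim) must equal nrow(C)")
  TRUE
})

#' Fitted OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant model with one
#' predictive component and `nOrtho` y-orthogonal components, fitted on
#' mean-centred (optionally unit-variance scaled) spectra against a +/-1
#' class code.
#'
#' @slot weightsPred,loadingsPred length-nchannel predictive weight and
#'   loading vectors; `scoresPred` the training predictive scores.
#' @slot q scalar regression coefficient of y on the predictive score.
#' @slot weightsOrtho,loadingsOrtho nchannel x nOrtho matrices;
#'   `scoresOrtho` n x nOrtho orthogonal scores.
#' @slot center,scaleVec centring and scaling vectors applied to X.
#' @slot yMean mean of the training class code removed before fitting.
#' @slot vip per-channel variable importance in projection (mean VIP^2 = 1).
#' @slot r2xTotal fraction (percent) of X variance captured by the
#'   predictive plus orthogonal components.
#' @slot nOrtho number of orthogonal components.
#' @slot wavenumbers training spectral axis (used to refuse mismatched
#'   prediction input).
#' @slot classLevels length-2 character, classes coded +1 then -1.
#'
#' @export
setClass("OPLSModel",
  representation(
    weightsPred = "numeric",
    loadingsPred = "numeric",
    scoresPred = "numeric",
    q = "numeric",
    weightsOrtho = "matrix",
    loadingsOrtho = "matrix",
    scoresOrtho = "matrix",
    center = "numeric",
    scaleVec = "numeric",
    yMean = "numeric",
    vip = "numeric",
    r2xTotal = "numeric",
    nOrtho = "integer",
    wavenumbers = "numeric",
    classLevels = "character"
  )
)

#' Spectral phasor map
#'
#' First (or higher) harmonic Fourier coordinates (G, S) of every pixel
#' spectrum of a hyperspectral cube, normalized by total pixel intensity.
#' Pixels whose total intensity falls below the validity floor carry
#' G = S = 0 and validMask = FALSE.
#'
#' @slot G,S real matrices (ny x nx) of phasor coordinates.
#' @slot intensity total per-pixel signal.
#' @slot harmonic harmonic number used.
#' @slot validMask logical matrix, TRUE where intensity >= floor.
#'
#' @export
setClass("PhasorMap",
  representation(
    G = "matrix",
    S = "matrix",
    intensity = "matrix",
    harmonic = "integer",
    validMask = "matrix"
  )
)

setValidity("PhasorMap", function(object) {
  if (!all(dim(object@G) == dim(object@S)) ||
      !all(dim(object@G) == dim(object@intensity)))
    return("G, S and intensity must share dimensions")
  if (object@harmonic < 1L) return("harmonic must be >= 1")
  r2 <- object@G[object@validMask]^2 + object@S[object@validMask]^2
  if (length(r2) && max(r2) > 1 + 1e-9)
    return("valid phasor coordinates must lie inside the unit circle")
  TRUE
})

#' Phasor-plane segmentation of a cube
#'
#' @slot labels integer matrix (ny x nx); 0 = background (invalid pixels),
#'   1..k = clusters.
#' @slot regionNames character vector naming labels 1..k (e.g. "nucleus",
#'   "cytoplasm", "intermediate").
#' @slot centers k x 2 matrix of cluster centres in (G, S).
#' @slot rule record of the naming rule applied.
#'
#' @export
setClass("RegionSegmentation",
  representation(
    labels = "matrix",
    regionNames = "character",
    centers = "matrix",
    rule = "character"
  )
)
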