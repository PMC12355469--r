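## The fast single-wavenumber SRS classifier: lipid-to-protein ratio map
## I2850/(I2850+I2930), off-resonance-corrected probe map I2222 - I2100,
## cell/cytoplasm segmentation, per-cell medians normalized to area,
## ROC-calibrated thresholds, and quadrant class calls.

#' Bundle registered single-wavenumber SRS frames
#'
#' @param f2850,f2930,f2222,f2100 numeric matrices of identical shape:
#'   lipid CH2, protein CH3, probe alkyne on-resonance and off-resonance
#'   frames. Negative values (possible after noise) are clipped to 0.
#' @param pixelSize micrometres per pixel.
#' @return list of class "FrameSet" with elements `frames` (named list) and
#'   `pixel_size`.
#' @export
frameSet <- function(f2850, f2930, f2222, f2100, pixelSize = 0.3) {
  frames <- list(`2850` = f2850, `2930` = f2930, `2222` = f2222,
                 `2100` = f2100)
  d <- dim(f2850)
  if (!all(vapply(frames, function(f) all(dim(f) == d), TRUE)))
    stop("frames must share one shape")
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  frames <- lapply(frames, function(f) pmax(f, 0))
  structure(list(frames = frames, pixel_size = pixelSize),
            class = "FrameSet")
}

#' Simulate a registered SRS frame set for one cell population
#'
#' Phantom cells of one class are rendered at the four classifier
#' wavenumbers (2100, 2222, 2850, 2930 cm^-1) through the full endmember
#' model, so the frames carry the class's probe, lipid, protein and
#' silent-region-background contrast as well as its cell-size difference.
#'
#' @param nCells number of cells.
#' @param profile a [classProfile()].
#' @param library endmember spec list.
#' @param imageShape c(ny, nx) pixels.
#' @param geometry phantom geometry overrides (see [makePhantom()]).
#' @param noise a [noiseParams()] list.
#' @param seed RNG seed.
#' @param pixelSizeUm micrometres per pixel.
#' @return list(frameset, phantoms, class).
#' @export
simulateFrameSet <- function(nCells, profile, library = endmemberLibrary(),
                             imageShape = c(448L, 448L), geometry = list(),
                             noise = noiseParams(readSD = 0.01), seed = 1,
                             pixelSizeUm = 0.3) {
  geometry$radiusScale <- profile$cell_radius_scale
  phantoms <- makePhantom(nCells, imageShape, geometry, seed = seed,
                          pixelSizeUm = pixelSizeUm)
  axis <- c(2100, 2222, 2850, 2930)
  img <- simulateHSImage(phantoms, profile, library, axis, noise,
                         seed = seed + 1L)
  a <- cubeData(img)
  fs <- frameSet(a[, , 3], a[, , 4], a[, , 2], a[, , 1],
                 pixelSize = pixelSizeUm)
  list(frameset = fs, phantoms = phantoms, class = profile$class_label)
}

#' Lipid-to-protein ratio map
#'
#' Per pixel r = I2850 / (I2850 + I2930); r lies in `[0, 1]`; pixels with a
#' zero denominator are NA (invalid) and excluded from downstream medians.
#'
#' @param f2850,f2930 registered frames.
#' @return ratio matrix with NA at invalid pixels.
#' @export
ratioMap <- function(f2850, f2930) {
  if (!all(dim(f2850) == dim(f2930))) stop("frame shapes differ")
  den <- f2850 + f2930
  r <- ifelse(den > 0, f2850 / den, NA_real_)
  matrix(r, nrow(f2850), ncol(f2850))
}

#' Background-corrected probe map
#'
#' Per pixel p = max(I2222 - I2100, 0): the off-resonance frame removes the
#' silent-region background; negative differences are clipped to 0 since
#' the probe signal is physically non-negative.
#'
#' @param f2222,f2100 registered on/off-resonance frames.
#' @return probe intensity matrix (>= 0).
#' @export
probeMap <- function(f2222, f2100) {
  if (!all(dim(f2222) == dim(f2100))) stop("frame shapes differ")
  pmax(f2222 - f2100, 0)
}

#' Segment cells from an SRS frame set
#'
#' Cells are found on the protein (2930 cm^-1) frame: Gaussian smoothing,
#' Otsu threshold, hole filling, connected components, and a minimum-area
#' filter. Within each cell the nucleus proxy is the largest connected
#' low-lipid-ratio core (ratio below the within-cell Otsu split), and
#' cytoplasm = cell minus nucleus proxy.
#'
#' @param fs a [frameSet()].
#' @param sigma Gaussian smoothing sigma (pixels).
#' @param minAreaUm2 minimum cell area (square micrometres).
#' @return list with `labels` (integer matrix, 0 = background), `cells`
#'   (list of per-cell logical masks), `cytoplasm` (matching list),
#'   `nucleus` (matching list) and `rule` (segmentation record). Zero cells
#'   found gives empty lists with a warning.
#' @export
segmentCells <- function(fs, sigma = 2, minAreaUm2 = 12) {
  stopifnot(inherits(fs, "FrameSet"))
  f <- fs$frames[["2930"]]
  sm <- as.matrix(EBImage::gblur(EBImage::Image(f), sigma = sigma))
  if (diff(range(sm)) == 0) {
    warning("blank frame: no cells found")
    return(list(labels = matrix(0L, nrow(f), ncol(f)), cells = list(),
                cytoplasm = list(), nucleus = list(), rule = "blank"))
  }
  thr <- .otsuThreshold(as.numeric(sm))
  mask <- sm > thr
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(f), ncol(f))
  minPix <- minAreaUm2 / fs$pixel_size^2
  keep <- which(tabulate(lab[lab > 0]) >= minPix)
  if (!length(keep)) {
    warning("no cells above the minimum area")
    return(list(labels = matrix(0L, nrow(f), ncol(f)), cells = list(),
                cytoplasm = list(), nucleus = list(), rule = "none kept"))
  }
  labels <- matrix(0L, nrow(f), ncol(f))
  cells <- cytoplasm <- nucleus <- vector("list", length(keep))
  r <- ratioMap(fs$frames[["2850"]], fs$frames[["2930"]])
  for (i in seq_along(keep)) {
    cm <- lab == keep[i]
    labels[cm] <- i
    rv <- r[cm]
    nuc <- matrix(FALSE, nrow(f), ncol(f))
    rvOk <- rv[!is.na(rv)]
    if (length(rvOk) > 10 && diff(range(rvOk)) > 0) {
      cut <- .otsuThreshold(rvOk)
      core <- cm & !is.na(r) & r < cut
      # keep the largest connected low-ratio core as the nucleus proxy
      cl <- EBImage::bwlabel(EBImage::Image(core * 1))
      cl <- matrix(as.integer(cl), nrow(f), ncol(f))
      if (max(cl) > 0) {
        big <- which.max(tabulate(cl[cl > 0]))
        nuc <- cl == big
      }
    }
    cells[[i]] <- cm
    nucleus[[i]] <- nuc
    cytoplasm[[i]] <- cm & !nuc
  }
  list(labels = labels, cells = cells, cytoplasm = cytoplasm,
       nucleus = nucleus,
       rule = paste("cells: gblur + otsu + fillHull + bwlabel + min-area;",
                    "nucleus proxy: largest connected low-ratio core;",
                    "cytoplasm = cell minus nucleus proxy"))
}

#' Per-cell marker table
#'
#' For each cell, the median lipid-to-protein ratio over the cell mask
#' divided by the cell area (um^2), and the median probe signal over the
#' cytoplasm mask divided by the cytoplasm area. NA (invalid) pixels are
#' excluded before the medians; cells with an empty cytoplasm mask are
#' dropped with a warning.
#'
#' @param ratio ratio image from [ratioMap()].
#' @param probe probe image from [probeMap()].
#' @param seg segmentation from [segmentCells()] (or a compatible list of
#'   `cells` and `cytoplasm` masks).
#' @param pixelSize micrometres per pixel.
#' @param class optional known class label attached to every cell.
#' @return data.frame: cell_id, cell_area_um2, cytoplasm_area_um2,
#'   lp_per_area, mb_per_area, class.
#' @export
perCellMarkers <- function(ratio, probe, seg, pixelSize, class = NA) {
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  px2 <- pixelSize^2
  rows <- list()
  for (i in seq_along(seg$cells)) {
    cm <- seg$cells[[i]]
    cy <- seg$cytoplasm[[i]]
    if (!any(cy)) {
      warning(sprintf("cell %d dropped: empty cytoplasm mask", i))
      next
    }
    rv <- ratio[cm]
    rv <- rv[!is.na(rv)]
    pv <- probe[cy]
    pv <- pv[!is.na(pv)]
    if (!length(rv) || !length(pv)) {
      warning(sprintf("cell %d dropped: no valid pixels", i))
      next
    }
    cellArea <- sum(cm) * px2
    cytoArea <- sum(cy) * px2
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = i, cell_area_um2 = cellArea, cytoplasm_area_um2 = cytoArea,
      lp_per_area = median(rv) / cellArea,
      mb_per_area = median(pv) / cytoArea,
      class = class, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cell_id = integer(0), cell_area_um2 = numeric(0),
                      cytoplasm_area_um2 = numeric(0),
                      lp_per_area = numeric(0), mb_per_area = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Calibrate quadrant thresholds by ROC analysis
#'
#' One ROC per marker with precursor as the positive, high-valued class;
#' thresholds at maximal Youden's J.
#'
#' @param markerTable data.frame from [perCellMarkers()] with known `class`
#'   labels; needs both classes and >= 5 cells per class.
#' @param positive positive class label (default "precursor").
#' @return list: `thresholds` (mb_threshold, lp_threshold, provenance),
#'   `roc_lp`, `roc_mb`.
#' @export
calibrateThresholds <- function(markerTable, positive = "precursor") {
  tab <- markerTable[!is.na(markerTable$class), ]
  counts <- table(tab$class)
  if (length(counts) < 2L) stop("both classes must be present")
  if (any(counts < 5L)) stop("need at least 5 cells per class")
  rocLP <- rocCurve(tab$lp_per_area, tab$class, positive = positive,
                    direction = ">")
  rocMB <- rocCurve(tab$mb_per_area, tab$class, positive = positive,
                    direction = ">")
  list(thresholds = list(mb_threshold = rocMB$threshold,
                         lp_threshold = rocLP$threshold,
                         provenance = "calibrated"),
       roc_lp = rocLP, roc_mb = rocMB)
}

#' Fixed threshold pair
#'
#' @param mbThreshold,lpThreshold finite marker thresholds (probe units per
#'   um^2 and ratio per um^2).
#' @return threshold list with provenance "fixed".
#' @export
fixedThresholds <- function(mbThreshold, lpThreshold) {
  if (!is.finite(mbThreshold) || !is.finite(lpThreshold))
    stop("thresholds must be finite")
  list(mb_threshold = mbThreshold, lp_threshold = lpThreshold,
       provenance = "fixed")
}

#' Quadrant classification of a marker table
#'
#' Both markers above their thresholds -> precursor; both below ->
#' erythrocyte_like; mixed quadrants -> indeterminate. Cells with a missing
#' marker value are flagged, not classified.
#'
#' @param markerTable data.frame from [perCellMarkers()].
#' @param thresholds list with `mb_threshold` and `lp_threshold` (from
#'   [calibrateThresholds()]`$thresholds` or [fixedThresholds()]).
#' @return the marker table with a `call` column in
#'   \{precursor, erythrocyte_like, indeterminate, NA\}.
#' @export
classifyQuadrant <- function(markerTable, thresholds) {
  mb <- markerTable$mb_per_area
  lp <- markerTable$lp_per_area
  call <- rep(NA_character_, nrow(markerTable))
  ok <- !is.na(mb) & !is.na(lp)
  hi <- ok & mb > thresholds$mb_threshold & lp > thresholds$lp_threshold
  lo <- ok & mb <= thresholds$mb_threshold & lp <= thresholds$lp_threshold
  call[hi] <- "precursor"
  call[lo] <- "erythrocyte_like"
  call[ok & !hi & !lo] <- "indeterminate"
  markerTable$call <- call
  markerTable
}
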