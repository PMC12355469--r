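## Readers/writers for every artifact the pipeline exchanges, plus the CLI
## that chains the stages. Cubes travel in a versioned single-file container
## (serialized R list with a fixed layout: cube array + wavenumber axis +
## attributes + optional ground-truth group); 2-d maps as TIFF (unit-scaled
## 32-bit float with a JSON sidecar recording the scale); tables as CSV;
## thresholds and summaries as JSON. Every stage is reproducible from its
## declared inputs, the config and the seed alone.

.CUBE_FORMAT <- "RamanEry-cube"
.CUBE_VERSION <- 1L

.violation <- function(name, detail) {
  stop(sprintf("cube layout violation [%s]: %s", name, detail), call. = FALSE)
}

#' Write a hyperspectral cube container
#'
#' @param img an [HSImage-class].
#' @param path output file (conventionally .rds).
#' @return invisibly, the path.
#' @export
writeCube <- function(img, path) {
  stopifnot(is(img, "HSImage"))
  validObject(img)
  md <- img@metadata
  obj <- list(
    format = .CUBE_FORMAT, version = .CUBE_VERSION,
    cube = img@cube, wavenumbers_cm1 = img@wavenumbers,
    attrs = list(pixel_size_um = img@pixelSize, modality = img@modality,
                 class_label = md$class_label, seed = md$seed),
    ground_truth = md$ground_truth)
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' Read a hyperspectral cube container
#'
#' Validates the layout and returns an [HSImage-class]; violations are
#' reported by name (bad_format, missing_cube, missing_wavenumbers,
#' shape_mismatch, nonincreasing_wavenumbers, missing_attrs).
#'
#' @param path container file from [writeCube()].
#' @return an [HSImage-class].
#' @export
readCube <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, .CUBE_FORMAT))
    .violation("bad_format", "not a RamanEry cube container")
  if (is.null(obj$cube) || length(dim(obj$cube)) != 3L)
    .violation("missing_cube", "dataset 'cube' absent or not 3-d")
  if (is.null(obj$wavenumbers_cm1))
    .violation("missing_wavenumbers", "dataset 'wavenumbers_cm1' absent")
  if (length(obj$wavenumbers_cm1) != dim(obj$cube)[3])
    .violation("shape_mismatch",
               "channel dimension does not match wavenumber length")
  if (any(diff(obj$wavenumbers_cm1) <= 0))
    .violation("nonincreasing_wavenumbers",
               "wavenumbers must be strictly increasing")
  if (is.null(obj$attrs) || is.null(obj$attrs$pixel_size_um) ||
      is.null(obj$attrs$modality))
    .violation("missing_attrs", "attrs pixel_size_um / modality required")
  md <- list()
  if (!is.null(obj$attrs$class_label)) md$class_label <- obj$attrs$class_label
  if (!is.null(obj$attrs$seed)) md$seed <- obj$attrs$seed
  if (!is.null(obj$ground_truth)) md$ground_truth <- obj$ground_truth
  HSImage(obj$cube, obj$wavenumbers_cm1,
          pixelSize = obj$attrs$pixel_size_um,
          modality = obj$attrs$modality, metadata = md)
}

#' Write a cohort of spectra as long-format CSV
#'
#' Columns: sample_id, group_id, class, wavenumber_cm1, intensity.
#'
#' @param se `SummarizedExperiment` as produced by
#'   [simulateCohortSpectra()].
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
writeSpectraCSV <- function(se, path) {
  cm <- cohortMatrix(se)
  n <- nrow(cm$X)
  m <- length(cm$axis)
  dt <- data.table::data.table(
    sample_id = rep(cm$groups, each = m),
    group_id = rep(cm$groups, each = m),
    class = rep(cm$y, each = m),
    wavenumber_cm1 = rep(as.numeric(cm$axis), n),
    intensity = as.numeric(t(cm$X)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a long-format spectra CSV
#'
#' @param path CSV with columns sample_id, group_id, class, wavenumber_cm1,
#'   intensity; every sample must sit on the same wavenumber axis.
#' @return `SummarizedExperiment` (channels x cells).
#' @export
readSpectraCSV <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample_id", "group_id", "class", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(dt)))
    stop("spectra CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(dt$sample_id)
  rows <- split(seq_len(nrow(dt)),
                factor(dt$sample_id, levels = ids))
  ref <- dt$wavenumber_cm1[rows[[1]]]
  same <- vapply(rows, function(ix) {
    a <- dt$wavenumber_cm1[ix]
    length(a) == length(ref) && all(a == ref)
  }, TRUE)
  if (!all(same)) stop("ragged axes: samples sit on different wavenumber grids")
  X <- vapply(rows, function(ix) dt$intensity[ix], numeric(length(ref)))
  first <- vapply(rows, `[`, 0L, 1L)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = X),
    rowData = S4Vectors::DataFrame(wavenumber_cm1 = ref),
    colData = S4Vectors::DataFrame(class = dt$class[first],
                                   cell_id = as.character(ids),
                                   row.names = as.character(ids)))
}

#' Write a 2-d map as unit-scaled float TIFF with a JSON sidecar
#'
#' TIFF stores the map divided by its recorded positive scale (maximum
#' absolute value), so values survive the `[0, 1]` storage range; the
#' sidecar `<path>.json` records the scale.
#'
#' @param map numeric matrix.
#' @param path output .tif path.
#' @return invisibly, the path.
#' @export
writeMapTIFF <- function(map, path) {
  sc <- max(abs(map), na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- 1
  m <- pmin(pmax(map / sc, 0), 1)
  m[is.na(m)] <- 0
  suppressWarnings(tiff::writeTIFF(m, path, bits.per.sample = 32L))
  jsonlite::write_json(list(scale = sc), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a map written by [writeMapTIFF()]
#' @param path .tif path with its .json sidecar.
#' @return numeric matrix.
#' @export
readMapTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  sc <- jsonlite::read_json(paste0(path, ".json"))$scale
  m * sc
}

#' Read a run configuration (YAML)
#'
#' Top level: `seed`, `out_dir`, `log_level`, plus one block per stage
#' (simulate, preprocess, decompose, train, phasor, classify, report).
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "log_level", "simulate", "preprocess",
             "decompose", "train", "phasor", "classify", "report")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  cfg
}

## ---- CLI ------------------------------------------------------------------

.cliLog <- function(...) cat(sprintf(...), "\n", file = stderr())

# Parse "--key value" pairs; returns a named list or a condition-free NULL
# on unknown flags (caller prints usage and exits 2).
.parseFlags <- function(args, allowed) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- gsub("-", "_", substring(a, 3))
    if (!key %in% allowed) return(NULL)
    if (i + 1L > length(args)) return(NULL)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

.num <- function(x, default) if (is.null(x)) default else as.numeric(x)
.int <- function(x, default) if (is.null(x)) default else as.integer(x)
.chr <- function(x, default) if (is.null(x)) default else x

.presetSizes <- function(preset) {
  switch(preset,
    "two-class" = list(nCohort = 50L, nFrameCells = 30L,
                       frameShape = c(448L, 448L), axis = ramanAxis()),
    "two-class-small" = list(nCohort = 12L, nFrameCells = 6L,
                             frameShape = c(160L, 160L),
                             axis = ramanAxis(from = 600, to = 1800)),
    stop("unknown preset: ", preset))
}

.cliSimulate <- function(opts) {
  preset <- .chr(opts$preset, "two-class")
  seed <- .int(opts$seed, 1L)
  out <- .chr(opts$out, ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sz <- .presetSizes(preset)
  profiles <- defaultClassProfiles()
  se <- simulateCohortSpectra(sz$nCohort, profiles, axis = sz$axis,
                              seed = seed)
  writeSpectraCSV(se, file.path(out, "cohort_spectra.csv"))
  for (cl in names(profiles)) {
    fsSeed <- seed + match(cl, names(profiles))
    sim <- simulateFrameSet(sz$nFrameCells, profiles[[cl]],
                            imageShape = sz$frameShape, seed = fsSeed)
    saveRDS(sim, file.path(out, sprintf("frames_%s.rds", cl)),
            compress = FALSE)
  }
  # one small hyperspectral image per class for decompose/phasor stages
  for (cl in names(profiles)) {
    ph <- makePhantom(3L, c(96L, 96L),
                      list(radiusScale = profiles[[cl]]$cell_radius_scale),
                      seed = seed + 10L)
    img <- simulateHSImage(ph, profiles[[cl]], axis = sz$axis,
                           noise = noiseParams(readSD = 0.01),
                           seed = seed + 11L)
    writeCube(img, file.path(out, sprintf("cube_%s.rds", cl)))
  }
  .cliLog("simulate: preset=%s seed=%d -> %s", preset, seed, out)
  0L
}

.cliPreprocess <- function(opts) {
  inPath <- opts$`in`
  if (is.null(inPath)) return(2L)
  out <- .chr(opts$out, ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- preprocessConfig(
    baselineMethod = .chr(opts$baseline, "none"),
    norm = .chr(opts$norm, "vector"),
    crop = if (!is.null(opts$crop_silent) && opts$crop_silent == "true")
      list(c(600, 1800), c(2800, 3100)) else NULL)
  se <- readSpectraCSV(inPath)
  cm <- cohortMatrix(se)
  done <- lapply(seq_len(nrow(cm$X)), function(i)
    preprocessSpectrum(cm$X[i, ], cm$axis, cfg))
  ax <- done[[1]]$axis
  X <- t(vapply(done, `[[`, numeric(length(ax)), "spectrum"))
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(X)),
    rowData = S4Vectors::DataFrame(wavenumber_cm1 = ax),
    colData = SummarizedExperiment::colData(se))
  writeSpectraCSV(se2, file.path(out, "preprocessed_spectra.csv"))
  .cliLog("preprocess: %d spectra -> %s", nrow(X), out)
  0L
}

.cliDecompose <- function(opts) {
  inPath <- opts$`in`
  if (is.null(inPath)) return(2L)
  out <- .chr(opts$out, ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  img <- readCube(inPath)
  cs <- mcrALS(img, k = .int(opts$k, 10L),
               contrastWeight = .num(opts$contrast, 0),
               tolLOF = .num(opts$tol, 1e-6),
               maxIter = .int(opts$max_iter, 500L),
               init = .chr(opts$init, "purest"),
               seed = .int(opts$seed, 1L))
  saveRDS(cs, file.path(out, "components.rds"), compress = FALSE)
  maps <- concentrationMaps(cs)
  for (j in seq_len(dim(maps)[3]))
    writeMapTIFF(maps[, , j], file.path(out, sprintf("component_%02d.tif", j)))
  diag <- data.table::data.table(
    component = seq_len(nrow(cs@S)),
    signal_fraction_percent = cs@signalFractions)
  data.table::fwrite(diag, file.path(out, "decompose_diagnostics.csv"))
  data.table::fwrite(
    data.table::data.table(lof_percent = cs@lofPercent,
                           iterations = cs@iterations,
                           converged = cs@converged),
    file.path(out, "decompose_fit.csv"))
  .cliLog("decompose: k=%d LOF=%.3f%% -> %s", nrow(cs@S), cs@lofPercent, out)
  0L
}

.cliTrain <- function(opts) {
  inPath <- opts$`in`
  if (is.null(inPath)) return(2L)
  out <- .chr(opts$out, ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  se <- readSpectraCSV(inPath)
  cm <- cohortMatrix(se)
  nOrtho <- .int(opts$n_ortho, 3L)
  folds <- .int(opts$folds, 7L)
  seed <- .int(opts$seed, 1L)
  lv <- c("precursor", "erythrocyte_like")
  if (!all(cm$y %in% lv)) lv <- unique(cm$y)
  cv <- crossValidate(cm$X, cm$y, cm$groups, nOrtho = nOrtho,
                      kFolds = folds, seed = seed, classLevels = lv)
  fit <- oplsFit(cm$X, cm$y, nOrtho = nOrtho, classLevels = lv,
                 wavenumbers = cm$axis)
  metrics <- data.table::data.table(
    sensitivity = cv$sensitivity, specificity = cv$specificity,
    mcc = cv$mcc, TP = cv$TP, FP = cv$FP, TN = cv$TN, FN = cv$FN,
    r2x_total = fit@r2xTotal)
  nPerm <- .int(opts$permutations, 0L)
  if (nPerm >= 99L) {
    pt <- permutationTest(cm$X, cm$y, cm$groups, nPerm = nPerm,
                          nOrtho = nOrtho, kFolds = folds, seed = seed)
    metrics$permutation_p <- pt$p_value
  }
  data.table::fwrite(metrics, file.path(out, "cv_metrics.csv"))
  data.table::fwrite(
    data.table::data.table(wavenumber_cm1 = cm$axis, vip = vipScores(fit),
                           weight_pred = fit@weightsPred),
    file.path(out, "vip.csv"))
  data.table::fwrite(data.table::as.data.table(cv$predictions),
                     file.path(out, "cv_predictions.csv"))
  .cliLog("train: sens=%.3f spec=%.3f mcc=%.3f -> %s",
          cv$sensitivity, cv$specificity, cv$mcc, out)
  0L
}

.cliPhasor <- function(opts) {
  inPath <- opts$`in`
  if (is.null(inPath)) return(2L)
  out <- .chr(opts$out, ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  img <- readCube(inPath)
  pm <- spectralPhasor(img, harmonic = .int(opts$harmonic, 1L))
  seg <- phasorSegment(pm, img, nClusters = .int(opts$clusters, 3L),
                       seed = .int(opts$seed, 1L))
  writeMapTIFF(pm@G, file.path(out, "phasor_G.tif"))
  writeMapTIFF(pm@S, file.path(out, "phasor_S.tif"))
  writeMapTIFF(pm@intensity, file.path(out, "phasor_intensity.tif"))
  writeMapTIFF(seg@labels, file.path(out, "phasor_labels.tif"))
  data.table::fwrite(
    data.table::data.table(label = seq_along(seg@regionNames),
                           region = seg@regionNames,
                           G = seg@centers[, 1], S = seg@centers[, 2]),
    file.path(out, "phasor_regions.csv"))
  .cliLog("phasor: %d regions -> %s", length(seg@regionNames), out)
  0L
}

.cliClassify <- function(opts) {
  out <- .chr(opts$out, ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tabs <- list()
  if (!is.null(opts$frames_rds)) {
    # comma-separated simulateFrameSet() .rds files (class carried inside)
    for (p in strsplit(opts$frames_rds, ",", fixed = TRUE)[[1]]) {
      sim <- readRDS(p)
      fs <- sim$frameset
      seg <- segmentCells(fs)
      tab <- perCellMarkers(ratioMap(fs$frames[["2850"]],
                                     fs$frames[["2930"]]),
                            probeMap(fs$frames[["2222"]],
                                     fs$frames[["2100"]]),
                            seg, fs$pixel_size, class = sim$class)
      tabs[[length(tabs) + 1L]] <- tab
    }
  } else if (!is.null(opts$frames)) {
    f <- strsplit(opts$frames, ",", fixed = TRUE)[[1]]
    if (length(f) != 4L) return(2L)
    px <- .num(opts$pixel_size, 0.3)
    fs <- frameSet(readMapTIFF(f[1]), readMapTIFF(f[2]),
                   readMapTIFF(f[3]), readMapTIFF(f[4]), pixelSize = px)
    seg <- segmentCells(fs)
    tabs[[1]] <- perCellMarkers(
      ratioMap(fs$frames[["2850"]], fs$frames[["2930"]]),
      probeMap(fs$frames[["2222"]], fs$frames[["2100"]]),
      seg, fs$pixel_size)
  } else return(2L)
  tab <- do.call(rbind, tabs)
  tab$cell_id <- seq_len(nrow(tab))
  thrSpec <- .chr(opts$thresholds, "auto")
  if (thrSpec == "auto") {
    cal <- calibrateThresholds(tab)
    thr <- cal$thresholds
    jsonlite::write_json(
      c(thr, list(lp_auc = cal$roc_lp$auc, mb_auc = cal$roc_mb$auc)),
      file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  } else {
    thr <- jsonlite::read_json(thrSpec)
    jsonlite::write_json(thr, file.path(out, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tab <- classifyQuadrant(tab, thr)
  data.table::fwrite(data.table::as.data.table(tab),
                     file.path(out, "marker_table.csv"))
  .cliLog("classify: %d cells -> %s", nrow(tab), out)
  0L
}

.cliReport <- function(opts) {
  dirIn <- .chr(opts$dir, ".")
  out <- .chr(opts$out, file.path(dirIn, "report.json"))
  rep <- list()
  mf <- file.path(dirIn, "cv_metrics.csv")
  if (file.exists(mf)) rep$opls_cv <- as.list(data.table::fread(mf)[1])
  tf <- file.path(dirIn, "thresholds.json")
  if (file.exists(tf)) rep$thresholds <- jsonlite::read_json(tf)
  mt <- file.path(dirIn, "marker_table.csv")
  if (file.exists(mt)) {
    tab <- data.table::fread(mt)
    rep$markers <- list(n_cells = nrow(tab),
                        calls = as.list(table(tab$call)))
    if ("class" %in% names(tab) && !all(is.na(tab$class))) {
      ok <- !is.na(tab$class) & tab$call != "indeterminate"
      rep$markers$quadrant_accuracy <-
        mean(tab$call[ok] == tab$class[ok])
      rep$markers$indeterminate_fraction <-
        mean(tab$call == "indeterminate")
    }
  }
  df <- file.path(dirIn, "decompose_fit.csv")
  if (file.exists(df)) rep$mcr <- as.list(data.table::fread(df)[1])
  jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA)
  .cliLog("report -> %s", out)
  0L
}

.cliUsage <- function() {
  .cliLog(paste(
    "usage: ramanery <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate   --preset two-class|two-class-small --seed N --out DIR",
    "  preprocess --in cohort.csv --norm vector --baseline none --out DIR",
    "  decompose  --in cube.rds --k 10 --contrast 0 --tol 1e-6",
    "             --max-iter 500 --init purest --seed N --out DIR",
    "  train      --in spectra.csv --n-ortho 3 --folds 7",
    "             --permutations 999 --seed N --out DIR",
    "  phasor     --in cube.rds --harmonic 1 --clusters 3 --seed N --out DIR",
    "  classify   --frames-rds a.rds,b.rds | --frames 4 TIFFs",
    "             --thresholds auto|file.json --pixel-size 0.3 --out DIR",
    "  report     --dir DIR --out report.json",
    sep = "\n"))
  2L
}

.cliAllowed <- list(
  simulate = c("preset", "seed", "out"),
  preprocess = c("in", "norm", "baseline", "crop_silent", "out"),
  decompose = c("in", "k", "contrast", "tol", "max_iter", "init", "seed",
                "out"),
  train = c("in", "n_ortho", "folds", "permutations", "seed", "out"),
  phasor = c("in", "harmonic", "clusters", "seed", "out"),
  classify = c("frames_rds", "frames", "thresholds", "pixel_size", "out"),
  report = c("dir", "out"))

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (simulate, preprocess, decompose,
#' train, phasor, classify, report). Designed to be called from the thin
#' Rscript wrapper shipped in `inst/cli/ramanery.R`; returns the exit code
#' (0 success, 2 usage error) instead of quitting so it can be driven from
#' tests.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
ramanCLI <- function(argv) {
  if (!length(argv)) return(invisible(.cliUsage()))
  sub <- argv[1]
  if (!sub %in% names(.cliAllowed)) return(invisible(.cliUsage()))
  opts <- .parseFlags(argv[-1], .cliAllowed[[sub]])
  if (is.null(opts)) return(invisible(.cliUsage()))
  code <- tryCatch(switch(sub,
    simulate = .cliSimulate(opts),
    preprocess = .cliPreprocess(opts),
    decompose = .cliDecompose(opts),
    train = .cliTrain(opts),
    phasor = .cliPhasor(opts),
    classify = .cliClassify(opts),
    report = .cliReport(opts)),
    error = function(e) {
      .cliLog("error: %s", conditionMessage(e))
      1L
    })
  if (code == 2L) return(invisible(.cliUsage()))
  invisible(code)
}

#' Run the full pipeline on the synthetic preset
#'
#' Chains simulate -> preprocess -> train -> classify -> report (plus a
#' decompose and phasor pass on one simulated cube) into one output
#' directory. Identical config + seed reproduce every artifact byte for
#' byte.
#'
#' @param outDir output directory.
#' @param seed global seed.
#' @param preset "two-class" or "two-class-small".
#' @param permutations permutation count for the train stage (0 = skip).
#' @return invisibly, 0 on success.
#' @export
runPipeline <- function(outDir, seed = 1, preset = "two-class-small",
                        permutations = 0L) {
  s <- as.character(seed)
  stopifnot(ramanCLI(c("simulate", "--preset", preset, "--seed", s,
                       "--out", outDir)) == 0L)
  stopifnot(ramanCLI(c("preprocess", "--in",
                       file.path(outDir, "cohort_spectra.csv"),
                       "--out", outDir)) == 0L)
  stopifnot(ramanCLI(c("train", "--in",
                       file.path(outDir, "preprocessed_spectra.csv"),
                       "--permutations", as.character(permutations),
                       "--seed", s, "--out", outDir)) == 0L)
  stopifnot(ramanCLI(c("decompose", "--in",
                       file.path(outDir, "cube_precursor.rds"),
                       "--k", "4", "--seed", s, "--out", outDir)) == 0L)
  stopifnot(ramanCLI(c("phasor", "--in",
                       file.path(outDir, "cube_precursor.rds"),
                       "--seed", s, "--out", outDir)) == 0L)
  stopifnot(ramanCLI(c(
    "classify", "--frames-rds",
    paste(file.path(outDir, "frames_precursor.rds"),
          file.path(outDir, "frames_erythrocyte_like.rds"), sep = ","),
    "--thresholds", "auto", "--out", outDir)) == 0L)
  stopifnot(ramanCLI(c("report", "--dir", outDir,
                       "--out", file.path(outDir, "report.json"))) == 0L)
  invisible(0L)
}
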