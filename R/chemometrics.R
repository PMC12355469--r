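## Chemometrics: PCA, OPLS-DA with VIP, group-aware cross-validated
## classification metrics, permutation testing, ROC analysis, and the
## Mann-Whitney rank test. Class coding throughout: the first class level
## ("precursor") is +1, the second ("erythrocyte_like") is -1; the decision
## threshold on the continuous prediction is 0.

.codeClasses <- function(y, classLevels = NULL) {
  if (is.null(classLevels)) classLevels <- unique(as.character(y))
  if (length(classLevels) != 2L)
    stop("exactly two classes required, got: ",
         paste(classLevels, collapse = ", "))
  code <- ifelse(as.character(y) == classLevels[1], 1, -1)
  list(code = code, levels = classLevels)
}

#' Principal component analysis of a spectra matrix
#'
#' Thin wrapper around singular value decomposition of the centred
#' (optionally scaled) matrix, reporting scores, orthonormal loadings and
#' percent explained variance.
#'
#' @param X samples x channels matrix.
#' @param nComponents number of components (default full rank).
#' @param center,scale. passed to scaling; centring defaults on.
#' @return list(scores, loadings, explained) with `explained` in percent,
#'   non-increasing.
#' @export
spectraPCA <- function(X, nComponents = NULL, center = TRUE, scale. = FALSE) {
  if (all(apply(X, 2, var) == 0)) stop("constant matrix has no PCA")
  pc <- prcomp(X, center = center, scale. = scale.)
  ev <- pc$sdev^2
  expl <- 100 * ev / sum(ev)
  n <- if (is.null(nComponents)) length(ev) else min(nComponents, length(ev))
  list(scores = pc$x[, seq_len(n), drop = FALSE],
       loadings = pc$rotation[, seq_len(n), drop = FALSE],
       explained = expl[seq_len(n)])
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures (one predictive component,
#' `nOrtho` y-orthogonal components) for a binary response. Each orthogonal
#' weight is the current X loading stripped of its projection on the
#' predictive weight, so every orthogonal score is exactly uncorrelated with
#' the class code. With `nOrtho = 0` the model reduces to one-component
#' PLS1.
#'
#' @param X samples x channels matrix.
#' @param y class labels (two levels) or a +/-1 numeric code.
#' @param nOrtho number of orthogonal components (>= 0). The default model
#'   size used for fingerprint-range spectra is 1 predictive + 3 orthogonal
#'   components.
#' @param scale. unit-variance scale X (default FALSE: spectra are assumed
#'   vector-normalized, only mean-centring is applied).
#' @param classLevels optional explicit ordering of the two classes
#'   (first = +1).
#' @param wavenumbers optional axis stored for prediction-time checks.
#' @return an [OPLSModel-class].
#' @export
oplsFit <- function(X, y, nOrtho = 3L, scale. = FALSE, classLevels = NULL,
                    wavenumbers = numeric(0)) {
  X <- as.matrix(X)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    code <- y
    levels <- if (is.null(classLevels)) c("pos", "neg") else classLevels
  } else {
    cc <- .codeClasses(y, classLevels)
    code <- cc$code
    levels <- cc$levels
  }
  if (length(unique(code)) < 2L) stop("y must contain both classes")
  if (nOrtho < 0) stop("nOrtho must be >= 0")
  ctr <- colMeans(X)
  scl <- if (scale.) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    s
  } else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yMean <- mean(code)
  yc <- code - yMean
  ssxTot <- sum(Xc^2)
  m <- ncol(Xc)
  Wo <- matrix(0, m, nOrtho)
  Po <- matrix(0, m, nOrtho)
  To <- matrix(0, nrow(Xc), nOrtho)
  E <- Xc
  for (h in seq_len(nOrtho)) {
    w <- crossprod(E, yc) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-9 * sqrt(sum(p^2))) {
      # Degenerate case: the loading of the predictive score carries no
      # y-orthogonal part (exact for noise-free planted structure). Take
      # the dominant direction of the y-orthogonal residual instead.
      Eperp <- E - t %*% t(crossprod(E, t)) / sum(t^2)
      if (sum(Eperp^2) < 1e-20 * sum(E^2)) break  # nothing left to remove
      sv <- svd(Eperp, nu = 0, nv = 1)
      wo <- sv$v[, 1]
      wo <- wo - as.numeric(crossprod(w, wo)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) break
    }
    wo <- wo / nwo
    to <- E %*% wo
    # keep the orthogonal score exactly uncorrelated with the response
    to <- to - yc * as.numeric(crossprod(yc, to)) / sum(yc^2)
    po <- crossprod(E, to) / sum(to^2)
    E <- E - to %*% t(po)
    Wo[, h] <- wo
    Po[, h] <- po
    To[, h] <- to
  }
  w <- crossprod(E, yc) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  t <- as.numeric(E %*% w)
  p <- as.numeric(crossprod(E, t) / sum(t^2))
  q <- sum(yc * t) / sum(t^2)
  ssModel <- sum((t %*% t(p))^2) + sum((To %*% t(Po))^2)
  w <- as.numeric(w)
  # VIP of the single predictive component: sqrt(m) * |w| / ||w||
  vip <- sqrt(m) * abs(w) / sqrt(sum(w^2))
  new("OPLSModel",
      weightsPred = w, loadingsPred = p, scoresPred = t, q = q,
      weightsOrtho = Wo, loadingsOrtho = Po, scoresOrtho = To,
      center = ctr, scaleVec = scl, yMean = yMean,
      vip = vip, r2xTotal = 100 * ssModel / ssxTot,
      nOrtho = as.integer(ncol(Wo)), wavenumbers = as.numeric(wavenumbers),
      classLevels = levels)
}

#' Predict with an OPLS-DA model
#'
#' New spectra are centred/scaled with the training parameters, the
#' orthogonal variation is filtered out sequentially, and the predictive
#' score times the regression coefficient (plus the training class-code
#' mean) gives the continuous prediction; the class call is its sign
#' relative to `threshold`.
#'
#' @param model an [OPLSModel-class].
#' @param Xnew samples x channels matrix on the training channel grid.
#' @param threshold decision threshold on the continuous prediction.
#' @param wavenumbers optional axis of Xnew; must match training when both
#'   are known.
#' @return list(yhat, class) with `class` in the training class labels.
#' @export
oplsPredict <- function(model, Xnew, threshold = 0,
                        wavenumbers = NULL) {
  Xnew <- matrix(as.numeric(Xnew), ncol = length(model@center))
  if (!is.null(wavenumbers) && length(model@wavenumbers) &&
      (length(wavenumbers) != length(model@wavenumbers) ||
       any(wavenumbers != model@wavenumbers)))
    stop("wavenumber axis does not match the training axis")
  E <- sweep(sweep(Xnew, 2, model@center), 2, model@scaleVec, "/")
  for (h in seq_len(model@nOrtho)) {
    to <- E %*% model@weightsOrtho[, h]
    E <- E - to %*% t(model@loadingsOrtho[, h])
  }
  t <- as.numeric(E %*% model@weightsPred)
  yhat <- t * model@q + model@yMean
  cls <- ifelse(yhat > threshold, model@classLevels[1], model@classLevels[2])
  list(yhat = yhat, class = cls)
}

#' Classification metrics from a confusion table
#'
#' @param TP,FP,TN,FN non-negative counts (positives = first class).
#' @return list(sensitivity, specificity, mcc); MCC is 0 by convention when
#'   any marginal of the table is zero.
#' @export
confusionMetrics <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be non-negative")
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) 0 else (TP * TN - FP * FN) / sqrt(denom2)
  list(sensitivity = sens, specificity = spec, mcc = mcc)
}

# Group-stratified fold assignment: groups (cells) of each class are dealt
# round-robin into folds after a seeded shuffle, so no group spans folds and
# every fold keeps both classes where counts allow.
.groupFolds <- function(y, groups, kFolds, seed, maxRetry = 20L) {
  for (attempt in seq_len(maxRetry)) {
    gclass <- tapply(as.character(y), groups, function(v) v[1])
    gnames <- names(gclass)
    fold <- integer(length(gnames))
    names(fold) <- gnames
    withSeed(seed + attempt - 1L, {
      for (cl in unique(gclass)) {
        g <- sample(gnames[gclass == cl])
        fold[g] <- rep_len(seq_len(kFolds), length(g))
      }
    })
    sampleFold <- fold[as.character(groups)]
    ok <- all(vapply(seq_len(kFolds), function(f)
      length(unique(y[sampleFold != f])) == 2L, TRUE))
    if (ok) return(sampleFold)
  }
  stop("could not build folds keeping both classes in every training set")
}

#' Group-stratified cross-validated OPLS-DA
#'
#' Folds never split a group (cell); centring/scaling and the whole model
#' are re-fitted inside each training fold; out-of-fold predictions are
#' pooled into one confusion table.
#'
#' @param X samples x channels matrix.
#' @param y class labels (two levels; first level = positive class).
#' @param groups group (cell) identifier per sample.
#' @param nOrtho orthogonal components.
#' @param kFolds number of folds (default 7).
#' @param threshold decision threshold on the continuous prediction.
#' @param scale. unit-variance scaling inside folds.
#' @param seed fold-assignment seed.
#' @param classLevels optional explicit class ordering (first = positive).
#' @return list: per-sample `predictions` (yhat, class, fold), confusion
#'   counts, sensitivity, specificity, mcc, threshold.
#' @export
crossValidate <- function(X, y, groups = seq_len(nrow(X)), nOrtho = 3L,
                          kFolds = 7L, threshold = 0, scale. = FALSE,
                          seed = 1, classLevels = NULL) {
  X <- as.matrix(X)
  if (kFolds < 2L) stop("kFolds must be >= 2")
  cc <- .codeClasses(y, classLevels)
  fold <- .groupFolds(y, groups, kFolds, seed)
  yhat <- numeric(nrow(X))
  for (f in seq_len(kFolds)) {
    test <- fold == f
    if (!any(test)) next
    fit <- oplsFit(X[!test, , drop = FALSE], y[!test], nOrtho = nOrtho,
                   scale. = scale., classLevels = cc$levels)
    yhat[test] <- oplsPredict(fit, X[test, , drop = FALSE],
                              threshold = threshold)$yhat
  }
  predClass <- ifelse(yhat > threshold, cc$levels[1], cc$levels[2])
  pos <- as.character(y) == cc$levels[1]
  TP <- sum(pos & predClass == cc$levels[1])
  FN <- sum(pos & predClass != cc$levels[1])
  TN <- sum(!pos & predClass == cc$levels[2])
  FP <- sum(!pos & predClass != cc$levels[2])
  met <- confusionMetrics(TP, FP, TN, FN)
  list(predictions = data.frame(yhat = yhat, class = predClass, fold = fold,
                                truth = as.character(y),
                                group = as.character(groups),
                                stringsAsFactors = FALSE),
       TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = met$sensitivity, specificity = met$specificity,
       mcc = met$mcc, threshold = threshold)
}

#' Permutation test of an OPLS-DA cross-validation statistic
#'
#' Class labels are permuted at the group level (all spectra of a cell swap
#' together), the cross-validated statistic (default: MCC) is recomputed
#' under each permutation, and the add-one-smoothed p-value
#' p = (1 + #\{null >= observed\}) / (nPerm + 1) is reported.
#'
#' @param X,y,groups as in [crossValidate()].
#' @param nPerm number of permutations (>= 99; default 999).
#' @param nOrtho,kFolds,scale. model settings.
#' @param statistic function(cv) -> scalar; default extracts `mcc`.
#' @param seed RNG seed.
#' @return list(p_value, observed, null) with the full null distribution.
#' @export
permutationTest <- function(X, y, groups = seq_len(nrow(X)), nPerm = 999L,
                            nOrtho = 3L, kFolds = 7L, scale. = FALSE,
                            statistic = function(cv) cv$mcc, seed = 1) {
  if (nPerm < 99L) stop("nPerm must be >= 99")
  X <- as.matrix(X)
  groups <- as.character(groups)
  obs <- statistic(crossValidate(X, y, groups, nOrtho = nOrtho,
                                 kFolds = kFolds, scale. = scale.,
                                 seed = seed))
  gclass <- tapply(as.character(y), groups, function(v) v[1])
  gnames <- names(gclass)
  null <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    perm <- setNames(sample(gclass), gnames)
    yb <- as.character(perm[groups])
    statistic(tryCatch(
      crossValidate(X, yb, groups, nOrtho = nOrtho, kFolds = kFolds,
                    scale. = scale., seed = seed + b,
                    classLevels = unique(as.character(y))),
      error = function(e) list(mcc = NA_real_)))
  }, 0))
  ok <- !is.na(null)
  p <- (1 + sum(null[ok] >= obs)) / (sum(ok) + 1)
  list(p_value = p, observed = obs, null = null)
}

#' ROC analysis
#'
#' Threshold sweep over the unique marker values; AUC by the trapezoid rule
#' (equal to the normalized Mann-Whitney U statistic); operating threshold
#' at maximal Youden's J, ties broken toward higher specificity.
#'
#' @param values numeric marker values.
#' @param labels class labels; `positive` names the positive class.
#' @param positive positive-class label (default first unique label).
#' @param direction ">" means positives take HIGH values (default);
#'   "<" means positives take low values.
#' @return list: thresholds, tpr, fpr, auc, threshold (chosen), sensitivity
#'   and specificity at the chosen threshold, `degenerate` flag for
#'   constant input.
#' @export
rocCurve <- function(values, labels, positive = NULL, direction = ">") {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  if (is.null(positive)) positive <- unique(labels)[1]
  if (!any(labels == positive) || all(labels == positive))
    stop("both classes must be present")
  v <- if (direction == ">") values else -values
  if (diff(range(v)) == 0) {
    return(list(thresholds = numeric(0), tpr = c(0, 1), fpr = c(0, 1),
                auc = 0.5, threshold = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, degenerate = TRUE))
  }
  pos <- labels == positive
  cand <- sort(unique(v))
  # cut points between consecutive unique values, plus outer extremes
  thr <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
           cand[length(cand)] + 1)
  tpr <- vapply(thr, function(t) mean(v[pos] > t), 0)
  fpr <- vapply(thr, function(t) mean(v[!pos] > t), 0)
  ord <- order(fpr, tpr)
  auc <- pracma::trapz(fpr[ord], tpr[ord])
  j <- tpr - fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.min(fpr[best])]
  chosen <- thr[best]
  list(thresholds = if (direction == ">") thr else -thr,
       tpr = tpr, fpr = fpr, auc = auc,
       threshold = if (direction == ">") chosen else -chosen,
       sensitivity = tpr[best], specificity = 1 - fpr[best],
       degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value from the null U distribution when the samples
#' are tie-free and n1*n2 <= 400; exhaustive enumeration of group
#' assignments for small tied samples; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric samples (each non-empty).
#' @return list(U, p_value, method); U is the statistic of sample `a`
#'   (number of (a, b) pairs with a > b, ties counting 1/2), so
#'   U_a + U_b = n1*n2.
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 * n2 <= 400) {
    pLow <- pwilcox(U, n1, n2)
    pHigh <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(U = U, p_value = p, method = "exact"))
  }
  if (ties && choose(n1 + n2, n1) <= 2e5) {
    combs <- utils::combn(n1 + n2, n1)
    uNull <- apply(combs, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    pLow <- mean(uNull <= U)
    pHigh <- mean(uNull >= U)
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(U = U, p_value = p, method = "exact-enumeration"))
  }
  tieTab <- table(pooled)
  tieCorr <- sum(tieTab^3 - tieTab) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tieCorr))
  mu <- n1 * n2 / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal-approximation")
}
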