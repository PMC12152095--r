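# NIPALS PLS1 on mean-centered X and y; returns coefficient paths so the
# fit at every latent-variable count 1..A is available from one pass.
plsNipals <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  xMean <- colMeans(X); yMean <- mean(y)
  Xc <- sweep(X, 2L, xMean)
  yc <- y - yMean
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  Xr <- Xc; yr <- yc
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break            # X residual orthogonal to y: stop
    w <- w / nw
    t <- Xr %*% w
    tt <- sum(t^2)
    if (tt < 1e-28) break
    pLoad <- crossprod(Xr, t) / tt
    q <- sum(yr * t) / tt
    Xr <- Xr - t %*% t(pLoad)
    yr <- yr - q * t
    a <- k
    W[, k] <- w; P[, k] <- pLoad; Q[k] <- q
  }
  A <- a
  if (A == 0L) stop("response is uncorrelated with every predictor")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  Q <- Q[seq_len(A)]
  # regression coefficients for each truncation 1..A
  R <- W %*% solve(t(P) %*% W)       # p x A, X-weights in original space
  coefPath <- sapply(seq_len(A), function(k)
    R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)])
  list(coefPath = matrix(coefPath, ncol = A), xMean = xMean, yMean = yMean,
       maxLv = A)
}

plsPredict <- function(model, X, lv) {
  b <- model$coefPath[, lv]
  as.numeric(sweep(as.matrix(X), 2L, model$xMean) %*% b) + model$yMean
}

#' Regression performance metrics
#'
#' \eqn{R^2 = 1 - SSE/SST} (SST about the mean of the observed values)
#' and \eqn{RMSE = \sqrt{SSE/n}}.
#'
#' @param yTrue,yHat numeric vectors of equal length (>= 2).
#' @return named vector \code{c(r2, rmse)}; \code{r2} is NA with a
#'   warning when \code{yTrue} has zero variance.
#' @examples
#' regressionMetrics(c(0, 1, 2, 3), c(0.5, 0.5, 2.5, 2.5))  # R2 0.8, RMSE 0.5
#' @export
regressionMetrics <- function(yTrue, yHat) {
  if (length(yTrue) != length(yHat) || length(yTrue) < 2L)
    stop("yTrue and yHat must have equal length >= 2")
  sse <- sum((yTrue - yHat)^2)
  sst <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sst > 0) 1 - sse / sst else {
    warning("zero-variance response: R^2 undefined")
    NA_real_
  }
  c(r2 = r2, rmse = sqrt(sse / length(yTrue)))
}

#' Fit a PLS1 regression of aphid counts with CV-based LV selection
#'
#' Mean-centering NIPALS PLS1. The latent-variable count is chosen at the
#' minimum k-fold cross-validated RMSE (RMSECV), with a one-standard-error
#' tie-break toward fewer components. Reports calibration metrics
#' (R2_cal, RMSEC), cross-validation metrics (R2_cv, RMSECV) and, when a
#' test set is supplied, prediction metrics (R2_pred, RMSEP).
#'
#' @param X training spectra matrix (pre-treated as desired).
#' @param y training counts.
#' @param maxLv largest LV count searched (capped by data size/rank).
#' @param folds CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param testX,testY optional held-out set for prediction metrics.
#' @return list of class "PLSReport" with the fitted model, chosen
#'   \code{lv} and all metrics; \code{rmsecPath} holds RMSEC for each LV.
#' @export
fitPls <- function(X, y, maxLv = 50L, folds = 10L, seed = 1L,
                   testX = NULL, testY = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds || folds < 2L) stop("need n >= folds >= 2")
  if (stats::sd(y) == 0) stop("constant response")
  A <- min(maxLv, n - ceiling(n / folds) - 1L, ncol(X))
  if (A < 1L) stop("too few samples for PLS")

  model <- plsNipals(X, y, A)
  A <- model$maxLv

  rmsecPath <- vapply(seq_len(A), function(k) {
    regressionMetrics(y, plsPredict(model, X, k))[["rmse"]]
  }, numeric(1))

  foldId <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  cvPred <- matrix(NA_real_, n, A)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    mf <- plsNipals(X[tr, , drop = FALSE], y[tr], A)
    kMax <- mf$maxLv
    for (k in seq_len(A))
      cvPred[!tr, k] <- plsPredict(mf, X[!tr, , drop = FALSE], min(k, kMax))
  }
  rmsecvPath <- sqrt(colMeans((cvPred - y)^2))
  se <- apply((cvPred - y)^2, 2L, function(e) stats::sd(e) / sqrt(n)) /
    (2 * rmsecvPath)                     # delta-method SE of the RMSE
  se[!is.finite(se)] <- 0
  kMin <- which.min(rmsecvPath)
  lv <- min(which(rmsecvPath <= rmsecvPath[kMin] + se[kMin]))

  calib <- regressionMetrics(y, plsPredict(model, X, lv))
  cv <- regressionMetrics(y, cvPred[, lv])
  pred <- c(r2 = NA_real_, rmse = NA_real_)
  if (!is.null(testX)) {
    pred <- regressionMetrics(testY, plsPredict(model, testX, lv))
  }
  structure(list(model = model, lv = lv,
                 r2Cal = calib[["r2"]], rmsec = calib[["rmse"]],
                 r2Cv = cv[["r2"]], rmsecv = cv[["rmse"]],
                 r2Pred = pred[["r2"]], rmsep = pred[["rmse"]],
                 rmsecPath = rmsecPath, rmsecvPath = rmsecvPath,
                 folds = folds, seed = seed),
            class = "PLSReport")
}

#' @export
print.PLSReport <- function(x, ...) {
  cat(sprintf(
    "PLSReport: LV=%d  R2cal=%.3f RMSEC=%.3g  R2cv=%.3f RMSECV=%.3g  R2pred=%.3f RMSEP=%.3g\n",
    x$lv, x$r2Cal, x$rmsec, x$r2Cv, x$rmsecv, x$r2Pred, x$rmsep))
  invisible(x)
}

#' Severity band of an aphid count
#'
#' Low: count < 20; Medium: 20 <= count <= 50; High: count > 50. The
#' boundary counts 20 and 50 belong to Medium, consistent with 50
#' aphids/leaf being the economic-threshold reference. Every non-negative
#' count maps to exactly one band.
#'
#' @param count non-negative numeric vector of aphid counts.
#' @return factor with levels Low, Medium, High.
#' @examples
#' severityBand(c(10, 35, 60))
#' @export
severityBand <- function(count) {
  if (any(count < 0)) stop("counts must be non-negative")
  cut(count, breaks = c(-Inf, 20 - .Machine$double.eps^0.5, 50, Inf),
      labels = c("Low", "Medium", "High"), right = TRUE)
}

#' Compare PLS pre-treatments on a counted spectra table
#'
#' Fits one PLS regression of \code{aphid_count} per pre-treatment (raw,
#' SNV, log(1/R), first and second Savitzky-Golay derivatives), using the
#' same train/test split and CV folds for every treatment, and flags the
#' best model by prediction R-squared.
#'
#' @param table spectra table with an \code{aphid_count} column.
#' @param treatments character vector of pre-treatment names.
#' @param splitFrac training fraction (default 0.75, e.g. 150/50).
#' @param maxLv,folds,seed passed to [fitPls()]; the split is also drawn
#'   from \code{seed}.
#' @return data.frame with one row per treatment
#'   (\code{pretreatment, LV, R2cal, RMSEC, R2cv, RMSECV, R2pred, RMSEP,
#'   best}) and the shared split indices as attribute
#'   \code{"trainIdx"}.
#' @export
comparePretreatments <- function(table,
                                 treatments = c("raw", "snv", "log1r",
                                                "d1", "d2"),
                                 splitFrac = 0.75, maxLv = 50L,
                                 folds = 10L, seed = 1L) {
  if (!"aphid_count" %in% names(table)) stop("table must carry aphid_count")
  X0 <- spectraMatrix(table)
  y <- as.numeric(table$aphid_count)
  n <- nrow(X0)
  trainIdx <- withSeed(seed, sort(sample.int(n, floor(splitFrac * n))))
  testIdx <- setdiff(seq_len(n), trainIdx)

  rows <- lapply(treatments, function(tr) {
    Xt <- applyPretreatment(X0, tr)
    rep <- fitPls(Xt[trainIdx, , drop = FALSE], y[trainIdx],
                  maxLv = maxLv, folds = folds, seed = seed,
                  testX = Xt[testIdx, , drop = FALSE], testY = y[testIdx])
    data.frame(pretreatment = tr, LV = rep$lv,
               R2cal = rep$r2Cal, RMSEC = rep$rmsec,
               R2cv = rep$r2Cv, RMSECV = rep$rmsecv,
               R2pred = rep$r2Pred, RMSEP = rep$rmsep)
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$R2pred)
  attr(out, "trainIdx") <- trainIdx
  out
}
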