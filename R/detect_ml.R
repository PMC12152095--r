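#' Random-forest wavelength ranking and selection
#'
#' Ranks every band by bagged random-forest permutation importance
#' (out-of-bag mean decrease in accuracy), optionally averaged over
#' several forest seeds, rescales importances so the maximum is 1, and
#' selects the wavelengths whose scaled importance exceeds the threshold
#' (default 0.5).
#'
#' @param table labeled spectra table with a \code{label} column and
#'   \code{R_<wavelength>} band columns; at least two classes.
#' @param nTrees trees per forest (default 200, bagging).
#' @param seed integer seed; seed + s - 1 is used for forest s.
#' @param threshold selection cut on the max-normalized importance.
#' @param nSeeds forests to average over.
#' @return list of class "FeatureRanking": \code{importance} (named by
#'   wavelength, max 1), \code{selected} (wavelengths), \code{selectedIdx}
#'   (band indices), \code{threshold}.
#' @export
rfRankFeatures <- function(table, nTrees = 200L, seed = 1L,
                           threshold = 0.5, nSeeds = 1L) {
  X <- spectraMatrix(table)
  y <- factor(table$label)
  if (nlevels(y) < 2L) stop("feature ranking needs at least two classes")
  colnames(X) <- make.names(colnames(X))
  imp <- rowMeans(vapply(seq_len(nSeeds), function(s) {
    fit <- withSeed(seed + s - 1L,
      randomForest::randomForest(X, y, ntree = nTrees, importance = TRUE))
    randomForest::importance(fit, type = 1L)[, 1L]
  }, numeric(ncol(X))))
  imp <- pmax(imp, 0)
  if (max(imp) == 0) stop("all importances are zero; no signal in features")
  imp <- imp / max(imp)
  wl <- tableWavelengths(table)
  names(imp) <- sprintf("%.2f", wl)
  selIdx <- which(imp > threshold)
  structure(list(importance = imp, selected = wl[selIdx],
                 selectedIdx = selIdx, threshold = threshold),
            class = "FeatureRanking")
}

#' PCA dimensionality reduction of a spectra table
#'
#' Centered principal component analysis; the first
#' \code{nComponents} score columns replace the band columns.
#'
#' @param table spectra table.
#' @param nComponents components to keep (default 3).
#' @return list with \code{scores} (table with PC columns and the
#'   original non-band columns), \code{loadings}, \code{explainedVariance}
#'   and \code{center}.
#' @export
pcaReduce <- function(table, nComponents = 3L) {
  X <- spectraMatrix(table)
  if (nrow(X) <= nComponents)
    stop("need more samples than components")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 0)
  if (nComponents > rank)
    stop("nComponents = ", nComponents, " exceeds data rank ", rank)
  keep <- seq_len(nComponents)
  meta <- table[, setdiff(names(table), bandColumns(table)), drop = FALSE]
  scores <- as.data.frame(pc$x[, keep, drop = FALSE])
  names(scores) <- paste0("PC", keep)
  list(scores = cbind(meta, scores),
       loadings = pc$rotation[, keep, drop = FALSE],
       explainedVariance = pc$sdev[keep]^2,
       center = pc$center)
}

# inner grid search for the RBF-SVM (cost x gamma), small k-fold CV
tuneSvmRbf <- function(X, y, seed, folds = 3L) {
  # e1071::svm standardizes features internally, so the natural gamma
  # scale is 1/p (its own default); the grid spans a decade either side
  gammaScale <- 1 / ncol(X)
  grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = gammaScale * c(0.1, 1, 10))
  foldId <- withSeed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      id[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    id
  })
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- foldId != f
      if (nlevels(droplevels(y[tr])) < 2L) next
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g])
      correct <- correct + sum(stats::predict(fit, X[!tr, , drop = FALSE]) ==
                                 y[!tr])
    }
    correct
  }, numeric(1))
  grid[which.max(acc), ]
}

#' Train a two-class infestation classifier
#'
#' Supported kinds: \code{"lda"} (linear discriminant analysis),
#' \code{"svm_rbf"} (support vector machine, radial basis kernel, with a
#' small inner cross-validated grid search over cost and gamma unless
#' both are supplied), \code{"knn"} (k-nearest neighbours, k = 5,
#' Euclidean distance) and \code{"ann"} (single-hidden-layer feedforward
#' network, ReLU-free logistic units via nnet, fixed-seed weights). All
#' models expose a probability-like score for the infested class so AUC
#' can be computed.
#'
#' @param table labeled spectra table (\code{label} column, band columns),
#'   or a plain matrix together with \code{y}.
#' @param kind one of "lda", "svm_rbf", "knn", "ann".
#' @param hyperparams named list of overrides (svm: cost, gamma, tune;
#'   knn: k; ann: size, decay, maxit).
#' @param seed integer seed (weight initialization, probability
#'   calibration, inner tuning folds).
#' @param y class factor when \code{table} is a matrix.
#' @return object of class "aphidClassifier".
#' @export
trainClassifier <- function(table, kind = c("lda", "svm_rbf", "knn", "ann"),
                            hyperparams = list(), seed = 1L, y = NULL) {
  kind <- match.arg(kind)
  if (is.data.frame(table)) {
    X <- spectraMatrix(table)
    y <- factor(table$label)
  } else {
    X <- as.matrix(table)
    if (is.null(y)) stop("y must be supplied with a matrix input")
    y <- factor(y)
  }
  if (nlevels(y) != 2L) stop("classifier requires exactly two classes")
  if (any(!is.finite(X))) stop("features must be finite")
  positive <- levels(y)[2L]

  fit <- switch(kind,
    # hyperspectral bands are collinear by nature; MASS::lda still yields
    # a usable discriminant, so its collinearity warning is muffled
    lda = withCallingHandlers(MASS::lda(X, grouping = y),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    svm_rbf = {
      hp <- hyperparams
      if (is.null(hp$cost) || is.null(hp$gamma)) {
        if (!isFALSE(hp$tune)) {
          best <- tuneSvmRbf(X, y, seed)
          hp$cost <- best$cost; hp$gamma <- best$gamma
        } else {
          hp$cost <- 10
          hp$gamma <- 1 / ncol(X)
        }
      }
      withSeed(seed, e1071::svm(X, y, kernel = "radial", cost = hp$cost,
                                gamma = hp$gamma, probability = TRUE))
    },
    knn = list(k = if (is.null(hyperparams$k)) 5L else hyperparams$k,
               X = X, y = y),
    ann = {
      size <- if (is.null(hyperparams$size)) 32L else hyperparams$size
      decay <- if (is.null(hyperparams$decay)) 1e-3 else hyperparams$decay
      maxit <- if (is.null(hyperparams$maxit)) 200L else hyperparams$maxit
      withSeed(seed, nnet::nnet(X, class.ind2(y), size = size, decay = decay,
                                maxit = maxit, softmax = TRUE, trace = FALSE,
                                MaxNWts = 50000L))
    }
  )
  structure(list(kind = kind, fit = fit, levels = levels(y),
                 positive = positive, nFeatures = ncol(X), seed = seed),
            class = "aphidClassifier")
}

# two-column class indicator matrix for nnet's softmax interface
class.ind2 <- function(y) {
  M <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  M[cbind(seq_along(y), as.integer(y))] <- 1
  M
}

#' Predict classes and infested-class scores
#'
#' @param model an "aphidClassifier".
#' @param newX feature matrix (or spectra table).
#' @return list with \code{class} (factor) and \code{score} (numeric
#'   probability-like score of the positive class).
#' @export
predictClassifier <- function(model, newX) {
  if (is.data.frame(newX)) newX <- spectraMatrix(newX)
  newX <- as.matrix(newX)
  if (ncol(newX) != model$nFeatures)
    stop("feature count mismatch: model expects ", model$nFeatures)
  pos <- model$positive
  out <- switch(model$kind,
    lda = {
      p <- stats::predict(model$fit, newX)
      list(class = p$class, score = p$posterior[, pos])
    },
    svm_rbf = {
      p <- stats::predict(model$fit, newX, probability = TRUE)
      list(class = p, score = attr(p, "probabilities")[, pos])
    },
    knn = {
      p <- class::knn(model$fit$X, newX, model$fit$y, k = model$fit$k,
                      prob = TRUE)
      winnerProb <- attr(p, "prob")
      score <- ifelse(p == pos, winnerProb, 1 - winnerProb)
      list(class = p, score = score)
    },
    ann = {
      pr <- stats::predict(model$fit, newX)
      cls <- factor(model$levels[max.col(pr)], levels = model$levels)
      list(class = cls, score = pr[, pos])
    }
  )
  out$class <- factor(out$class, levels = model$levels)
  out
}

#' Binary classification metrics
#'
#' Precision, recall, F1 (positive class), per-class recalls
#' (classA/classB, the first/second factor level) and overall accuracy
#' from predicted and true labels.
#'
#' @param truth,pred factors on the same two levels.
#' @param positive positive-class label (default second level).
#' @return named numeric vector.
#' @export
classificationMetrics <- function(truth, pred,
                                  positive = levels(factor(truth))[2L]) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  lev <- levels(truth)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall /
          (precision + recall) else NA_real_
  recalls <- vapply(lev, function(cl) {
    n <- sum(truth == cl)
    if (n) sum(pred == cl & truth == cl) / n else NA_real_
  }, numeric(1))
  c(accuracy = mean(pred == truth), precision = precision, recall = recall,
    f1 = f1, classA = recalls[[1L]], classB = recalls[[2L]],
    balancedAccuracy = mean(recalls, na.rm = TRUE))
}

aucScore <- function(truth, score, positive) {
  truth <- factor(truth)
  neg <- setdiff(levels(truth), positive)
  if (!sum(truth == positive) || !sum(truth == neg)) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                 levels = c(neg, positive),
                                 direction = "<", quiet = TRUE)))
}

stratifiedFolds <- function(y, folds, seed) {
  id <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      i <- which(y == cl)
      id[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  id
}

#' Detection evaluation protocol
#'
#' The full evaluation scheme for a classifier kind: a stratified 60/40
#' train/test split (per-class floor rounding, so 336 balanced samples
#' give 200 training and 136 test spectra), repeated stratified k-fold
#' cross-validation on the training portion (fold metrics averaged over
#' \code{iterations} random re-partitions), and final metrics on the
#' held-out test set. Per-class accuracies are class-conditional recalls
#' (class A = first level, healthy; class B = second level, infested);
#' AUC, F1 and precision take the infested class as positive. For the
#' RBF-SVM, hyperparameters are chosen once by inner grid search on the
#' training portion and then held fixed across folds.
#'
#' @param table labeled spectra table.
#' @param kind classifier kind, see [trainClassifier()].
#' @param hyperparams hyperparameter overrides.
#' @param splitFrac training fraction (default 0.6).
#' @param folds CV folds (default 10).
#' @param iterations CV repetitions (default 50).
#' @param seed master seed; split, folds and model seeds derive from it.
#' @return list of class "ClassifierReport".
#' @export
evaluateProtocol <- function(table, kind = "svm_rbf", hyperparams = list(),
                             splitFrac = 0.6, folds = 10L, iterations = 50L,
                             seed = 1L) {
  X <- spectraMatrix(table)
  y <- factor(table$label)
  if (nlevels(y) != 2L) stop("protocol requires two classes")

  trainIdx <- withSeed(seed, {
    unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      sample(i, floor(splitFrac * length(i)))
    }))
  })
  testIdx <- setdiff(seq_along(y), trainIdx)
  yTr <- droplevels(y[trainIdx]); yTe <- y[testIdx]
  if (min(table(yTr)) < folds)
    stop("fold count ", folds, " exceeds minority-class size ",
         min(table(yTr)))
  XTr <- X[trainIdx, , drop = FALSE]; XTe <- X[testIdx, , drop = FALSE]

  hp <- hyperparams
  if (kind == "svm_rbf" && (is.null(hp$cost) || is.null(hp$gamma)) &&
      !isFALSE(hp$tune)) {
    best <- tuneSvmRbf(XTr, yTr, seed)
    hp$cost <- best$cost; hp$gamma <- best$gamma
  }

  cv <- matrix(NA_real_, iterations * folds, 5L,
               dimnames = list(NULL, c("classA", "classB", "auc", "f1",
                                       "precision")))
  row <- 0L
  for (it in seq_len(iterations)) {
    foldId <- stratifiedFolds(yTr, folds, seed + 1000L * it)
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- foldId != f
      model <- trainClassifier(XTr[tr, , drop = FALSE], kind, hp,
                               seed = seed + row, y = yTr[tr])
      p <- predictClassifier(model, XTr[!tr, , drop = FALSE])
      m <- classificationMetrics(yTr[!tr], p$class)
      cv[row, ] <- c(m[["classA"]], m[["classB"]],
                     aucScore(yTr[!tr], p$score, model$positive),
                     m[["f1"]], m[["precision"]])
    }
  }
  cvMeans <- colMeans(cv, na.rm = TRUE)

  finalModel <- trainClassifier(XTr, kind, hp, seed = seed, y = yTr)
  pTest <- predictClassifier(finalModel, XTe)
  mTest <- classificationMetrics(yTe, pTest$class)
  structure(list(
    kind = kind,
    cv = list(classA = cvMeans[["classA"]], classB = cvMeans[["classB"]],
              auc = cvMeans[["auc"]], f1 = cvMeans[["f1"]],
              precision = cvMeans[["precision"]]),
    test = list(classA = mTest[["classA"]], classB = mTest[["classB"]],
                auc = aucScore(yTe, pTest$score, finalModel$positive),
                f1 = mTest[["f1"]], precision = mTest[["precision"]],
                accuracy = mTest[["accuracy"]],
                balancedAccuracy = mTest[["balancedAccuracy"]]),
    folds = folds, iterations = iterations, seed = seed,
    nTrain = length(trainIdx), nTest = length(testIdx),
    hyperparams = hp, model = finalModel,
    trainIdx = sort(trainIdx)),
    class = "ClassifierReport")
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf("ClassifierReport (%s): %d train / %d test, %d-fold CV x %d\n",
              x$kind, x$nTrain, x$nTest, x$folds, x$iterations))
  cat(sprintf("  CV   A=%.3f B=%.3f AUC=%.3f F1=%.3f Prec=%.3f\n",
              x$cv$classA, x$cv$classB, x$cv$auc, x$cv$f1, x$cv$precision))
  cat(sprintf("  Test A=%.3f B=%.3f AUC=%.3f F1=%.3f Prec=%.3f\n",
              x$test$classA, x$test$classB, x$test$auc, x$test$f1,
              x$test$precision))
  invisible(x)
}

#' Pixel-wise infestation map from a trained classifier
#'
#' Applies the training pre-treatment chain to every plant-pixel
#' spectrum, restricts to the selected bands, and predicts a class per
#' pixel.
#'
#' @param cube a [Hypercube-class].
#' @param mask logical plant mask.
#' @param model an "aphidClassifier".
#' @param pretreatment pre-treatment name(s) applied in order
#'   (see [applyPretreatment]): "raw", "snv", "log1r", "d1", "d2".
#' @param selectedIdx band indices kept after pre-treatment (NULL = all);
#'   must resolve on the cube grid and match the model's feature count.
#' @return class-map matrix: NA off plant, TRUE where predicted infested.
#' @export
predictPixelMap <- function(cube, mask, model, pretreatment = "snv",
                            selectedIdx = NULL) {
  m <- asLogicalMask(mask)
  idx <- which(m)
  if (!length(idx)) stop("mask is empty")
  X <- pixelMatrix(cube)[idx, , drop = FALSE]
  for (tr in pretreatment) if (tr != "raw") X <- applyPretreatment(X, tr)
  if (!is.null(selectedIdx)) {
    if (max(selectedIdx) > ncol(X))
      stop("selected band indices do not resolve on this cube grid")
    X <- X[, selectedIdx, drop = FALSE]
  }
  if (ncol(X) != model$nFeatures)
    stop("prepared features (", ncol(X), ") do not match model (",
         model$nFeatures, ")")
  p <- predictClassifier(model, X)
  d <- dim(cubeValues(cube))
  out <- matrix(NA, d[1], d[2])
  out[idx] <- p$class == model$positive
  out
}

#' Write a class map as a green/yellow PNG
#'
#' Healthy plant pixels are green, infested yellow, background black.
#'
#' @param classMap matrix from [predictPixelMap()].
#' @param path PNG path.
#' @return invisibly the path.
#' @export
writeClassMapPNG <- function(classMap, path) {
  h <- nrow(classMap); w <- ncol(classMap)
  img <- array(0, dim = c(h, w, 3L))
  plant <- !is.na(classMap)
  img[, , 1L][plant & classMap] <- 1          # yellow = infested
  img[, , 2L][plant] <- 1
  png::writePNG(img, path)
  invisible(path)
}
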