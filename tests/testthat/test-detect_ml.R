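test_that("classification metrics agree with a hand confusion matrix", {
  # TP=8, FP=2, FN=1, TN=9 with "infested" positive
  truth <- c(rep("infested", 9), rep("healthy", 11))
  pred <- c(rep("infested", 8), "healthy",            # 8 TP, 1 FN
            rep("infested", 2), rep("healthy", 9))    # 2 FP, 9 TN
  m <- classificationMetrics(truth, pred, positive = "infested")
  expect_equal(unname(m["precision"]), 0.8)
  expect_equal(unname(m["recall"]), 8 / 9)
  expect_equal(unname(m["f1"]), 0.842, tolerance = 1e-3)
  expect_equal(unname(m["classB"]), 8 / 9)   # infested recall
  expect_equal(unname(m["classA"]), 9 / 11)  # healthy recall
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
})

test_that("AUC is 1 for a perfect ranker and 0.5 for a constant scorer", {
  truth <- rep(c("healthy", "infested"), each = 10)
  perfect <- c(stats::runif(10, 0, 0.4), stats::runif(10, 0.6, 1))
  expect_equal(aphidSID:::aucScore(truth, perfect, "infested"), 1)
  expect_equal(aphidSID:::aucScore(truth, rep(0.5, 20), "infested"), 0.5)
})

test_that("random-forest ranking recovers a planted informative band set", {
  wl <- defaultGrid()
  win <- resolveWindow(wl, 710, 825)
  planted <- seq(win$loIdx, win$hiIdx, by = 2L)
  tab <- plantedSignalTable(informativeIdx = planted, seed = 21)
  rk <- rfRankFeatures(tab, seed = 21, nSeeds = 2L)
  expect_gte(mean(planted %in% rk$selectedIdx), 0.9)
  expect_true(all(rk$selected >= 700 & rk$selected <= 825))
  expect_equal(max(rk$importance), 1)
})

test_that("pure-noise features yield an almost-empty selection", {
  set.seed(31)
  wl <- defaultGrid()
  X <- matrix(stats::rnorm(100 * 224), 100, 224)
  tab <- cbind(data.frame(label = rep(c("healthy", "infested"), each = 50)),
               stats::setNames(as.data.frame(X), sprintf("R_%.2f", wl)))
  rk <- rfRankFeatures(tab, seed = 1, nSeeds = 3L)
  expect_lte(length(rk$selectedIdx), 0.15 * 224)
  # a threshold above the max importance selects nothing
  rkEmpty <- rfRankFeatures(tab, seed = 1, threshold = 1 + 1e-9)
  expect_identical(length(rkEmpty$selectedIdx), 0L)
  expect_error(rfRankFeatures(tab[tab$label == "healthy", ]), "two classes")
})

test_that("PCA reduction orders components and reconstructs low-rank data", {
  set.seed(7)
  B <- matrix(stats::rnorm(3 * 20), 3, 20)
  S <- matrix(stats::rnorm(30 * 3), 30, 3)
  X <- S %*% B                                  # exactly rank 3
  tab <- cbind(data.frame(label = "x"),
               stats::setNames(as.data.frame(X), sprintf("R_%d", 1:20)))
  red <- pcaReduce(tab, 3L)
  expect_true(all(diff(red$explainedVariance) <= 1e-12))
  recon <- as.matrix(red$scores[, c("PC1", "PC2", "PC3")]) %*%
    t(red$loadings)
  expect_lt(max(abs(sweep(X, 2L, red$center) - recon)), 1e-9)
  # third component of planar data carries no variance
  planar <- X[, 1:2] %*% matrix(stats::rnorm(2 * 6), 2, 6)
  tabP <- cbind(data.frame(label = "x"),
                stats::setNames(as.data.frame(planar), sprintf("R_%d", 1:6)))
  expect_lt(pcaReduce(tabP, 3L)$explainedVariance[3], 1e-18)
  expect_error(pcaReduce(tab, 40L), "more samples|rank")
})

test_that("all four classifier kinds fit separable data perfectly", {
  set.seed(8)
  X <- rbind(matrix(stats::rnorm(60, 0), 30),
             matrix(stats::rnorm(60, 6), 30))
  y <- rep(c("healthy", "infested"), each = 30)
  for (kind in c("lda", "svm_rbf", "knn", "ann")) {
    model <- trainClassifier(X, kind, seed = 2, y = y)
    p <- predictClassifier(model, X)
    expect_identical(as.character(p$class), y)
    expect_true(all(p$score >= 0 & p$score <= 1))
  }
  expect_error(trainClassifier(X, "forest", y = y), "arg")
})

test_that("the RBF kernel solves XOR data where LDA cannot", {
  set.seed(9)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(stats::rnorm(40, 0, 0.3), 20), 2L, -centers[k, ])))
  y <- rep(c("healthy", "healthy", "infested", "infested"), each = 20)
  svmAcc <- mean(as.character(predictClassifier(
    trainClassifier(X, "svm_rbf", seed = 1, y = y), X)$class) == y)
  ldaAcc <- mean(as.character(predictClassifier(
    trainClassifier(X, "lda", seed = 1, y = y), X)$class) == y)
  expect_identical(svmAcc, 1)
  expect_lt(ldaAcc, 1)
})

test_that("ANN training is reproducible under a fixed seed", {
  set.seed(10)
  X <- matrix(stats::rnorm(200), 50)
  y <- rep(c("healthy", "infested"), 25)
  m1 <- trainClassifier(X, "ann", seed = 33, y = y)
  m2 <- trainClassifier(X, "ann", seed = 33, y = y)
  expect_identical(m1$fit$wts, m2$fit$wts)
  expect_identical(predictClassifier(m1, X)$score,
                   predictClassifier(m2, X)$score)
})

test_that("the evaluation protocol reproduces the 200/136 split on 336
           balanced samples and is deterministic", {
  tab <- makeLabeledDataset(168L, sceneConfig(), seed = 13)
  r1 <- evaluateProtocol(tab, "lda", folds = 10L, iterations = 2L, seed = 5)
  expect_identical(r1$nTrain, 200L)
  expect_identical(r1$nTest, 136L)
  r2 <- evaluateProtocol(tab, "lda", folds = 10L, iterations = 2L, seed = 5)
  expect_identical(r1$cv, r2$cv)
  expect_identical(r1$test, r2$test)
  expect_identical(r1$trainIdx, r2$trainIdx)
  # stratified split preserves the class ratio exactly here
  expect_identical(as.integer(table(tab$label[r1$trainIdx])), c(100L, 100L))
  expect_error(evaluateProtocol(tab[c(1:6, 169:174), ], "lda", folds = 10L),
               "minority")
})

test_that("perfectly separable data drive every protocol metric to 1", {
  set.seed(14)
  X <- rbind(matrix(stats::rnorm(40 * 5, 0), 40),
             matrix(stats::rnorm(40 * 5, 8), 40))
  tab <- cbind(data.frame(sample_id = sprintf("s%02d", 1:80),
                          label = rep(c("healthy", "infested"), each = 40)),
               stats::setNames(as.data.frame(X), sprintf("R_%d", 1:5)))
  r <- evaluateProtocol(tab, "lda", folds = 5L, iterations = 2L, seed = 3)
  expect_equal(r$cv$classA, 1)
  expect_equal(r$cv$classB, 1)
  expect_equal(r$test$auc, 1)
  expect_equal(r$test$f1, 1)
})

test_that("label permutation collapses AUC to chance", {
  tab <- makeLabeledDataset(60L, sceneConfig(), seed = 17)
  set.seed(18)
  tab$label <- sample(tab$label)
  r <- evaluateProtocol(snvTable(tab), "svm_rbf", folds = 5L,
                        iterations = 3L, seed = 19)
  # small n: a fixed permutation can carry spurious signal, so the band
  # around chance is wider than in the full-campaign check
  expect_gte(r$cv$auc, 0.35)
  expect_lte(r$cv$auc, 0.65)
})

test_that("pixel maps localize infestation and stay clean on healthy leaves", {
  cfg <- noiselessConfig()
  trScene <- makeScene(cfg, seed = 23)
  X <- matrix(cubeValues(trScene$cube), ncol = dim(trScene$cube)[3])
  hIdx <- which(leafMask(trScene$truth) & !infestedMask(trScene$truth))
  iIdx <- which(infestedMask(trScene$truth))
  Xtr <- aphidSID:::snvRows(rbind(X[hIdx, ], X[iIdx, ]))
  y <- rep(c("healthy", "infested"), c(length(hIdx), length(iIdx)))
  model <- trainClassifier(Xtr, "svm_rbf", seed = 1, y = y)

  teScene <- makeScene(cfg, seed = 24)
  cm <- predictPixelMap(teScene$cube, leafMask(teScene$truth), model,
                        pretreatment = "snv")
  expect_identical(dim(cm), dim(leafMask(teScene$truth)))
  pred <- !is.na(cm) & cm
  expect_gte(maskIoU(pred, infestedMask(teScene$truth)), 0.8)

  hCfg <- noiselessConfig(aphidCount = 0L)
  hScene <- makeScene(hCfg, seed = 25)
  cmh <- predictPixelMap(hScene$cube, leafMask(hScene$truth), model,
                         pretreatment = "snv")
  expect_lte(mean(cmh[!is.na(cmh)]), 0.05)
  expect_error(predictPixelMap(teScene$cube, leafMask(teScene$truth), model,
                               pretreatment = "snv", selectedIdx = 1:5),
               "match")
})
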