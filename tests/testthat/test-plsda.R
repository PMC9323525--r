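test_that("classEncoding builds the fixed-order dummy matrix", {
  enc <- classEncoding(c("processed", "direct", "direct"))
  expect_identical(enc$classes, c("direct", "processed"))
  expect_identical(unname(enc$Y),
    cbind(c(0, 1, 1), c(1, 0, 0)))
  expect_identical(colnames(enc$Y), c("direct", "processed"))
  expect_error(classEncoding(c("direct", "juice")), "outside")
  expect_error(classEncoding(rep("direct", 4)), "both classes")
})

test_that("sum of squared VIP scores equals the variable count", {
  sep <- separableMatrix(seed = 31)
  for (a in 1:3) {
    m <- fitPLSDA(sep$X, sep$labels, nLV = a)
    expect_equal(sum(vip(m)^2), ncol(sep$X), tolerance = 1e-8)
  }
  v <- vip(fitPLSDA(sep$X, sep$labels, 2))
  expect_identical(attr(v, "important"), unclass(v) >= 1)
  # the two informative variables carry the importance
  expect_true(all(which(attr(v, "important"))[1:2] %in% 1:2))
})

test_that("one-variable, one-LV PLS-DA reduces to a midpoint threshold", {
  # with a single predictor the argmax-dummy rule is a cut at the point where
  # the two predicted dummies cross; verify against explicit enumeration
  x <- matrix(c(1, 2, 3, 10, 11, 12, 13), ncol = 1)
  labels <- rep(c("direct", "processed"), c(3, 4))
  m <- fitPLSDA(x, labels, 1)
  grid <- matrix(seq(0, 14, by = 0.25), ncol = 1)
  pred <- predictPLSDA(m, grid)$class
  # prediction is a step function of x: direct below the cut, processed above
  expect_true(all(diff(pred == "processed") >= 0))
  cut <- max(grid[pred == "direct"])
  # the crossing point solved from yhat1 = yhat2 in closed form
  beta <- m@coefficients[1, ]
  cutExact <- m@xCenter + (m@yCenter[2] - m@yCenter[1]) / (beta[1] - beta[2])
  expect_lt(abs(cut - cutExact), 0.25 + 1e-9)
  expect_identical(predictPLSDA(m, x)$class, labels)
})

test_that("separable data give zero calibration and CV error", {
  sep <- separableMatrix(seed = 32)
  enc <- classEncoding(sep$labels)
  cv <- crossValidatePLSDA(sep$X, enc, maxLV = 5)
  expect_identical(cv$cvTable$misclassified[cv$nLV], 0L)
  m <- fitPLSDA(sep$X, enc, cv$nLV)
  expect_identical(predictPLSDA(m, sep$X)$class, sep$labels)
  cm <- confusionMatrix(truth = sep$labels,
    predicted = predictPLSDA(m, sep$X)$class)
  expect_equal(misclassificationError(cm), 0)
})

test_that("CV picks by parsimony: smallest LV within one error of the minimum", {
  sep <- separableMatrix(seed = 33)
  cv <- crossValidatePLSDA(sep$X, sep$labels, maxLV = 4)
  e <- cv$cvTable$misclassified
  expect_identical(cv$nLV, which(e <= min(e) + 1L)[1L])
})

test_that("permuted labels give chance-level error", {
  sep <- separableMatrix(n1 = 10, n2 = 10, seed = 34)
  set.seed(35)
  rates <- vapply(1:10, function(r) {
    lab <- sample(sep$labels)
    cv <- crossValidatePLSDA(sep$X, lab, maxLV = 3)
    cv$cvTable$errorRate[cv$nLV]
  }, 0)
  expect_gt(mean(rates), 0.3)
  expect_lt(mean(rates), 0.7)
})

test_that("predictions agree with mixOmics on separable data", {
  sep <- separableMatrix(n1 = 9, n2 = 9, seed = 36)
  colnames(sep$X) <- paste0("v", seq_len(ncol(sep$X)))
  m <- fitPLSDA(sep$X, sep$labels, 2)
  ref <- mixOmics::plsda(sep$X, factor(sep$labels), ncomp = 2)
  refPred <- predict(ref, sep$X)$class$max.dist[, 2]
  expect_identical(predictPLSDA(m, sep$X)$class, unname(as.character(refPred)))
})

test_that("full-rank single-response PLS matches OLS at maximal LVs", {
  set.seed(37)
  X <- matrix(rnorm(30 * 4), 30)
  labels <- rep(c("direct", "processed"), 15)
  m <- fitPLSDA(X, labels, 4)
  Y <- classEncoding(labels)$Y
  ols <- lm.fit(cbind(1, X), Y)$coefficients[-1, ]
  expect_equal(m@coefficients, ols, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("venetian blinds re-stratify when a fold loses a class", {
  sep <- separableMatrix(n1 = 3, n2 = 3, seed = 38)
  # classes alternate, so with 2 blinds one blind holds all of one class and
  # its complement (the training set) holds only the other
  alt <- c(1, 4, 2, 5, 3, 6) # direct, processed, direct, processed, ...
  lab <- sep$labels[alt]
  expect_warning(
    cv1 <- crossValidatePLSDA(sep$X[alt, ], lab, maxLV = 2,
      scheme = "venetian_k", k = 2L),
    "re-stratifying"
  )
  expect_s3_class(cv1$cvTable, "data.frame")
  # grouped labels hit each blind with both classes: no warning
  expect_silent(
    crossValidatePLSDA(sep$X, sep$labels, maxLV = 2,
      scheme = "venetian_k", k = 2L)
  )
})

test_that("vipEEMMap refolds importance emission-fastest", {
  em <- c(300, 310, 320)
  ex <- c(250, 260)
  v <- 1:6
  mp <- vipEEMMap(v, em, ex)
  expect_identical(dim(mp), c(3L, 2L))
  expect_equal(unname(mp[, 1]), c(1, 2, 3))
  expect_equal(unname(mp[, 2]), c(4, 5, 6))
})

test_that("metric worked examples evaluate exactly", {
  # 1 error in 35 -> 0.029; 3 in 35 -> 0.086 at three decimals
  cmA <- confusionMatrix(TP = 14, TN = 20, FP = 0, FN = 1)
  expect_identical(round(misclassificationError(cmA), 3), 0.029)
  cmB <- confusionMatrix(TP = 14, TN = 18, FP = 2, FN = 1)
  expect_identical(round(misclassificationError(cmB), 3), 0.086)
  # sensitivity 14/(14+1) = 0.93, specificity 17/(17+3) = 0.85
  cmC <- confusionMatrix(TP = 14, TN = 17, FP = 3, FN = 1)
  expect_identical(round(sensitivity(cmC), 2), 0.93)
  expect_identical(round(specificity(cmC), 2), 0.85)
})

test_that("metrics equal brute-force label counting on random assignments", {
  set.seed(39)
  for (r in 1:5) {
    truth <- sample(c("direct", "processed"), 30, replace = TRUE,
      prob = c(0.45, 0.55))
    if (length(unique(truth)) < 2) next
    pred <- sample(c("direct", "processed"), 30, replace = TRUE)
    cm <- confusionMatrix(truth = truth, predicted = pred)
    expect_equal(misclassificationError(cm), mean(truth != pred))
    expect_equal(sensitivity(cm),
      mean(pred[truth == "direct"] == "direct"))
    expect_equal(specificity(cm),
      mean(pred[truth == "processed"] == "processed"))
  }
  expect_error(sensitivity(confusionMatrix(TP = 0, TN = 5, FP = 2, FN = 0)),
    "undefined")
  expect_error(specificity(confusionMatrix(TP = 5, TN = 0, FP = 0, FN = 1)),
    "undefined")
})
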