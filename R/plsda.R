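#' Two-class dummy encoding
#'
#' Builds the sample x 2 matrix of 0/1 class membership dummies. Column order
#' is fixed by \code{classes}; with the default labels the first column
#' ("class 1") is \code{direct}.
#'
#' @param labels factor/character vector of per-sample class labels.
#' @param classes ordered pair of class labels defining the column order.
#' @return list with \code{Y} (n x 2 matrix) and \code{classes}.
#' @export
classEncoding <- function(labels, classes = c("direct", "processed")) {
  labels <- as.character(labels)
  if (!all(labels %in% classes)) {
    stop("labels contain classes outside: ", paste(classes, collapse = ", "))
  }
  if (length(unique(labels)) != 2L) stop("both classes must be present")
  Y <- cbind(as.numeric(labels == classes[1L]), as.numeric(labels == classes[2L]))
  colnames(Y) <- classes
  list(Y = Y, classes = classes, labels = labels)
}

#' Fit a two-class PLS-DA model
#'
#' NIPALS PLS2 regression of the centered class-membership dummies on the
#' mean-centered spectra. Class prediction is the argmax over the two
#' predicted dummy columns. VIP scores are computed from the retained latent
#' variables.
#'
#' @param Xmat samples x variables matrix.
#' @param encoding a \code{\link{classEncoding}} (or a label vector, encoded
#'   with default class order).
#' @param nLV number of latent variables.
#' @return A \linkS4class{PLSDAModel}.
#' @export
fitPLSDA <- function(Xmat, encoding, nLV) {
  if (!is.list(encoding)) encoding <- classEncoding(encoding)
  Xmat <- as.matrix(Xmat)
  n <- nrow(Xmat)
  p <- ncol(Xmat)
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(n - 1L, p)) {
    stop(sprintf("nLV must be in [1, %d]", min(n - 1L, p)))
  }
  if (nrow(encoding$Y) != n) stop("encoding does not match the sample count")
  xc <- colMeans(Xmat)
  Xc <- sweep(Xmat, 2L, xc)
  if (all(apply(Xc, 2L, function(v) all(abs(v) < 1e-12)))) {
    stop("X is constant: no spectral variation to model")
  }
  yc <- colMeans(encoding$Y)
  Yc <- sweep(encoding$Y, 2L, yc)

  Wm <- matrix(0, p, nLV)
  Pm <- matrix(0, p, nLV)
  Qm <- matrix(0, 2L, nLV)
  Tm <- matrix(0, n, nLV)
  ssy <- numeric(nLV)
  Xr <- Xc
  Yr <- Yc
  ssyTot <- sum(Yc^2)
  attained <- 0L
  for (a in seq_len(nLV)) {
    # stop early once X or Y is exhausted (exactly separable / rank-deficient)
    if (max(colSums(Yr^2)) < 1e-12 * max(ssyTot, 1e-300) ||
      sum(Xr^2) < 1e-24 * max(sum(Xc^2), 1e-300)) break
    u <- Yr[, which.max(colSums(Yr^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(500L)) {
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      tv <- Xr %*% w
      q <- crossprod(Yr, tv) / sum(tv^2)
      u <- Yr %*% q / sum(q^2)
      if (sqrt(sum((tv - t_old)^2)) < 1e-12 * sqrt(sum(tv^2))) break
      t_old <- tv
    }
    if (nw < 1e-300) break
    pv <- crossprod(Xr, tv) / sum(tv^2)
    Wm[, a] <- w
    Pm[, a] <- pv
    Qm[, a] <- q
    Tm[, a] <- tv
    ssy[a] <- sum(tv^2) * sum(q^2)
    attained <- a
    Xr <- Xr - tcrossprod(tv, pv)
    Yr <- Yr - tcrossprod(tv, q)
  }
  if (attained < 1L) stop("could not extract a latent variable: degenerate X/Y")
  if (attained < nLV) {
    nLV <- attained
    Wm <- Wm[, seq_len(nLV), drop = FALSE]
    Pm <- Pm[, seq_len(nLV), drop = FALSE]
    Qm <- Qm[, seq_len(nLV), drop = FALSE]
    Tm <- Tm[, seq_len(nLV), drop = FALSE]
    ssy <- ssy[seq_len(nLV)]
  }
  # regression coefficients on the original (centered) X
  Bcoef <- Wm %*% solve(crossprod(Pm, Wm), t(Qm))

  if (sum(ssy) <= 0) stop("zero explained Y variance: VIP undefined")
  # VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a ), ||w_a|| = 1
  vip <- sqrt(p * as.numeric(Wm^2 %*% ssy) / sum(ssy))

  new("PLSDAModel",
    nLV = nLV, weights = Wm, xLoadings = Pm, yLoadings = Qm,
    coefficients = Bcoef, xCenter = xc, yCenter = yc,
    classes = encoding$classes, vip = vip, ssyPerLV = ssy,
    cvTable = data.frame()
  )
}

#' Predict from a PLS-DA model
#'
#' @param model a \linkS4class{PLSDAModel}.
#' @param Xnew samples x variables matrix on the same variable set.
#' @return list with \code{yhat} (predicted dummy matrix) and \code{class}
#'   (argmax label per sample).
#' @export
predictPLSDA <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  Yhat <- sweep(Xnew, 2L, model@xCenter) %*% model@coefficients
  Yhat <- sweep(Yhat, 2L, model@yCenter, `+`)
  cls <- model@classes[max.col(Yhat, ties.method = "first")]
  list(yhat = Yhat, class = cls)
}

#' Cross-validate a PLS-DA model over latent-variable counts
#'
#' Leave-one-out (default) or venetian-blinds cross-validation; reports the
#' misclassification error per candidate LV count and chooses, by parsimony,
#' the smallest count whose error is within one misclassified sample of the
#' minimum.
#'
#' @param Xmat samples x variables matrix.
#' @param encoding a \code{\link{classEncoding}} or label vector.
#' @param maxLV largest LV count to evaluate.
#' @param scheme \code{"leave_one_out"} or \code{"venetian_k"}.
#' @param k number of venetian blinds when \code{scheme = "venetian_k"}.
#' @return list with \code{cvTable} (data.frame LV / errors / error rate) and
#'   \code{nLV} (chosen count).
#' @export
crossValidatePLSDA <- function(Xmat, encoding, maxLV,
                               scheme = c("leave_one_out", "venetian_k"), k = 5L) {
  scheme <- match.arg(scheme)
  if (!is.list(encoding)) encoding <- classEncoding(encoding)
  Xmat <- as.matrix(Xmat)
  n <- nrow(Xmat)
  maxLV <- min(maxLV, n - 2L, ncol(Xmat))
  if (maxLV < 1L) stop("maxLV must be >= 1")
  folds <- if (scheme == "leave_one_out") {
    as.list(seq_len(n))
  } else {
    out <- split(seq_len(n), rep_len(seq_len(k), n))
    noBoth <- vapply(out, function(f) {
      length(unique(encoding$labels[-f])) < 2L
    }, TRUE)
    if (any(noBoth)) {
      warning("a venetian fold left a one-class training set; re-stratifying by class",
        call. = FALSE)
      ord <- order(encoding$labels)
      out <- split(ord, rep_len(seq_len(k), n))
    }
    out
  }
  errors <- integer(maxLV)
  for (f in folds) {
    enc_tr <- classEncoding(encoding$labels[-f], encoding$classes)
    for (a in seq_len(maxLV)) {
      m <- fitPLSDA(Xmat[-f, , drop = FALSE], enc_tr, a)
      pred <- predictPLSDA(m, Xmat[f, , drop = FALSE])$class
      errors[a] <- errors[a] + sum(pred != encoding$labels[f])
    }
  }
  cvTable <- data.frame(
    nLV = seq_len(maxLV), misclassified = errors, errorRate = errors / n
  )
  # parsimony: smallest LV within one misclassified sample of the minimum
  nLV <- which(errors <= min(errors) + 1L)[1L]
  list(cvTable = cvTable, nLV = nLV)
}

#' VIP scores of a fitted PLS-DA model
#'
#' Variable importance in projection, normalised so the mean squared VIP over
#' variables is exactly 1. Variables with VIP at or above 1 are conventionally
#' flagged as important.
#'
#' @param model a \linkS4class{PLSDAModel}.
#' @return numeric vector of per-variable VIP scores with an
#'   \code{important} (VIP >= 1) logical attribute.
#' @export
vip <- function(model) {
  v <- model@vip
  attr(v, "important") <- v >= 1
  v
}

#' Refold a VIP vector into an emission x excitation importance map
#'
#' @param vipVector VIP scores of an unfolded-EEM model, length |em| * |ex|.
#' @param em,ex the wavelength grids.
#' @return |em| x |ex| matrix (see \code{\link{refoldVector}}).
#' @export
vipEEMMap <- function(vipVector, em, ex) {
  refoldVector(as.numeric(vipVector), em, ex)
}
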