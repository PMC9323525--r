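#' Principal component analysis of a spectral matrix
#'
#' Mean-centering (default) or autoscaling followed by singular value
#' decomposition. Scores are the preprocessed data projected onto the
#' loadings; explained variances are the squared singular values as a percent
#' of the total preprocessed sum of squares. The solution is deterministic up
#' to sign, resolved by making each loading's largest-magnitude element
#' positive.
#'
#' @param Xmat samples x variables numeric matrix, no missing values.
#' @param nComponents number of components to keep (default: all).
#' @param preprocessing \code{"mean_center"} or \code{"autoscale"}.
#' @return A \linkS4class{PCAModel}.
#' @export
fitPCA <- function(Xmat, nComponents = NULL,
                   preprocessing = c("mean_center", "autoscale")) {
  preprocessing <- match.arg(preprocessing)
  Xmat <- as.matrix(Xmat)
  if (nrow(Xmat) < 2L) stop("need >= 2 samples")
  if (anyNA(Xmat)) stop("PCA requires a complete matrix; fill masked cells upstream")
  ctr <- colMeans(Xmat)
  scl <- rep(1, ncol(Xmat))
  if (preprocessing == "autoscale") {
    scl <- apply(Xmat, 2L, sd)
    scl[scl == 0] <- 1
  }
  Xc <- sweep(sweep(Xmat, 2L, ctr), 2L, scl, "/")
  maxrank <- min(nrow(Xmat) - 1L, ncol(Xmat))
  if (is.null(nComponents)) nComponents <- maxrank
  if (nComponents > maxrank) {
    stop(sprintf("nComponents = %d exceeds max rank %d", nComponents, maxrank))
  }
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  P <- sv$v
  # sign convention
  for (a in seq_len(ncol(P))) {
    if (P[which.max(abs(P[, a])), a] < 0) P[, a] <- -P[, a]
  }
  scores <- Xc %*% P
  ev <- 100 * sv$d[seq_len(nComponents)]^2 / sum(Xc^2)
  new("PCAModel",
    loadings = P, scores = scores, explainedVariance = ev,
    center = ctr, scale = scl, preprocessing = preprocessing
  )
}

#' Leave-one-out cross-validation of PCA rank
#'
#' For every candidate rank a, each sample in turn is left out, a PCA is
#' fitted to the remaining samples, and the left-out sample (centered/scaled
#' with the training statistics) is projected onto the first a loadings; the
#' table reports the predictive residual sum of squares (PRESS) per rank.
#' No automatic rank choice is made.
#'
#' @param Xmat samples x variables matrix.
#' @param maxComponents largest rank to evaluate.
#' @param preprocessing as in \code{\link{fitPCA}}.
#' @return data.frame with columns \code{nComponents} and \code{press}.
#' @export
crossValidatePCA <- function(Xmat, maxComponents,
                             preprocessing = c("mean_center", "autoscale")) {
  preprocessing <- match.arg(preprocessing)
  Xmat <- as.matrix(Xmat)
  n <- nrow(Xmat)
  if (n < 3L) stop("need >= 3 samples for cross-validation")
  maxComponents <- min(maxComponents, n - 2L, ncol(Xmat))
  press <- numeric(maxComponents)
  for (i in seq_len(n)) {
    fit <- fitPCA(Xmat[-i, , drop = FALSE],
      nComponents = maxComponents, preprocessing = preprocessing
    )
    x <- (Xmat[i, ] - fit@center) / fit@scale
    t_i <- crossprod(fit@loadings, x)
    for (a in seq_len(maxComponents)) {
      resid <- x - fit@loadings[, seq_len(a), drop = FALSE] %*% t_i[seq_len(a)]
      press[a] <- press[a] + sum(resid^2)
    }
  }
  data.frame(nComponents = seq_len(maxComponents), press = press)
}
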