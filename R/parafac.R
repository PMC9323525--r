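#' Fit a PARAFAC model by alternating least squares
#'
#' Trilinear decomposition \eqn{X_{ijk} = \sum_f a_{if} b_{jf} c_{kf} +
#' e_{ijk}} of a samples x emission x excitation array, minimising the sum of
#' squared residuals over non-missing cells. Masked (\code{NA}) cells are
#' ignored in every least-squares update (missing-data ALS); they are never
#' imputed. Non-negativity on all three modes is on by default, reflecting the
#' physical non-negativity of concentrations and spectra. The best of
#' \code{nStarts} random initialisations is retained; components are sorted by
#' explained sum of squares, the spectral loadings are normalised to unit
#' Euclidean norm with the magnitude pushed into the scores, and the sign
#' indeterminacy (relevant only without the non-negativity constraint) is
#' resolved by making each loading's largest-magnitude element positive.
#'
#' @param X a 3-way array (samples x em x ex) or an \linkS4class{EEMDataset}.
#' @param nComponents number of trilinear components F.
#' @param nonneg constrain all three modes to be non-negative.
#' @param tol convergence tolerance on the change in model fit between
#'   iterations, measured as the change in the explained fraction of the
#'   observed sum of squares (the fit percent divided by 100). This fit-based
#'   criterion is robust to the slowly creeping "swamp" phases ALS exhibits
#'   when two components share an excitation profile.
#' @param maxIter maximum ALS iterations per start.
#' @param nStarts number of random initialisations.
#' @param seed optional integer seed for the initialisations.
#' @return A \linkS4class{ParafacModel}; the residual-sum-of-squares trace of
#'   the winning start is attached as attribute \code{ssrTrace}.
#' @export
fitParafac <- function(X, nComponents, nonneg = TRUE, tol = 1e-8,
                       maxIter = 2000L, nStarts = 10L, seed = NULL) {
  grids <- list(em = numeric(), ex = numeric())
  if (is(X, "EEMDataset")) {
    grids <- list(em = X@em, ex = X@ex)
    X <- X@array
  }
  d <- dim(X)
  if (length(d) != 3L) stop("X must be a 3-way array")
  f <- as.integer(nComponents)
  if (f < 1L) stop("nComponents must be >= 1")
  if (any(d < f)) {
    stop(sprintf(
      "nComponents = %d exceeds an array dimension (%s)", f,
      paste(d, collapse = " x ")
    ))
  }
  if (!length(grids$em)) grids <- list(em = seq_len(d[2L]), ex = seq_len(d[3L]))
  if (all(is.na(X))) stop("X is entirely missing")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  best <- NULL
  for (s in seq_len(nStarts)) {
    fit <- .parafacALS(X, f, nonneg, tol, maxIter)
    if (is.null(best) || fit$ssr < best$ssr) best <- fit
  }

  A <- best$A; B <- best$B; C <- best$C
  # push magnitude into the scores, unit-norm spectral loadings
  nb <- sqrt(colSums(B^2)); nc <- sqrt(colSums(C^2))
  nb[nb == 0] <- 1; nc[nc == 0] <- 1
  B <- sweep(B, 2L, nb, "/"); C <- sweep(C, 2L, nc, "/")
  A <- sweep(A, 2L, nb * nc, "*")
  # sign convention: largest-|element| of each loading positive
  for (fc in seq_len(f)) {
    sb <- sign(B[which.max(abs(B[, fc])), fc]); if (sb == 0) sb <- 1
    sc <- sign(C[which.max(abs(C[, fc])), fc]); if (sc == 0) sc <- 1
    B[, fc] <- B[, fc] * sb; C[, fc] <- C[, fc] * sc
    A[, fc] <- A[, fc] * sb * sc
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  sstot <- sum(X^2, na.rm = TRUE)
  model <- new("ParafacModel",
    nComponents = f, scores = A, emLoadings = B, exLoadings = C,
    fitPercent = 100 * (1 - best$ssr / sstot), corcondia = NA_real_,
    nIter = best$iter, converged = best$converged,
    em = as.numeric(grids$em), ex = as.numeric(grids$ex)
  )
  model@corcondia <- coreConsistency(model, X)
  if (!best$converged) {
    warning(sprintf(
      "ALS did not converge within %d iterations (relative fit change %.2e)",
      maxIter, best$lastDelta
    ), call. = FALSE)
  }
  attr(model, "ssrTrace") <- best$trace
  model
}

# One ALS run from a fresh random start. Factor layout: A n x f, B J x f,
# C K x f. Mode unfoldings are fixed once; per-iteration work is a handful of
# dense matrix products plus the batched NNLS solves.
.parafacALS <- function(X, f, nonneg, tol, maxIter) {
  d <- dim(X)
  n <- d[1L]; J <- d[2L]; K <- d[3L]
  W <- !is.na(X)
  X0 <- X; X0[!W] <- 0
  X1 <- matrix(X0, n)                     # n  x JK  (em fastest)
  W1 <- matrix(W, n) * 1
  X2 <- matrix(aperm(X0, c(2L, 1L, 3L)), J) # J x nK (sample fastest)
  W2 <- matrix(aperm(W, c(2L, 1L, 3L)) * 1, J)
  X3 <- matrix(aperm(X0, c(3L, 1L, 2L)), K) # K x nJ
  W3 <- matrix(aperm(W, c(3L, 1L, 2L)) * 1, K)
  anyMiss <- !all(W)

  pairs <- .pairCols(f)
  A <- matrix(runif(n * f), n)
  B <- matrix(runif(J * f), J)
  C <- matrix(runif(K * f), K)

  kr <- function(right, left) { # rows: left index fastest
    left[rep(seq_len(nrow(left)), nrow(right)), , drop = FALSE] *
      right[rep(seq_len(nrow(right)), each = nrow(left)), , drop = FALSE]
  }
  gramH <- function(Z, Xm, Wm) {
    Zpq <- Z[, pairs$p, drop = FALSE] * Z[, pairs$q, drop = FALSE]
    Gp <- if (anyMiss) Wm %*% Zpq else {
      matrix(colSums(Zpq), nrow(Xm), length(pairs$p), byrow = TRUE)
    }
    list(Gp = Gp, H = Xm %*% Z)
  }

  sstot <- sum(X0^2)
  objective <- function(A_, B_, C_) {
    R <- X1 - tcrossprod(A_, kr(C_, B_))
    if (anyMiss) sum((R * W1)^2) else sum(R^2)
  }
  ssr_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  delta <- Inf
  beta <- 0.5 # extrapolation step, adapted on acceptance/rejection
  A_old <- A; B_old <- B; C_old <- C
  while (iter < maxIter) {
    iter <- iter + 1L
    Z1 <- kr(C, B)
    gh <- gramH(Z1, X1, W1)
    A <- .batchSolve(gh$Gp, gh$H, f, nonneg)
    A <- .reviveDead(A)
    Z2 <- kr(C, A)
    gh <- gramH(Z2, X2, W2)
    B <- .batchSolve(gh$Gp, gh$H, f, nonneg)
    B <- .reviveDead(B)
    Z3 <- kr(B, A)
    gh <- gramH(Z3, X3, W3)
    C <- .batchSolve(gh$Gp, gh$H, f, nonneg)
    C <- .reviveDead(C)
    ssr <- objective(A, B, C)

    # monotone line extrapolation along the last ALS step; accepted only when
    # it lowers the objective, so the descent property is preserved
    if (iter > 3L) {
      Ae <- A + beta * (A - A_old)
      Be <- B + beta * (B - B_old)
      Ce <- C + beta * (C - C_old)
      if (nonneg) {
        Ae[Ae < 0] <- 0; Be[Be < 0] <- 0; Ce[Ce < 0] <- 0
      }
      ssr_e <- objective(Ae, Be, Ce)
      if (ssr_e < ssr) {
        A <- Ae; B <- Be; C <- Ce; ssr <- ssr_e
        beta <- min(beta * 2, 32)
      } else {
        beta <- max(beta * 0.25, 0.25)
      }
    }
    A_old <- A; B_old <- B; C_old <- C

    trace[iter] <- ssr
    if (ssr > ssr_prev * (1 + 1e-8) + 1e-12) {
      warning(sprintf(
        "ALS objective increased at iteration %d (%.6g -> %.6g)",
        iter, ssr_prev, ssr
      ), call. = FALSE)
    }
    delta <- if (is.finite(ssr_prev)) abs(ssr_prev - ssr) / max(sstot, 1e-300) else Inf
    ssr_prev <- ssr
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    A = A, B = B, C = C, ssr = ssr_prev, iter = iter, converged = converged,
    trace = trace, lastDelta = delta
  )
}

.pairCols <- function(f) {
  q <- rep(seq_len(f), times = seq_len(f))
  p <- unlist(lapply(seq_len(f), seq_len))
  list(p = p, q = q)
}

# A zero column stalls ALS (singular Gram); reseed it with small positive noise.
.reviveDead <- function(U) {
  dead <- colSums(abs(U)) < 1e-12 | !is.finite(colSums(U))
  if (any(dead)) {
    U[, dead] <- matrix(runif(nrow(U) * sum(dead), 1e-3, 1), nrow(U))
  }
  U
}

#' Percent of sum of squares explained by a PARAFAC model
#'
#' \eqn{100 (1 - SS_{res} / SS_{tot})} over the non-missing cells of X,
#' computed by direct cell-wise residual summation.
#'
#' @param model a \linkS4class{ParafacModel}.
#' @param X the array (or \linkS4class{EEMDataset}) the model was fitted to.
#' @return percent, at most 100 (negative for models worse than the mean-zero
#'   model).
#' @export
explainedVariance <- function(model, X) {
  if (is(X, "EEMDataset")) X <- X@array
  if (all(is.na(X))) stop("X is entirely missing: explained variance undefined")
  R <- X - .parafacReconstruct(model)
  100 * (1 - sum(R^2, na.rm = TRUE) / sum(X^2, na.rm = TRUE))
}

.parafacReconstruct <- function(model) {
  d <- c(nrow(model@scores), nrow(model@emLoadings), nrow(model@exLoadings))
  Z <- model@emLoadings[rep(seq_len(d[2L]), d[3L]), , drop = FALSE] *
    model@exLoadings[rep(seq_len(d[3L]), each = d[2L]), , drop = FALSE]
  array(tcrossprod(model@scores, Z), d)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' With the fitted loadings held fixed, the least-squares Tucker3 core G of X
#' is computed; a valid trilinear model should yield a core close to the
#' F x F x F superidentity T (ones on the superdiagonal). The diagnostic is
#' \eqn{100 (1 - \sum (g_{def} - t_{def})^2 / \sum t_{def}^2)}. Masked cells
#' are filled with the model reconstruction before the core regression.
#'
#' @param model a \linkS4class{ParafacModel}.
#' @param X the array (or \linkS4class{EEMDataset}) the model was fitted to.
#' @return percent (can be negative for badly over-factored models).
#' @export
coreConsistency <- function(model, X) {
  if (is(X, "EEMDataset")) X <- X@array
  f <- model@nComponents
  if (anyNA(X)) {
    R <- .parafacReconstruct(model)
    X[is.na(X)] <- R[is.na(X)]
  }
  pinvCond <- function(M, name) {
    sv <- svd(M)
    if (sv$d[1L] <= 0 || sv$d[length(sv$d)] / sv$d[1L] < 1e-12) {
      stop(sprintf(
        "%s loadings are numerically singular (condition number %.3g)",
        name, sv$d[1L] / max(sv$d[length(sv$d)], 1e-300)
      ))
    }
    sv$v %*% (t(sv$u) / sv$d)
  }
  pA <- pinvCond(model@scores, "score")
  pB <- pinvCond(model@emLoadings, "emission")
  pC <- pinvCond(model@exLoadings, "excitation")
  d <- dim(X)
  M1 <- array(0, c(f, d[2L], d[3L]))
  for (k in seq_len(d[3L])) M1[, , k] <- pA %*% X[, , k]
  M2 <- array(0, c(f, f, d[3L]))
  for (k in seq_len(d[3L])) M2[, , k] <- M1[, , k] %*% t(pB)
  G <- array(matrix(M2, f * f) %*% t(pC), c(f, f, f))
  Tsup <- array(0, c(f, f, f))
  for (i in seq_len(f)) Tsup[i, i, i] <- 1
  100 * (1 - sum((G - Tsup)^2) / sum(Tsup^2))
}

#' Split-half stability of a PARAFAC solution
#'
#' Samples are partitioned into two halves (randomly, stratified by class when
#' labels are available), a model is fitted independently to each half, the
#' components are matched by Tucker congruence, and the similarity is
#' 100 times the mean absolute congruence over matched components and both
#' spectral modes (emission and excitation).
#'
#' @param X a 3-way array or \linkS4class{EEMDataset} (labels taken from the
#'   dataset when present).
#' @param nComponents components F to fit in each half.
#' @param labels optional class labels for stratification.
#' @param seed integer seed controlling the partition and the ALS starts.
#' @param ... further arguments to \code{\link{fitParafac}}.
#' @return list with \code{similarity} (percent), the two half models, and the
#'   sample indices of each half.
#' @export
splitHalf <- function(X, nComponents, labels = NULL, seed = NULL, ...) {
  if (is(X, "EEMDataset")) {
    if (is.null(labels)) labels <- X@labels
    X <- X@array
  }
  n <- dim(X)[1L]
  if (n < 2L * nComponents) {
    stop(sprintf(
      "need >= %d samples for split-half at F = %d, have %d",
      2L * nComponents, nComponents, n
    ))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  idx <- seq_len(n)
  if (!is.null(labels)) {
    half1 <- unlist(lapply(split(idx, labels), function(g) {
      sample(g, floor(length(g) / 2))
    }), use.names = FALSE)
  } else {
    half1 <- sample(idx, floor(n / 2))
  }
  half2 <- setdiff(idx, half1)
  if (min(length(half1), length(half2)) < nComponents) {
    stop("a split half has fewer samples than components")
  }
  m1 <- fitParafac(X[half1, , , drop = FALSE], nComponents, ...)
  m2 <- fitParafac(X[half2, , , drop = FALSE], nComponents, ...)
  mt <- matchComponents(m1, m2)
  congB <- abs(.congruence(m1@emLoadings, m2@emLoadings[, mt$permutation, drop = FALSE]))
  congC <- abs(.congruence(m1@exLoadings, m2@exLoadings[, mt$permutation, drop = FALSE]))
  list(
    similarity = 100 * mean(c(diag(congB), diag(congC))),
    model1 = m1, model2 = m2, half1 = half1, half2 = half2
  )
}

.congruence <- function(U, V) {
  # Tucker congruence matrix between columns of U and V
  nu <- sqrt(colSums(U^2)); nv <- sqrt(colSums(V^2))
  nu[nu == 0] <- 1; nv[nv == 0] <- 1
  crossprod(U, V) / outer(nu, nv)
}

#' Match components between two PARAFAC solutions
#'
#' Finds the column permutation of the second solution maximising the total
#' combined emission/excitation Tucker congruence with the first. Exhaustive
#' over permutations for F <= 6, greedy otherwise.
#'
#' @param modelA,modelB \linkS4class{ParafacModel} objects, or lists with
#'   elements \code{emLoadings} and \code{exLoadings} (e.g. generator truth).
#' @return list with \code{permutation} (index into B's components for each of
#'   A's) and \code{congruence} (matched per-component mean |congruence|).
#' @export
matchComponents <- function(modelA, modelB) {
  getL <- function(m) {
    if (is(m, "ParafacModel")) list(B = m@emLoadings, C = m@exLoadings)
    else list(B = as.matrix(m$emLoadings), C = as.matrix(m$exLoadings))
  }
  a <- getL(modelA); b <- getL(modelB)
  f <- ncol(a$B)
  if (ncol(b$B) != f) {
    stop(sprintf("component counts differ: %d vs %d", f, ncol(b$B)))
  }
  Phi <- (abs(.congruence(a$B, b$B)) + abs(.congruence(a$C, b$C))) / 2
  if (f <= 6L) {
    perms <- .permutations(f)
    tot <- vapply(perms, function(p) sum(Phi[cbind(seq_len(f), p)]), 0)
    perm <- perms[[which.max(tot)]]
  } else {
    perm <- integer(f)
    avail <- seq_len(f)
    for (i in order(-apply(Phi, 1L, max))) {
      j <- avail[which.max(Phi[i, avail])]
      perm[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  list(permutation = perm, congruence = Phi[cbind(seq_len(f), perm)])
}

.permutations <- function(f) {
  if (f == 1L) return(list(1L))
  sub <- .permutations(f - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(f)) {
      out[[length(out) + 1L]] <- append(p, f, after = pos - 1L)
    }
  }
  out
}

#' Scan candidate component numbers and select one
#'
#' Fits each candidate F, records fit percent, CORCONDIA, and (optionally)
#' split-half similarity, and selects the largest candidate whose CORCONDIA is
#' at or above the floor. If none qualifies the smallest candidate is returned
#' with a warning.
#'
#' @param X a 3-way array or \linkS4class{EEMDataset}.
#' @param candidates integer vector of F values to scan (default 3:5).
#' @param corcondiaFloor acceptance floor for CORCONDIA, percent.
#' @param includeSplitHalf also compute split-half similarity per candidate.
#' @param labels,seed passed to \code{\link{splitHalf}}.
#' @param ... further arguments to \code{\link{fitParafac}}.
#' @return list with \code{nComponents} (selected F), \code{diagnostics}
#'   (data.frame), and \code{models} (one per candidate).
#' @export
selectNComponents <- function(X, candidates = 3:5, corcondiaFloor = 80,
                              includeSplitHalf = FALSE, labels = NULL,
                              seed = NULL, ...) {
  if (!length(candidates)) stop("candidates must be nonempty")
  candidates <- sort(unique(as.integer(candidates)))
  models <- list()
  tab <- data.frame(
    nComponents = candidates, fitPercent = NA_real_, corcondia = NA_real_,
    splitHalfSimilarity = NA_real_
  )
  for (i in seq_along(candidates)) {
    fc <- candidates[i]
    m <- fitParafac(X, fc, seed = seed, ...)
    models[[i]] <- m
    tab$fitPercent[i] <- m@fitPercent
    tab$corcondia[i] <- m@corcondia
    if (includeSplitHalf) {
      tab$splitHalfSimilarity[i] <- splitHalf(
        X, fc, labels = labels, seed = seed, ...
      )$similarity
    }
  }
  pass <- which(tab$corcondia >= corcondiaFloor)
  if (length(pass)) {
    best <- candidates[max(pass)]
  } else {
    best <- candidates[1L]
    warning(sprintf(
      "no candidate reached CORCONDIA >= %g%%; returning smallest (F = %d)",
      corcondiaFloor, best
    ), call. = FALSE)
  }
  list(nComponents = best, diagnostics = tab, models = models)
}

#' Class-wise comparison of PARAFAC component scores
#'
#' Two-sample pooled-variance Student's t-test of the per-class mean score of
#' each component, with a significance flag at the 0.05 level.
#'
#' @param scores samples x F score matrix (e.g. \code{parafacScores(model)}).
#' @param labels two-class factor/character vector, one per sample.
#' @return data.frame with per-component class means/sds, t statistic, p value
#'   and significance flag.
#' @export
compareClassScores <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (any(table(labels) < 2L)) stop("each class needs >= 2 samples")
  lv <- levels(labels)
  out <- lapply(seq_len(ncol(scores)), function(fc) {
    x <- scores[labels == lv[1L], fc]
    y <- scores[labels == lv[2L], fc]
    tt <- t.test(x, y, var.equal = TRUE)
    data.frame(
      component = fc,
      mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, significant = tt$p.value < 0.05
    )
  })
  res <- do.call(rbind, out)
  attr(res, "classes") <- lv
  res
}
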