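# Batched small non-negative least squares.
#
# ALS updates of one PARAFAC mode solve, for every row i of that mode,
#   min_x 0.5 x' G_i x - h_i' x   s.t. x >= 0,
# where G_i is the (possibly row-specific, under missing data) F x F Gram of
# the Khatri-Rao design and h_i the corresponding cross-product. For the small
# F used with EEMs (<= ~8) the exact solution is found by enumerating all 2^F
# passive sets and checking the KKT conditions, fully vectorised over rows.
# Grams are kept packed: column (p,q), p <= q, of `Gp` holds G[p,q] per row.

.pairIndex <- function(f) {
  # f x f matrix mapping (p,q) to the packed column index
  idx <- matrix(0L, f, f)
  cnt <- 0L
  for (q in seq_len(f)) {
    for (p in seq_len(q)) {
      cnt <- cnt + 1L
      idx[p, q] <- cnt
      idx[q, p] <- cnt
    }
  }
  idx
}

# Cholesky solve of the packed-per-row SPD systems restricted to subset S.
# Returns r x |S| solutions; rows where the factorization breaks down get NA.
.batchCholSolve <- function(Gp, H, S, pidx) {
  p <- length(S)
  r <- nrow(H)
  L <- vector("list", p * p)
  dim(L) <- c(p, p)
  ok <- rep(TRUE, r)
  for (i in seq_len(p)) {
    di <- Gp[, pidx[S[i], S[i]]]
    if (i > 1L) for (k in seq_len(i - 1L)) di <- di - L[[i, k]]^2
    bad <- !(di > 0) | !is.finite(di)
    di[bad] <- 1 # placeholder, rows flagged invalid
    ok <- ok & !bad
    L[[i, i]] <- sqrt(di)
    if (i < p) {
      for (j in seq.int(i + 1L, p)) {
        v <- Gp[, pidx[S[j], S[i]]]
        if (i > 1L) for (k in seq_len(i - 1L)) v <- v - L[[j, k]] * L[[i, k]]
        L[[j, i]] <- v / L[[i, i]]
      }
    }
  }
  # forward then backward substitution, vectorised over rows
  Y <- matrix(0, r, p)
  for (i in seq_len(p)) {
    v <- H[, S[i]]
    if (i > 1L) for (k in seq_len(i - 1L)) v <- v - L[[i, k]] * Y[, k]
    Y[, i] <- v / L[[i, i]]
  }
  X <- matrix(0, r, p)
  for (i in rev(seq_len(p))) {
    v <- Y[, i]
    if (i < p) for (k in seq.int(i + 1L, p)) v <- v - L[[k, i]] * X[, k]
    X[, i] <- v / L[[i, i]]
  }
  X[!ok, ] <- NA_real_
  X
}

# Exact batched NNLS (or plain LS when nonneg = FALSE).
# Gp: r x f(f+1)/2 packed Grams; H: r x f cross-products.
.batchSolve <- function(Gp, H, f, nonneg = TRUE) {
  pidx <- .pairIndex(f)
  r <- nrow(H)
  if (!nonneg) {
    X <- .batchCholSolve(Gp, H, seq_len(f), pidx)
    bad <- which(!stats::complete.cases(X))
    for (i in bad) X[i, ] <- .rowFallback(Gp[i, ], H[i, ], f, pidx, nonneg = FALSE)
    return(X)
  }
  if (f > 10L) { # enumeration impractical; per-row active-set solver
    X <- matrix(0, r, f)
    for (i in seq_len(r)) X[i, ] <- .rowFallback(Gp[i, ], H[i, ], f, pidx, TRUE)
    return(X)
  }
  X <- matrix(0, r, f)
  unresolved <- rep(TRUE, r)
  # tolerances live on two scales: the gradient check on the scale of h,
  # the feasibility check on the scale of the candidate solution itself
  gTol <- 1e-10 * pmax(.rowAbsMax(H), 1e-300)
  subsets <- .subsetsBySize(f)
  for (S in subsets) {
    if (!any(unresolved)) break
    rows <- which(unresolved)
    if (length(S) == 0L) {
      pass <- rows[rowSums(H[rows, , drop = FALSE] > gTol[rows]) == 0L]
      if (length(pass)) {
        X[pass, ] <- 0
        unresolved[pass] <- FALSE
      }
      next
    }
    sol <- .batchCholSolve(
      Gp[rows, , drop = FALSE], H[rows, , drop = FALSE], S, pidx
    )
    cand <- matrix(0, length(rows), f)
    cand[, S] <- sol
    xTol <- 1e-12 * .rowAbsMax(sol)
    feas <- rowSums(sol < -xTol) == 0L & stats::complete.cases(sol)
    comp <- setdiff(seq_len(f), S)
    if (length(comp)) {
      # gradient on the active set: G x - h >= 0 required
      grad <- matrix(0, length(rows), length(comp))
      for (ci in seq_along(comp)) {
        j <- comp[ci]
        g <- -H[rows, j]
        for (p in S) g <- g + Gp[rows, pidx[j, p]] * cand[, p]
        grad[, ci] <- g
      }
      feas <- feas & rowSums(grad < -gTol[rows]) == 0L
    }
    pass <- rows[feas]
    if (length(pass)) {
      X[pass, ] <- pmax(cand[feas, , drop = FALSE], 0)
      unresolved[pass] <- FALSE
    }
  }
  for (i in which(unresolved)) {
    X[i, ] <- .rowFallback(Gp[i, ], H[i, ], f, pidx, TRUE)
  }
  X
}

.rowAbsMax <- function(M) {
  v <- abs(M[, 1L])
  if (ncol(M) > 1L) for (j in 2:ncol(M)) v <- pmax(v, abs(M[, j]))
  v
}

.subsetsBySize <- function(f) {
  subs <- lapply(0:(2^f - 1L), function(m) which(bitwAnd(m, 2^(seq_len(f) - 1L)) > 0L))
  subs[order(-lengths(subs))]
}

# Per-row fallback for numerically awkward systems: rebuild the dense Gram,
# regularise minimally, and delegate to an active-set solver.
.rowFallback <- function(gp, h, f, pidx, nonneg) {
  G <- matrix(gp[pidx], f, f)
  G <- G + diag(f) * (1e-12 * max(diag(G), 1))
  if (!nonneg) return(as.numeric(solve(G, h)))
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R)) {
    G <- G + diag(f) * (1e-8 * max(diag(G), 1))
    R <- chol(G)
  }
  d <- backsolve(R, h, transpose = TRUE)
  as.numeric(pracma::lsqnonneg(R, d)$x)
}
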