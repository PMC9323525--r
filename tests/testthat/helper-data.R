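# Shared builders for small deterministic test objects.

toyEEM <- function(em = c(300, 310, 320), ex = c(250, 260),
                   intensity = NULL, sampleId = "toy", mask = NULL) {
  if (is.null(intensity)) {
    intensity <- matrix(seq_len(length(em) * length(ex)), length(em))
  }
  EEM(intensity, em = em, ex = ex, sampleId = sampleId, mask = mask)
}

# Exact trilinear array from nonnegative random factors (seeded).
trilinearArray <- function(n, J, K, f, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * f, 0.5, 2), n)
  B <- matrix(runif(J * f), J)
  C <- matrix(runif(K * f), K)
  X <- array(0, c(n, J, K))
  for (i in seq_len(n)) X[i, , ] <- B %*% (t(C) * A[i, ])
  list(X = X, A = A, B = B, C = C)
}

# A small two-class, linearly separable spectral matrix.
separableMatrix <- function(n1 = 8, n2 = 10, p = 12, gap = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2)
  X[seq_len(n1), 1:2] <- X[seq_len(n1), 1:2] + gap
  labels <- rep(c("direct", "processed"), c(n1, n2))
  list(X = X, labels = labels)
}
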