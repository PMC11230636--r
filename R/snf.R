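# Similarity network fusion: scaled-exponential affinity kernels with
# K-neighbor local scaling, K-NN sparsified transition kernels, and T
# rounds of cross-layer diffusion.

.euclid_dist <- function(X) {
  # pairwise Euclidean distances between rows
  g <- tcrossprod(X)
  d2 <- outer(diag(g), diag(g), "+") - 2 * g
  sqrt(pmax(d2, 0))
}

# scaled-exponential affinity with K-neighbor local bandwidth scaling.
# The local bandwidth is floored at 1% of the layer's mean off-diagonal
# distance: exact ties (duplicate profiles, e.g. all-zero mutation rows)
# would otherwise collapse the bandwidth to machine epsilon and assign
# those samples unbounded mutual affinity that cross-diffusion can never
# temper.
.affinity <- function(D, K, mu) {
  eps <- .Machine$double.eps
  D <- (D + t(D)) / 2
  diag(D) <- 0
  sortedD <- apply(D, 2, sort)
  means <- colMeans(sortedD[2:(K + 1), , drop = FALSE]) + eps
  Sig <- outer(means, means, "+") / 3 + D / 3 + eps
  floor_sig <- 0.01 * mean(D[upper.tri(D)])
  Sig <- pmax(Sig, max(floor_sig, eps))
  W <- stats::dnorm(D, 0, mu * Sig)
  (W + t(W)) / 2
}

# keep the K largest entries of each row, renormalize rows to sum 1
.dominate <- function(W, K) {
  S <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  for (i in seq_len(nrow(W))) {
    ord <- order(W[i, ], decreasing = TRUE)[seq_len(K)]
    S[i, ord] <- W[i, ord]
  }
  S / rowSums(S)
}

# half-mass row normalization: off-diagonal entries share half of each
# row's mass and the diagonal is pinned at 1/2, so every sample keeps a
# constant self-similarity during cross-diffusion
.row_normalize <- function(W) {
  off <- rowSums(W) - diag(W)
  off[off == 0] <- 1
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' Fuse per-layer sample similarities into one matrix
#'
#' Implements similarity network fusion over a list of sample x feature
#' matrices sharing one ordered sample universe. Per layer, Euclidean
#' sample distances become a scaled-exponential affinity kernel with
#' bandwidth `mu` and `K`-neighbor local scaling; a row-normalized full
#' kernel and a K-NN-sparsified kernel are formed, and `t_iter` rounds of
#' cross-layer diffusion exchange information between layers. The fused
#' `W` is the average of the diffused layer matrices, symmetrized, with a
#' strictly positive diagonal. With a single layer the procedure
#' degenerates to that layer's own diffusion limit.
#'
#' @param layers list of numeric matrices, samples in rows (same rownames,
#'   same order across layers).
#' @param K neighbor count (default 20); reduced to `n - 1` with a warning
#'   when it reaches the sample count.
#' @param mu kernel bandwidth / local-model variance (default 0.5).
#' @param t_iter diffusion iterations (default 20).
#' @return symmetric fused similarity matrix with attribute `params`.
#' @export
snf_fuse <- function(layers, K = 20, mu = 0.5, t_iter = 20) {
  if (!length(layers)) stop("need at least one layer")
  ids <- rownames(layers[[1]])
  if (is.null(ids)) stop("layers need sample rownames")
  for (l in layers)
    if (!identical(rownames(l), ids))
      stop("layers must share one ordered sample universe")
  n <- length(ids)
  if (K >= n) {
    warning(sprintf("K = %d >= n = %d; reduced to %d", K, n, n - 1L))
    K <- n - 1L
  }
  P <- lapply(layers, function(X) {
    W <- .affinity(.euclid_dist(as.matrix(X)), K, mu)
    W <- .row_normalize(W)
    (W + t(W)) / 2
  })
  S <- lapply(P, .dominate, K = K)
  L <- length(P)
  for (iter in seq_len(t_iter)) {
    Pn <- vector("list", L)
    for (j in seq_len(L)) {
      other <- if (L > 1)
        Reduce(`+`, P[-j]) / (L - 1)
      else P[[j]]
      Pn[[j]] <- S[[j]] %*% other %*% t(S[[j]])
    }
    for (j in seq_len(L)) {
      Wj <- .row_normalize(Pn[[j]])
      P[[j]] <- (Wj + t(Wj)) / 2
    }
  }
  W <- Reduce(`+`, P) / L
  W <- .row_normalize(W)
  W <- (W + t(W) + diag(n)) / 2
  dimnames(W) <- list(ids, ids)
  attr(W, "params") <- list(K = K, mu = mu, t_iter = t_iter,
                            n_layers = L)
  W
}
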