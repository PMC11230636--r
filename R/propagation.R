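# Network-propagation smoothing of the binary patient x gene mutation
# matrix: F_{t+1} = alpha * F_t %*% A + (1 - alpha) * F_0, with a
# row-stochastic network operator A.

#' Build the binary patient x gene mutation matrix
#'
#' Entry (s, g) is 1 iff sample `s` carries at least one (nonsilent,
#' sanitized) mutation in gene `g`; multiplicity is ignored. Samples with
#' no mutation in the gene subset keep an all-zero row, reported with a
#' warning.
#'
#' @param mutations sanitized, hypermutator-filtered mutation data.frame.
#' @param gene_subset genes to keep as columns (the stratification genes).
#' @param sample_ids optional sample universe (rows); defaults to the
#'   samples present in `mutations`.
#' @return binary matrix, samples x genes.
#' @export
binarize_mutations <- function(mutations, gene_subset, sample_ids = NULL) {
  if (!length(gene_subset)) stop("gene_subset must be nonempty")
  if (is.null(sample_ids)) sample_ids <- sort(unique(mutations$sample_id))
  F0 <- matrix(0, length(sample_ids), length(gene_subset),
               dimnames = list(sample_ids, gene_subset))
  mm <- mutations[mutations$gene_id %in% gene_subset &
                  mutations$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(mm)) F0[cbind(mm$sample_id, mm$gene_id)] <- 1
  zero <- rowSums(F0) == 0
  if (any(zero))
    warning(sum(zero), " sample(s) have no mutation in the gene subset")
  F0
}

#' Row-stochastic normalization of a gene network
#'
#' Returns the propagation operator `A` over `gene_order`:
#' `A[i, j] = w(i, j) / sum_j w(i, j)` using only edges whose both ends
#' lie in `gene_order`. A gene with no surviving edge gets a
#' self-retention row (`A[i, i] = 1`) so propagation mass is conserved;
#' every row sums to exactly 1. Network genes absent from `gene_order` are
#' dropped (counted in attribute `dropped_genes`).
#'
#' @param net a `gene_network`.
#' @param gene_order character vector fixing the row/column order (the
#'   mutation-matrix gene order).
#' @return row-stochastic square matrix over `gene_order`.
#' @export
normalize_network <- function(net, gene_order) {
  if (!length(gene_order)) stop("gene_order must be nonempty")
  W <- matrix(0, length(gene_order), length(gene_order),
              dimnames = list(gene_order, gene_order))
  ed <- net$edges[net$edges$gene_a %in% gene_order &
                  net$edges$gene_b %in% gene_order, , drop = FALSE]
  if (nrow(ed)) {
    W[cbind(ed$gene_a, ed$gene_b)] <- ed$weight
    W[cbind(ed$gene_b, ed$gene_a)] <- ed$weight
  }
  deg <- rowSums(W)
  iso <- deg == 0
  A <- W / ifelse(deg == 0, 1, deg)
  if (any(iso)) A[cbind(which(iso), which(iso))] <- 1
  attr(A, "dropped_genes") <- setdiff(net$nodes, gene_order)
  attr(A, "isolated_genes") <- gene_order[iso]
  A
}

#' Smooth mutation profiles by network propagation
#'
#' Iterates `F_{t+1} = alpha * F_t %*% A + (1 - alpha) * F0` from
#' `F = F0` until the Frobenius norm of the step falls below `tol`.
#' With a row-stochastic `A` each patient's row sum is conserved, and the
#' fixed point equals the closed form
#' `(1 - alpha) * F0 %*% solve(I - alpha * A)`.
#'
#' @param F0 binary patient x gene matrix (see [binarize_mutations()]).
#' @param A row-stochastic operator over the same gene order (see
#'   [normalize_network()]).
#' @param alpha restart-free diffusion weight in `[0, 1)` (default 0.7).
#' @param tol Frobenius-norm stopping tolerance (default `1e-6`).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   final step norm.
#' @param quantile_normalize optionally map each patient's smoothed values
#'   onto the across-patient mean order statistics after convergence
#'   (rank-based quantile normalization; off by default).
#' @return object of class `smoothed_profile`: list with `F` (smoothed
#'   matrix), `alpha`, `iterations`, `final_step_norm`.
#' @export
propagate <- function(F0, A, alpha = 0.7, tol = 1e-6, max_iter = 1000,
                      quantile_normalize = FALSE) {
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1); alpha = 1 has no fixed-point guarantee")
  if (!identical(colnames(F0), rownames(A)))
    stop("gene order of F0 and A must agree")
  Fm <- F0
  base <- (1 - alpha) * F0
  step <- Inf
  it <- 0L
  while (step >= tol) {
    if (it >= max_iter)
      stop(sprintf("propagation did not converge in %d iterations (last step norm %.3e)",
                   max_iter, step))
    Fn <- alpha * (Fm %*% A) + base
    step <- sqrt(sum((Fn - Fm)^2))
    Fm <- Fn
    it <- it + 1L
  }
  if (alpha == 0) { Fm <- F0; step <- 0 }
  if (quantile_normalize) Fm <- .quantile_normalize_rows(Fm)
  structure(list(F = Fm, alpha = alpha, iterations = it,
                 final_step_norm = step),
            class = "smoothed_profile")
}

# rank-based quantile normalization across patients (rows share the mean
# sorted profile)
.quantile_normalize_rows <- function(M) {
  ref <- colMeans(t(apply(M, 1, sort)))
  t(apply(M, 1, function(r) ref[rank(r, ties.method = "average")]))
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf("<smoothed_profile> %d patients x %d genes, alpha=%.2f, %d iterations, final step %.2e\n",
              nrow(x$F), ncol(x$F), x$alpha, x$iterations,
              x$final_step_norm))
  invisible(x)
}

#' Log-transform and z-score an expression matrix
#'
#' Per gene: `y = log2(x + 1)`, then `(y - mean(y)) / sd(y)` across
#' samples with the population standard deviation (divisor `n`).
#' Zero-variance genes are set to all-zero with a warning.
#'
#' @param expr nonnegative expression matrix (gene x sample).
#' @return standardized matrix with the same dimnames.
#' @export
zscore_expression <- function(expr) {
  y <- log2(unclass(expr) + 1)
  mu <- rowMeans(y)
  sd_pop <- sqrt(rowMeans((y - mu)^2))
  flat <- sd_pop == 0
  if (any(flat))
    warning(sum(flat), " zero-variance gene(s) set to all-zero")
  z <- (y - mu) / ifelse(flat, 1, sd_pop)
  z[flat, ] <- 0
  z
}
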