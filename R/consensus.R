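# Subsampled consensus clustering of the fused similarity matrix, and
# silhouette-based selection of the cluster count.

#' Consensus clustering of a fused similarity matrix
#'
#' For each of `reps` repetitions, `ceiling(p_item * n)` samples are drawn
#' without replacement; each drawn sample is represented by its row of `W`
#' restricted to the subsample; pairwise distance is `1 - Spearman`
#' correlation of those rows; average-linkage hierarchical clustering is
#' cut at each `k = 2..maxK`. The consensus entry `M_k(i, j)` is the
#' co-clustered count divided by the co-sampled count (pairs never
#' co-sampled get 0, counted in attribute `never_cosampled`). Final labels
#' per `k` come from average-linkage clustering of `1 - M_k`.
#'
#' @param W symmetric similarity matrix with sample dimnames (see
#'   [snf_fuse()]).
#' @param maxK largest cluster count to evaluate (default 6).
#' @param reps subsampling repetitions (default 5000).
#' @param p_item item sampling proportion (default 0.8).
#' @param seed integer seed controlling the subsampling stream.
#' @return object of class `consensus_result`: list keyed `"2" .. maxK`,
#'   each with `M` (consensus matrix, diagonal 1) and `labels` (integer
#'   cluster vector named by sample).
#' @export
consensus_cluster <- function(W, maxK = 6, reps = 5000, p_item = 0.8,
                              seed = 1) {
  n <- nrow(W)
  if (maxK < 2 || maxK >= n) stop("need 2 <= maxK < n")
  if (p_item <= 0 || p_item > 1) stop("p_item must lie in (0, 1]")
  ids <- rownames(W)
  if (!is.null(seed)) set.seed(seed)
  m <- ceiling(p_item * n)
  ks <- 2:maxK
  conn <- lapply(ks, function(k) matrix(0, n, n))
  names(conn) <- as.character(ks)
  pair_count <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    R <- W[idx, idx, drop = FALSE]
    ranks <- t(apply(R, 1, rank))       # Spearman: rank each row, then cor
    cr <- suppressWarnings(stats::cor(t(ranks)))
    cr[is.na(cr)] <- 0
    d <- 1 - cr
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    pair_count[idx, idx] <- pair_count[idx, idx] + 1
    for (k in ks) {
      lab <- stats::cutree(hc, k)
      co <- outer(lab, lab, "==") * 1
      ck <- as.character(k)
      conn[[ck]][idx, idx] <- conn[[ck]][idx, idx] + co
    }
  }
  never <- sum(pair_count[upper.tri(pair_count)] == 0)
  if (never > 0)
    warning(never, " sample pair(s) were never co-sampled; consensus set to 0")
  denom <- ifelse(pair_count == 0, 1, pair_count)
  out <- lapply(ks, function(k) {
    M <- conn[[as.character(k)]] / denom
    M[pair_count == 0] <- 0
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    labels <- stats::cutree(hc, k)
    names(labels) <- ids
    list(M = M, labels = labels)
  })
  names(out) <- as.character(ks)
  structure(out, class = "consensus_result", never_cosampled = never,
            reps = reps, p_item = p_item, seed = seed)
}

#' Per-sample silhouette widths on a distance matrix
#'
#' `sil(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is the mean
#' distance from `i` to the other members of its cluster and `b(i)` the
#' smallest mean distance from `i` to any other cluster. Samples in
#' singleton clusters get silhouette 0.
#'
#' @param D symmetric distance matrix, zero diagonal.
#' @param labels cluster labels (any atomic type), one per row of `D`.
#' @return numeric vector of silhouette widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(D, labels) {
  n <- nrow(D)
  if (length(labels) != n) stop("labels must match the distance matrix")
  labs <- unique(labels)
  if (length(labs) < 2) stop("silhouette needs at least 2 clusters")
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { sil[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(labs, labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  sil
}

#' Choose the cluster count by mean silhouette and name the subtypes
#'
#' Converts the fused similarity into distances `D = max(W) - W` (zero
#' diagonal), computes silhouette widths for each candidate `k` from the
#' consensus labels, picks the `k` with the largest mean silhouette, and
#' renames clusters `CLASS A`, `CLASS B`, ... by descending cluster size.
#'
#' @param cons a `consensus_result`.
#' @param W the fused similarity matrix used for clustering.
#' @return object of class `subtype_assignment`: list with `assignment`
#'   (data.frame `sample_id`, `class`, `silhouette`), `k` (chosen),
#'   `mean_silhouette` (named vector over k), and `labels_per_k`.
#' @export
silhouette_and_choose_k <- function(cons, W) {
  D <- max(W) - unclass(W)
  diag(D) <- 0
  ks <- names(cons)
  sil_k <- setNames(rep(NA_real_, length(ks)), ks)
  sils <- list()
  for (k in ks) {
    lab <- cons[[k]]$labels
    if (length(unique(lab)) < 2) {
      warning("k = ", k, " produced an empty cluster; skipped")
      next
    }
    s <- silhouette_widths(D, lab)
    sils[[k]] <- s
    sil_k[k] <- mean(s)
  }
  if (all(is.na(sil_k))) stop("no valid clustering at any k")
  best <- ks[which.max(sil_k)]
  lab <- cons[[best]]$labels
  sizes <- sort(table(lab), decreasing = TRUE)
  new_names <- setNames(paste("CLASS", LETTERS[seq_along(sizes)]),
                        names(sizes))
  cls <- unname(new_names[as.character(lab)])
  structure(list(assignment = data.frame(sample_id = names(lab),
                                         class = cls,
                                         silhouette = sils[[best]],
                                         stringsAsFactors = FALSE),
                 k = as.integer(best),
                 mean_silhouette = sil_k,
                 labels_per_k = lapply(cons, `[[`, "labels")),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> k = %d, mean silhouette = %.3f\n",
              x$k, x$mean_silhouette[as.character(x$k)]))
  print(table(x$assignment$class))
  invisible(x)
}
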