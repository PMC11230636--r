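# Subtype classifier: candidate selection, the mean-interval
# separability filter, elastic-net panel selection, SVM training with
# grid search, prediction (including pseudo-bulk profiles), and the
# confusion-matrix metrics.

#' Confusion-matrix metrics for a binary classifier
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`
#' (reported unscaled in `[-1, 1]`; 0 when the denominator vanishes).
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return list of class `classifier_metrics` with the four counts and
#'   `ACC`, `SEN`, `SPE`, `MCC`.
#' @export
classifier_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  denom <- sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tp + fp)) * sqrt((tn + fn))
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 ACC = (tp + tn) / (tp + tn + fp + fn),
                 SEN = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 SPE = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 MCC = if (denom == 0) 0 else (tp * tn - fp * fn) / denom),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | ACC=%.4f SEN=%.4f SPE=%.4f MCC=%.4f\n",
              x$TP, x$TN, x$FP, x$FN, x$ACC, x$SEN, x$SPE, x$MCC))
  invisible(x)
}

#' @rdname classifier_metrics
#' @param truth,predicted label vectors.
#' @param positive label treated as the positive class.
#' @export
metrics_from_labels <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  classifier_metrics(tp, tn, fp, fn)
}

#' Select classifier candidate genes between subtypes
#'
#' Differential expression between the two subtypes (Mann-Whitney + BH,
#' fold change on raw means) at the stricter classifier thresholds;
#' candidates are the genes with `p_adjusted < p_cut` and
#' `|log2fc| > fc_cut`.
#'
#' @param expr expression matrix (gene x sample).
#' @param labels subtype label per sample (named by sample or aligned to
#'   columns).
#' @param p_cut adjusted-p threshold (default 0.001).
#' @param fc_cut absolute log2 fold-change threshold (default 1).
#' @return character vector of candidate genes; the full differential
#'   table is attached as attribute `table`.
#' @export
select_candidates <- function(expr, labels, p_cut = 0.001, fc_cut = 1) {
  labels <- .align_labels(expr, labels)
  grp <- sort(unique(labels))
  if (length(grp) != 2) stop("exactly two subtypes are required")
  if (min(table(labels)) < 2) stop("each subtype needs >= 2 samples")
  de <- differential_expression(
    unclass(expr)[, labels == grp[2], drop = FALSE],
    unclass(expr)[, labels == grp[1], drop = FALSE],
    p_cut = p_cut, fc_cut = fc_cut, min_mean = -Inf)
  cand <- de$gene_id[de$p_adjusted < p_cut & abs(de$log2fc) > fc_cut]
  structure(cand, table = de)
}

.align_labels <- function(expr, labels) {
  if (inherits(labels, "subtype_assignment")) {
    a <- labels$assignment
    labels <- setNames(a$class, a$sample_id)
  }
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(expr), names(labels))
    if (length(miss)) stop("no label for sample(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    labels <- labels[colnames(expr)]
  }
  if (length(labels) != ncol(expr))
    stop("labels must cover every expression column")
  as.character(labels)
}

#' Filter candidates by disjoint subtype mean intervals
#'
#' Per gene and subtype, the mean interval `[mu - sigma, mu + sigma]` of
#' `log2(x + 1)` expression is computed (sample sd, divisor `n - 1`); a
#' gene is retained iff the two subtype intervals are disjoint. Closed
#' intervals sharing an endpoint count as overlapping, and a
#' zero-variance gene contributes a point interval under the same rule.
#'
#' @inheritParams select_candidates
#' @param candidates genes to screen.
#' @return character vector of genes with non-overlapping subtype
#'   expression; per-gene interval table in attribute `intervals`.
#' @export
mean_interval_filter <- function(expr, labels, candidates) {
  if (!length(candidates)) stop("candidates must be nonempty")
  labels <- .align_labels(expr, labels)
  grp <- sort(unique(labels))
  if (length(grp) != 2) stop("exactly two subtypes are required")
  y <- log2(unclass(expr)[candidates, , drop = FALSE] + 1)
  stat <- lapply(grp, function(g) {
    v <- y[, labels == g, drop = FALSE]
    mu <- rowMeans(v)
    sdv <- apply(v, 1, stats::sd)
    sdv[is.na(sdv)] <- 0
    cbind(mu = mu, sd = sdv)
  })
  lo1 <- stat[[1]][, "mu"] - stat[[1]][, "sd"]
  hi1 <- stat[[1]][, "mu"] + stat[[1]][, "sd"]
  lo2 <- stat[[2]][, "mu"] - stat[[2]][, "sd"]
  hi2 <- stat[[2]][, "mu"] + stat[[2]][, "sd"]
  disjoint <- hi1 < lo2 | hi2 < lo1     # touching endpoints overlap
  iv <- data.frame(gene_id = candidates,
                   mu_1 = unname(stat[[1]][, "mu"]), sd_1 = unname(stat[[1]][, "sd"]),
                   mu_2 = unname(stat[[2]][, "mu"]), sd_2 = unname(stat[[2]][, "sd"]),
                   disjoint = unname(disjoint), stringsAsFactors = FALSE)
  structure(candidates[disjoint], intervals = iv)
}

# stratified fold ids for cv.glmnet / the SVM grid search
.stratified_folds <- function(labels, nfolds) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

#' Elastic-net selection of the classifier gene panel
#'
#' Fits a two-class logistic model with mixed L1/L2 penalty over a
#' regularization path on `log2(x + 1)` expression of the interval-pass
#' genes; lambda is chosen by stratified cross-validation and the panel
#' is the set of genes with nonzero coefficients. The panel size is
#' data-driven, not forced. If every coefficient is zero at the chosen
#' lambda the full input set is returned with a warning.
#'
#' @inheritParams select_candidates
#' @param genes interval-pass genes (>= 2 for a penalized fit; a single
#'   gene is returned as-is).
#' @param elastic_alpha L1 mixing weight in `(0, 1]` (default 0.5).
#' @param nfolds cross-validation folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param lambda optional fixed lambda vector overriding the path.
#' @return character vector of panel genes.
#' @export
sparse_panel_selection <- function(expr, labels, genes, elastic_alpha = 0.5,
                                   nfolds = 10, seed = 1, lambda = NULL) {
  labels <- .align_labels(expr, labels)
  if (length(genes) < 2) return(genes)
  X <- t(log2(unclass(expr)[genes, , drop = FALSE] + 1))
  y <- factor(labels)
  if (!is.null(seed)) set.seed(seed)
  foldid <- .stratified_folds(labels, nfolds)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          alpha = elastic_alpha, foldid = foldid,
                          lambda = lambda)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  panel <- names(beta)[beta != 0]
  if (!length(panel)) {
    warning("all coefficients zero at the selected lambda; falling back to the full gene set")
    panel <- genes
  }
  panel
}

#' Train and evaluate the subtype SVM on a stratified split
#'
#' Splits samples `train_frac` / `1 - train_frac` stratified by subtype,
#' standardizes `log2(x + 1)` panel expression with the training set's
#' per-gene mean and sd, selects the SVM cost by stratified
#' cross-validated grid search on the training split only, fits the final
#' maximum-margin model, and reports held-out confusion metrics plus a
#' continuous decision score per sample.
#'
#' @inheritParams select_candidates
#' @param panel panel gene ids.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed (split + folds).
#' @param cost_grid SVM cost grid (default `2^(-3:3)`).
#' @param kernel SVM kernel (default `"linear"`).
#' @param nfolds grid-search folds (default 5).
#' @param positive positive class for SEN/SPE/MCC; default the
#'   lexicographically last class (`CLASS B` under the package naming
#'   convention).
#' @return list of class `subtype_classifier_fit` with `model` (a
#'   `subtype_classifier` usable with [predict_subtype()]), `metrics`
#'   (held-out [classifier_metrics()]), `test_scores` (decision values),
#'   `train_ids`, `test_ids`, `best_cost`.
#' @export
train_and_evaluate <- function(expr, labels, panel, train_frac = 0.7,
                               seed = 1, cost_grid = 2^(-3:3),
                               kernel = "linear", nfolds = 5,
                               positive = NULL) {
  labels <- .align_labels(expr, labels)
  if (!length(panel)) stop("panel must be nonempty")
  grp <- sort(unique(labels))
  if (length(grp) != 2) stop("exactly two subtypes are required")
  if (is.null(positive)) positive <- grp[2]
  if (!is.null(seed)) set.seed(seed)
  idx_train <- unlist(lapply(grp, function(g) {
    idx <- which(labels == g)
    sample(idx, round(train_frac * length(idx)))
  }))
  idx_test <- setdiff(seq_along(labels), idx_train)
  if (length(unique(labels[idx_train])) < 2)
    stop("a class is absent from the training split")

  y_all <- log2(unclass(expr)[panel, , drop = FALSE] + 1)
  ytr <- y_all[, idx_train, drop = FALSE]
  center <- rowMeans(ytr)
  scale_ <- apply(ytr, 1, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  Xtr <- t((ytr - center) / scale_)
  ltr <- factor(labels[idx_train], levels = grp)

  # stratified CV grid search over the cost grid, training split only
  fold <- .stratified_folds(labels[idx_train], nfolds)
  cv_acc <- vapply(cost_grid, function(cst) {
    correct <- 0L
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      if (length(unique(ltr[tr])) < 2) next
      fit <- e1071::svm(Xtr[tr, , drop = FALSE], ltr[tr], kernel = kernel,
                        cost = cst, scale = FALSE)
      correct <- correct +
        sum(stats::predict(fit, Xtr[!tr, , drop = FALSE]) == ltr[!tr])
    }
    correct / length(ltr)
  }, numeric(1))
  best_cost <- cost_grid[which.max(cv_acc)]
  fit <- e1071::svm(Xtr, ltr, kernel = kernel, cost = best_cost,
                    scale = FALSE)
  model <- structure(list(svm = fit, panel = panel, center = center,
                          scale = scale_, classes = grp,
                          positive = positive, cost = best_cost,
                          kernel = kernel),
                     class = "subtype_classifier")
  test_expr <- unclass(expr)[, idx_test, drop = FALSE]
  pred <- predict_subtype(model, test_expr)
  metrics <- metrics_from_labels(labels[idx_test], pred$class, positive)
  structure(list(model = model, metrics = metrics,
                 test_scores = pred,
                 train_ids = colnames(expr)[idx_train],
                 test_ids = colnames(expr)[idx_test],
                 best_cost = best_cost),
            class = "subtype_classifier_fit")
}

#' Predict subtypes for new expression profiles
#'
#' Profiles are `log2(x + 1)`-transformed and standardized with the
#' training-set per-gene center/scale before scoring. All panel genes
#' must be present; missing genes raise an error naming them.
#'
#' @param model a `subtype_classifier` (from [train_and_evaluate()]).
#' @param expr expression matrix (gene x sample) containing the panel
#'   genes; pseudo-bulk profiles from [pseudobulk()] work directly.
#' @return data.frame `sample_id`, `class`, `score` (signed decision
#'   value).
#' @export
predict_subtype <- function(model, expr) {
  miss <- setdiff(model$panel, rownames(expr))
  if (length(miss))
    stop("profiles are missing panel gene(s): ",
         paste(miss, collapse = ", "))
  y <- log2(unclass(expr)[model$panel, , drop = FALSE] + 1)
  X <- t((y - model$center) / model$scale)
  pred <- stats::predict(model$svm, X, decision.values = TRUE)
  score <- as.numeric(attr(pred, "decision.values"))
  data.frame(sample_id = colnames(expr),
             class = as.character(pred),
             score = score, stringsAsFactors = FALSE, row.names = NULL)
}

#' Sum single-cell expression into pseudo-bulk profiles
#'
#' Per sample and gene, counts are summed over that sample's cells. The
#' result can be fed to [predict_subtype()], which applies the training
#' standardization downstream.
#'
#' @param counts cell x gene nonnegative count matrix (cells in rows).
#' @param cell_map named vector mapping each cell (rowname) to a sample
#'   id; every cell must be mapped.
#' @return gene x sample matrix of summed expression.
#' @export
pseudobulk <- function(counts, cell_map) {
  cells <- rownames(counts)
  if (is.null(cells)) stop("counts need cell rownames")
  unmapped <- setdiff(cells, names(cell_map))
  if (length(unmapped))
    stop("unmapped cell(s): ", paste(utils::head(unmapped, 5), collapse = ", "))
  grp <- factor(cell_map[cells])
  t(rowsum(unclass(counts), grp))
}
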