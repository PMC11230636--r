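# two-subtype expression builder: `sep` genes separate the groups, the
# rest are noise
sep_expr <- function(n_per = 30, n_noise = 20, n_sep = 1, lfc = 3,
                     sd = 0.4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  genes <- c(sprintf("SEP%d", seq_len(n_sep)),
             sprintf("NOISE%02d", seq_len(n_noise)))
  base <- runif(length(genes), 4, 6)
  eff <- c(rep(lfc, n_sep), rep(0, n_noise))
  grp <- rep(c(0, 1), each = n_per)
  y <- base + outer(eff, grp) + matrix(rnorm(length(genes) * n, sd = sd),
                                       length(genes), n)
  expr <- 2^y - 1
  dimnames(expr) <- list(genes, sprintf("s%03d", 1:n))
  labels <- setNames(rep(c("CLASS A", "CLASS B"), each = n_per),
                     colnames(expr))
  list(expr = expr, labels = labels)
}

test_that("confusion metrics reproduce the printed formulas", {
  m <- classifier_metrics(tp = 50, tn = 40, fp = 10, fn = 0)
  expect_equal(m$ACC, 0.90)
  expect_equal(m$SEN, 1.00)
  expect_equal(m$SPE, 0.80)
  expect_equal(m$MCC, 2000 / sqrt(50 * 50 * 60 * 40), tolerance = 1e-12)
  expect_equal(m$MCC, 0.8165, tolerance = 1e-4)

  perfect <- classifier_metrics(30, 30, 0, 0)
  expect_equal(c(perfect$ACC, perfect$SEN, perfect$SPE, perfect$MCC),
               c(1, 1, 1, 1))
  # inverting predictions flips the MCC sign
  inv <- classifier_metrics(tp = 0, tn = 0, fp = 30, fn = 30)
  expect_equal(inv$MCC, -1)
  m2 <- classifier_metrics(20, 10, 5, 7)
  m2_inv <- classifier_metrics(tp = 7, tn = 5, fp = 10, fn = 20)
  expect_equal(m2_inv$MCC, -m2$MCC)
  # degenerate denominator convention
  expect_equal(classifier_metrics(0, 10, 0, 0)$MCC, 0)
})

test_that("chance-level predictions give MCC near zero", {
  set.seed(21)
  mccs <- replicate(50, {
    truth <- sample(rep(c("A", "B"), 30))
    pred <- sample(rep(c("A", "B"), 30))
    metrics_from_labels(truth, pred, positive = "B")$MCC
  })
  expect_lt(abs(mean(mccs)), 0.1)
})

test_that("candidate selection applies both the p and fold-change criteria", {
  d <- sep_expr(n_sep = 2, n_noise = 15, seed = 2)
  cand <- select_candidates(d$expr, d$labels)
  expect_true(all(c("SEP1", "SEP2") %in% cand))
  expect_false(any(grepl("NOISE", cand)))
  tab <- attr(cand, "table")
  # significant but sub-fold-change genes are excluded
  weak <- tab[abs(tab$log2fc) <= 1 & tab$p_adjusted < 0.001, "gene_id"]
  expect_true(all(!weak %in% cand))
})

test_that("mean-interval filter retains only genes with disjoint subtype intervals", {
  # constructed profiles: disjoint [4,6]/[7,9], overlapping [4,6]/[5,7],
  # touching [4,6]/[6,8]
  mk <- function(mu1, mu2) {
    v <- c(mu1 - 1, mu1, mu1, mu1 + 1, mu2 - 1, mu2, mu2, mu2 + 1)
    2^v - 1
  }
  expr <- rbind(disjoint = mk(5, 8), overlap = mk(5, 6), touch = mk(5, 7))
  colnames(expr) <- paste0("s", 1:8)
  labels <- setNames(rep(c("CLASS A", "CLASS B"), each = 4),
                     colnames(expr))
  # sample sd of (mu-1, mu, mu, mu+1) is sqrt(2/3); widen to sd 1 via
  # explicit check of the implementation's intervals instead
  keep <- mean_interval_filter(expr, labels, rownames(expr))
  iv <- attr(keep, "intervals")
  expect_true(iv$disjoint[iv$gene_id == "disjoint"])
  expect_false(iv$disjoint[iv$gene_id == "overlap"])
  expect_equal(sort(unname(keep)), sort(iv$gene_id[iv$disjoint]))

  # touching endpoints count as overlapping: build exact point intervals
  expr2 <- rbind(g1 = 2^c(4, 4, 6, 6) - 1)   # sd > 0 both groups? no: sd 0
  colnames(expr2) <- paste0("s", 1:4)
  lab2 <- setNames(c("A", "A", "B", "B"), colnames(expr2))
  keep2 <- mean_interval_filter(expr2, lab2, "g1")
  expect_equal(as.character(keep2), "g1")    # point intervals 4 and 6 disjoint
  expr3 <- rbind(g1 = 2^c(5, 5, 5, 5) - 1)   # identical point intervals
  colnames(expr3) <- paste0("s", 1:4)
  keep3 <- mean_interval_filter(expr3, lab2, "g1")
  expect_equal(length(keep3), 0L)
})

test_that("elastic net keeps a single perfect separator among noise", {
  for (s in 1:3) {
    d <- sep_expr(n_sep = 1, n_noise = 25, seed = s)
    panel <- sparse_panel_selection(d$expr, d$labels,
                                    rownames(d$expr), seed = s)
    expect_true("SEP1" %in% panel)
  }
  # deterministic given the seed
  d <- sep_expr(n_sep = 1, n_noise = 25, seed = 7)
  p1 <- sparse_panel_selection(d$expr, d$labels, rownames(d$expr), seed = 3)
  p2 <- sparse_panel_selection(d$expr, d$labels, rownames(d$expr), seed = 3)
  expect_identical(p1, p2)
})

test_that("an over-penalized fit falls back to the full gene set", {
  d <- sep_expr(n_sep = 1, n_noise = 10, seed = 4)
  expect_warning(
    panel <- sparse_panel_selection(d$expr, d$labels, rownames(d$expr),
                                    seed = 1, lambda = c(1e6, 9e5)),
    "falling back")
  expect_setequal(panel, rownames(d$expr))
})

test_that("training, held-out metrics, and prediction consistency", {
  d <- sep_expr(n_sep = 3, n_noise = 10, lfc = 3, seed = 5)
  fit <- train_and_evaluate(d$expr, d$labels,
                            panel = c("SEP1", "SEP2", "SEP3"), seed = 1)
  expect_gte(fit$metrics$ACC, 0.95)
  expect_equal(length(fit$train_ids), round(0.7 * 60))
  # training profiles reproduce their fitted labels
  pred_tr <- predict_subtype(fit$model,
                             d$expr[, fit$train_ids, drop = FALSE])
  expect_gte(mean(pred_tr$class == d$labels[fit$train_ids]), 0.95)
  # determinism of the whole selection + training path
  fit2 <- train_and_evaluate(d$expr, d$labels,
                             panel = c("SEP1", "SEP2", "SEP3"), seed = 1)
  expect_identical(fit$metrics, fit2$metrics)
  expect_identical(fit$test_ids, fit2$test_ids)

  # missing panel gene is a named error
  expect_error(predict_subtype(fit$model,
                               d$expr[c("SEP1", "SEP2"), , drop = FALSE]),
               "SEP3")
})

test_that("pseudo-bulk sums per-sample cell expression", {
  counts <- matrix(c(1, 2, 3,
                     1, 2, 3,
                     10, 0, 5), 3, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"), c("gA", "gB", "gC")))
  map <- c(c1 = "s1", c2 = "s1", c3 = "s2")
  pb <- pseudobulk(counts, map)
  expect_equal(pb[, "s1"], c(gA = 2, gB = 4, gC = 6))  # two identical cells double
  expect_equal(pb[, "s2"], c(gA = 10, gB = 0, gC = 5)) # one cell passes through
  # permutation invariance over cells
  pb2 <- pseudobulk(counts[c(3, 1, 2), ], map)
  expect_equal(pb2[, colnames(pb)], pb)
  expect_error(pseudobulk(counts, map[1:2]), "unmapped")
})

test_that("pseudo-bulk profiles flow through the classifier", {
  d <- sep_expr(n_sep = 2, n_noise = 5, seed = 6)
  fit <- train_and_evaluate(d$expr, d$labels, panel = c("SEP1", "SEP2"),
                            seed = 2)
  # build single-cell counts whose per-sample sums equal held-out profiles
  test_expr <- d$expr[, fit$test_ids[1:4], drop = FALSE]
  cells <- do.call(rbind, lapply(seq_len(4), function(i)
    rbind(t(test_expr[, i] / 2), t(test_expr[, i] / 2))))
  rownames(cells) <- sprintf("cell%02d", seq_len(nrow(cells)))
  map <- setNames(rep(fit$test_ids[1:4], each = 2), rownames(cells))
  pb <- pseudobulk(cells, map)
  pred <- predict_subtype(fit$model, pb)
  expect_equal(setNames(pred$class, pred$sample_id)[fit$test_ids[1:4]],
               setNames(d$labels[fit$test_ids[1:4]], fit$test_ids[1:4]))
})
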