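test_that("differential expression: null, low-abundance and threshold logic", {
  set.seed(1)
  base <- matrix(runif(40, 2, 4), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("t", 1:10)))
  tum <- om(base); nrm <- om(base, samples = paste0("n", 1:10))
  de <- differential_expression(tum, nrm)
  expect_false(any(de$is_deg))                  # identical groups
  expect_true(all(de$p_value == 1 | de$p_value > 0.9))

  # strong shift but means < 1 in both groups -> excluded
  lowt <- om(matrix(0.8, 1, 10)); lown <- om(matrix(0.1, 1, 10))
  de2 <- differential_expression(lowt, lown)
  expect_false(de2$is_deg)

  expect_error(differential_expression(om(matrix(1, 2, 1)), tum),
               "2 samples")
})

test_that("planted fold changes are recovered with high recall", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    set.seed(s)
    n_gene <- 80; n_planted <- 25
    baseline <- runif(n_gene, 3, 8)
    eff <- c(rep(2, n_planted), rep(0, n_gene - n_planted))
    yt <- baseline + eff + matrix(rnorm(n_gene * 50, sd = 0.5), n_gene)
    yn <- baseline + matrix(rnorm(n_gene * 50, sd = 0.5), n_gene)
    de <- differential_expression(om(2^yt - 1), om(2^yn - 1))
    hits <- hits + sum(de$is_deg[seq_len(n_planted)])
    total <- total + n_planted
  }
  expect_gte(hits / total, 0.9)
})

test_that("DMP calling enforces the strict delta-beta threshold", {
  set.seed(2)
  bt <- matrix(runif(200, 0.3, 0.32), 2, 100)
  bn <- bt
  bt[1, ] <- bn[1, ] + 0.19      # huge p, |delta| = 0.19 -> not a DMP
  bt[2, ] <- bn[2, ] + 0.30      # planted shift 0.3 -> DMP
  dmp <- call_dmps(om(bt, "methylation_beta"), om(bn, "methylation_beta",
                                                  samples = paste0("n", 1:100)))
  expect_false(dmp$is_dmp[1])
  expect_lt(dmp$p_adjusted[1], 0.05)           # significant but sub-threshold
  expect_true(dmp$is_dmp[2])

  same <- om(matrix(runif(100, 0.4, 0.6), 1, 100), "methylation_beta")
  dmp0 <- call_dmps(same, om(unclass(same), "methylation_beta",
                             samples = paste0("n", 1:100)))
  expect_false(any(dmp0$is_dmp))
})

test_that("CNV gain/loss groups use the strict 20% rule", {
  v <- matrix(0, 3, 100)
  v[1, 1:25] <- 1.5     # 25% above +1 -> gain
  v[2, 1:20] <- 1.5     # exactly 20% -> neither
  cf <- classify_cnv_groups(om(v, "cnv_gene"))
  expect_equal(cf$group, c("gain", "neither", "neither"))
  expect_false(any(classify_cnv_groups(om(matrix(0, 1, 10), "cnv_gene"))$gain))
})

test_that("Spearman evidence matches monotone limits and a hand-ranked oracle", {
  x <- seq_len(10); y <- x^2
  reg <- om(rbind(up = x, down = rev(x)))
  tgt <- om(rbind(t1 = y), samples = colnames(reg))
  pairs <- data.frame(regulator_id = c("up", "down"), target_id = "t1")
  res <- correlate_regulator_target(pairs, reg, tgt)
  expect_equal(res$rho, c(1, -1))

  # 8-point sample with ties; average ranks written out by hand
  xv <- c(1, 2, 2, 4, 5, 6, 7, 8)
  yv <- c(3, 1, 4, 4, 6, 8, 7, 9)
  rx <- c(1, 2.5, 2.5, 4, 5, 6, 7, 8)
  ry <- c(2, 1, 3.5, 3.5, 5, 7, 6, 8)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res2 <- correlate_regulator_target(
    data.frame(regulator_id = "r", target_id = "t"),
    om(rbind(r = xv)), om(rbind(t = yv)))
  expect_equal(res2$rho, rho_oracle, tolerance = 1e-12)

  expect_warning(correlate_regulator_target(
    data.frame(regulator_id = "r", target_id = "t"),
    om(rbind(r = rep(1, 8))), om(rbind(t = yv))), "constant")
})

test_that("DDG assembly requires DEG status plus passing evidence", {
  set.seed(3)
  n <- 40; samples <- paste0("s", 1:n)
  grp <- rep(c(0, 1), each = n / 2)
  # geneA: DEG with anti-correlated promoter probe; geneB: DEG without
  # evidence; geneC: strong evidence but not a DEG
  expr <- rbind(geneA = 50 + 200 * grp + rnorm(n),
                geneB = 50 + 200 * grp + rnorm(n),
                geneC = 50 + rnorm(n))
  nrm <- rbind(geneA = 50 + rnorm(n), geneB = 50 + rnorm(n),
               geneC = 50 + rnorm(n))
  beta <- rbind(p1 = 0.6 - 0.25 - 0.15 * grp + rnorm(n, sd = 0.02),
                p2 = 0.6 - 0.25 - 0.15 * grp + rnorm(n, sd = 0.02))
  beta_n <- rbind(p1 = 0.6 + rnorm(n, sd = 0.02),
                  p2 = 0.6 + rnorm(n, sd = 0.02))
  fam <- data.frame(family_id = "F1", gene_id = c("geneA", "geneB", "geneC"))
  de <- differential_expression(om(expr, samples = samples),
                                om(nrm, samples = paste0("n", 1:n)))
  dmps <- call_dmps(om(pmin(pmax(beta, 0), 1), "methylation_beta",
                       samples = samples),
                    om(pmin(pmax(beta_n, 0), 1), "methylation_beta",
                       samples = paste0("n", 1:n)))
  ann <- data.frame(probe_id = c("p1", "p2"), region = "promoter",
                    target_gene_id = c("geneA", "geneC"))
  out <- assemble_ddgs(de, fam, dmps, ann,
                       om(pmin(pmax(beta, 0), 1), "methylation_beta",
                          samples = samples),
                       expr_tumor = om(expr, samples = samples))
  expect_equal(out$ddgs, "geneA")
  expect_setequal(out$candidates, c("geneA", "geneB"))
  expect_equal(out$evidence$evidence_type, "promoter_meth")
  expect_lt(out$evidence$rho, -0.2)
  # invariants: DDG subset of DEG subset of family universe
  expect_true(all(out$ddgs %in% out$candidates))
  expect_true(all(out$candidates %in% fam$gene_id))
})

test_that("the default cohort yields DDGs covering the planted evidence genes", {
  co <- cached_cohort(seed = 1)
  de <- differential_expression(co$expression_tumor, co$expression_normal)
  dmps <- call_dmps(co$methylation, co$methylation_normal)
  dmi <- differential_expression(co$mirna, co$mirna_normal)
  cf <- classify_cnv_groups(co$cnv_gene)
  out <- assemble_ddgs(de, co$families, dmps, co$probe_annotation,
                       co$methylation, dmi, co$mirna, co$mirna_targets,
                       cf, co$cnv_gene, co$expression_tumor)
  expect_true(all(out$ddgs %in% co$truth$planted_degs))
  expect_gte(length(out$ddgs), 0.8 * length(co$truth$planted_degs))
  # every stored evidence row satisfies its own invariant
  expect_true(all(abs(out$evidence$rho) > 0.2))
  expect_true(all(out$evidence$p_adjusted < 0.05))
  # BH is monotone in the raw p ordering
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adjusted[ord]) >= -1e-15))
})
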