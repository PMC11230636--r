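test_that("binarization records presence, not multiplicity", {
  recs <- rbind(mut_df("s1", "G1", c(5, 9, 20)), mut_df("s2", "G2", 7))
  expect_warning(F0 <- binarize_mutations(recs, c("G1", "G2", "G3"),
                                          c("s1", "s2", "s3")),
                 "no mutation")
  expect_equal(F0["s1", "G1"], 1)
  expect_equal(sort(unique(as.vector(F0))), c(0, 1))
  expect_equal(unname(rowSums(F0)["s3"]), 0)
  expect_error(binarize_mutations(recs, character(0)), "nonempty")
})

test_that("network normalization is row-stochastic with self-retention", {
  net <- gene_network(data.frame(gene_a = "g1", gene_b = "g2"),
                      nodes = c("g1", "g2", "g3"))
  A <- normalize_network(net, c("g1", "g2", "g3"))
  expect_equal(unname(A[1:2, 1:2]), matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(A["g3", ]), c(0, 0, 1))   # isolated: self-indicator
  expect_equal(unname(rowSums(A)), rep(1, 3), tolerance = 1e-12)

  set.seed(5)
  genes <- paste0("g", 1:15)
  ed <- subset(expand.grid(gene_a = genes, gene_b = genes,
                           stringsAsFactors = FALSE),
               gene_a < gene_b & runif(15 * 15) < 0.3)
  ed$weight <- runif(nrow(ed), 0.5, 2)
  A2 <- normalize_network(gene_network(ed, nodes = genes), genes)
  expect_equal(unname(rowSums(A2)), rep(1, 15), tolerance = 1e-12)
})

test_that("alpha = 0 returns the raw mutation matrix", {
  F0 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("s1", "s2"), c("g1", "g2")))
  A <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  sm <- propagate(F0, A, alpha = 0)
  expect_equal(sm$F, F0)
})

test_that("the two-gene fixed point matches the closed form", {
  F0 <- matrix(c(1, 0), 1, 2, dimnames = list("p1", c("g1", "g2")))
  A <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  sm <- propagate(F0, A, alpha = 0.7)
  expect_equal(unname(sm$F[1, ]), c(0.3 / 0.51, 0.21 / 0.51),
               tolerance = 1e-6)
  expect_lt(sm$final_step_norm, 1e-6)
})

test_that("iterated propagation equals the matrix-inverse oracle and conserves mass", {
  for (s in 1:20) {
    set.seed(s)
    n_gene <- 20; n_pat <- 6
    W <- matrix(runif(n_gene^2) < 0.2, n_gene, n_gene) * runif(n_gene^2)
    W <- W + t(W); diag(W) <- 0
    dimnames(W) <- list(paste0("g", 1:n_gene), paste0("g", 1:n_gene))
    deg <- rowSums(W)
    A <- W / ifelse(deg == 0, 1, deg)
    iso <- which(deg == 0)
    if (length(iso)) A[cbind(iso, iso)] <- 1
    F0 <- matrix(rbinom(n_pat * n_gene, 1, 0.2), n_pat, n_gene,
                 dimnames = list(paste0("p", 1:n_pat), rownames(W)))
    sm <- propagate(F0, A, alpha = 0.7, tol = 1e-9, max_iter = 5000)
    oracle <- 0.3 * F0 %*% solve(diag(n_gene) - 0.7 * A)
    expect_lt(max(abs(sm$F - oracle)), 1e-8)
    expect_equal(rowSums(sm$F), rowSums(F0), tolerance = 1e-9)
  }
})

test_that("alpha = 1 and non-convergence are rejected", {
  F0 <- matrix(c(1, 0), 1, 2, dimnames = list("p", c("a", "b")))
  A <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(propagate(F0, A, alpha = 1), "alpha")
  expect_error(propagate(F0, A, alpha = 0.99, max_iter = 2), "converge")
})

test_that("z-scoring matches the population-sd example and its invariants", {
  x <- 2^c(2, 4, 6) - 1
  z <- zscore_expression(om(rbind(g = x)))
  expect_equal(unname(z[1, ]), c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  expect_warning(z0 <- zscore_expression(om(rbind(g = c(0, 0, 0)))),
                 "zero-variance")
  expect_equal(unname(z0[1, ]), c(0, 0, 0))

  set.seed(9)
  m <- om(matrix(runif(200, 0, 50), 10, 20))
  zz <- zscore_expression(m)
  expect_equal(unname(rowMeans(zz)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(sqrt(rowMeans(zz^2))), rep(1, 10), tolerance = 1e-9)
})
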