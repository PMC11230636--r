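test_that("TMB arithmetic and the strict hypermutator rule", {
  recs <- mut_df(rep("s1", 76), "G1", seq_len(76))
  expect_equal(compute_tmb(recs)$tmb, 2.0)
  expect_equal(compute_tmb(recs[0, ], sample_ids = "s1")$tmb, 0.0)
  recs2 <- mut_df(rep("s2", 1141), "G1", rep(1:500, length.out = 1141))
  expect_gt(compute_tmb(recs2)$tmb, 30)

  # exactly 30 mut/Mb (1140 mutations) is retained; 1141 is excluded
  both <- rbind(mut_df(rep("sA", 1140), "G1", rep(1:500, length.out = 1140)),
                recs2)
  fh <- filter_hypermutators(both)
  expect_true("sA" %in% fh$retained_samples)
  expect_equal(fh$excluded$sample_id, "s2")
  # no hypermutators -> identity
  fh2 <- filter_hypermutators(recs)
  expect_equal(nrow(fh2$mutations), 76)
  expect_equal(nrow(fh2$excluded), 0)
})

test_that("in-domain counting uses closed intervals and aggregates per gene", {
  dom <- data.frame(gene_id = c("A", "B"), domain_id = "D",
                    start_aa = 5, end_aa = 15, e_value = 0)
  recs <- rbind(mut_df("s1", "A", c(5, 10, 15)),   # all inside (boundaries)
                mut_df("s1", "A", c(4, 16)),        # outside
                mut_df("s2", "B", c(6, 7)))
  cnt <- map_mutations_to_domains(recs, dom)
  expect_equal(cnt$n_in_domain[cnt$gene_id == "A"], 3L)
  expect_equal(cnt$n_in_domain[cnt$gene_id == "B"], 2L)
  expect_equal(sum(cnt$n_in_domain), 5L)
})

test_that("entropy statistic hits its analytic limits and the derived case", {
  expect_equal(domain_entropy(c(5, 5, 5, 5)), 1.0)
  expect_equal(domain_entropy(c(8, 0, 0)), 0.0)
  expect_equal(domain_entropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
               tolerance = 1e-12)
  # invariances: gene order and positive scaling
  expect_equal(domain_entropy(c(1, 4, 2)), domain_entropy(c(4, 2, 1)))
  expect_equal(domain_entropy(c(2, 8, 4)), domain_entropy(c(1, 4, 2)))
  # degenerate cases
  expect_equal(domain_entropy(7), 0)                   # single carrier
  expect_true(is.na(domain_entropy(c(0, 0))))          # no mutations
  expect_true(attr(domain_entropy(c(0, 0)), "flagged"))
})

test_that("permutation p-value respects the +1 formula floor and ceiling", {
  # observed exceeds anything 999 permutations can produce
  p_floor <- permutation_test_domain(observed = 100,
                                     gene_totals = c(A = 10),
                                     gene_lengths = c(A = 1000),
                                     domain_residues = c(A = 10),
                                     n_perm = 999, seed = 1)
  expect_equal(as.numeric(p_floor), 1 / 1000)
  # observed of 0 is never beaten
  p_ceil <- permutation_test_domain(0, c(A = 10), c(A = 1000), c(A = 10),
                                    n_perm = 999, seed = 1)
  expect_equal(as.numeric(p_ceil), 1.0)
  # zero mutations -> flagged p = 1
  p0 <- permutation_test_domain(0, c(A = 0), c(A = 100), c(A = 10),
                                n_perm = 99)
  expect_true(attr(p0, "flagged"))
})

test_that("permutation p converges to the exact binomial null probability", {
  # one gene, protein length 4, domain of 2 residues, 1 observed in-domain
  # mutation: exact null P(X >= 1) = 0.5
  p <- permutation_test_domain(1, c(A = 1), c(A = 4), c(A = 2),
                               n_perm = 9999, seed = 42)
  expect_equal(as.numeric(p), 0.5, tolerance = 3 * sqrt(0.25 / 9999) + 1e-4)
})

test_that("p is monotone decreasing in the observed count at fixed stream", {
  ps <- vapply(0:10, function(obs)
    as.numeric(permutation_test_domain(obs, c(A = 20, B = 15),
                                       c(A = 500, B = 400),
                                       c(A = 50, B = 50),
                                       n_perm = 499, seed = 7)),
    numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("seeded permutation runs are bit-reproducible", {
  args <- list(12, c(A = 30, B = 10), c(A = 300, B = 200),
               c(A = 40, B = 30), 999, 11)
  expect_identical(do.call(permutation_test_domain, args),
                   do.call(permutation_test_domain, args))
})

test_that("stratification genes require a mutation in a significant high-entropy domain", {
  burden <- data.frame(domain_id = c("D1", "D2", "D3"),
                       p_adjusted = c(0.01, 0.01, 0.20),
                       entropy_S = c(0.6, 0.4, 0.9))
  counts <- data.frame(domain_id = c("D1", "D1", "D2", "D3"),
                       gene_id = c("g1", "g2", "g3", "g4"),
                       n_in_domain = c(2L, 0L, 5L, 5L))
  sel <- select_stratification_genes(burden, counts)
  # g1: mutated in qualifying D1; g2: zero mutations; g3: low entropy;
  # g4: not significant
  expect_equal(sel, "g1")
})

test_that("the cohort's hotspot domains are recovered and the decoy is entropy-filtered", {
  co <- cached_cohort(seed = 1)
  b <- test_domain_burden(co$mutations, co$domains, co$protein_lengths,
                          n_perm = 999, seed = 1)
  hot <- b[b$domain_id %in% co$truth$hotspot_domains, ]
  expect_true(all(hot$significant & hot$high_entropy))
  decoy <- b[b$domain_id == co$truth$decoy_domain, ]
  expect_true(decoy$significant)
  expect_false(decoy$high_entropy)
  sg <- select_stratification_genes(b)
  per_gene <- attr(b, "per_gene")
  hot_mutated <- per_gene$gene_id[per_gene$domain_id %in%
                                    co$truth$hotspot_domains &
                                  per_gene$n_in_domain >= 1]
  expect_true(all(hot_mutated %in% sg))
  expect_true(length(sg) >= 15)
})
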