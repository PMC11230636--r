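test_that("CIN ratio follows the strict alteration rule", {
  scores <- c(rep(0.5, 10), rep(0, 29))
  names(scores) <- paste0("arm", seq_along(scores))
  r <- cin_ratio(scores)
  expect_equal(r$cin_ratio, 10 / 39)
  expect_equal(r$n_arms_total, 39)

  # exactly 0.1 / -0.1 are not alterations
  r2 <- cin_ratio(setNames(c(0.1, -0.1, 0.100001, -0.2), paste0("a", 1:4)))
  expect_equal(r2$n_arms_altered, 2)
  expect_equal(cin_ratio(setNames(rep(0, 5), paste0("a", 1:5)))$cin_ratio, 0)
  expect_error(cin_ratio(numeric(0)), "empty")

  # missing arms leave both numerator and denominator
  m <- matrix(c(0.5, NA, 0, 0.2), 2, 2,
              dimnames = list(c("1p", "1q"), c("s1", "s2")))
  r3 <- cin_ratio(om(m, "cnv_arm", features = c("1p", "1q"),
                     samples = c("s1", "s2")))
  expect_equal(r3$n_arms_total, c(1, 2))
  expect_equal(r3$cin_ratio, c(1, 0.5))
})

test_that("planted subtype-B instability exceeds subtype A", {
  co <- cached_cohort(seed = 1)
  r <- cin_ratio(co$cnv_arm)
  lab <- co$truth$labels[r$sample_id]
  expect_gt(mean(r$cin_ratio[lab == "B"]), mean(r$cin_ratio[lab == "A"]))
})

test_that("mutation association tests match exact-hypergeometric and null expectations", {
  # small cohort: 5/15 vs 0/15 has expected counts < 5, so Fisher's exact
  # test is used; oracle by exhaustive hypergeometric enumeration (only
  # k = 0 and k = 5 have point probability <= the observed table's)
  asg <- data.frame(sample_id = sprintf("s%03d", 1:30),
                    class = rep(c("CLASS A", "CLASS B"), each = 15))
  bm <- matrix(0, 30, 1, dimnames = list(asg$sample_id, "exclusive"))
  bm[1:5, "exclusive"] <- 1
  res <- mutation_association(asg, bm)
  expect_equal(res$test, "fisher_exact")
  p_oracle <- sum(vapply(c(0, 5), function(k)
    choose(15, k) * choose(15, 5 - k) / choose(30, 5), numeric(1)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(res$`total_CLASS A`, 15)
  expect_equal(res$`total_CLASS B`, 15)

  # large balanced cohort: chi-square branch, no association
  asg2 <- data.frame(sample_id = sprintf("s%03d", 1:120),
                     class = rep(c("CLASS A", "CLASS B"), each = 60))
  bm2 <- matrix(0, 120, 1, dimnames = list(asg2$sample_id, "balanced"))
  bm2[seq(1, 120, 2), "balanced"] <- 1        # 30/60 vs 30/60
  res2 <- mutation_association(asg2, bm2)
  expect_equal(res2$test, "chi_square")
  expect_gt(res2$p_value, 0.9)
})

test_that("features mutated nowhere are skipped", {
  asg <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    class = rep(c("A", "B"), 2))
  bm <- matrix(0, 4, 2, dimnames = list(asg$sample_id, c("f1", "f2")))
  bm[, "f1"] <- c(1, 1, 0, 0)
  res <- mutation_association(asg, bm)
  expect_equal(res$feature_id, "f1")
})

test_that("log-rank statistic matches a hand-computed observed-expected table", {
  # 6 subjects; group 1 dies at 1, 3, 5; group 2 dies at 2, 4, censored 6.
  # O1 = 3; E1 = 1/2 + 2/5 + 1/2 + 1/3 + 1/2 = 2.23333;
  # V = 9/36 + 6/25 + 1/4 + 2/9 + 1/4 = 1.21222; chi = 0.76667^2 / V
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     time_months = 1:6,
                     event = c(1, 1, 1, 1, 1, 0))
  asg <- data.frame(sample_id = paste0("s", 1:6),
                    class = rep(c("g1", "g2"), 3))
  res <- logrank_compare(surv, asg)
  chi_hand <- (3 - (0.5 + 0.4 + 0.5 + 1 / 3 + 0.5))^2 /
    (0.25 + 0.24 + 0.25 + 2 / 9 + 0.25)
  expect_equal(res$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(unname(res$medians), c(3, 4))
})

test_that("log-rank edge cases and power at the planted hazard ratio", {
  surv <- data.frame(sample_id = paste0("s", 1:4), time_months = 1:4,
                     event = 0)
  asg <- data.frame(sample_id = paste0("s", 1:4), class = rep(c("a", "b"), 2))
  expect_error(logrank_compare(surv, asg), "no events")

  # identical survival with random labels: statistic near zero
  set.seed(11)
  t0 <- rexp(80, 0.05)
  surv0 <- data.frame(sample_id = paste0("s", 1:80), time_months = t0,
                      event = 1)
  asg0 <- data.frame(sample_id = paste0("s", 1:80),
                     class = sample(rep(c("a", "b"), 40)))
  expect_gt(logrank_compare(surv0, asg0)$p_value, 0.01)

  # planted hazard ratio 2 at n = 60/60 with ~30% censoring is detected
  # in the large majority of simulations (analytic power ~0.9 at these
  # event counts)
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    lam <- rep(c(0.03, 0.06), each = 60)
    te <- rexp(120, lam); tc <- rexp(120, 0.015)
    sv <- data.frame(sample_id = sprintf("s%03d", 1:120),
                     time_months = pmin(te, tc),
                     event = as.integer(te <= tc))
    ag <- data.frame(sample_id = sv$sample_id,
                     class = rep(c("A", "B"), each = 60))
    hits <- hits + (logrank_compare(sv, ag)$p_value < 0.05)
  }
  expect_gte(hits / 40, 0.75)
})

test_that("adjusted Rand index matches pair-counting limits and oracle", {
  expect_equal(truth_ari(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1.0)
  expect_equal(truth_ari(rep(1, 8), rep(c(1, 2), 4)), 0.0)
  # frozen exhaustive pair-count value for two fixed 6-item partitions
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(truth_ari(a, b), -1 / 9, tolerance = 1e-12)
  skip_if_not_installed("mclust")
  expect_equal(truth_ari(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
  expect_error(truth_ari(1:3, 1:4), "equal length")
})
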