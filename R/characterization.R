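# Subtype characterization: chromosomal-instability ratios, mutation and
# domain association tests, and survival separation.

#' Chromosomal-instability ratio per sample
#'
#' An arm is altered iff its CNV score is strictly greater than
#' `threshold` or strictly smaller than `-threshold`; the CIN ratio is
#' the altered-arm count over the number of arms with a score. Arms with
#' missing scores are excluded from numerator and denominator.
#'
#' @param arm_scores arm-level CNV matrix (arms x samples) or a single
#'   named score vector for one sample.
#' @param threshold alteration threshold (default 0.1, strict).
#' @return data.frame `sample_id`, `n_arms_total`, `n_arms_altered`,
#'   `cin_ratio`.
#' @export
cin_ratio <- function(arm_scores, threshold = 0.1) {
  if (is.null(dim(arm_scores)))
    arm_scores <- matrix(arm_scores, ncol = 1,
                         dimnames = list(names(arm_scores), "sample"))
  v <- unclass(arm_scores)
  if (!nrow(v)) stop("empty arm score input")
  tot <- colSums(!is.na(v))
  if (any(tot == 0)) stop("sample(s) with no scored arms")
  alt <- colSums(!is.na(v) & (v > threshold | v < -threshold))
  data.frame(sample_id = colnames(v),
             n_arms_total = unname(tot), n_arms_altered = unname(alt),
             cin_ratio = unname(alt / tot),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between subtype and binary mutation features
#'
#' Per feature, a subtype x mutated contingency table is tested with the
#' chi-square test (continuity-corrected when 2x2); Fisher's exact test
#' is substituted when any expected cell count is below 5. Features
#' mutated in no sample are skipped; BH adjustment across tested
#' features.
#'
#' @param assignment a `subtype_assignment` or data.frame with
#'   `sample_id`, `class`.
#' @param binmat binary matrix, samples x features.
#' @return data.frame with per-feature per-class mutated counts and
#'   totals, `test`, `p_value`, `p_adjusted`.
#' @export
mutation_association <- function(assignment, binmat) {
  if (inherits(assignment, "subtype_assignment"))
    assignment <- assignment$assignment
  ids <- intersect(assignment$sample_id, rownames(binmat))
  cls <- factor(assignment$class[match(ids, assignment$sample_id)])
  if (nlevels(cls) < 2) stop("need at least two subtypes")
  bm <- unclass(binmat)[ids, , drop = FALSE]
  sizes <- table(cls)
  rows <- lapply(colnames(bm), function(f) {
    mut <- bm[, f] > 0
    if (!any(mut)) return(NULL)
    tab <- rbind(mutated = tapply(mut, cls, sum),
                 unmutated = tapply(!mut, cls, sum))
    stopifnot(all(colSums(tab) == as.integer(sizes)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test <- "fisher_exact"
      p <- stats::fisher.test(tab)$p.value
    } else {
      test <- "chi_square"
      p <- suppressWarnings(
        stats::chisq.test(tab, correct = nrow(tab) == 2 &&
                                         ncol(tab) == 2)$p.value)
    }
    out <- data.frame(feature_id = f, test = test, p_value = p,
                      stringsAsFactors = FALSE)
    for (l in levels(cls)) {
      out[[paste0("mutated_", l)]] <- tab["mutated", l]
      out[[paste0("total_", l)]] <- sum(tab[, l])
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no feature mutated in any sample")
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Log-rank comparison of survival between subtypes
#'
#' Standard log-rank test over the pooled event times plus per-group
#' Kaplan-Meier medians (smallest time at which the KM estimate drops to
#' 0.5 or below; `NA` when never reached).
#'
#' @param survival_df data.frame `sample_id`, `time_months`, `event`.
#' @param assignment a `subtype_assignment` or data.frame `sample_id`,
#'   `class`.
#' @return list with `statistic` (log-rank chi-square), `df`, `p_value`,
#'   `medians` (named per group), `n`, `events`.
#' @export
logrank_compare <- function(survival_df, assignment) {
  if (inherits(assignment, "subtype_assignment"))
    assignment <- assignment$assignment
  df <- merge(survival_df, assignment[, c("sample_id", "class")],
              by = "sample_id")
  if (length(unique(df$class)) < 2) stop("need at least two groups")
  if (sum(df$event) == 0) stop("no events")
  sd_fit <- survival::survdiff(
    survival::Surv(time_months, event) ~ class, data = df)
  dfree <- length(sd_fit$n) - 1
  p <- stats::pchisq(sd_fit$chisq, df = dfree, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ class,
                          data = df)
  st <- summary(sf)$table
  med <- if (is.null(dim(st))) st["median"] else
    setNames(st[, "median"], sub("^class=", "", rownames(st)))
  list(statistic = unname(sd_fit$chisq), df = dfree, p_value = p,
       medians = med, n = nrow(df), events = sum(df$event))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' approximately 0 for independent ones. Used to score recovery of
#' planted subtype labels.
#'
#' @param a,b label vectors of equal length (names are ignored; order
#'   aligns the samples).
#' @return ARI in `[-1, 1]`.
#' @export
truth_ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}
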