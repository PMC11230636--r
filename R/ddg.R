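# Driver-dysregulated gene (DDG) discovery: Mann-Whitney differential
# testing, DMP calling, CNV gain/loss grouping, Spearman evidence
# screening, and the union/intersection assembly rule.

.mwu_p <- function(x, y) {
  # two-sided Mann-Whitney U, normal approximation with tie and continuity
  # correction; degenerate all-equal input yields p = 1
  if (length(unique(c(x, y))) == 1L) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  if (is.na(p)) 1 else p
}

#' Mann-Whitney differential expression between two sample groups
#'
#' Per shared feature: two-sided Mann-Whitney U p-value (normal
#' approximation with tie and continuity correction), BH adjustment across
#' features, and `log2fc = log2((mean_test + 1) / (mean_control + 1))` on
#' the raw scale. A feature is differential (`is_deg`) iff
#' `|log2fc| > fc_cut`, `p_adjusted < p_cut`, and its mean is at least
#' `min_mean` in at least one group (low-abundance exclusion).
#'
#' Used for tumor-vs-normal mRNA/miRNA calls and, with stricter
#' thresholds, for subtype-vs-subtype classifier candidates.
#'
#' @param test,control `omics_matrix` (or matrix) feature x sample; the
#'   shared feature set is tested.
#' @param p_cut adjusted-p threshold (default 0.05).
#' @param fc_cut absolute log2 fold-change threshold (default 1).
#' @param min_mean mean-abundance floor (default 1; set to `-Inf` to
#'   disable for non-abundance data).
#' @return data.frame with `gene_id`, `mean_test`, `mean_control`,
#'   `log2fc`, `p_value`, `p_adjusted`, `is_deg`.
#' @export
differential_expression <- function(test, control, p_cut = 0.05,
                                    fc_cut = 1, min_mean = 1) {
  if (ncol(test) < 2 || ncol(control) < 2)
    stop("each group needs at least 2 samples")
  feats <- intersect(rownames(test), rownames(control))
  if (!length(feats)) stop("no shared features between the groups")
  tv <- unclass(test)[feats, , drop = FALSE]
  cv <- unclass(control)[feats, , drop = FALSE]
  p <- vapply(feats, function(g) .mwu_p(tv[g, ], cv[g, ]), numeric(1))
  mt <- rowMeans(tv); mc <- rowMeans(cv)
  lfc <- log2((mt + 1) / (mc + 1))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = feats,
             mean_test = unname(mt), mean_control = unname(mc),
             log2fc = unname(lfc), p_value = unname(p),
             p_adjusted = unname(padj),
             is_deg = unname(abs(lfc) > fc_cut & padj < p_cut &
                             pmax(mt, mc) >= min_mean),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially methylated probes
#'
#' Per shared probe: `delta_beta = mean_tumor - mean_normal`, Mann-Whitney
#' p-value with BH adjustment; a probe is a DMP iff
#' `|delta_beta| > delta_cutoff` and `p_adjusted < p_cut`.
#'
#' @param beta_tumor,beta_normal methylation beta matrices (probe x
#'   sample).
#' @param delta_cutoff absolute mean-difference threshold (default 0.2).
#' @param p_cut adjusted-p threshold (default 0.05).
#' @return data.frame with `probe_id`, `mean_tumor`, `mean_normal`,
#'   `delta_beta`, `p_value`, `p_adjusted`, `is_dmp`.
#' @export
call_dmps <- function(beta_tumor, beta_normal, delta_cutoff = 0.2,
                      p_cut = 0.05) {
  if (ncol(beta_tumor) < 2 || ncol(beta_normal) < 2)
    stop("each group needs at least 2 samples")
  probes <- intersect(rownames(beta_tumor), rownames(beta_normal))
  if (!length(probes)) stop("no shared probes")
  tv <- unclass(beta_tumor)[probes, , drop = FALSE]
  nv <- unclass(beta_normal)[probes, , drop = FALSE]
  p <- vapply(probes, function(pr) .mwu_p(tv[pr, ], nv[pr, ]), numeric(1))
  mt <- rowMeans(tv); mn <- rowMeans(nv)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(probe_id = probes,
             mean_tumor = unname(mt), mean_normal = unname(mn),
             delta_beta = unname(mt - mn),
             p_value = unname(p), p_adjusted = unname(padj),
             is_dmp = unname(abs(mt - mn) > delta_cutoff & padj < p_cut),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes into copy-number gain/loss groups
#'
#' A gene is in the gain group iff strictly more than `frac` of samples
#' have a CNV score strictly greater than `gain_level`; the loss group is
#' symmetric with `loss_level`. A gene can be flagged as both.
#'
#' @param cnv_gene gene-level CNV score matrix (gene x sample).
#' @param gain_level,loss_level score thresholds (defaults +1 / -1).
#' @param frac strict sample-fraction threshold (default 0.2).
#' @return data.frame `gene_id`, `gain_frac`, `loss_frac`, `gain`,
#'   `loss`, `group` (`gain`, `loss`, `both`, `neither`).
#' @export
classify_cnv_groups <- function(cnv_gene, gain_level = 1, loss_level = -1,
                                frac = 0.2) {
  v <- unclass(cnv_gene)
  gf <- rowMeans(v > gain_level)
  lf <- rowMeans(v < loss_level)
  gain <- gf > frac
  loss <- lf > frac
  data.frame(gene_id = rownames(v),
             gain_frac = unname(gf), loss_frac = unname(lf),
             gain = unname(gain), loss = unname(loss),
             group = unname(ifelse(gain & loss, "both",
                            ifelse(gain, "gain",
                            ifelse(loss, "loss", "neither")))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman screen of regulator-target pairs
#'
#' For each (regulator, target) pair: Spearman rank correlation with
#' average-rank tie handling over the shared tumor samples, two-sided
#' p-value by the asymptotic t-approximation, and BH adjustment across all
#' pairs in the batch. Pairs with a constant vector are skipped with a
#' warning.
#'
#' @param pairs data.frame with columns `regulator_id`, `target_id`.
#' @param regulator_values matrix with regulators in rows (beta, miRNA
#'   abundance, or CNV score) over tumor samples.
#' @param target_values matrix with target genes in rows (expression) over
#'   the same samples (columns matched by name).
#' @return `pairs` with added `n`, `rho`, `p_value`, `p_adjusted`.
#' @export
correlate_regulator_target <- function(pairs, regulator_values,
                                       target_values) {
  shared <- intersect(colnames(regulator_values), colnames(target_values))
  if (length(shared) < 5) stop("need >= 5 shared samples")
  rv <- unclass(regulator_values)[, shared, drop = FALSE]
  tv <- unclass(target_values)[, shared, drop = FALSE]
  rho <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- rv[pairs$regulator_id[i], ]
    t <- tv[pairs$target_id[i], ]
    if (stats::sd(r) == 0 || stats::sd(t) == 0) {
      warning("constant vector for pair ", pairs$regulator_id[i], " ~ ",
              pairs$target_id[i], "; skipped")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(r, t, method = "spearman", exact = FALSE))
    rho[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  pairs$n <- length(shared)
  pairs$rho <- rho
  pairs$p_value <- p
  pairs$p_adjusted <- stats::p.adjust(p, method = "BH")
  pairs
}

#' Assemble driver-dysregulated genes
#'
#' A candidate is a differentially expressed gene that belongs to a gene
#' family. A candidate becomes a DDG iff at least one evidence link passes
#' the correlation threshold (`|rho| > rho_cut`, BH-adjusted p <
#' `alpha`, adjusted within each evidence batch):
#' \itemize{
#'   \item a DMP annotated to the gene (promoter / gene body / distal
#'     enhancer) whose beta correlates with the gene's tumor expression;
#'   \item a differentially expressed miRNA listed as targeting the gene
#'     whose abundance correlates with the gene's expression;
#'   \item a gain/loss CNV flag with the gene's CNV score correlating with
#'     its expression.
#' }
#' With `combine = "intersection"` a DDG must instead carry passing
#' evidence in every omics modality. No sign constraint is placed on rho;
#' the direction is reported for downstream filtering.
#'
#' @param deg result of [differential_expression()] on tumor vs normal
#'   mRNA.
#' @param families data.frame `family_id`, `gene_id` (family membership).
#' @param dmps result of [call_dmps()].
#' @param probe_annotation data.frame `probe_id`, `region`,
#'   `target_gene_id`.
#' @param beta_tumor tumor methylation matrix (probe x sample).
#' @param dmi [differential_expression()] result on tumor-vs-normal miRNA.
#' @param mirna_tumor tumor miRNA matrix.
#' @param mirna_targets data.frame `mirna_id`, `gene_id`.
#' @param cnv_flags result of [classify_cnv_groups()].
#' @param cnv_gene gene-level CNV matrix.
#' @param expr_tumor tumor expression matrix.
#' @param rho_cut,alpha evidence thresholds (defaults 0.2 / 0.05).
#' @param combine `"union"` (any evidence suffices; default) or
#'   `"intersection"`.
#' @return list with `ddgs` (character), `candidates` (family DEGs), and
#'   `evidence` (data.frame `gene_id`, `evidence_type`, `regulator_id`,
#'   `rho`, `p_adjusted`), where every stored row satisfies the evidence
#'   invariant.
#' @export
assemble_ddgs <- function(deg, families, dmps = NULL,
                          probe_annotation = NULL, beta_tumor = NULL,
                          dmi = NULL, mirna_tumor = NULL,
                          mirna_targets = NULL, cnv_flags = NULL,
                          cnv_gene = NULL, expr_tumor = NULL,
                          rho_cut = 0.2, alpha = 0.05,
                          combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  fam_genes <- unique(families$gene_id)
  candidates <- intersect(deg$gene_id[deg$is_deg], fam_genes)
  ev <- list()

  if (!is.null(dmps) && !is.null(probe_annotation) && length(candidates)) {
    dmp_ids <- dmps$probe_id[dmps$is_dmp]
    ann <- probe_annotation[probe_annotation$probe_id %in% dmp_ids &
                            probe_annotation$target_gene_id %in% candidates, ,
                            drop = FALSE]
    if (nrow(ann)) {
      pairs <- data.frame(regulator_id = ann$probe_id,
                          target_id = ann$target_gene_id,
                          region = ann$region, stringsAsFactors = FALSE)
      pairs <- correlate_regulator_target(pairs, beta_tumor, expr_tumor)
      pairs$evidence_type <- c(promoter = "promoter_meth",
                               gene_body = "body_meth",
                               distal_enhancer = "enhancer_meth")[pairs$region]
      ev$meth <- pairs
    }
  }
  if (!is.null(dmi) && !is.null(mirna_targets) && length(candidates)) {
    dmi_ids <- dmi$gene_id[dmi$is_deg]
    tm <- mirna_targets[mirna_targets$mirna_id %in% dmi_ids &
                        mirna_targets$gene_id %in% candidates, , drop = FALSE]
    if (nrow(tm)) {
      pairs <- data.frame(regulator_id = tm$mirna_id, target_id = tm$gene_id,
                          stringsAsFactors = FALSE)
      pairs <- correlate_regulator_target(pairs, mirna_tumor, expr_tumor)
      pairs$evidence_type <- "mirna"
      ev$mirna <- pairs
    }
  }
  if (!is.null(cnv_flags) && !is.null(cnv_gene) && length(candidates)) {
    cf <- cnv_flags[(cnv_flags$gain | cnv_flags$loss) &
                    cnv_flags$gene_id %in% candidates, , drop = FALSE]
    if (nrow(cf)) {
      pairs <- data.frame(regulator_id = cf$gene_id, target_id = cf$gene_id,
                          stringsAsFactors = FALSE)
      pairs <- correlate_regulator_target(pairs, cnv_gene, expr_tumor)
      pairs$evidence_type <- ifelse(cf$gain & cf$loss, "cnv_gain",
                             ifelse(cf$gain, "cnv_gain", "cnv_loss"))
      ev$cnv <- pairs
    }
  }

  keep_cols <- c("target_id", "evidence_type", "regulator_id", "rho",
                 "p_adjusted")
  passing <- lapply(ev, function(pairs) {
    ok <- !is.na(pairs$rho) & abs(pairs$rho) > rho_cut &
          pairs$p_adjusted < alpha
    pairs[ok, keep_cols, drop = FALSE]
  })
  evidence <- if (length(passing)) do.call(rbind, passing) else
    data.frame(target_id = character(0), evidence_type = character(0),
               regulator_id = character(0), rho = numeric(0),
               p_adjusted = numeric(0))
  names(evidence)[1] <- "gene_id"
  rownames(evidence) <- NULL
  stopifnot(all(abs(evidence$rho) > rho_cut),
            all(evidence$p_adjusted < alpha))

  modality <- c(promoter_meth = "meth", body_meth = "meth",
                enhancer_meth = "meth", mirna = "mirna",
                cnv_gain = "cnv", cnv_loss = "cnv")
  ddgs <- if (combine == "union") {
    sort(intersect(candidates, unique(evidence$gene_id)))
  } else {
    tested_mod <- unique(modality[evidence$evidence_type])
    per_gene <- split(modality[evidence$evidence_type], evidence$gene_id)
    sort(names(per_gene)[vapply(per_gene, function(m)
      all(tested_mod %in% m), logical(1))])
  }
  list(ddgs = ddgs, candidates = sort(candidates), evidence = evidence)
}
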