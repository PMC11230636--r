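# Seeded synthetic multi-omics cohort with planted two-subtype structure:
# domain-localized mutation hotspots, subtype-differential expression with
# methylation/miRNA/CNV evidence links, arm-level instability, survival
# separation, and a family-structured gene network.

#' Configuration for the synthetic cohort generator
#'
#' Defaults define the reference study conditions used throughout the
#' package's validation: 120 tumor samples split evenly into two latent
#' subtypes, 10 gene families of 6 members (each family sharing one
#' domain), 3 mutation-hotspot domains plus one low-entropy decoy, 40
#' planted subtype-differential genes at log2 fold change 2 with Gaussian
#' noise sd 0.5 on the log2 scale, methylation/miRNA/CNV evidence links
#' for the planted genes, arm-level instability enriched in subtype B,
#' and exponential survival with a subtype-B hazard ratio of 2 around a
#' subtype-A median of 20.55 months.
#'
#' @param n_samples tumor sample count.
#' @param subtype_fraction_B fraction of samples in subtype B.
#' @param n_families,members_per_family gene-family structure.
#' @param n_background_genes genes outside any family.
#' @param n_hotspot_domains family domains receiving subtype-B-enriched,
#'   family-dispersed in-domain mutations.
#' @param domain_mutation_rate_in_hotspot expected in-domain mutations per
#'   subtype-B sample per hotspot domain (Poisson mean).
#' @param background_mutation_rate per-sample per-gene probability of a
#'   background mutation at a uniform protein position.
#' @param n_planted_degs planted subtype-differential family genes.
#' @param deg_log2fc planted log2 fold change (subtype B vs A).
#' @param expression_noise_sd Gaussian noise sd on the log2 scale.
#' @param meth_effect_delta_beta tumor-vs-normal promoter beta shift for
#'   methylation-linked genes (with an additional B-vs-A modulation of one
#'   third of this value driving the expression correlation).
#' @param mirna_target_rho target Spearman correlation between a planted
#'   miRNA regulator and its target's expression (negative).
#' @param cnv_arm_instability_prob_B per-arm alteration probability in
#'   subtype B.
#' @param cnv_arm_instability_prob_A background per-arm alteration
#'   probability (subtype A).
#' @param hazard_ratio_B subtype-B hazard relative to A.
#' @param median_survival_A_months subtype-A median survival.
#' @param censoring_rate rate (per month) of the independent exponential
#'   censoring time.
#' @param network_within_family_p,network_background_p edge probabilities
#'   of the gene network.
#' @param n_normal_samples size of the normal-tissue comparison group.
#' @param seed integer seed; a fixed seed makes the cohort fully
#'   reproducible.
#' @return validated config list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_samples = 120,
                                    subtype_fraction_B = 0.5,
                                    n_families = 10,
                                    members_per_family = 6,
                                    n_background_genes = 140,
                                    n_hotspot_domains = 3,
                                    domain_mutation_rate_in_hotspot = 0.8,
                                    background_mutation_rate = 0.05,
                                    n_planted_degs = 40,
                                    deg_log2fc = 2,
                                    expression_noise_sd = 0.5,
                                    meth_effect_delta_beta = 0.3,
                                    mirna_target_rho = -0.7,
                                    cnv_arm_instability_prob_B = 0.4,
                                    cnv_arm_instability_prob_A = 0.1,
                                    hazard_ratio_B = 2,
                                    median_survival_A_months = 20.55,
                                    censoring_rate = 0.02,
                                    network_within_family_p = 0.4,
                                    network_background_p = 0.02,
                                    n_normal_samples = 50,
                                    seed = 1) {
  cfg <- as.list(environment())
  probs <- c("subtype_fraction_B", "background_mutation_rate",
             "cnv_arm_instability_prob_B", "cnv_arm_instability_prob_A",
             "network_within_family_p", "network_background_p")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$subtype_fraction_B <= 0 || cfg$subtype_fraction_B >= 1)
    stop("subtype_fraction_B must lie in (0, 1)")
  if (cfg$n_hotspot_domains >= cfg$n_families)
    stop("need n_hotspot_domains < n_families (one family hosts the decoy)")
  if (cfg$n_planted_degs > cfg$n_families * cfg$members_per_family)
    stop("n_planted_degs exceeds the family gene count")
  if (cfg$mirna_target_rho > 0)
    stop("mirna_target_rho must be <= 0 (repressive regulator)")
  neg <- c("domain_mutation_rate_in_hotspot", "deg_log2fc",
           "expression_noise_sd", "meth_effect_delta_beta",
           "hazard_ratio_B", "median_survival_A_months", "censoring_rate")
  for (p in neg) if (cfg[[p]] < 0) stop(p, " must be >= 0")
  structure(cfg, class = "synthetic_cohort_config")
}

# the 39 autosomal chromosome-arm labels of GISTIC-style broad tables
# (21p and 22p acrocentric arms omitted)
.arm_labels <- function() {
  arms <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  setdiff(arms, c("21p", "22p", "13p", "14p", "15p"))
}

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic multi-omics cohort with planted truth
#'
#' Produces every input layer the subtyping pipeline consumes, with known
#' ground truth: subtype labels, planted differential genes, and planted
#' hotspot domains. See [synthetic_cohort_config()] for the planted
#' effects. Structure:
#' \itemize{
#'   \item each family's members share one domain (interval 101-150 on a
#'     500-residue protein); hotspot domains receive Poisson in-domain
#'     mutations in subtype B, allocated uniformly across members
#'     (high-entropy); one decoy domain concentrates all its planted
#'     mutations in a single member (low entropy);
#'   \item tumor expression adds `deg_log2fc` for planted genes in
#'     subtype B on the log2 scale; normal expression is baseline + noise;
#'   \item planted genes are cycled through three evidence modalities:
#'     anti-correlated promoter methylation, an anti-correlated miRNA
#'     regulator (both also shifted tumor-vs-normal), or concordant
#'     gene-level copy number;
#'   \item arm-level scores mark each of 39 arms altered with probability
#'     `cnv_arm_instability_prob_B` in B and
#'     `cnv_arm_instability_prob_A` in A;
#'   \item survival is exponential with hazard ratio `hazard_ratio_B` and
#'     independent exponential censoring;
#'   \item the network has dense within-family edges and sparse background
#'     edges.
#' }
#' Setting `deg_log2fc = 0` disables all expression-linked evidence
#' planting, and equal hotspot/background mutation rates plus equal arm
#' probabilities and `hazard_ratio_B = 1` give a fully null cohort.
#'
#' @param config a `synthetic_cohort_config`.
#' @return object of class `synthetic_cohort`: list with `mutations`,
#'   `domains`, `families`, `protein_lengths`, `expression_tumor`,
#'   `expression_normal`, `methylation`, `methylation_normal`, `mirna`,
#'   `mirna_normal`, `mirna_targets`, `probe_annotation`, `cnv_gene`,
#'   `cnv_arm`, `network`, `survival`, `truth` (labels, planted DEG ids,
#'   hotspot domain ids) and `config`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  nB <- round(config$subtype_fraction_B * n)
  labels <- setNames(rep("A", n), samples)
  labels[sample.int(n, nB)] <- "B"
  isB <- labels == "B"

  fam_ids <- sprintf("FAM%02d", seq_len(config$n_families))
  fam_genes <- lapply(fam_ids, function(f)
    sprintf("%s_G%d", f, seq_len(config$members_per_family)))
  names(fam_genes) <- fam_ids
  families <- data.frame(
    family_id = rep(fam_ids, each = config$members_per_family),
    gene_id = unlist(fam_genes), stringsAsFactors = FALSE)
  bg_genes <- sprintf("BG%03d", seq_len(config$n_background_genes))
  all_genes <- c(families$gene_id, bg_genes)
  protein_lengths <- setNames(
    c(rep(500L, nrow(families)), rep(400L, length(bg_genes))), all_genes)

  # --- domains: one shared domain per family; decoy on the family after
  # the hotspots
  domains <- data.frame(
    gene_id = families$gene_id,
    domain_id = paste0("DOM_", families$family_id),
    start_aa = 101L, end_aa = 150L, e_value = 1e-10,
    stringsAsFactors = FALSE)
  hot_doms <- paste0("DOM_", fam_ids[seq_len(config$n_hotspot_domains)])
  decoy_fam <- fam_ids[config$n_hotspot_domains + 1]
  decoy_dom <- "DOM_DECOY"
  domains <- rbind(domains, data.frame(
    gene_id = fam_genes[[decoy_fam]], domain_id = decoy_dom,
    start_aa = 201L, end_aa = 250L, e_value = 1e-10,
    stringsAsFactors = FALSE))

  # --- mutations
  mut <- list()
  add_mut <- function(sample, gene, pos) {
    ref <- sample(.aa_letters, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.aa_letters, r), 1), "")
    data.frame(sample_id = sample, gene_id = gene,
               protein_pos = as.integer(pos), ref_aa = ref, alt_aa = alt,
               variant_class = "missense", stringsAsFactors = FALSE)
  }
  # background: per sample x gene Bernoulli at a uniform position
  hitmat <- matrix(stats::runif(n * length(all_genes)) <
                     config$background_mutation_rate,
                   n, length(all_genes))
  hits <- which(hitmat, arr.ind = TRUE)
  if (nrow(hits)) {
    g <- all_genes[hits[, 2]]
    mut$bg <- add_mut(samples[hits[, 1]], g,
                      1L + floor(stats::runif(nrow(hits)) * protein_lengths[g]))
  }
  # hotspot domains: Poisson in-domain mutations per B sample, member
  # chosen uniformly (family-dispersed => high entropy)
  for (d in seq_len(config$n_hotspot_domains)) {
    members <- fam_genes[[fam_ids[d]]]
    cnt <- stats::rpois(sum(isB), config$domain_mutation_rate_in_hotspot)
    who <- rep(samples[isB], cnt)
    if (length(who)) {
      gene <- sample(members, length(who), replace = TRUE)
      pos <- sample(101:150, length(who), replace = TRUE)
      mut[[paste0("hot", d)]] <- add_mut(who, gene, pos)
    }
  }
  # decoy: same burden but concentrated in one member (low entropy)
  cnt <- stats::rpois(sum(isB), config$domain_mutation_rate_in_hotspot)
  who <- rep(samples[isB], cnt)
  if (length(who))
    mut$decoy <- add_mut(who, fam_genes[[decoy_fam]][1],
                         sample(201:250, length(who), replace = TRUE))
  mutations <- do.call(rbind, mut)
  rownames(mutations) <- NULL
  # collapse coincidental duplicate (sample, gene, pos, alt) rows
  key <- paste(mutations$sample_id, mutations$gene_id,
               mutations$protein_pos, mutations$alt_aa)
  mutations <- mutations[!duplicated(key), , drop = FALSE]

  # --- expression
  normals <- sprintf("N%03d", seq_len(config$n_normal_samples))
  baseline <- setNames(stats::runif(length(all_genes), 3, 8), all_genes)
  planted <- sample(families$gene_id, config$n_planted_degs)
  eff <- setNames(numeric(length(all_genes)), all_genes)
  eff[planted] <- config$deg_log2fc
  noise <- function(nc) matrix(stats::rnorm(length(all_genes) * nc,
                                            sd = config$expression_noise_sd),
                               length(all_genes), nc)
  y_tum <- baseline + outer(eff, as.numeric(isB)) + noise(n)
  y_nrm <- baseline + noise(length(normals))
  v_tum <- pmax(2^y_tum - 1, 0)
  v_nrm <- pmax(2^y_nrm - 1, 0)
  dimnames(v_tum) <- list(all_genes, samples)
  dimnames(v_nrm) <- list(all_genes, normals)
  expr_tumor <- omics_matrix(v_tum, "mrna_tpm")
  expr_normal <- omics_matrix(v_nrm, "mrna_tpm")

  # --- evidence planting: cycle planted genes through the modalities
  plant_on <- config$deg_log2fc > 0
  modality <- rep(c("meth", "mirna", "cnv"), length.out = length(planted))
  meth_genes <- planted[plant_on & modality == "meth"]
  mirna_genes <- planted[plant_on & modality == "mirna"]
  cnv_genes <- planted[plant_on & modality == "cnv"]

  # methylation: one promoter probe per meth-linked gene + noise probes
  probe_sig <- if (length(meth_genes)) paste0("P_", meth_genes) else character(0)
  probe_noise <- sprintf("PN%03d", seq_len(20))
  probes <- c(probe_sig, probe_noise)
  base_beta <- setNames(stats::runif(length(probes), 0.4, 0.7), probes)
  beta_t <- matrix(stats::rnorm(length(probes) * n, sd = 0.05),
                   length(probes), n, dimnames = list(probes, samples)) +
    base_beta
  beta_n <- matrix(stats::rnorm(length(probes) * config$n_normal_samples,
                                sd = 0.05),
                   length(probes), config$n_normal_samples,
                   dimnames = list(probes, normals)) + base_beta
  if (length(probe_sig)) {
    beta_t[probe_sig, ] <- beta_t[probe_sig, ] -
      config$meth_effect_delta_beta -
      (config$meth_effect_delta_beta / 3) *
        matrix(as.numeric(isB), length(probe_sig), n, byrow = TRUE)
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  methylation <- omics_matrix(clip01(beta_t), "methylation_beta")
  methylation_normal <- omics_matrix(clip01(beta_n), "methylation_beta")
  probe_annotation <- data.frame(
    probe_id = probes,
    region = c(rep("promoter", length(probe_sig)),
               sample(PROBE_REGIONS, length(probe_noise), replace = TRUE)),
    target_gene_id = c(meth_genes,
                       sample(bg_genes, length(probe_noise), replace = TRUE)),
    stringsAsFactors = FALSE)

  # miRNA: one repressive regulator per mirna-linked gene + noise miRNAs;
  # tumor-vs-normal shift makes them DMi, the B-vs-A modulation drives the
  # anti-correlation with the target's expression
  mir_sig <- if (length(mirna_genes))
    sprintf("MIR%03d", seq_along(mirna_genes)) else character(0)
  mir_noise <- sprintf("MIRN%02d", seq_len(10))
  mirs <- c(mir_sig, mir_noise)
  base_mir <- setNames(stats::runif(length(mirs), 4.5, 6), mirs)
  mod <- abs(config$mirna_target_rho) * 1.4   # B-vs-A log2 dip
  ym_t <- base_mir + matrix(stats::rnorm(length(mirs) * n, sd = 0.3),
                            length(mirs), n, dimnames = list(mirs, samples))
  ym_n <- base_mir + matrix(stats::rnorm(length(mirs) * config$n_normal_samples,
                                         sd = 0.3),
                            length(mirs), config$n_normal_samples,
                            dimnames = list(mirs, normals))
  if (length(mir_sig)) {
    ym_t[mir_sig, ] <- ym_t[mir_sig, ] - 1.2 -
      mod * matrix(as.numeric(isB), length(mir_sig), n, byrow = TRUE)
  }
  mirna <- omics_matrix(pmax(2^ym_t - 1, 0), "mirna")
  mirna_normal <- omics_matrix(pmax(2^ym_n - 1, 0), "mirna")
  mirna_targets <- data.frame(
    mirna_id = c(mir_sig, mir_noise),
    gene_id = c(mirna_genes,
                sample(bg_genes, length(mir_noise), replace = TRUE)),
    stringsAsFactors = FALSE)

  # gene-level CNV: concordant gains for the cnv-linked genes in B
  cnv <- matrix(stats::rnorm(length(all_genes) * n, sd = 0.1),
                length(all_genes), n, dimnames = list(all_genes, samples))
  if (length(cnv_genes))
    cnv[cnv_genes, isB] <- cnv[cnv_genes, isB] + 1.5
  cnv_gene <- omics_matrix(cnv, "cnv_gene")

  # arm-level CNV
  arms <- .arm_labels()
  pA <- config$cnv_arm_instability_prob_A
  pB <- config$cnv_arm_instability_prob_B
  altered <- matrix(stats::runif(length(arms) * n) <
                      rep(ifelse(isB, pB, pA), each = length(arms)),
                    length(arms), n)
  arm_scores <- matrix(stats::rnorm(length(arms) * n, sd = 0.03),
                       length(arms), n, dimnames = list(arms, samples))
  sign_flip <- matrix(sample(c(-1, 1), length(arms) * n, replace = TRUE),
                      length(arms), n)
  arm_scores[altered] <- (0.5 * sign_flip)[altered]
  cnv_arm <- omics_matrix(arm_scores, "cnv_arm")

  # --- survival
  lamA <- log(2) / config$median_survival_A_months
  lam <- ifelse(isB, lamA * config$hazard_ratio_B, lamA)
  t_ev <- stats::rexp(n, lam)
  t_cn <- if (config$censoring_rate > 0)
    stats::rexp(n, config$censoring_rate) else rep(Inf, n)
  survival <- data.frame(sample_id = samples,
                         time_months = pmin(t_ev, t_cn),
                         event = as.integer(t_ev <= t_cn),
                         stringsAsFactors = FALSE)

  # --- network
  edges <- list()
  for (f in fam_ids) {
    g <- fam_genes[[f]]
    pr <- t(utils::combn(g, 2))
    keep <- stats::runif(nrow(pr)) < config$network_within_family_p
    if (any(keep))
      edges[[f]] <- data.frame(gene_a = pr[keep, 1], gene_b = pr[keep, 2],
                               stringsAsFactors = FALSE)
  }
  n_bg_pairs <- round(config$network_background_p *
                        choose(length(all_genes), 2))
  if (n_bg_pairs > 0) {
    a <- sample(all_genes, n_bg_pairs, replace = TRUE)
    b <- sample(all_genes, n_bg_pairs, replace = TRUE)
    ok <- a != b
    edges$bg <- data.frame(gene_a = a[ok], gene_b = b[ok],
                           stringsAsFactors = FALSE)
  }
  network <- gene_network(do.call(rbind, edges), nodes = all_genes)

  structure(list(
    mutations = mutations, domains = domains, families = families,
    protein_lengths = protein_lengths,
    expression_tumor = expr_tumor, expression_normal = expr_normal,
    methylation = methylation, methylation_normal = methylation_normal,
    mirna = mirna, mirna_normal = mirna_normal,
    mirna_targets = mirna_targets, probe_annotation = probe_annotation,
    cnv_gene = cnv_gene, cnv_arm = cnv_arm,
    network = network, survival = survival,
    truth = list(labels = labels, planted_degs = sort(planted),
                 hotspot_domains = hot_doms, decoy_domain = decoy_dom),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d tumor samples (%d subtype B), %d genes, %d mutations, seed %d\n",
              x$config$n_samples, sum(x$truth$labels == "B"),
              nrow(x$expression_tumor), nrow(x$mutations),
              x$config$seed))
  invisible(x)
}

#' Null configuration with every planted effect removed
#'
#' Convenience wrapper: hotspot and decoy mutation rates equal the
#' background process (rate 0 on top of background), no differential
#' expression or evidence links, equal arm-instability probabilities,
#' hazard ratio 1. Used for calibration and false-positive checks.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_cohort_config()].
#' @export
null_cohort_config <- function(seed = 1, ...) {
  synthetic_cohort_config(domain_mutation_rate_in_hotspot = 0,
                          deg_log2fc = 0,
                          meth_effect_delta_beta = 0,
                          mirna_target_rho = 0,
                          cnv_arm_instability_prob_B = 0.1,
                          cnv_arm_instability_prob_A = 0.1,
                          hazard_ratio_B = 1,
                          seed = seed, ...)
}

#' Write a synthetic cohort to a directory in the interchange formats
#'
#' Emits every layer as tab-separated text (mutations, domains, families,
#' matrices, probe annotation, miRNA targets, network edge list,
#' survival) plus the truth labels, so the pipeline can be exercised
#' purely from files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory.
#' @return invisible vector of written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(data.frame(Tumor_Sample_Barcode = cohort$mutations$sample_id,
                  Hugo_Symbol = cohort$mutations$gene_id,
                  Protein_position = cohort$mutations$protein_pos,
                  Reference_AA = cohort$mutations$ref_aa,
                  Alternate_AA = cohort$mutations$alt_aa,
                  Variant_Classification = cohort$mutations$variant_class),
       "mutations"),
    wt(cohort$domains, "domains"), wt(cohort$families, "families"),
    wt(data.frame(gene_id = names(cohort$protein_lengths),
                  length_aa = cohort$protein_lengths), "protein_lengths"),
    wt(cohort$probe_annotation, "probe_annotation"),
    wt(cohort$mirna_targets, "mirna_targets"),
    wt(cohort$network$edges, "network"),
    wt(data.frame(sample_id = cohort$survival$sample_id,
                  time_months = cohort$survival$time_months,
                  event = cohort$survival$event), "survival"),
    wt(data.frame(sample_id = names(cohort$truth$labels),
                  subtype = cohort$truth$labels), "truth_labels"))
  mats <- c("expression_tumor", "expression_normal", "methylation",
            "methylation_normal", "mirna", "mirna_normal", "cnv_gene",
            "cnv_arm")
  for (m in mats)
    paths <- c(paths, write_omics_matrix(cohort[[m]],
                                         file.path(out_dir, paste0(m, ".tsv"))))
  invisible(paths)
}
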