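# End-to-end orchestration: config validation, stage sequencing, run
# manifest, and the one-command synthetic demo.

#' Default pipeline configuration
#'
#' Every stage parameter with its reference default. The `"full"` profile
#' uses 5000 consensus repetitions and 9999 permutations; the `"demo"`
#' profile scales both down (500 / 999) for desk-scale runs while leaving
#' all scientific thresholds untouched.
#'
#' @param profile `"full"` or `"demo"`.
#' @param seed global seed; per-stage streams are derived from it.
#' @return named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(profile = c("full", "demo"), seed = 1) {
  profile <- match.arg(profile)
  structure(list(
    profile = profile,
    seed = seed,
    synthetic = NULL,            # synthetic_cohort_config or NULL (file inputs)
    input_dir = NULL,            # directory of write_cohort()-style files
    out_dir = NULL,
    tmb_cutoff = 30,
    coding_megabases = 38,
    n_perm = if (profile == "demo") 999 else 9999,
    burden_alpha = 0.05,
    entropy_cutoff = 0.5,
    de_p_cut = 0.05, de_fc_cut = 1, de_min_mean = 1,
    dmp_delta = 0.2,
    cnv_gain_level = 1, cnv_loss_level = -1, cnv_frac = 0.2,
    rho_cut = 0.2, evidence_alpha = 0.05,
    ddg_combine = "union",
    alpha = 0.7, tol = 1e-6, max_iter = 1000,
    quantile_normalize = FALSE,
    K = 20, mu = 0.5, t_iter = 20,
    maxK = 6,
    reps = if (profile == "demo") 500 else 5000,
    p_item = 0.8,
    cin_threshold = 0.1,
    classifier_p_cut = 0.001, classifier_fc_cut = 1,
    elastic_alpha = 0.5, train_frac = 0.7,
    cost_grid = 2^(-3:3)), class = "pipeline_config")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks all ranges; every
#' violation is reported in one aggregated error.
#'
#' @param config partial named list of overrides (possibly empty).
#' @param profile base profile when `config` does not name one.
#' @return complete `pipeline_config`.
#' @export
validate_config <- function(config = list(), profile = "full") {
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  if (!is.null(config$profile)) profile <- config$profile
  base <- default_pipeline_config(profile,
                                  seed = if (is.null(config$seed)) 1
                                         else config$seed)
  errs <- character(0)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(unclass(base),
                           config[intersect(names(config), names(base))])
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$alpha >= 0 && cfg$alpha < 1, "alpha must lie in [0, 1)")
  chk(cfg$p_item > 0 && cfg$p_item <= 1, "p_item must lie in (0, 1]")
  chk(cfg$tol > 0, "tol must be > 0")
  chk(cfg$maxK >= 2, "maxK must be >= 2")
  chk(cfg$reps >= 1, "reps must be >= 1")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$entropy_cutoff >= 0 && cfg$entropy_cutoff <= 1,
      "entropy_cutoff must lie in [0, 1]")
  chk(cfg$train_frac > 0 && cfg$train_frac < 1,
      "train_frac must lie in (0, 1)")
  chk(cfg$mu > 0, "mu must be > 0")
  chk(cfg$K >= 1, "K must be >= 1")
  chk(cfg$ddg_combine %in% c("union", "intersection"),
      "ddg_combine must be 'union' or 'intersection'")
  for (p in c("tmb_cutoff", "coding_megabases", "de_p_cut", "dmp_delta",
              "rho_cut", "evidence_alpha", "burden_alpha",
              "classifier_p_cut", "cin_threshold"))
    chk(cfg[[p]] > 0, paste0(p, " must be > 0"))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

.load_cohort_dir <- function(dir) {
  need <- c("mutations.tsv", "domains.tsv", "families.tsv",
            "protein_lengths.tsv", "expression_tumor.tsv",
            "expression_normal.tsv", "network.tsv", "survival.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("input directory is missing: ", paste(miss, collapse = ", "))
  pl <- utils::read.delim(file.path(dir, "protein_lengths.tsv"))
  protein_lengths <- setNames(pl$length_aa, pl$gene_id)
  opt <- function(name, reader, ...)
    if (file.exists(file.path(dir, name))) reader(file.path(dir, name), ...)
    else NULL
  list(
    mutations = read_mutations(file.path(dir, "mutations.tsv"),
                               protein_lengths)$records,
    domains = read_domains(file.path(dir, "domains.tsv"), protein_lengths),
    families = utils::read.delim(file.path(dir, "families.tsv"),
                                 stringsAsFactors = FALSE),
    protein_lengths = protein_lengths,
    expression_tumor = read_omics_matrix(
      file.path(dir, "expression_tumor.tsv"), "mrna_tpm"),
    expression_normal = read_omics_matrix(
      file.path(dir, "expression_normal.tsv"), "mrna_tpm"),
    methylation = opt("methylation.tsv", read_omics_matrix,
                      "methylation_beta"),
    methylation_normal = opt("methylation_normal.tsv", read_omics_matrix,
                             "methylation_beta"),
    mirna = opt("mirna.tsv", read_omics_matrix, "mirna"),
    mirna_normal = opt("mirna_normal.tsv", read_omics_matrix, "mirna"),
    mirna_targets = opt("mirna_targets.tsv", utils::read.delim,
                        stringsAsFactors = FALSE),
    probe_annotation = opt("probe_annotation.tsv", read_probe_annotation),
    cnv_gene = opt("cnv_gene.tsv", read_omics_matrix, "cnv_gene"),
    cnv_arm = opt("cnv_arm.tsv", read_omics_matrix, "cnv_arm"),
    network = read_network(file.path(dir, "network.tsv")),
    survival = read_survival(file.path(dir, "survival.tsv")),
    truth = NULL)
}

#' Run the full subtyping pipeline
#'
#' Stage order: hypermutator filtering, domain-burden testing,
#' stratification-gene selection, DDG assembly, mutation binarization +
#' network propagation, expression z-scoring, similarity network fusion,
#' consensus clustering, silhouette model selection, characterization
#' (CIN, mutation association, survival), and classifier panel training.
#' Inputs come from `config$synthetic` (a generated cohort), a
#' `cohort` object passed directly, or `config$input_dir` (files written
#' by [write_cohort()]).
#'
#' @param config a (partial) pipeline configuration; see
#'   [validate_config()].
#' @param cohort optional `synthetic_cohort`-shaped list overriding the
#'   config input source.
#' @return list of class `pipeline_result` with every stage output
#'   (`burden`, `stratification_genes`, `ddg`, `smoothed`, `fused`,
#'   `consensus`, `assignment`, `cin`, `association`, `survival_test`,
#'   `classifier`, `ari` when truth is known) and `manifest` (parameters,
#'   seeds, per-stage counts). When `config$out_dir` is set all artifacts
#'   are written there.
#' @export
run_pipeline <- function(config = list(), cohort = NULL) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  if (is.null(cohort)) {
    if (!is.null(cfg$synthetic)) {
      cohort <- generate_cohort(cfg$synthetic)
    } else if (!is.null(cfg$input_dir)) {
      if (!dir.exists(cfg$input_dir))
        stop("input path does not exist: ", cfg$input_dir)
      cohort <- .load_cohort_dir(cfg$input_dir)
    } else stop("no input: set config$synthetic, config$input_dir, or pass a cohort")
  }
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # 1. hypermutator filter
  hm <- stage("filter_hypermutators",
    filter_hypermutators(cohort$mutations, cfg$tmb_cutoff,
                         cfg$coding_megabases,
                         sample_ids = colnames(cohort$expression_tumor)))
  counts$samples_retained <- length(hm$retained_samples)
  counts$samples_excluded_tmb <- nrow(hm$excluded)

  # 2. domain burden -> stratification genes
  burden <- stage("domain_burden",
    test_domain_burden(hm$mutations, cohort$domains,
                       cohort$protein_lengths, n_perm = cfg$n_perm,
                       seed = cfg$seed, alpha = cfg$burden_alpha,
                       entropy_cutoff = cfg$entropy_cutoff))
  strat <- stage("stratification_genes",
    select_stratification_genes(burden, entropy_cutoff = cfg$entropy_cutoff,
                                alpha = cfg$burden_alpha))
  counts$domains_tested <- nrow(burden)
  counts$domains_significant <- sum(burden$significant)
  counts$stratification_genes <- length(strat)
  if (!length(strat))
    stop("stage 'stratification_genes' failed: no gene passed the burden + entropy filters")

  # 3. DDGs
  de <- stage("differential_expression",
    differential_expression(cohort$expression_tumor,
                            cohort$expression_normal,
                            p_cut = cfg$de_p_cut, fc_cut = cfg$de_fc_cut,
                            min_mean = cfg$de_min_mean))
  dmps <- if (!is.null(cohort$methylation) &&
              !is.null(cohort$methylation_normal))
    stage("call_dmps", call_dmps(cohort$methylation,
                                 cohort$methylation_normal,
                                 delta_cutoff = cfg$dmp_delta,
                                 p_cut = cfg$de_p_cut)) else NULL
  dmi <- if (!is.null(cohort$mirna) && !is.null(cohort$mirna_normal))
    stage("dmi", differential_expression(cohort$mirna, cohort$mirna_normal,
                                         p_cut = cfg$de_p_cut,
                                         fc_cut = cfg$de_fc_cut,
                                         min_mean = cfg$de_min_mean)) else NULL
  cnv_flags <- if (!is.null(cohort$cnv_gene))
    stage("classify_cnv_groups",
          classify_cnv_groups(cohort$cnv_gene, cfg$cnv_gain_level,
                              cfg$cnv_loss_level, cfg$cnv_frac)) else NULL
  ddg <- stage("assemble_ddgs",
    assemble_ddgs(de, cohort$families, dmps, cohort$probe_annotation,
                  cohort$methylation, dmi, cohort$mirna,
                  cohort$mirna_targets, cnv_flags, cohort$cnv_gene,
                  cohort$expression_tumor, rho_cut = cfg$rho_cut,
                  alpha = cfg$evidence_alpha, combine = cfg$ddg_combine))
  counts$family_degs <- length(ddg$candidates)
  counts$ddgs <- length(ddg$ddgs)

  # 4. subtype recognition
  F0 <- stage("binarize_mutations",
    suppressWarnings(binarize_mutations(hm$mutations, strat,
                                        hm$retained_samples)))
  A <- stage("normalize_network", normalize_network(cohort$network, strat))
  sm <- stage("propagate",
    propagate(F0, A, alpha = cfg$alpha, tol = cfg$tol,
              max_iter = cfg$max_iter,
              quantile_normalize = cfg$quantile_normalize))
  layers <- list(mutation = sm$F)
  expr_genes <- if (length(ddg$ddgs) >= 2) ddg$ddgs else ddg$candidates
  if (length(expr_genes) >= 2) {
    z <- stage("zscore_expression",
      suppressWarnings(zscore_expression(
        unclass(cohort$expression_tumor)[expr_genes,
                                         rownames(F0), drop = FALSE])))
    layers$expression <- t(z)
  }
  counts$fusion_layers <- length(layers)
  W <- stage("snf_fuse",
    snf_fuse(layers, K = cfg$K, mu = cfg$mu, t_iter = cfg$t_iter))
  cons <- stage("consensus_cluster",
    consensus_cluster(W, maxK = cfg$maxK, reps = cfg$reps,
                      p_item = cfg$p_item, seed = cfg$seed))
  assignment <- stage("silhouette_and_choose_k",
    silhouette_and_choose_k(cons, W))
  counts$chosen_k <- assignment$k

  # 5. characterization
  cin <- if (!is.null(cohort$cnv_arm))
    stage("cin_ratio", cin_ratio(cohort$cnv_arm, cfg$cin_threshold)) else NULL
  assoc <- stage("mutation_association",
    mutation_association(assignment, F0))
  surv <- if (!is.null(cohort$survival))
    stage("logrank_compare", logrank_compare(cohort$survival, assignment))
    else NULL

  # 6. classifier
  clf <- stage("classifier", {
    labels <- setNames(assignment$assignment$class,
                       assignment$assignment$sample_id)
    expr <- unclass(cohort$expression_tumor)[, names(labels), drop = FALSE]
    cand <- select_candidates(expr, labels, p_cut = cfg$classifier_p_cut,
                              fc_cut = cfg$classifier_fc_cut)
    if (length(cand) < 2) {
      NULL
    } else {
      ip <- mean_interval_filter(expr, labels, cand)
      if (!length(ip)) NULL else {
        panel <- sparse_panel_selection(expr, labels, ip,
                                        elastic_alpha = cfg$elastic_alpha,
                                        seed = cfg$seed)
        fit <- train_and_evaluate(expr, labels, panel,
                                  train_frac = cfg$train_frac,
                                  seed = cfg$seed,
                                  cost_grid = cfg$cost_grid)
        fit$candidates <- as.character(cand)
        fit$interval_pass <- as.character(ip)
        fit
      }
    }
  })
  if (!is.null(clf)) counts$panel_genes <- length(clf$model$panel)

  ari <- if (!is.null(cohort$truth)) {
    lab <- cohort$truth$labels[assignment$assignment$sample_id]
    truth_ari(assignment$assignment$class, lab)
  } else NULL
  if (!is.null(ari)) counts$truth_ari <- ari

  manifest <- list(package_version = as.character(utils::packageVersion("driversub")),
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   parameters = unclass(cfg)[setdiff(names(cfg),
                                                     c("synthetic"))],
                   synthetic = if (!is.null(cfg$synthetic))
                     unclass(cfg$synthetic) else NULL,
                   counts = counts)
  res <- structure(list(burden = burden, stratification_genes = strat,
                        de = de, ddg = ddg, smoothed = sm, fused = W,
                        consensus = cons, assignment = assignment,
                        cin = cin, association = assoc,
                        survival_test = surv, classifier = clf,
                        ari = ari, manifest = manifest, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    json <- list()
    if (!is.null(clf))
      json$classifier <- list(panel = clf$model$panel,
                              cost = clf$best_cost,
                              metrics = unclass(clf$metrics))
    if (!is.null(surv))
      json$survival <- list(statistic = surv$statistic, p = surv$p_value,
                            medians = as.list(surv$medians))
    tables <- list(domain_burden = burden, ddg_evidence = ddg$evidence)
    if (!is.null(cin)) tables$cin <- cin
    tables$mutation_association <- assoc
    write_results(assignment, tables = tables, json = json,
                  manifest = manifest, out_dir = cfg$out_dir)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  stratification genes: %d | DDGs: %d | chosen k: %d\n",
              length(x$stratification_genes), length(x$ddg$ddgs),
              x$assignment$k))
  if (!is.null(x$ari)) cat(sprintf("  ARI vs planted truth: %.3f\n", x$ari))
  if (!is.null(x$classifier))
    cat(sprintf("  panel size: %d | held-out ACC: %.3f MCC: %.3f\n",
                length(x$classifier$model$panel),
                x$classifier$metrics$ACC, x$classifier$metrics$MCC))
  invisible(x)
}

#' One-command synthetic demo
#'
#' Generates the default synthetic cohort and runs the full pipeline with
#' the demo profile (500 consensus repetitions, 999 permutations).
#'
#' @param seed global seed (also seeds the cohort).
#' @param out_dir optional output directory.
#' @return a `pipeline_result`.
#' @export
run_demo <- function(seed = 1, out_dir = NULL) {
  cfg <- default_pipeline_config("demo", seed = seed)
  cfg$synthetic <- synthetic_cohort_config(seed = seed)
  cfg$out_dir <- out_dir
  run_pipeline(cfg)
}
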