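# Protein-domain mutation-burden testing: TMB filtering, in-domain
# counting, permutation p-values, the family-dispersion entropy statistic,
# and stratification-gene selection.

#' Tumor mutational burden per sample
#'
#' TMB = nonsilent point-mutation count / coding megabases. The input is
#' assumed sanitized (silent and non-point records already removed), so
#' every row counts.
#'
#' @param mutations sanitized mutation data.frame (see
#'   [sanitize_mutations()]).
#' @param coding_megabases size of the coding exome in Mb (default 38).
#' @param sample_ids optional sample universe so zero-mutation samples get
#'   TMB 0.
#' @return data.frame with `sample_id`, `n_nonsilent`, `tmb`.
#' @export
compute_tmb <- function(mutations, coding_megabases = 38, sample_ids = NULL) {
  counts <- table(mutations$sample_id)
  ids <- union(names(counts), sample_ids)
  n <- as.integer(counts[ids])
  n[is.na(n)] <- 0L
  data.frame(sample_id = ids, n_nonsilent = n,
             tmb = n / coding_megabases, stringsAsFactors = FALSE)
}

#' Exclude hypermutated samples
#'
#' Samples with TMB strictly greater than `tmb_cutoff` mutations/Mb are
#' removed; a sample at exactly the cutoff is retained.
#'
#' @inheritParams compute_tmb
#' @param tmb_cutoff exclusion threshold in mutations/Mb (default 30).
#' @return list with `mutations` (retained records), `retained_samples`,
#'   and `excluded` (data.frame of excluded samples with their TMB).
#' @export
filter_hypermutators <- function(mutations, tmb_cutoff = 30,
                                 coding_megabases = 38, sample_ids = NULL) {
  tmb <- compute_tmb(mutations, coding_megabases, sample_ids)
  excl <- tmb[tmb$tmb > tmb_cutoff, , drop = FALSE]
  keep <- setdiff(tmb$sample_id, excl$sample_id)
  list(mutations = mutations[mutations$sample_id %in% keep, , drop = FALSE],
       retained_samples = keep,
       excluded = excl)
}

#' Count mutations falling inside domain instances
#'
#' A mutation at position `p` is in-domain iff
#' `start_aa <= p <= end_aa` (closed interval). Counts are reported per
#' (domain, gene); a mutation inside overlapping instances of two
#' different domains counts once for each. Domain rows for genes with no
#' mutations still appear with count 0 so entropy denominators see every
#' carrier.
#'
#' @param mutations sanitized mutation data.frame.
#' @param domains validated domain data.frame.
#' @return data.frame `domain_id`, `gene_id`, `n_in_domain`.
#' @export
map_mutations_to_domains <- function(mutations, domains) {
  unknown <- setdiff(unique(domains$gene_id), unique(mutations$gene_id))
  # genes without mutations are fine; counts are simply zero
  res <- domains[, c("domain_id", "gene_id")]
  res <- res[!duplicated(paste(res$domain_id, res$gene_id)), , drop = FALSE]
  res$n_in_domain <- vapply(seq_len(nrow(res)), function(i) {
    iv <- domains[domains$domain_id == res$domain_id[i] &
                  domains$gene_id == res$gene_id[i], , drop = FALSE]
    mu <- mutations[mutations$gene_id == res$gene_id[i], , drop = FALSE]
    if (!nrow(mu)) return(0L)
    hit <- rep(FALSE, nrow(mu))
    for (j in seq_len(nrow(iv)))
      hit <- hit | (mu$protein_pos >= iv$start_aa[j] &
                    mu$protein_pos <= iv$end_aa[j])
    sum(hit)
  }, integer(1))
  rownames(res) <- NULL
  res
}

#' Permutation p-value for one domain's mutation burden
#'
#' Null model: every residue of a protein is equally likely to mutate.
#' For each permutation each gene's observed total mutation count is
#' re-placed uniformly and independently over its protein positions (with
#' replacement), so the permuted in-domain count of gene *g* is
#' Binomial(m_g, in-domain residues / protein length); the permuted
#' statistic is the family-wide total. The p-value is
#' `(#{permuted >= observed} + 1) / (n_perm + 1)` — ties count against the
#' observation, so p can never be 0 and never falls below
#' `1/(n_perm + 1)`.
#'
#' @param observed observed family-wide in-domain mutation count.
#' @param gene_totals named vector: per carrier gene, its total mutation
#'   count (all positions).
#' @param gene_lengths named vector of protein lengths for the same genes.
#' @param domain_residues named vector: in-domain residue count per gene
#'   (summed over that gene's instances of the domain).
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed for bit-reproducible runs.
#' @return p-value in `(0, 1]`. Zero total mutations returns `p = 1` with
#'   attribute `flagged = TRUE`.
#' @export
permutation_test_domain <- function(observed, gene_totals, gene_lengths,
                                    domain_residues, n_perm = 9999,
                                    seed = NULL) {
  if (any(gene_lengths <= 0)) stop("protein lengths must be positive")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (sum(gene_totals) == 0)
    return(structure(1.0, flagged = TRUE))
  if (!is.null(seed)) set.seed(seed)
  genes <- names(gene_totals)
  stat <- numeric(n_perm)
  for (g in genes) {
    m <- gene_totals[[g]]
    if (m == 0) next
    p_hit <- domain_residues[[g]] / gene_lengths[[g]]
    stat <- stat + stats::rbinom(n_perm, m, p_hit)
  }
  (sum(stat >= observed) + 1) / (n_perm + 1)
}

#' Normalized dispersion entropy of a domain's mutations across carriers
#'
#' `S = -sum(P_i * ln P_i) / ln(n)` where `P_i` is gene *i*'s share of the
#' domain's mutations over all `n` carrier genes (`0 * ln 0 = 0`). `S = 1`
#' when mutations are spread uniformly across the family, `S = 0` when one
#' carrier holds them all. A single-carrier domain is defined to have
#' `S = 0` (no family-dispersion evidence); a zero-count domain returns
#' `NA` with attribute `flagged`.
#'
#' @param counts numeric vector of per-carrier in-domain mutation counts
#'   (zeros allowed; carriers with no mutations still count toward `n`).
#' @return entropy in `[0, 1]`, or flagged `NA`.
#' @export
domain_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- length(counts)
  total <- sum(counts)
  if (total == 0) return(structure(NA_real_, flagged = TRUE))
  if (n == 1) return(0)
  p <- counts / total
  p <- p[p > 0]
  s <- -sum(p * log(p)) / log(n)
  if (s == 0) 0 else s     # avoid IEEE negative zero at the boundary
}

#' Test every domain for significant, family-dispersed mutation burden
#'
#' Runs [map_mutations_to_domains()], the permutation test, and
#' [domain_entropy()] over all domains, with Benjamini-Hochberg adjustment
#' across tested domains. Carrier sets are the genes listed in the domain
#' table for each domain.
#'
#' @param mutations sanitized, hypermutator-filtered mutation data.frame.
#' @param domains validated domain data.frame.
#' @param protein_lengths named vector of protein lengths covering the
#'   domain genes; domains on genes without a length are skipped with a
#'   warning.
#' @param n_perm permutations per domain (default 9999).
#' @param seed integer seed; per-domain streams are derived so results do
#'   not depend on domain evaluation order.
#' @param alpha BH significance level (default 0.05).
#' @param entropy_cutoff strict dispersion threshold (default 0.5).
#' @return data.frame, one row per domain: carrier count, observed
#'   in-domain total, `p_value`, `p_adjusted`, `entropy_S`, `significant`
#'   (`p_adjusted < alpha`), `high_entropy` (`S > entropy_cutoff`).
#'   Attribute `per_gene` keeps the (domain, gene) count table.
#' @export
test_domain_burden <- function(mutations, domains, protein_lengths,
                               n_perm = 9999, seed = 1, alpha = 0.05,
                               entropy_cutoff = 0.5) {
  nolen <- setdiff(unique(domains$gene_id), names(protein_lengths))
  if (length(nolen)) {
    warning("skipping domain instances on gene(s) without protein length: ",
            paste(nolen, collapse = ", "))
    domains <- domains[!domains$gene_id %in% nolen, , drop = FALSE]
  }
  if (!nrow(domains)) stop("no testable domain instances")
  counts <- map_mutations_to_domains(mutations, domains)
  gene_tot_tab <- table(mutations$gene_id)
  dom_ids <- unique(domains$domain_id)
  res <- lapply(seq_along(dom_ids), function(di) {
    d <- dom_ids[di]
    dd <- domains[domains$domain_id == d, , drop = FALSE]
    genes <- unique(dd$gene_id)
    per_gene <- setNames(integer(length(genes)), genes)
    cc <- counts[counts$domain_id == d, , drop = FALSE]
    per_gene[cc$gene_id] <- cc$n_in_domain
    resid <- vapply(genes, function(g) {
      iv <- dd[dd$gene_id == g, , drop = FALSE]
      pos <- unique(unlist(mapply(seq, iv$start_aa, iv$end_aa,
                                  SIMPLIFY = FALSE)))
      length(pos)
    }, numeric(1))
    tot <- setNames(as.numeric(gene_tot_tab[genes]), genes)
    tot[is.na(tot)] <- 0
    p <- permutation_test_domain(sum(per_gene), tot,
                                 protein_lengths[genes], resid,
                                 n_perm = n_perm,
                                 seed = if (is.null(seed)) NULL
                                        else seed + di)
    S <- domain_entropy(per_gene)
    data.frame(domain_id = d,
               n_family_genes_with_domain = length(genes),
               observed_in_domain_mutations = sum(per_gene),
               p_value = as.numeric(p),
               entropy_S = as.numeric(S),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adjusted < alpha
  res$high_entropy <- !is.na(res$entropy_S) & res$entropy_S > entropy_cutoff
  attr(res, "per_gene") <- counts
  res
}

#' Select stratification genes from domain-burden results
#'
#' A gene is a stratification gene iff it has at least one mutation inside
#' an instance of at least one domain that is both significant
#' (`p_adjusted < alpha`) and high-entropy (`S > entropy_cutoff`).
#'
#' @param burden result of [test_domain_burden()] (or a compatible
#'   data.frame with `domain_id`, `p_adjusted`, `entropy_S`).
#' @param per_gene_counts data.frame `domain_id`, `gene_id`,
#'   `n_in_domain`; defaults to the `per_gene` attribute of `burden`.
#' @param entropy_cutoff strict entropy threshold (default 0.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of stratification gene ids (sorted).
#' @export
select_stratification_genes <- function(burden,
                                        per_gene_counts = attr(burden, "per_gene"),
                                        entropy_cutoff = 0.5, alpha = 0.05) {
  if (is.null(per_gene_counts))
    stop("per-gene in-domain counts are required")
  ok <- burden$domain_id[burden$p_adjusted < alpha &
                         !is.na(burden$entropy_S) &
                         burden$entropy_S > entropy_cutoff]
  hits <- per_gene_counts[per_gene_counts$domain_id %in% ok &
                          per_gene_counts$n_in_domain >= 1, , drop = FALSE]
  sort(unique(hits$gene_id))
}
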