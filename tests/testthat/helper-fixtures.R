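# Shared fixtures. Cohorts are cached per (seed, null) so several test
# files can reuse the same generated object without paying generation
# twice.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed = 1, null = FALSE) {
  key <- paste0(if (null) "null" else "default", seed)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- if (null) null_cohort_config(seed = seed)
           else synthetic_cohort_config(seed = seed)
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

# minimal omics matrix builder
om <- function(values, layer = "mrna_tpm", features = NULL, samples = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(features))
    features <- if (!is.null(rownames(values))) rownames(values)
                else paste0("g", seq_len(nrow(values)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(values))) colnames(values)
               else paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  omics_matrix(values, layer, allow_missing = anyNA(values))
}

# mutation-record builder
mut_df <- function(sample_id, gene_id, protein_pos,
                   variant_class = "missense", ref_aa = "A", alt_aa = "V") {
  data.frame(sample_id = sample_id, gene_id = gene_id,
             protein_pos = as.integer(protein_pos), ref_aa = ref_aa,
             alt_aa = alt_aa, variant_class = variant_class,
             stringsAsFactors = FALSE)
}
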