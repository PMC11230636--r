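#' Omics layer vocabulary
#'
#' The five omics layers the pipeline understands. Layer tags drive
#' layer-specific validation and preprocessing rules.
#' @keywords internal
OMICS_LAYERS <- c("mrna_tpm", "mirna", "methylation_beta", "cnv_gene", "cnv_arm")

#' Variant-class vocabulary for somatic point mutations
#' @keywords internal
VARIANT_CLASSES <- c("missense", "nonsense", "splice", "frameshift",
                     "inframe_indel", "silent", "other")

#' Probe-region vocabulary
#' @keywords internal
PROBE_REGIONS <- c("promoter", "gene_body", "distal_enhancer")

# Variant classes that are point mutations in protein space. Frameshifts and
# in-frame indels are rejected upstream; silent mutations are dropped as
# non-functional.
POINT_CLASSES <- c("missense", "nonsense", "splice")

#' Construct a validated omics matrix
#'
#' A feature-by-sample numeric matrix tagged with the omics layer it
#' carries. Layer invariants are enforced at construction: methylation beta
#' values must lie in \[0, 1\]; TPM and miRNA abundances must be
#' nonnegative. Feature and sample identifiers must be unique.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry rownames and colnames.
#' @param layer one of `"mrna_tpm"`, `"mirna"`, `"methylation_beta"`,
#'   `"cnv_gene"`, `"cnv_arm"`.
#' @param allow_missing permit `NA` cells (pre-imputation matrices).
#' @return the matrix with a `layer` attribute and class `omics_matrix`.
#' @examples
#' m <- omics_matrix(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                     c("s1", "s2"))),
#'                   layer = "mrna_tpm")
#' omics_layer(m)
#' @export
omics_matrix <- function(values, layer = OMICS_LAYERS, allow_missing = FALSE) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!allow_missing && anyNA(values))
    stop("missing values present; construct with allow_missing = TRUE or impute first")
  obs <- values[!is.na(values)]
  if (layer == "methylation_beta" && length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop("methylation_beta values must lie in [0, 1]")
  if (layer %in% c("mrna_tpm", "mirna") && length(obs) && min(obs) < 0)
    stop(layer, " values must be nonnegative")
  structure(values, layer = layer, class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
omics_layer <- function(x) attr(x, "layer")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s  %d features x %d samples\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 5)), drop = FALSE], 5))
  invisible(x)
}

#' Validate a table of somatic point-mutation records
#'
#' Checks the column contract shared by all mutation-consuming operations:
#' `sample_id`, `gene_id`, `protein_pos` (1-based amino-acid index),
#' `ref_aa`, `alt_aa`, `variant_class` (controlled vocabulary).
#'
#' @param mutations data.frame of mutation records.
#' @return the validated data.frame, invisibly.
#' @export
validate_mutations <- function(mutations) {
  need <- c("sample_id", "gene_id", "protein_pos", "ref_aa", "alt_aa",
            "variant_class")
  miss <- setdiff(need, names(mutations))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(mutations$variant_class), VARIANT_CLASSES)
  if (length(bad))
    stop("unknown variant_class value(s): ", paste(bad, collapse = ", "))
  if (any(!is.na(mutations$protein_pos) & mutations$protein_pos < 1))
    stop("protein_pos must be >= 1")
  invisible(mutations)
}

#' Construct a weighted, undirected gene-interaction network
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (default 1). Self-loops are rejected; duplicate pairs are
#'   collapsed keeping the first weight.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node ids.
#' @return an object of class `gene_network`: list with `nodes` and an edge
#'   data.frame (`gene_a`, `gene_b`, `weight`).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    stop("edges need columns gene_a, gene_b")
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  if (any(edges$weight <= 0)) stop("edge weights must be > 0")
  key <- ifelse(edges$gene_a < edges$gene_b,
                paste(edges$gene_a, edges$gene_b),
                paste(edges$gene_b, edges$gene_a))
  edges <- edges[!duplicated(key), c("gene_a", "gene_b", "weight")]
  all_nodes <- sort(unique(c(edges$gene_a, edges$gene_b, nodes)))
  structure(list(nodes = all_nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Validate a protein-domain table
#'
#' Domain coordinates are 1-based closed amino-acid intervals
#' `[start_aa, end_aa]`. Instances with an e-value above `e_value_max` are
#' dropped (annotation confidence filter).
#'
#' @param domains data.frame with `gene_id`, `domain_id`, `start_aa`,
#'   `end_aa` and optionally `e_value` (default 0).
#' @param protein_lengths optional named vector of protein lengths used to
#'   check `end_aa` does not exceed the protein.
#' @param e_value_max annotation e-value ceiling (default `1e-5`).
#' @return validated, filtered data.frame.
#' @export
validate_domains <- function(domains, protein_lengths = NULL,
                             e_value_max = 1e-5) {
  need <- c("gene_id", "domain_id", "start_aa", "end_aa")
  miss <- setdiff(need, names(domains))
  if (length(miss))
    stop("domain table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(domains$e_value)) domains$e_value <- 0
  if (any(domains$start_aa < 1) || any(domains$end_aa < domains$start_aa))
    stop("domain intervals must satisfy 1 <= start_aa <= end_aa")
  if (!is.null(protein_lengths)) {
    len <- protein_lengths[domains$gene_id]
    bad <- !is.na(len) & domains$end_aa > len
    if (any(bad))
      stop("domain end exceeds protein length for gene(s): ",
           paste(unique(domains$gene_id[bad]), collapse = ", "))
  }
  domains[domains$e_value <= e_value_max, , drop = FALSE]
}
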