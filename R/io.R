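# Readers/writers for the tab-separated interchange formats, plus the
# stated preprocessing filters (missingness / zero-TPM removal, KNN
# imputation).

#' Default column mapping for MAF-like mutation tables
#'
#' Maps the package's canonical field names to the column headers of a
#' standard MAF dialect. Override individual entries via the `col_map`
#' argument of [read_mutations()].
#' @export
maf_col_map <- function() {
  list(sample_id     = "Tumor_Sample_Barcode",
       gene_id       = "Hugo_Symbol",
       protein_pos   = "Protein_position",
       ref_aa        = "Reference_AA",
       alt_aa        = "Alternate_AA",
       variant_class = "Variant_Classification")
}

# MAF Variant_Classification -> controlled vocabulary
.normalize_variant_class <- function(x) {
  map <- c(Missense_Mutation = "missense",
           Nonsense_Mutation = "nonsense",
           Nonstop_Mutation  = "other",
           Splice_Site       = "splice",
           Splice_Region     = "splice",
           Frame_Shift_Del   = "frameshift",
           Frame_Shift_Ins   = "frameshift",
           In_Frame_Del      = "inframe_indel",
           In_Frame_Ins      = "inframe_indel",
           Silent            = "silent")
  out <- ifelse(x %in% VARIANT_CLASSES, x,
                ifelse(x %in% names(map), unname(map[x]), "other"))
  out
}

#' Read and sanitize a MAF-like somatic mutation table
#'
#' Reads a tab-separated mutation table, normalizes variant classes to the
#' controlled vocabulary, and applies the sanitation rules for
#' protein-space analyses: non-point mutations (frameshift, in-frame indel,
#' other) are dropped, silent mutations are dropped, records whose
#' amino-acid position exceeds the protein length are dropped, records
#' whose stated reference amino acid disagrees with a supplied reference
#' sequence are dropped, and duplicate (sample, gene, position, alt) rows
#' are collapsed. Every rejection is logged with a reason code so that
#' `nrow(records) + nrow(rejected)` always equals the input row count.
#'
#' @param path tab-separated file with a header row.
#' @param protein_lengths named integer vector, gene id -> protein length
#'   (amino acids). Genes absent from this map are rejected with reason
#'   `no_reference_length`.
#' @param protein_sequences optional named character vector of one-letter
#'   amino-acid sequences used to verify `ref_aa`; when `NULL` the check is
#'   skipped.
#' @param col_map named list mapping canonical field names to file column
#'   headers; defaults to [maf_col_map()]. Partial overrides are merged.
#' @return list with `records` (sanitized data.frame of point mutations)
#'   and `rejected` (data.frame with the original row index and a
#'   `reason` code: `non_point`, `silent`, `bad_position`,
#'   `no_reference_length`, `pos_exceeds_length`, `ref_aa_mismatch`,
#'   `duplicate`).
#' @examples
#' maf <- system.file("extdata", "example_mutations.tsv",
#'                    package = "driversub")
#' res <- read_mutations(maf, protein_lengths = c(TP53 = 393, CTNNB1 = 781,
#'                                                AXIN1 = 862, ARID1A = 2285))
#' res$records
#' res$rejected
#' @export
read_mutations <- function(path, protein_lengths, protein_sequences = NULL,
                           col_map = maf_col_map()) {
  col_map <- utils::modifyList(maf_col_map(), as.list(col_map))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- vapply(col_map, function(cn) !cn %in% names(raw), logical(1))
  if (any(miss))
    stop("mutation file is missing mandatory column(s): ",
         paste(unlist(col_map[miss]), collapse = ", "))
  df <- data.frame(sample_id     = as.character(raw[[col_map$sample_id]]),
                   gene_id       = as.character(raw[[col_map$gene_id]]),
                   protein_pos   = suppressWarnings(
                                     as.integer(raw[[col_map$protein_pos]])),
                   ref_aa        = as.character(raw[[col_map$ref_aa]]),
                   alt_aa        = as.character(raw[[col_map$alt_aa]]),
                   variant_class = .normalize_variant_class(
                                     as.character(raw[[col_map$variant_class]])),
                   stringsAsFactors = FALSE)
  sanitize_mutations(df, protein_lengths, protein_sequences)
}

#' Sanitize an in-memory mutation table
#'
#' The filtering core of [read_mutations()], usable on tables built in
#' code. See that function for the rule set and reason codes.
#' @inheritParams read_mutations
#' @param mutations data.frame with the canonical mutation columns.
#' @return list with `records` and `rejected`.
#' @export
sanitize_mutations <- function(mutations, protein_lengths,
                               protein_sequences = NULL) {
  validate_mutations(mutations)
  n <- nrow(mutations)
  reason <- rep(NA_character_, n)

  non_point <- !(mutations$variant_class %in% c(POINT_CLASSES, "silent"))
  reason[non_point] <- "non_point"
  sil <- is.na(reason) & mutations$variant_class == "silent"
  reason[sil] <- "silent"
  badpos <- is.na(reason) &
    (is.na(mutations$protein_pos) | mutations$protein_pos < 1)
  reason[badpos] <- "bad_position"
  nolen <- is.na(reason) & !(mutations$gene_id %in% names(protein_lengths))
  reason[nolen] <- "no_reference_length"
  len <- unname(protein_lengths[mutations$gene_id])
  toolong <- is.na(reason) & !is.na(len) & mutations$protein_pos > len
  reason[toolong] <- "pos_exceeds_length"
  if (!is.null(protein_sequences)) {
    idx <- which(is.na(reason) & mutations$gene_id %in% names(protein_sequences))
    if (length(idx)) {
      ref_in_seq <- substr(protein_sequences[mutations$gene_id[idx]],
                           mutations$protein_pos[idx],
                           mutations$protein_pos[idx])
      reason[idx[ref_in_seq != mutations$ref_aa[idx]]] <- "ref_aa_mismatch"
    }
  }
  key <- paste(mutations$sample_id, mutations$gene_id,
               mutations$protein_pos, mutations$alt_aa, sep = "\r")
  dup <- is.na(reason) & duplicated(ifelse(is.na(reason), key, paste0(key, seq_len(n))))
  # duplicates judged among surviving records only
  surv_dup <- rep(FALSE, n)
  surv <- which(is.na(reason))
  surv_dup[surv[duplicated(key[surv])]] <- TRUE
  reason[surv_dup] <- "duplicate"

  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep),
                         sample_id = mutations$sample_id[!keep],
                         gene_id = mutations$gene_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(records = mutations[keep, , drop = FALSE], rejected = rejected)
}

#' Read a feature-by-sample omics matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each.
#' Blank cells and `NA` parse as missing. Duplicate feature ids and
#' layer-invariant violations (beta outside \[0,1\], negative TPM) raise
#' errors; non-rectangular tables are reported with the offending row.
#'
#' @param path tab-separated file.
#' @param layer omics layer tag, see [omics_matrix()].
#' @param allow_missing permit missing cells (default `TRUE`; call
#'   [filter_and_impute()] afterwards).
#' @return an `omics_matrix`.
#' @export
read_omics_matrix <- function(path, layer, allow_missing = TRUE) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(parts[[1]])
  widths <- lengths(parts)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1]
    stop(sprintf("non-rectangular table: row %d has %d fields, expected %d",
                 bad, widths[bad], ncols))
  }
  header <- parts[[1]]
  body <- parts[-1]
  features <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(features))
    stop("duplicate feature id(s): ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  vals <- vapply(body, function(p) {
    x <- p[-1]
    x[x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(ncols - 1))
  m <- matrix(t(vals), nrow = length(features), ncol = ncols - 1,
              dimnames = list(features, header[-1]))
  omics_matrix(m, layer = layer, allow_missing = allow_missing)
}

#' Write an omics matrix as TSV at full precision
#'
#' Values are serialized with `format(..., digits = 17)` so that a
#' write-then-read round trip reproduces the matrix exactly.
#' @param m an `omics_matrix` (or plain named matrix).
#' @param path output file.
#' @param id_col header for the feature-id column.
#' @export
write_omics_matrix <- function(m, path, id_col = "feature_id") {
  vals <- apply(unclass(m), c(1, 2), function(x)
    if (is.na(x)) "" else format(x, digits = 17, scientific = TRUE))
  df <- cbind(rownames(m), as.data.frame(vals, stringsAsFactors = FALSE))
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_support_tables
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_a", "gene_b")
  gene_network(df)
}

#' Readers for the small supporting tables
#'
#' `read_network()` reads an edge list (`gene_a`, `gene_b`, optional
#' `weight`); `read_probe_annotation()` a probe table (`probe_id`,
#' `region`, `target_gene_id`); `read_survival()` a clinical table
#' (`sample_id`, `time_months`, `event`, extra columns kept as
#' covariates); `read_domains()` a domain table (see
#' [validate_domains()]).
#'
#' @param path tab-separated file.
#' @name read_support_tables
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "region", "target_gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("probe annotation missing: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$region), PROBE_REGIONS)
  if (length(bad)) stop("unknown probe region(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_support_tables
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing: ", paste(miss, collapse = ", "))
  if (any(df$time_months < 0)) stop("survival times must be nonnegative")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' @rdname read_support_tables
#' @param protein_lengths optional named length vector for validation.
#' @export
read_domains <- function(path, protein_lengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_domains(df, protein_lengths)
}

#' Filter sparse features and impute missing values
#'
#' Applies the layer-appropriate preprocessing rule:
#' \itemize{
#'   \item `mrna_tpm`: genes with values `<= 0` in strictly more than
#'     `max_missing_frac` of samples are removed (no imputation; TPM
#'     matrices carry no `NA`s).
#'   \item `methylation_beta` / `mirna`: features missing in strictly more
#'     than `max_missing_frac` of samples are removed; remaining `NA`s are
#'     imputed as the mean of the `knn_k` nearest features, with
#'     feature-feature Euclidean distance computed over pairwise-complete
#'     samples and distance ties broken by feature order.
#'   \item CNV layers: missingness filter only.
#' }
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param m an `omics_matrix`.
#' @param max_missing_frac strict removal threshold (default 0.3).
#' @param knn_k neighbor count for imputation (default 15); reduced with a
#'   warning when fewer eligible neighbors exist.
#' @return an `omics_matrix` without missing values.
#' @export
filter_and_impute <- function(m, max_missing_frac = 0.3, knn_k = 15) {
  layer <- omics_layer(m)
  if (is.null(layer)) stop("input must be an omics_matrix with a layer tag")
  vals <- unclass(m)
  if (layer == "mrna_tpm") {
    frac0 <- rowMeans(vals <= 0 | is.na(vals))
    keep <- frac0 <= max_missing_frac
    if (!any(keep)) stop("all features removed by the zero-TPM filter")
    return(omics_matrix(vals[keep, , drop = FALSE], layer))
  }
  fracNA <- rowMeans(is.na(vals))
  keep <- fracNA <= max_missing_frac
  if (!any(keep)) stop("all features removed by the missingness filter")
  vals <- vals[keep, , drop = FALSE]
  if (anyNA(vals)) vals <- .knn_impute_rows(vals, knn_k)
  omics_matrix(vals, layer)
}

# Row-wise (feature-as-neighbor) KNN mean imputation over
# pairwise-complete Euclidean distances.
.knn_impute_rows <- function(vals, k) {
  has_na <- which(rowSums(is.na(vals)) > 0)
  out <- vals
  for (i in has_na) {
    xi <- vals[i, ]
    obs_i <- !is.na(xi)
    others <- setdiff(seq_len(nrow(vals)), i)
    d <- vapply(others, function(j) {
      shared <- obs_i & !is.na(vals[j, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((xi[shared] - vals[j, shared])^2))
    }, numeric(1))
    ord <- others[order(d, others)]   # distance ties broken by feature order
    ord <- ord[is.finite(d[match(ord, others)])]
    for (s in which(!obs_i)) {
      donors <- ord[!is.na(vals[ord, s])]
      if (!length(donors))
        stop("no donor features observed at sample ", colnames(vals)[s])
      kk <- min(k, length(donors))
      if (kk < k)
        warning(sprintf("knn_k reduced from %d to %d for feature %s",
                        k, kk, rownames(vals)[i]))
      out[i, s] <- mean(vals[donors[seq_len(kk)], s])
    }
  }
  out
}

#' Write the pipeline result bundle to a directory
#'
#' Emits subtype assignments, the domain-burden table, the DDG evidence
#' table, the classifier panel and metrics (JSON), and a run-manifest JSON
#' recording all parameters and seeds.
#'
#' @param assignment a `subtype_assignment` (or `NULL`).
#' @param tables named list of data.frames written as `<name>.tsv`.
#' @param json named list of objects written as `<name>.json`.
#' @param manifest named list written as `manifest.json`.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_results <- function(assignment = NULL, tables = list(), json = list(),
                          manifest = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wtab <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(assignment))
    paths <- c(paths, wtab(assignment$assignment, "subtype_assignments"))
  for (nm in names(tables)) paths <- c(paths, wtab(tables[[nm]], nm))
  for (nm in names(json)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(json[[nm]], p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  if (!is.null(manifest)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
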