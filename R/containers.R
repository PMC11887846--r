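#' Construct a per-nucleus count container
#'
#' Bundles a sparse nuclei-by-feature count matrix with its nucleus-level
#' metadata. This is the unit on which nucleus QC and pseudobulk aggregation
#' operate.
#'
#' @param counts Sparse (or dense) non-negative integer matrix, nuclei in
#'   rows, features in columns.
#' @param nucleus_meta Data frame with one row per nucleus. Must contain
#'   `nucleus_id`, `donor_id` and `cell_type`; QC columns (`total_counts`,
#'   `n_features_detected`, `mito_fraction`, and for ATAC `n_fragments`,
#'   `tss_enrichment`) are used when present.
#' @param feature_ids Character vector of unique feature identifiers,
#'   defaults to `colnames(counts)`.
#'
#' @return An object of class `nucleus_matrix`.
#' @export
nucleus_matrix <- function(counts, nucleus_meta, feature_ids = colnames(counts)) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  nucleus_meta <- tibble::as_tibble(nucleus_meta)
  if (is.null(feature_ids)) {
    feature_ids <- paste0("feature_", seq_len(ncol(counts)))
  }
  stopifnot(length(feature_ids) == ncol(counts))
  if (anyDuplicated(feature_ids)) {
    stop("feature_ids must be unique", call. = FALSE)
  }
  if (nrow(nucleus_meta) != nrow(counts)) {
    stop(sprintf(
      "nucleus metadata has %d rows but the count matrix has %d nuclei",
      nrow(nucleus_meta), nrow(counts)
    ), call. = FALSE)
  }
  req <- c("nucleus_id", "donor_id", "cell_type")
  missing_cols <- setdiff(req, names(nucleus_meta))
  if (length(missing_cols)) {
    stop("nucleus_meta lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(nucleus_meta$nucleus_id, feature_ids)
  structure(
    list(counts = counts, nucleus_meta = nucleus_meta,
         feature_ids = as.character(feature_ids)),
    class = "nucleus_matrix"
  )
}

#' @method print nucleus_matrix
#' @export
print.nucleus_matrix <- function(x, ...) {
  cat(sprintf(
    "<nucleus_matrix> %d nuclei x %d features, %d donors, %d cell types\n",
    nrow(x$counts), ncol(x$counts),
    dplyr::n_distinct(x$nucleus_meta$donor_id),
    dplyr::n_distinct(x$nucleus_meta$cell_type)
  ))
  invisible(x)
}

#' @export
dim.nucleus_matrix <- function(x) dim(x$counts)

#' Construct a pseudobulk assay
#'
#' A features-by-samples matrix of pseudobulk values, where each sample is a
#' donor or a donor/cell-type pair, together with the number of nuclei that
#' were aggregated into each sample. RNA pseudobulks carry summed integer
#' counts (`modality = "rna_counts"`); chromatin pseudobulks carry
#' non-negative real gene-activity scores (`modality = "atac_genescore"`).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param sample_meta Data frame with one row per sample: `sample_id`,
#'   `donor_id`, `cell_type` (or `"all"` for full pseudobulk), `n_cells`.
#' @param modality `"rna_counts"` or `"atac_genescore"`.
#' @param normalized Logical; whether cell-count normalization has been
#'   applied (gene scores only).
#'
#' @return An object of class `pseudobulk_assay`.
#' @export
pseudobulk_assay <- function(values, sample_meta,
                             modality = c("rna_counts", "atac_genescore"),
                             normalized = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  sample_meta <- tibble::as_tibble(sample_meta)
  if (nrow(sample_meta) != ncol(values)) {
    stop("sample_meta rows must match assay columns", call. = FALSE)
  }
  req <- c("sample_id", "donor_id", "cell_type", "n_cells")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols)) {
    stop("sample_meta lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (ncol(values) && any(sample_meta$n_cells < 1)) {
    stop("every pseudobulk sample must aggregate at least one nucleus",
         call. = FALSE)
  }
  if (any(values < 0)) stop("pseudobulk values must be non-negative", call. = FALSE)
  if (modality == "rna_counts" && length(values) &&
      any(values != round(values))) {
    stop("rna_counts pseudobulk values must be integers", call. = FALSE)
  }
  colnames(values) <- sample_meta$sample_id
  structure(
    list(values = values, sample_meta = sample_meta, modality = modality,
         normalized = isTRUE(normalized)),
    class = "pseudobulk_assay"
  )
}

#' @method print pseudobulk_assay
#' @export
print.pseudobulk_assay <- function(x, ...) {
  cat(sprintf(
    "<pseudobulk_assay:%s%s> %d features x %d samples (%d donors, %d cell types)\n",
    x$modality, if (x$normalized) ", normalized" else "",
    nrow(x$values), ncol(x$values),
    dplyr::n_distinct(x$sample_meta$donor_id),
    dplyr::n_distinct(x$sample_meta$cell_type)
  ))
  invisible(x)
}

#' @export
dim.pseudobulk_assay <- function(x) dim(x$values)

#' Subset a pseudobulk assay by sample
#'
#' @param pb A [pseudobulk_assay()].
#' @param keep Logical or integer index, or character `sample_id`s.
#' @return The subsetted assay.
#' @export
pb_subset_samples <- function(pb, keep) {
  stopifnot(inherits(pb, "pseudobulk_assay"))
  if (is.character(keep)) keep <- match(keep, pb$sample_meta$sample_id)
  pseudobulk_assay(pb$values[, keep, drop = FALSE],
                   pb$sample_meta[keep, , drop = FALSE],
                   modality = pb$modality, normalized = pb$normalized)
}

#' Subset a pseudobulk assay to one cell type
#'
#' @param pb A [pseudobulk_assay()].
#' @param cell_type Cell-type label to retain.
#' @return The subsetted assay.
#' @export
pb_subset_cell_type <- function(pb, cell_type) {
  pb_subset_samples(pb, pb$sample_meta$cell_type == cell_type)
}
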