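# Nucleus QC, pseudobulk aggregation, peak-derived gene-activity scores,
# cell-count normalization and parametric feature filtering.

#' QC thresholds for nucleus filtering
#'
#' Defaults follow the emulated study: RNA nuclei with total counts < 500,
#' fewer than 300 detected genes, or a mitochondrial fraction >= 0.15 are
#' removed; ATAC nuclei with fewer than 1000 or more than 100,000 unique
#' fragments, or a TSS enrichment score < 4, are removed. After nucleus
#' filtering, features detected in fewer than `min_nuclei` nuclei are
#' dropped.
#'
#' @param min_counts,min_genes,max_mito RNA thresholds.
#' @param min_fragments,max_fragments,min_tss ATAC thresholds.
#' @param min_nuclei Minimum nuclei a feature must be detected in.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_counts = 500, min_genes = 300,
                          max_mito = 0.15, min_fragments = 1000,
                          max_fragments = 100000, min_tss = 4,
                          min_nuclei = 500) {
  as.list(environment())
}

#' Filter nuclei and sparse features by QC thresholds
#'
#' Applies every threshold for which the corresponding metadata column is
#' present (`total_counts`, `n_features_detected`, `mito_fraction`,
#' `n_fragments`, `tss_enrichment`). Comparisons follow the stated rules
#' strictly: a nucleus with exactly 500 counts, 300 genes and mito fraction
#' 0.149 is kept.
#'
#' @param nm A [nucleus_matrix()].
#' @param thresholds A [qc_thresholds()] list.
#' @return The filtered [nucleus_matrix()]; a warning (not an error) is
#'   raised when nothing survives.
#' @export
qc_filter_nuclei <- function(nm, thresholds = qc_thresholds()) {
  stopifnot(inherits(nm, "nucleus_matrix"))
  meta <- nm$nucleus_meta
  keep <- rep(TRUE, nrow(meta))
  if ("total_counts" %in% names(meta)) {
    keep <- keep & meta$total_counts >= thresholds$min_counts
  }
  if ("n_features_detected" %in% names(meta)) {
    keep <- keep & meta$n_features_detected >= thresholds$min_genes
  }
  if ("mito_fraction" %in% names(meta)) {
    keep <- keep & meta$mito_fraction < thresholds$max_mito
  }
  if ("n_fragments" %in% names(meta)) {
    keep <- keep & meta$n_fragments >= thresholds$min_fragments &
      meta$n_fragments <= thresholds$max_fragments
  }
  if ("tss_enrichment" %in% names(meta)) {
    keep <- keep & meta$tss_enrichment >= thresholds$min_tss
  }
  counts <- nm$counts[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  detected <- Matrix::colSums(counts > 0)
  keep_feat <- detected >= thresholds$min_nuclei
  if (nrow(counts) == 0 || !any(keep_feat)) {
    warning("QC filtering left no nuclei or no features", call. = FALSE)
  }
  nucleus_matrix(counts[, keep_feat, drop = FALSE], meta,
                 feature_ids = nm$feature_ids[keep_feat])
}

#' Aggregate nuclei into pseudobulk samples
#'
#' Sums counts over nuclei within each donor/cell-type pair (default) or
#' within each donor across all cell types (full pseudobulk). Total counts
#' are conserved exactly; groups with zero nuclei are never emitted.
#'
#' @param nm A [nucleus_matrix()].
#' @param by `"donor_cell_type"` or `"donor"`.
#' @return A [pseudobulk_assay()] with modality `"rna_counts"`.
#' @export
aggregate_pseudobulk <- function(nm, by = c("donor_cell_type", "donor")) {
  by <- match.arg(by)
  stopifnot(inherits(nm, "nucleus_matrix"))
  meta <- nm$nucleus_meta
  group <- if (by == "donor_cell_type") {
    paste(meta$donor_id, meta$cell_type, sep = ".")
  } else {
    meta$donor_id
  }
  f <- factor(group, levels = sort(unique(group)))
  ind <- Matrix::sparseMatrix(
    i = as.integer(f), j = seq_along(f), x = 1,
    dims = c(nlevels(f), length(f))
  )
  vals <- as.matrix(ind %*% nm$counts)  # groups x features
  vals <- t(vals)
  rownames(vals) <- nm$feature_ids
  first <- match(levels(f), group)
  sample_meta <- tibble::tibble(
    sample_id = levels(f),
    donor_id = meta$donor_id[first],
    cell_type = if (by == "donor_cell_type") meta$cell_type[first] else "all",
    n_cells = as.integer(table(f))
  )
  pseudobulk_assay(vals, sample_meta, modality = "rna_counts")
}

#' Compute distance-weighted gene-activity scores from peak counts
#'
#' For each gene and sample, sums the accessibility counts of all peaks
#' within `window` bp of the gene body, weighted by an exponential decay of
#' the peak--gene distance: `w(d) = exp(-d / decay)` with `d = 0` for peaks
#' overlapping the gene body and otherwise the bp gap to the nearest
#' gene-body edge. The window is symmetric (100 kb up- and downstream by
#' default); strand is ignored for distance.
#'
#' @param peak_counts A [pseudobulk_assay()] whose rows are peaks.
#' @param peaks Peak tibble (`peak_id`, `chrom`, `start`, `end`).
#' @param genes Gene annotation tibble.
#' @param window Maximum peak--gene distance in bp (default 100000).
#' @param decay Exponential decay length in bp (default 5000).
#' @return A [pseudobulk_assay()] with modality `"atac_genescore"`, rows =
#'   genes. Genes with no in-window peak score 0 and are listed in the
#'   `"no_peak_genes"` attribute.
#' @export
compute_gene_scores <- function(peak_counts, peaks, genes,
                                window = 100000, decay = 5000) {
  stopifnot(inherits(peak_counts, "pseudobulk_assay"))
  missing_peaks <- setdiff(rownames(peak_counts$values), peaks$peak_id)
  if (length(missing_peaks)) {
    stop("peak count rows absent from the peak set: ",
         paste(utils::head(missing_peaks, 3), collapse = ", "),
         call. = FALSE)
  }
  pairs <- dplyr::inner_join(
    dplyr::select(genes, "gene_id", "chrom", gstart = "start", gend = "end"),
    dplyr::select(peaks, "peak_id", "chrom", pstart = "start", pend = "end"),
    by = "chrom", relationship = "many-to-many"
  )
  pairs <- pairs |>
    dplyr::mutate(d = pmax(0, .data$gstart - .data$pend,
                           .data$pstart - .data$gend)) |>
    dplyr::filter(.data$d <= window) |>
    dplyr::mutate(w = exp(-.data$d / decay))
  gene_ids <- genes$gene_id
  w_mat <- Matrix::sparseMatrix(
    i = match(pairs$gene_id, gene_ids),
    j = match(pairs$peak_id, rownames(peak_counts$values)),
    x = pairs$w,
    dims = c(length(gene_ids), nrow(peak_counts$values))
  )
  scores <- as.matrix(w_mat %*% peak_counts$values)
  rownames(scores) <- gene_ids
  out <- pseudobulk_assay(scores, peak_counts$sample_meta,
                          modality = "atac_genescore")
  attr(out, "no_peak_genes") <- setdiff(gene_ids, unique(pairs$gene_id))
  out
}

#' Normalize gene scores by aggregated cell counts
#'
#' Divides every sample column by its number of aggregated nuclei. A second
#' call on already-normalized scores is an error.
#'
#' @param pb A [pseudobulk_assay()] with modality `"atac_genescore"`.
#' @return The normalized assay with its normalization flag set.
#' @export
normalize_gene_scores <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_assay"))
  if (pb$modality != "atac_genescore") {
    stop("cell-count normalization applies to gene scores only",
         call. = FALSE)
  }
  if (pb$normalized) {
    stop("gene scores are already cell-count normalized", call. = FALSE)
  }
  if (any(pb$sample_meta$n_cells <= 0)) {
    stop("n_cells must be positive for normalization", call. = FALSE)
  }
  vals <- sweep(pb$values, 2, pb$sample_meta$n_cells, "/")
  pseudobulk_assay(vals, pb$sample_meta, modality = pb$modality,
                   normalized = TRUE)
}

#' Filter features by a minimum value in a minimum fraction of samples
#'
#' A feature is kept iff the number of samples meeting the per-modality
#' comparison is at least `ceiling(min_fraction * n_samples)`. Counts use
#' `value >= min_value` ("a minimum of 10 counts"); gene scores use
#' `value > min_value` ("scores above 0.1").
#'
#' @param pb A [pseudobulk_assay()].
#' @param min_value Threshold value (default 10 for counts, 0.1 for scores).
#' @param min_fraction Required fraction of samples, in (0, 1].
#' @return The row-filtered assay.
#' @export
filter_features <- function(pb,
                            min_value = if (pb$modality == "rna_counts") 10 else 0.1,
                            min_fraction = 0.75) {
  stopifnot(inherits(pb, "pseudobulk_assay"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  }
  n <- ncol(pb$values)
  need <- ceiling(min_fraction * n)
  ok <- if (pb$modality == "rna_counts") {
    rowSums(pb$values >= min_value)
  } else {
    rowSums(pb$values > min_value)
  }
  keep <- ok >= need
  pseudobulk_assay(pb$values[keep, , drop = FALSE], pb$sample_meta,
                   modality = pb$modality, normalized = pb$normalized)
}
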