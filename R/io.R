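#' @importFrom rlang .data
NULL

fixed_precision <- function(df, digits = 10) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, digits)))
}

#' Read a per-nucleus count matrix with its sidecar metadata
#'
#' Expects a Matrix Market file (nuclei in rows, features in columns), a
#' tab-separated nucleus metadata table whose rows parallel the matrix rows,
#' and a feature table (or plain list) whose rows parallel the columns.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param nucleus_meta_path Path to the nucleus metadata TSV.
#' @param feature_path Path to the feature TSV (first column = feature id).
#' @return A [nucleus_matrix()].
#' @export
read_nucleus_counts <- function(mtx_path, nucleus_meta_path, feature_path) {
  counts <- Matrix::readMM(mtx_path)
  meta <- readr::read_tsv(nucleus_meta_path, show_col_types = FALSE,
                          progress = FALSE)
  feats <- readr::read_tsv(feature_path, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(meta) != nrow(counts)) {
    stop(sprintf(
      "%s: %d metadata rows do not match %d matrix rows (first extra row: %d)",
      nucleus_meta_path, nrow(meta), nrow(counts),
      min(nrow(meta), nrow(counts)) + 1L
    ), call. = FALSE)
  }
  if (nrow(feats) != ncol(counts)) {
    stop(sprintf("%s: %d feature rows do not match %d matrix columns",
                 feature_path, nrow(feats), ncol(counts)), call. = FALSE)
  }
  nucleus_matrix(counts, meta, feature_ids = as.character(feats[[1]]))
}

#' Write a per-nucleus count matrix and its sidecars
#'
#' @param nm A [nucleus_matrix()].
#' @param mtx_path,nucleus_meta_path,feature_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_nucleus_counts <- function(nm, mtx_path, nucleus_meta_path, feature_path) {
  Matrix::writeMM(nm$counts, mtx_path)
  readr::write_tsv(nm$nucleus_meta, nucleus_meta_path, progress = FALSE)
  readr::write_tsv(tibble::tibble(feature_id = nm$feature_ids), feature_path,
                   progress = FALSE)
  invisible(c(mtx_path, nucleus_meta_path, feature_path))
}

#' Write a pseudobulk assay as Matrix Market plus TSV sidecars
#'
#' Emits `<prefix>.mtx` (features x samples), `<prefix>_samples.tsv`
#' (sample metadata including `modality` and `normalized`), and
#' `<prefix>_features.tsv`.
#'
#' @param pb A [pseudobulk_assay()].
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the paths written.
#' @export
write_pseudobulk_assay <- function(pb, prefix) {
  stopifnot(inherits(pb, "pseudobulk_assay"))
  paths <- paste0(prefix, c(".mtx", "_samples.tsv", "_features.tsv"))
  Matrix::writeMM(Matrix::Matrix(pb$values, sparse = TRUE), paths[1])
  readr::write_tsv(
    dplyr::mutate(pb$sample_meta, modality = pb$modality,
                  normalized = pb$normalized),
    paths[2], progress = FALSE
  )
  readr::write_tsv(tibble::tibble(feature_id = rownames(pb$values)),
                   paths[3], progress = FALSE)
  invisible(paths)
}

#' Read a pseudobulk assay written by [write_pseudobulk_assay()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [pseudobulk_assay()].
#' @export
read_pseudobulk_assay <- function(prefix) {
  vals <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  meta <- readr::read_tsv(paste0(prefix, "_samples.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  feats <- readr::read_tsv(paste0(prefix, "_features.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(meta) != ncol(vals) || nrow(feats) != nrow(vals)) {
    stop(prefix, ": sidecar dimensions do not match the matrix",
         call. = FALSE)
  }
  rownames(vals) <- feats$feature_id
  modality <- unique(meta$modality)
  normalized <- unique(meta$normalized)
  stopifnot(length(modality) == 1, length(normalized) == 1)
  pseudobulk_assay(
    vals,
    dplyr::select(dplyr::mutate(meta,
                                donor_id = as.character(.data$donor_id)),
                  -"modality", -"normalized"),
    modality = modality, normalized = normalized
  )
}

#' Read the donor cohort table
#'
#' Required columns: `donor_id`, `disease_status` (`case`/`control`), `sex`
#' (`F`/`M`), `age`, `pH`, `pmi`, `rin` (may contain missing values),
#' `lib_batch`. A `diagnosis` column is carried through when present.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per donor, sorted by `donor_id`.
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("donor_id", "disease_status", "sex", "age", "pH", "pmi",
           "rin", "lib_batch")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop(path, ": cohort table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_status <- setdiff(unique(x$disease_status), c("case", "control"))
  if (length(bad_status)) {
    stop(path, ": unknown disease_status value(s): ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  x |>
    dplyr::mutate(
      donor_id = as.character(.data$donor_id),
      lib_batch = as.character(.data$lib_batch),
      sex = as.character(.data$sex)
    ) |>
    dplyr::arrange(.data$donor_id)
}

#' Read a per-donor polygenic risk score table
#'
#' @param path TSV with a `donor_id` column and one numeric column per trait.
#' @return A tibble sorted by `donor_id`.
#' @export
read_prs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"donor_id" %in% names(x)) {
    stop(path, ": PRS table needs a donor_id column", call. = FALSE)
  }
  traits <- setdiff(names(x), "donor_id")
  if (!length(traits)) stop(path, ": PRS table has no trait columns", call. = FALSE)
  if (any(!vapply(x[traits], is.numeric, logical(1)))) {
    stop(path, ": PRS columns must be numeric", call. = FALSE)
  }
  dplyr::arrange(dplyr::mutate(x, donor_id = as.character(.data$donor_id)),
                 .data$donor_id)
}

#' Read a peak set from BED
#'
#' BED coordinates are 0-based half-open and kept that way throughout the
#' package. A fourth column supplies peak ids; otherwise ids are derived
#' from the coordinates.
#'
#' @param path Path to a BED file (no header).
#' @return Tibble with `peak_id`, `chrom`, `start`, `end`, sorted by
#'   position.
#' @export
read_peaks_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 3) stop(path, ": BED needs at least 3 columns", call. = FALSE)
  out <- tibble::tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    peak_id = if (ncol(x) >= 4) as.character(x[[4]]) else
      paste0(x[[1]], ":", x[[2]], "-", x[[3]])
  )
  if (any(out$start >= out$end)) {
    stop(path, ": BED intervals must satisfy start < end (row ",
         which(out$start >= out$end)[1], ")", call. = FALSE)
  }
  dplyr::arrange(dplyr::select(out, "peak_id", "chrom", "start", "end"),
                 .data$chrom, .data$start, .data$end)
}

#' Write a peak set as BED
#' @param peaks Peak tibble as returned by [read_peaks_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  readr::write_tsv(
    dplyr::select(dplyr::arrange(peaks, .data$chrom, .data$start, .data$end),
                  "chrom", "start", "end", "peak_id"),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `start`, `end`,
#' `strand`. Coordinates are interpreted as 0-based half-open by default;
#' set `one_based = TRUE` for GFF-style 1-based closed input, which is
#' converted on read.
#'
#' @param path Path to the TSV.
#' @param one_based Convert from 1-based closed coordinates.
#' @return Tibble sorted by position.
#' @export
read_gene_annotation <- function(path, one_based = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop(path, ": gene annotation lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- dplyr::mutate(x, start = as.integer(.data$start),
                     end = as.integer(.data$end))
  if (one_based) x <- dplyr::mutate(x, start = .data$start - 1L)
  if (any(!x$strand %in% c("+", "-"))) {
    stop(path, ": strand must be '+' or '-'", call. = FALSE)
  }
  if (any(x$start >= x$end)) {
    stop(path, ": gene intervals must satisfy start < end", call. = FALSE)
  }
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Read a GMT gene-set collection
#'
#' Each line: set id, description, then one or more member gene ids, all
#' tab-separated. Duplicate members within a set are removed with a warning.
#'
#' @param path Path to the GMT file.
#' @return Tibble with `set_id`, `description`, and a `members` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3)) {
    stop(sprintf("%s: line %d has %d field(s); GMT lines need set id, description and >=1 member",
                 path, which(n_fields < 3)[1], n_fields[which(n_fields < 3)[1]]),
         call. = FALSE)
  }
  sets <- purrr::map(parts, function(p) {
    members <- p[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicate members removed", p[1]),
              call. = FALSE)
      members <- unique(members)
    }
    tibble::tibble(set_id = p[1], description = p[2],
                   members = list(members))
  })
  out <- dplyr::bind_rows(sets)
  if (anyDuplicated(out$set_id)) {
    stop(path, ": duplicate set ids", call. = FALSE)
  }
  dplyr::arrange(out, .data$set_id)
}

#' Write a gene-set collection as GMT
#' @param sets Tibble from [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    dplyr::arrange(sets, .data$set_id),
    function(set_id, description, members, ...) {
      paste(c(set_id, description, members), collapse = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a binary peak-by-motif annotation
#'
#' TSV with a `peak_id` first column and one 0/1 column per motif.
#'
#' @param path Path to the TSV.
#' @param peaks Optional peak tibble; when given, peak ids are validated
#'   against it.
#' @return Tibble (peak_id + motif columns), sorted by `peak_id`.
#' @export
read_motif_annotation <- function(path, peaks = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "peak_id") {
    stop(path, ": first column of the motif table must be peak_id",
         call. = FALSE)
  }
  vals <- as.matrix(x[-1])
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop(path, ": motif annotation must be binary (0/1)", call. = FALSE)
  }
  if (!is.null(peaks)) {
    unknown <- setdiff(x$peak_id, peaks$peak_id)
    if (length(unknown)) {
      stop(path, ": motif table references unknown peak id(s): ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
  }
  dplyr::arrange(dplyr::mutate(x, peak_id = as.character(.data$peak_id)),
                 .data$peak_id)
}

#' Read and cross-validate the full input bundle
#'
#' Reads whichever inputs are supplied, validates cross-references (every
#' donor in the nucleus metadata and the PRS table must exist in the cohort;
#' motif peak ids must exist in the peak set) and returns them sorted and
#' ready for the pipeline.
#'
#' @param paths Named list of file paths. Recognized names: `cohort`,
#'   `prs`, `counts_mtx` + `nucleus_meta` + `features`, `peaks_bed`,
#'   `genes`, `gmt`, `motifs`.
#' @return A named list with elements `cohort`, and (when provided) `prs`,
#'   `nuclei`, `peaks`, `genes`, `gene_sets`, `motifs`.
#' @export
read_inputs <- function(paths) {
  if (is.null(paths$cohort)) stop("paths$cohort is required", call. = FALSE)
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  bundle <- list(cohort = read_cohort(paths$cohort))
  if (!is.null(paths$prs)) {
    bundle$prs <- read_prs(paths$prs)
    unknown <- setdiff(bundle$prs$donor_id, bundle$cohort$donor_id)
    if (length(unknown)) {
      stop("PRS table contains donor(s) absent from the cohort: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(paths$counts_mtx)) {
    bundle$nuclei <- read_nucleus_counts(paths$counts_mtx,
                                         paths$nucleus_meta, paths$features)
    unknown <- setdiff(bundle$nuclei$nucleus_meta$donor_id,
                       bundle$cohort$donor_id)
    if (length(unknown)) {
      stop("nucleus metadata contains donor(s) absent from the cohort: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(paths$peaks_bed)) bundle$peaks <- read_peaks_bed(paths$peaks_bed)
  if (!is.null(paths$genes)) bundle$genes <- read_gene_annotation(paths$genes)
  if (!is.null(paths$gmt)) bundle$gene_sets <- read_gmt(paths$gmt)
  if (!is.null(paths$motifs)) {
    bundle$motifs <- read_motif_annotation(paths$motifs, peaks = bundle$peaks)
  }
  bundle
}

#' Write pipeline results to a directory
#'
#' Differential results, enrichment tables and proportion comparisons are
#' written as TSV with fixed float precision and deterministic row order;
#' correlation networks additionally as GraphML. Re-running on identical
#' results produces byte-identical files.
#'
#' @param results Named list; recognized elements: `differential` (tibble),
#'   `pathway_enrichment`, `motif_enrichment`, `proportions` (tibbles),
#'   `network` (a `correlation_network`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a character vector of files written.
#' @export
write_outputs <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to output directory: ", out_dir, call. = FALSE)
  }
  written <- character()
  emit_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(fixed_precision(tibble::as_tibble(df)), path,
                     progress = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(results$differential)) {
    emit_tsv(dplyr::arrange(results$differential, .data$contrast,
                            .data$modality, .data$cell_type, .data$gene_id),
             "differential_results.tsv")
  }
  if (!is.null(results$pathway_enrichment)) {
    emit_tsv(results$pathway_enrichment, "pathway_enrichment.tsv")
  }
  if (!is.null(results$motif_enrichment)) {
    emit_tsv(results$motif_enrichment, "motif_enrichment.tsv")
  }
  if (!is.null(results$proportions)) {
    emit_tsv(results$proportions, "proportion_tests.tsv")
  }
  if (!is.null(results$risk_groups)) {
    emit_tsv(results$risk_groups$assignment, "risk_group_assignment.tsv")
    emit_tsv(results$risk_groups$balance, "risk_group_balance.tsv")
  }
  if (!is.null(results$network)) {
    emit_tsv(dplyr::arrange(results$network$edges, .data$from, .data$to),
             "network_edges.tsv")
    g <- as_igraph(results$network)
    path <- file.path(out_dir, "network.graphml")
    igraph::write_graph(g, path, format = "graphml")
    written <- c(written, path)
  }
  invisible(written)
}
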