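# End-to-end orchestration: configuration validation, staged execution from
# QC through networks, provenance logging, and output writing.

#' Default pipeline configuration
#'
#' Every threshold defaults to the emulated study's value: QC thresholds
#' per [qc_thresholds()]; count filter 10 counts in 75% of samples (90% for
#' covariate selection); gene-score filter above 0.1 in 75%; differential
#' FDR 0.1; enrichment FDR 0.05 with 250 genes per direction; extreme pools
#' of 20 donors; network edges at nominal p 0.05; promoter window 2 kb
#' upstream to 500 bp downstream.
#'
#' @param ... Overrides for any default field.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    qc = qc_thresholds(),
    count_min_value = 10, count_min_fraction = 0.75,
    covariate_min_fraction = 0.9,
    score_min_value = 0.1, score_min_fraction = 0.75,
    covariate_alpha = 0.05, n_covariate_pcs = 10,
    sd_threshold = 3, min_samples = 6,
    fdr_threshold = 0.1,
    n_extreme = 20,
    matching_covariates = c("age", "pH", "pmi", "rin"),
    enrichment_fdr = 0.05, top_n = 250,
    promoter_upstream = 2000, promoter_downstream = 500,
    network_p = 0.05, network_max_genes = 10,
    n_motif_genes = 3,
    caliper = 1,
    traits = "scz",
    contrasts = c("diagnosis", "risk"),
    out_dir = NULL
  )
  validate_config(utils::modifyList(defaults, list(...)))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills missing fields with defaults, rejects unknown keys, and checks
#' ranges; all problems are reported at once.
#'
#' @param config Named list of configuration values.
#' @return The normalized config (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  defaults <- list(
    seed = 1L, qc = qc_thresholds(),
    count_min_value = 10, count_min_fraction = 0.75,
    covariate_min_fraction = 0.9,
    score_min_value = 0.1, score_min_fraction = 0.75,
    covariate_alpha = 0.05, n_covariate_pcs = 10,
    sd_threshold = 3, min_samples = 6, fdr_threshold = 0.1,
    n_extreme = 20, matching_covariates = c("age", "pH", "pmi", "rin"),
    enrichment_fdr = 0.05, top_n = 250,
    promoter_upstream = 2000, promoter_downstream = 500,
    network_p = 0.05, network_max_genes = 10, n_motif_genes = 3,
    caliper = 1,
    traits = "scz", contrasts = c("diagnosis", "risk"), out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  errors <- character()
  if (length(unknown)) {
    errors <- c(errors, paste("unknown config key(s):",
                              paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  check_frac <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      errors <<- c(errors, paste0(name, " must lie in (0, 1], got ", v))
    }
  }
  for (nm in c("count_min_fraction", "covariate_min_fraction",
               "score_min_fraction")) check_frac(nm)
  for (nm in c("fdr_threshold", "enrichment_fdr", "network_p",
               "covariate_alpha")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      errors <- c(errors, paste0(nm, " must lie in [0, 1], got ", v))
    }
  }
  if (cfg$n_extreme < 1) errors <- c(errors, "n_extreme must be >= 1")
  if (cfg$sd_threshold <= 0) errors <- c(errors, "sd_threshold must be > 0")
  bad_contrast <- setdiff(cfg$contrasts, c("diagnosis", "risk"))
  if (length(bad_contrast)) {
    errors <- c(errors, paste("unknown contrast(s):",
                              paste(bad_contrast, collapse = ", ")))
  }
  if ("risk" %in% cfg$contrasts && !length(cfg$traits)) {
    errors <- c(errors, "risk contrast requested but no traits configured")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Assemble the samples-by-features table for the risk network: transformed
# expression and normalized log2 gene scores of the selected genes in their
# best cell type, plus PRS columns and disease status.
build_network_features <- function(rna_pb, atac_pb, gene_cell, donors,
                                   cohort, traits) {
  feature_cols <- list()
  meta_rows <- list()
  add_block <- function(pb, transform, suffix, modality) {
    for (i in seq_len(nrow(gene_cell))) {
      g <- gene_cell$gene_id[i]
      ct <- gene_cell$cell_type[i]
      sel <- pb$sample_meta$cell_type == ct & pb$sample_meta$donor_id %in% donors
      if (!any(sel) || !g %in% rownames(pb$values)) next
      sub <- pb_subset_samples(pb, sel)
      vals <- transform(sub)
      if (!g %in% rownames(vals)) next
      nm <- paste(g, ct, suffix, sep = ".")
      v <- vals[g, ][match(donors, sub$sample_meta$donor_id)]
      if (anyNA(v)) next
      feature_cols[[nm]] <<- unname(v)
      meta_rows[[nm]] <<- tibble::tibble(feature = nm, modality = modality,
                                         cell_type = ct)
    }
  }
  add_block(rna_pb, function(sub) transform_counts(sub)$matrix, "expr",
            "expression")
  add_block(atac_pb, function(sub) {
    norm <- if (sub$normalized) sub else normalize_gene_scores(sub)
    log2(norm$values + 1)
  }, "acc", "accessibility")
  co <- cohort[match(donors, cohort$donor_id), ]
  for (tr in traits) {
    nm <- paste0("PRS_", tr)
    feature_cols[[nm]] <- co[[paste0("prs_", tr)]]
    meta_rows[[nm]] <- tibble::tibble(feature = nm, modality = "prs",
                                      cell_type = NA_character_)
  }
  feature_cols$status <- as.numeric(co$disease_status == "case")
  meta_rows$status <- tibble::tibble(feature = "status", modality = "status",
                                     cell_type = NA_character_)
  list(
    table = dplyr::bind_cols(tibble::tibble(donor_id = donors),
                             tibble::as_tibble(feature_cols)),
    node_meta = dplyr::bind_rows(meta_rows),
    covariates = co
  )
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis on a data bundle: optional nucleus QC and
#' aggregation, covariate selection on the full pseudobulk, per-cell-type
#' differential expression and accessibility for the diagnosis contrast,
#' matched extreme-risk group construction and risk contrasts per trait,
#' pathway and motif over-representation, the multi-omic Spearman network
#' on the matched risk donors, and the paired cell-type proportion
#' comparison. Execution is deterministic given the bundle and config;
#' a rerun writes byte-identical outputs.
#'
#' @param data Bundle with `cohort`, `rna` (either `$assay` pseudobulk or a
#'   `nuclei` [nucleus_matrix()]), `atac` (`$assay` gene scores), and
#'   `annotations` (`genes`, `peaks`, `motifs`, `gene_sets`), as produced
#'   by [simulate_study()] or assembled from [read_inputs()].
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `covariates`
#'   (covariate_report), `selected_covariates`, `de`, `da`, `risk_groups`,
#'   `risk_de`, `risk_da` (per trait), `pathways`, `motifs`, `network`,
#'   `proportions`, `log`, `config`. If `config$out_dir` is set, outputs
#'   are written there.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  config <- validate_config(config)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  cohort <- data$cohort
  res <- list(config = config)

  rna_pb <- stage("pseudobulk", {
    if (!is.null(data$rna$nuclei)) {
      nm <- qc_filter_nuclei(data$rna$nuclei, config$qc)
      note("qc: retained %d of %d nuclei", nrow(nm$counts),
           nrow(data$rna$nuclei$counts))
      aggregate_pseudobulk(nm, by = "donor_cell_type")
    } else {
      data$rna$assay
    }
  })
  atac_pb <- data$atac$assay
  note("pseudobulk: rna %d x %d, atac %d x %d", nrow(rna_pb$values),
       ncol(rna_pb$values), nrow(atac_pb$values), ncol(atac_pb$values))

  res$covariates <- stage("covariate_selection", {
    full <- rna_pb$values
    donor <- rna_pb$sample_meta$donor_id
    agg <- t(rowsum(t(full), donor))  # features x donors
    donors <- colnames(agg)
    full_pb <- pseudobulk_assay(
      agg,
      tibble::tibble(sample_id = donors, donor_id = donors,
                     cell_type = "all",
                     n_cells = as.integer(tapply(rna_pb$sample_meta$n_cells,
                                                 donor, sum)[donors])),
      modality = "rna_counts"
    )
    full_pb <- filter_features(full_pb, min_value = config$count_min_value,
                               min_fraction = config$covariate_min_fraction)
    tr <- transform_counts(full_pb)
    p <- pca_scores(t(tr$matrix), n_pcs = config$n_covariate_pcs)
    tab <- cohort[match(donors, cohort$donor_id), ]
    associate_covariates_with_pcs(p$scores, tab,
                                  alpha = config$covariate_alpha,
                                  n_pcs = config$n_covariate_pcs)
  })
  continuous <- c("age", "pH", "pmi", "rin")
  selected <- intersect(continuous, res$covariates$selected)
  res$selected_covariates <- selected
  note("covariates selected: %s",
       paste(res$covariates$selected, collapse = ", "))

  if ("diagnosis" %in% config$contrasts) {
    res$de <- stage("differential_expression", run_differential(
      rna_pb, cohort, contrast = "diagnosis", covariates = selected,
      min_value = config$count_min_value,
      min_fraction = config$count_min_fraction,
      fdr_threshold = config$fdr_threshold,
      min_samples = config$min_samples, sd_threshold = config$sd_threshold
    ))
    res$da <- stage("differential_accessibility", run_differential(
      atac_pb, cohort, contrast = "diagnosis", covariates = selected,
      min_value = config$score_min_value,
      min_fraction = config$score_min_fraction,
      fdr_threshold = config$fdr_threshold,
      min_samples = config$min_samples, sd_threshold = config$sd_threshold
    ))
    note("diagnosis: %d DE / %d DA genes at FDR<=%g",
         nrow(significant_genes(res$de)), nrow(significant_genes(res$da)),
         config$fdr_threshold)
  }

  if ("risk" %in% config$contrasts) {
    res$risk_groups <- list()
    res$risk_de <- list()
    res$risk_da <- list()
    for (tr in config$traits) {
      rg <- stage(paste0("risk_groups:", tr), define_risk_groups(
        cohort, tr, n_extreme = config$n_extreme,
        covariates = config$matching_covariates, caliper = config$caliper
      ))
      res$risk_groups[[tr]] <- rg
      rt <- risk_contrast_table(cohort, rg)
      note("risk:%s: %d matched pairs", tr, nrow(rg$pairs))
      res$risk_de[[tr]] <- stage(paste0("risk_de:", tr), run_differential(
        rna_pb, rt, contrast = paste0("risk:", tr), covariates = selected,
        min_value = config$count_min_value,
        min_fraction = config$count_min_fraction,
        fdr_threshold = config$fdr_threshold,
        min_samples = config$min_samples, sd_threshold = config$sd_threshold
      ))
      res$risk_da[[tr]] <- stage(paste0("risk_da:", tr), run_differential(
        atac_pb, rt, contrast = paste0("risk:", tr), covariates = selected,
        min_value = config$score_min_value,
        min_fraction = config$score_min_fraction,
        fdr_threshold = config$fdr_threshold,
        min_samples = config$min_samples, sd_threshold = config$sd_threshold
      ))
    }
  }

  if (!is.null(data$annotations$gene_sets) && !is.null(res$de)) {
    res$pathways <- stage("pathway_enrichment", suppressWarnings(
      pathway_enrichment(res$de, data$annotations$gene_sets,
                         top_n = config$top_n,
                         fdr_threshold = config$enrichment_fdr)
    ))
  }

  primary <- config$traits[1]
  if (!is.null(res$risk_de) && !is.null(data$annotations$motifs)) {
    res$motifs <- stage("motif_enrichment", {
      tab <- res$risk_de[[primary]]$table
      top <- dplyr::arrange(tab, .data$fdr, .data$p_value, .data$gene_id)
      genes <- utils::head(intersect(top$gene_id,
                                     data$annotations$genes$gene_id),
                           config$n_motif_genes)
      dplyr::bind_rows(purrr::map(genes, function(g) {
        motif_enrichment(g, data$annotations$genes, data$annotations$peaks,
                         data$annotations$motifs,
                         upstream = config$promoter_upstream,
                         downstream = config$promoter_downstream,
                         fdr_threshold = config$enrichment_fdr)
      }))
    })
  }

  n_matched_primary <- if (length(res$risk_groups))
    2 * nrow(res$risk_groups[[primary]]$pairs) else 0
  if (!is.null(res$risk_de) && n_matched_primary >= 5) {
    res$network <- stage("network", {
      rg <- res$risk_groups[[primary]]
      donors <- sort(c(rg$pairs$high_donor, rg$pairs$low_donor))
      de_tab <- res$risk_de[[primary]]$table
      da_tab <- res$risk_da[[primary]]$table
      sig <- de_tab |>
        dplyr::filter(!is.na(.data$fdr),
                      .data$fdr <= config$fdr_threshold,
                      .data$gene_id %in% da_tab$gene_id)
      if (!nrow(sig)) {
        sig <- de_tab |>
          dplyr::filter(.data$gene_id %in% da_tab$gene_id) |>
          dplyr::arrange(.data$p_value)
      }
      gene_cell <- sig |>
        dplyr::arrange(.data$fdr, .data$p_value, .data$gene_id) |>
        dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
        utils::head(config$network_max_genes) |>
        dplyr::select("gene_id", "cell_type")
      nf <- build_network_features(rna_pb, atac_pb, gene_cell, donors,
                                   cohort, config$traits)
      spearman_network(nf$table, nf$node_meta,
                       covariate_table = impute_rin(nf$covariates),
                       p_threshold = config$network_p)
    })
    note("network: %d nodes, %d edges", nrow(res$network$nodes),
         nrow(res$network$edges))
  } else if (!is.null(res$risk_de)) {
    note("network: skipped (fewer than 5 matched donors)")
  }

  res$proportions <- stage("proportions", {
    props <- dplyr::bind_rows(
      pb_cell_type_proportions(rna_pb, modality = "rna"),
      pb_cell_type_proportions(atac_pb, modality = "atac")
    )
    compare_proportions(props, "atac", "rna")
  })
  note("proportions: median donor-wise Pearson r = %.3f",
       res$proportions$median_r)

  res$log <- log
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    out <- list(
      differential = dplyr::bind_rows(
        purrr::map(purrr::compact(c(list(res$de, res$da), res$risk_de,
                                    res$risk_da)), "table")
      ),
      pathway_enrichment = res$pathways,
      motif_enrichment = res$motifs,
      proportions = res$proportions$tests,
      network = res$network,
      risk_groups = if (length(res$risk_groups))
        res$risk_groups[[primary]] else NULL
    )
    write_outputs(purrr::compact(out), config$out_dir)
    jsonlite::write_json(
      c(unclass(config)[setdiff(names(config), c("qc", "out_dir"))],
        list(qc = config$qc)),
      file.path(config$out_dir, "config.json"),
      auto_unbox = TRUE, null = "null", digits = NA
    )
    readr::write_lines(log, file.path(config$out_dir, "pipeline_log.txt"))
  }
  res
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
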