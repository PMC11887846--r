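# Over-representation enrichment (gene sets, TF motifs), multi-omic
# Spearman correlation networks, cross-study effect-size correlation, and
# paired cell-type proportion comparisons.

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p value `P(X >= k)` for the overlap of a
#' selection with each set, all intersected with the universe, followed by
#' BH adjustment across sets.
#'
#' @param selection Character vector of selected ids (subset of universe).
#' @param universe Character vector of all tested ids.
#' @param sets Tibble with `set_id` and a `members` list-column (as from
#'   [read_gmt()]), or a named list of id vectors.
#' @param direction Label stored in the `direction` column (default
#'   `"n/a"`).
#' @return Tibble: `set_id`, `overlap_k`, `set_size_K`, `selection_n`,
#'   `universe_N`, `p_value`, `fdr`, `direction`.
#' @export
hypergeometric_enrichment <- function(selection, universe, sets,
                                      direction = "n/a") {
  universe <- unique(universe)
  selection <- unique(selection)
  if (!all(selection %in% universe)) {
    stop("selection must be a subset of the universe", call. = FALSE)
  }
  if (!is.data.frame(sets)) {
    sets <- tibble::tibble(set_id = names(sets), members = unname(sets))
  }
  n_cap <- length(universe)
  n_sel <- length(selection)
  res <- purrr::map2_dfr(sets$set_id, sets$members, function(id, mem) {
    mem <- intersect(unique(mem), universe)
    k <- length(intersect(mem, selection))
    K <- length(mem)
    p <- stats::phyper(k - 1, K, n_cap - K, n_sel, lower.tail = FALSE)
    tibble::tibble(set_id = id, overlap_k = k, set_size_K = K,
                   selection_n = n_sel, universe_N = n_cap, p_value = p)
  })
  res$fdr <- bh_adjust(res$p_value)
  res$direction <- direction
  dplyr::arrange(res, .data$p_value, .data$set_id)
}

#' Pathway over-representation of top differential genes
#'
#' For each cell type and regulation direction, takes the `top_n` genes
#' ranked by (FDR ascending, |log2FC| descending, gene id ascending) among
#' genes with the matching sign of log2FC, and tests the gene sets for
#' over-representation against the genes tested in that cell type.
#' Directions with fewer than 10 genes are skipped with a warning.
#'
#' @param diff A `differential_result` or its tidy table.
#' @param gene_sets Gene-set tibble (see [read_gmt()]).
#' @param top_n Genes per direction (default 250).
#' @param fdr_threshold Significance threshold on the enrichment FDR
#'   (default 0.05); stored in the `significant` column.
#' @return Tibble of enrichment results with `cell_type` and `direction`
#'   (`"up"` / `"down"`).
#' @export
pathway_enrichment <- function(diff, gene_sets, top_n = 250,
                               fdr_threshold = 0.05) {
  table <- if (inherits(diff, "differential_result")) diff$table else diff
  out <- list()
  for (ct in sort(unique(table$cell_type))) {
    sub <- dplyr::filter(table, .data$cell_type == ct,
                         !is.na(.data$p_value))
    universe <- sub$gene_id
    for (dir in c("up", "down")) {
      cand <- dplyr::filter(sub, if (dir == "up") .data$log2FC > 0 else
        .data$log2FC < 0)
      if (nrow(cand) < 10) {
        warning("cell type '", ct, "', direction '", dir,
                "': fewer than 10 genes; skipped", call. = FALSE)
        next
      }
      cand <- dplyr::arrange(cand, .data$fdr, dplyr::desc(abs(.data$log2FC)),
                             .data$gene_id)
      sel <- cand$gene_id[seq_len(min(top_n, nrow(cand)))]
      enr <- hypergeometric_enrichment(sel, universe, gene_sets,
                                       direction = dir)
      enr$cell_type <- ct
      out[[paste(ct, dir)]] <- enr
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res$significant <- res$fdr <= fdr_threshold
  res
}

#' TF motif enrichment in a gene's promoter peaks
#'
#' Tests whether the peaks falling in a gene's promoter window carry each
#' transcription-factor motif more often than expected from the motif's
#' presence across all peaks, with an upper-tail hypergeometric test and BH
#' adjustment. The promoter window is strand-aware: `upstream` bp before to
#' `downstream` bp after the TSS.
#'
#' @param gene_id Gene to test.
#' @param genes Gene annotation tibble.
#' @param peaks Peak tibble.
#' @param motifs Binary peak-by-motif tibble (see
#'   [read_motif_annotation()]).
#' @param upstream,downstream Promoter window in bp (defaults 2000 / 500).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return Enrichment tibble (motifs as sets) with a `gene_id` column; a
#'   zero-row tibble with attribute `no_promoter_peaks = TRUE` when the
#'   window contains no peak.
#' @export
motif_enrichment <- function(gene_id, genes, peaks, motifs,
                             upstream = 2000, downstream = 500,
                             fdr_threshold = 0.05) {
  g <- genes[genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("gene '", gene_id, "' not found", call. = FALSE)
  tss <- if (g$strand == "+") g$start else g$end
  win <- if (g$strand == "+") {
    c(tss - upstream, tss + downstream)
  } else {
    c(tss - downstream, tss + upstream)
  }
  prom <- peaks$peak_id[peaks$chrom == g$chrom &
                          peaks$start < win[2] & peaks$end > win[1]]
  if (!length(prom)) {
    out <- tibble::tibble(set_id = character(), overlap_k = integer(),
                          set_size_K = integer(), selection_n = integer(),
                          universe_N = integer(), p_value = numeric(),
                          fdr = numeric(), direction = character(),
                          gene_id = character(), significant = logical())
    attr(out, "no_promoter_peaks") <- TRUE
    return(out)
  }
  motif_sets <- tibble::tibble(
    set_id = setdiff(names(motifs), "peak_id"),
    members = purrr::map(setdiff(names(motifs), "peak_id"),
                         ~ motifs$peak_id[motifs[[.x]] == 1])
  )
  res <- hypergeometric_enrichment(prom, peaks$peak_id, motif_sets)
  res$gene_id <- gene_id
  res$significant <- res$fdr <= fdr_threshold
  res
}

#' Exact (tie-aware) Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test of paired differences. Zero
#' differences are dropped (classic treatment). For `n <= exact_limit`
#' non-zero differences the null distribution of the statistic is computed
#' exactly over all sign assignments of the (average-tied) ranks via a
#' generating-function convolution; above that a normal approximation with
#' continuity and tie correction is used. All differences zero yields
#' `p = 1` with a flag.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest n for the exact distribution (default 25).
#' @return List with `statistic` (V), `p_value`, `n_used`, `method`,
#'   `all_zero`.
#' @export
signed_rank_test <- function(d, exact_limit = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2*V (integer) over independent signs
    w <- as.integer(round(2 * r))
    total <- sum(w)
    f <- c(1, numeric(total))
    for (wi in w) {
      shifted <- c(numeric(wi), f[seq_len(total + 1 - wi)])
      f <- (f + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1)])
    p_ge <- sum(f[seq.int(v2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = v, p_value = p, n_used = n, method = method,
       all_zero = FALSE)
}

#' Compare cell-type proportions between two modalities
#'
#' Paired, donor-wise comparison of per-cell-type proportions (e.g.
#' snRNA-seq vs snATAC-seq): a two-sided Wilcoxon signed-rank test per cell
#' type with BH adjustment across cell types, plus per-donor Pearson
#' correlations of the proportion profiles across cell types and their
#' median.
#'
#' @param props Long tibble: `donor_id`, `cell_type`, `modality`,
#'   `proportion`. Proportions should sum to 1 per donor and modality.
#' @param modality_a,modality_b The two modality labels to compare
#'   (defaults: the first two present).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return List with `tests` (cell_type, statistic, p_value, fdr,
#'   significant, n_donors, all_zero), `donor_correlations` (donor_id, r),
#'   `median_r`.
#' @export
compare_proportions <- function(props, modality_a = NULL, modality_b = NULL,
                                fdr_threshold = 0.05) {
  mods <- sort(unique(props$modality))
  if (is.null(modality_a)) modality_a <- mods[1]
  if (is.null(modality_b)) modality_b <- mods[2]
  wide <- props |>
    dplyr::filter(.data$modality %in% c(modality_a, modality_b)) |>
    tidyr::pivot_wider(id_cols = c("donor_id", "cell_type"),
                       names_from = "modality",
                       values_from = "proportion") |>
    tidyr::drop_na()
  sums <- props |>
    dplyr::group_by(.data$donor_id, .data$modality) |>
    dplyr::summarize(s = sum(.data$proportion), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    warning("proportions do not sum to 1 for every donor/modality",
            call. = FALSE)
  }
  tests <- wide |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      t <- signed_rank_test(df[[modality_a]] - df[[modality_b]])
      tibble::tibble(statistic = t$statistic, p_value = t$p_value,
                     n_donors = nrow(df), all_zero = t$all_zero,
                     method = t$method)
    }) |>
    dplyr::ungroup()
  tests$fdr <- bh_adjust(tests$p_value)
  tests$significant <- tests$fdr <= fdr_threshold
  donor_cor <- wide |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarize(
      r = if (dplyr::n() >= 3 &&
              stats::sd(.data[[modality_a]]) > 0 &&
              stats::sd(.data[[modality_b]]) > 0) {
        stats::cor(.data[[modality_a]], .data[[modality_b]])
      } else NA_real_,
      .groups = "drop"
    )
  list(tests = tests, donor_correlations = donor_cor,
       median_r = stats::median(donor_cor$r, na.rm = TRUE))
}

#' Cell-type proportions per donor from a pseudobulk assay
#'
#' @param pb A [pseudobulk_assay()] aggregated per donor/cell type.
#' @param modality Label for the output `modality` column.
#' @return Long tibble: `donor_id`, `cell_type`, `modality`, `proportion`.
#' @export
pb_cell_type_proportions <- function(pb, modality = pb$modality) {
  pb$sample_meta |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::mutate(proportion = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$donor_id, .data$cell_type,
                     modality = modality, .data$proportion)
}

#' Pearson correlation of effect sizes between two studies
#'
#' For each pair of cell types (one from each result table), correlates the
#' log2 fold changes of the genes present in both.
#'
#' @param fc_a,fc_b Tibbles with `gene_id`, `cell_type`, `log2FC`.
#' @return Tibble: `cell_type_a`, `cell_type_b`, `r`, `n_shared` (`r` is
#'   `NA` for fewer than 3 shared genes).
#' @export
cross_study_fc_correlation <- function(fc_a, fc_b) {
  cts_a <- sort(unique(fc_a$cell_type))
  cts_b <- sort(unique(fc_b$cell_type))
  purrr::map_dfr(cts_a, function(ca) {
    sub_a <- dplyr::filter(fc_a, .data$cell_type == ca)
    purrr::map_dfr(cts_b, function(cb) {
      sub_b <- dplyr::filter(fc_b, .data$cell_type == cb)
      j <- dplyr::inner_join(
        dplyr::select(sub_a, "gene_id", a = "log2FC"),
        dplyr::select(sub_b, "gene_id", b = "log2FC"),
        by = "gene_id"
      )
      j <- tidyr::drop_na(j)
      tibble::tibble(
        cell_type_a = ca, cell_type_b = cb,
        r = if (nrow(j) >= 3) stats::cor(j$a, j$b) else NA_real_,
        n_shared = nrow(j)
      )
    })
  })
}
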