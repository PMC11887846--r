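# Seeded simulation of a postmortem-brain multi-omic cohort: donor
# covariates, PRS coupled to a latent disease liability, pseudobulk counts
# and gene scores with planted effects, and toy annotations.

with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Simulate a donor cohort
#'
#' Draws donor covariates from the distributions of the emulated
#' postmortem-brain cohort: age ~ N(54.27, 13.64), PMI ~ N(33.90, 14.82)
#' truncated at 0 hours, brain pH ~ N(6.60, 0.24), 38% female. Case status
#' is assigned by thresholding a latent standard-normal disease liability so
#' that `round(n_donors * case_fraction)` donors are cases; the liability is
#' kept in the `liability` column so that polygenic scores can be coupled to
#' it. Among cases, diagnoses are drawn with probabilities 38/7/7/5
#' (schizophrenia / schizoaffective / MDD / bipolar). When `n_donors >= 2`,
#' exactly one donor's RIN is set missing to exercise median imputation
#' downstream. Library batches are assigned round-robin.
#'
#' @param n_donors Number of donors (>= 0).
#' @param case_fraction Fraction of donors that are cases; default 57/92.
#' @param seed Integer seed.
#' @param n_batches Number of library batches (round-robin), default 4.
#' @return Tibble, one row per donor.
#' @export
simulate_cohort <- function(n_donors, case_fraction = 57 / 92, seed = 1,
                            n_batches = 4) {
  if (n_donors < 0) stop("n_donors must be >= 0", call. = FALSE)
  if (case_fraction < 0 || case_fraction > 1) {
    stop("case_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (n_donors == 0) {
    return(tibble::tibble(
      donor_id = character(), disease_status = character(),
      diagnosis = character(), sex = character(), age = numeric(),
      pH = numeric(), pmi = numeric(), rin = numeric(),
      lib_batch = character(), liability = numeric()
    ))
  }
  with_seed_(seed, {
    liability <- stats::rnorm(n_donors)
    n_cases <- round(n_donors * case_fraction)
    is_case <- rank(-liability, ties.method = "first") <= n_cases
    diagnosis <- ifelse(is_case, NA_character_, "control")
    if (n_cases > 0) {
      diagnosis[is_case] <- sample(
        c("schizophrenia", "SCA", "MDD", "bipolar"), n_cases, replace = TRUE,
        prob = c(38, 7, 7, 5) / 57
      )
    }
    rin <- rnorm_trunc(n_donors, 7.2, 0.8, lower = 5, upper = 10)
    if (n_donors >= 2) rin[sample.int(n_donors, 1)] <- NA_real_
    tibble::tibble(
      donor_id = sprintf("d%03d", seq_len(n_donors)),
      disease_status = ifelse(is_case, "case", "control"),
      diagnosis = diagnosis,
      sex = ifelse(stats::runif(n_donors) < 0.38, "F", "M"),
      age = rnorm_trunc(n_donors, 54.27, 13.64, lower = 18),
      pH = rnorm_trunc(n_donors, 6.60, 0.24, lower = 4, upper = 9),
      pmi = rnorm_trunc(n_donors, 33.90, 14.82, lower = 0),
      rin = rin,
      lib_batch = paste0("b", (seq_len(n_donors) - 1L) %% n_batches + 1L),
      liability = liability
    )
  })
}

#' Add a simulated polygenic risk score to a cohort
#'
#' The score is built as `r * liability + sqrt(1 - r^2) * noise` and then
#' standardized, so it is marginally standard normal and correlates with the
#' latent disease liability at `liability_correlation` in expectation.
#' Because case status thresholds the same liability, both tails of the PRS
#' distribution contain cases and controls for `|r| < 1`.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param trait Trait name; the score is stored as column `prs_<trait>`.
#' @param liability_correlation Correlation with the latent liability, in
#'   `[-1, 1]`; default 0.3.
#' @param seed Integer seed.
#' @return The cohort with the PRS column appended.
#' @export
simulate_prs <- function(cohort, trait, liability_correlation = 0.3,
                         seed = 1) {
  if (abs(liability_correlation) > 1) {
    stop("liability_correlation must lie in [-1, 1]", call. = FALSE)
  }
  col <- paste0("prs_", trait)
  if (col %in% names(cohort)) {
    stop("cohort already has a PRS column for trait '", trait, "'",
         call. = FALSE)
  }
  if (!"liability" %in% names(cohort)) {
    stop("cohort lacks the latent liability column", call. = FALSE)
  }
  with_seed_(seed, {
    r <- liability_correlation
    raw <- r * cohort$liability +
      sqrt(1 - r^2) * stats::rnorm(nrow(cohort))
    cohort[[col]] <- if (nrow(cohort) > 1 && stats::sd(raw) > 0) {
      as.numeric(scale(raw))
    } else {
      raw
    }
    cohort
  })
}

#' Specify planted effects and noise for the simulators
#'
#' @param status_frac Fraction of genes per cell type with a planted
#'   case-vs-control effect.
#' @param status_log2fc Magnitude of planted status effects (sign random).
#' @param risk_frac Fraction of genes carrying a PRS-linked effect in the
#'   targeted cell type.
#' @param risk_log2fc_per_sd Planted slope: log2 change in expected signal
#'   per standard deviation of PRS.
#' @param dispersion Negative-binomial dispersion of pseudobulk counts.
#' @param hidden_sd SD of per-gene loadings on a single hidden donor-level
#'   factor (log2 scale); 0 disables it.
#' @param batch_sd SD of gene-by-batch offsets (log2 scale).
#' @param covariate_sd SD of per-gene log2 effects per SD of age and pH.
#' @param score_noise_sd Residual SD of log2 gene scores.
#' @param baseline_log_mu Mean of per-gene baseline log-mean counts
#'   (natural log scale).
#' @param score_baseline_log2 Mean per-gene baseline log2 gene score.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(status_frac = 0.1, status_log2fc = 1,
                       risk_frac = 0.1, risk_log2fc_per_sd = 0.5,
                       dispersion = 0.1, hidden_sd = 0.5, batch_sd = 0.2,
                       covariate_sd = 0.1, score_noise_sd = 0.5,
                       baseline_log_mu = log(50), score_baseline_log2 = 4) {
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  structure(as.list(environment()), class = "truth_spec")
}

# Draw per-cell-type gene effects and per-donor factors; shared by the count
# and gene-score simulators. Everything is recorded before noise is drawn.
# `eligible` restricts which genes may carry planted effects (effects on
# genes the pipeline cannot measure would conflate coverage with power);
# when more effects are requested than eligible genes exist, the surplus is
# drawn from the remainder.
sample_affected <- function(n_affected, eligible) {
  elig <- which(eligible)
  if (n_affected <= length(elig)) return(sample(elig, n_affected))
  c(elig, sample(which(!eligible), n_affected - length(elig)))
}

draw_truth <- function(cohort, cell_types, n_genes, spec, risk_cell_type,
                       prs_trait, eligible = rep(TRUE, n_genes)) {
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  effects <- purrr::map(cell_types, function(ct) {
    n_status <- round(spec$status_frac * n_genes)
    status_idx <- sample_affected(n_status, eligible)
    status_fc <- numeric(n_genes)
    status_fc[status_idx] <- spec$status_log2fc *
      sample(c(-1, 1), n_status, replace = TRUE)
    risk_fc <- numeric(n_genes)
    if (!is.null(risk_cell_type) && ct == risk_cell_type &&
        !is.null(prs_trait)) {
      n_risk <- round(spec$risk_frac * n_genes)
      risk_idx <- sample_affected(n_risk, eligible)
      risk_fc[risk_idx] <- spec$risk_log2fc_per_sd *
        sample(c(-1, 1), n_risk, replace = TRUE)
    }
    tibble::tibble(
      cell_type = ct, gene_id = gene_ids,
      status_log2fc = status_fc,
      risk_log2fc_per_sd = risk_fc,
      hidden_loading = stats::rnorm(n_genes, 0, spec$hidden_sd),
      age_log2_per_sd = stats::rnorm(n_genes, 0, spec$covariate_sd),
      ph_log2_per_sd = stats::rnorm(n_genes, 0, spec$covariate_sd)
    )
  })
  batches <- sort(unique(cohort$lib_batch))
  batch_effects <- purrr::map(cell_types, function(ct) {
    tibble::tibble(
      cell_type = ct,
      gene_id = rep(gene_ids, times = length(batches)),
      lib_batch = rep(batches, each = n_genes),
      batch_log2 = stats::rnorm(n_genes * length(batches), 0, spec$batch_sd)
    )
  })
  list(
    gene_ids = gene_ids,
    gene_effects = dplyr::bind_rows(effects),
    batch_effects = dplyr::bind_rows(batch_effects),
    donor_factors = tibble::tibble(
      donor_id = cohort$donor_id,
      hidden_factor = stats::rnorm(nrow(cohort))
    )
  )
}

# Expected log2 signal (before baseline and library size) for every
# gene x sample combination of one cell type.
planted_log2_signal <- function(truth, cohort, ct, prs_trait) {
  eff <- dplyr::filter(truth$gene_effects, .data$cell_type == ct)
  bat <- dplyr::filter(truth$batch_effects, .data$cell_type == ct) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "lib_batch",
                       values_from = "batch_log2")
  bat <- as.matrix(bat[match(eff$gene_id, bat$gene_id), -1, drop = FALSE])
  h <- truth$donor_factors$hidden_factor[
    match(cohort$donor_id, truth$donor_factors$donor_id)]
  status <- as.numeric(cohort$disease_status == "case")
  age_z <- as.numeric(scale(cohort$age))
  ph_z <- as.numeric(scale(cohort$pH))
  prs <- if (!is.null(prs_trait)) cohort[[paste0("prs_", prs_trait)]] else
    numeric(nrow(cohort))
  sig <- outer(eff$status_log2fc, status) +
    outer(eff$risk_log2fc_per_sd, prs) +
    outer(eff$hidden_loading, h) +
    outer(eff$age_log2_per_sd, age_z) +
    outer(eff$ph_log2_per_sd, ph_z) +
    bat[, match(cohort$lib_batch, colnames(bat)), drop = FALSE]
  rownames(sig) <- eff$gene_id
  sig
}

#' Simulate pseudobulk expression counts with planted effects
#'
#' Counts are negative binomial per gene and cell-type--donor sample, with
#' log mean = gene baseline + log library-size factor + ln(2) times the
#' planted log2 effects (status, PRS slope, hidden factor, batch, age and pH
#' covariates). Library-size factors span a 4-fold range. With
#' `level = "nucleus"` the same expectations drive per-nucleus Poisson
#' draws (gamma-mixed, so their sums are negative binomial) that aggregate
#' to the pseudobulk, for exercising QC and aggregation.
#'
#' @param cohort Cohort tibble (with PRS columns if risk effects are
#'   planted).
#' @param cell_types Character vector of cell-type labels.
#' @param n_genes Number of genes.
#' @param spec A [truth_spec()].
#' @param seed Integer seed.
#' @param risk_cell_type Cell type carrying PRS-linked effects; default the
#'   first cell type when `prs_trait` is given.
#' @param prs_trait Trait whose PRS drives risk effects, or `NULL`.
#' @param level `"pseudobulk"` (default) or `"nucleus"`.
#' @param cells_per_sample Range of nuclei aggregated per sample (used when
#'   `n_cells_matrix` is not given).
#' @param n_cells_matrix Optional donors-by-cell-type matrix of aggregated
#'   nucleus counts (see [simulate_cell_composition()]).
#' @return A list with `assay` (a [pseudobulk_assay()]; for
#'   `level = "nucleus"` also `nuclei`, a [nucleus_matrix()]) and `truth`
#'   (a `simulation_truth` list recording every planted quantity).
#' @export
simulate_expression_counts <- function(cohort, cell_types, n_genes,
                                       spec = truth_spec(), seed = 1,
                                       risk_cell_type = NULL,
                                       prs_trait = NULL,
                                       level = c("pseudobulk", "nucleus"),
                                       cells_per_sample = c(50, 200),
                                       n_cells_matrix = NULL) {
  level <- match.arg(level)
  if (is.null(risk_cell_type) && !is.null(prs_trait)) {
    risk_cell_type <- cell_types[1]
  }
  with_seed_(seed, {
    baseline <- stats::rnorm(n_genes, spec$baseline_log_mu, 1)
    # effects go to genes likely to clear the count filter (>= ~10 counts
    # in most samples even at the smallest library-size factor)
    eligible <- baseline >= log(30)
    truth <- draw_truth(cohort, cell_types, n_genes, spec, risk_cell_type,
                        prs_trait, eligible = eligible)
    names(baseline) <- truth$gene_ids
    n_d <- nrow(cohort)
    assays <- list()
    nuc_counts <- list()
    nuc_meta <- list()
    for (ct in cell_types) {
      sig <- planted_log2_signal(truth, cohort, ct, prs_trait)
      libf <- exp(stats::runif(n_d, log(0.5), log(2)))
      n_cells <- if (is.null(n_cells_matrix)) {
        sample(seq(cells_per_sample[1], cells_per_sample[2]), n_d,
               replace = TRUE)
      } else {
        as.integer(n_cells_matrix[cohort$donor_id, ct])
      }
      mu <- exp(baseline + log(2) * sig +
                  rep(log(libf), each = n_genes))
      if (level == "pseudobulk") {
        vals <- matrix(
          stats::rnbinom(n_genes * n_d, mu = as.vector(mu),
                         size = 1 / spec$dispersion),
          nrow = n_genes
        )
      } else {
        # gamma-Poisson: a gamma rate per gene/sample, split over nuclei
        lambda <- matrix(
          stats::rgamma(n_genes * n_d, shape = 1 / spec$dispersion,
                        scale = as.vector(mu) * spec$dispersion),
          nrow = n_genes
        )
        vals <- matrix(0, n_genes, n_d)
        for (j in seq_len(n_d)) {
          per_nuc <- matrix(
            stats::rpois(n_genes * n_cells[j], lambda[, j] / n_cells[j]),
            nrow = n_cells[j], byrow = TRUE
          )
          vals[, j] <- colSums(per_nuc)
          nuc_counts[[length(nuc_counts) + 1L]] <- per_nuc
          nuc_meta[[length(nuc_meta) + 1L]] <- tibble::tibble(
            donor_id = cohort$donor_id[j], cell_type = ct,
            n_nuclei = n_cells[j]
          )
        }
      }
      rownames(vals) <- truth$gene_ids
      assays[[ct]] <- list(
        values = vals,
        meta = tibble::tibble(
          sample_id = paste(cohort$donor_id, ct, sep = "."),
          donor_id = cohort$donor_id, cell_type = ct, n_cells = n_cells
        )
      )
    }
    assay <- pseudobulk_assay(
      do.call(cbind, purrr::map(assays, "values")),
      dplyr::bind_rows(purrr::map(assays, "meta")),
      modality = "rna_counts"
    )
    truth_out <- structure(
      list(gene_effects = truth$gene_effects,
           batch_effects = truth$batch_effects,
           donor_factors = truth$donor_factors,
           baseline = tibble::tibble(gene_id = truth$gene_ids,
                                     log_mu = baseline),
           spec = unclass(spec), seed = seed, modality = "rna_counts",
           risk_cell_type = risk_cell_type, prs_trait = prs_trait),
      class = "simulation_truth"
    )
    out <- list(assay = assay, truth = truth_out)
    if (level == "nucleus") {
      big <- Matrix::Matrix(do.call(rbind, nuc_counts), sparse = TRUE)
      meta <- dplyr::bind_rows(nuc_meta)
      meta <- tibble::tibble(
        nucleus_id = sprintf("n%07d", seq_len(nrow(big))),
        donor_id = rep(meta$donor_id, times = meta$n_nuclei),
        cell_type = rep(meta$cell_type, times = meta$n_nuclei)
      )
      meta$total_counts <- Matrix::rowSums(big)
      meta$n_features_detected <- Matrix::rowSums(big > 0)
      meta$mito_fraction <- stats::rbeta(nrow(big), 1.5, 40)
      out$nuclei <- nucleus_matrix(big, meta,
                                   feature_ids = truth$gene_ids)
    }
    out
  })
}

#' Simulate pseudobulk gene-activity scores with planted effects
#'
#' Scores are log-normal and strictly positive: the underlying log2 signal
#' is gene baseline + planted effects + Gaussian noise, and the emitted raw
#' score is scaled by the number of nuclei aggregated per sample, so that
#' cell-count normalization downstream recovers the per-cell signal.
#'
#' @inheritParams simulate_expression_counts
#' @return A list with `assay` (modality `"atac_genescore"`, unnormalized)
#'   and `truth`.
#' @export
simulate_gene_scores <- function(cohort, cell_types, n_genes,
                                 spec = truth_spec(), seed = 1,
                                 risk_cell_type = NULL, prs_trait = NULL,
                                 cells_per_sample = c(50, 200),
                                 n_cells_matrix = NULL) {
  if (is.null(risk_cell_type) && !is.null(prs_trait)) {
    risk_cell_type <- cell_types[1]
  }
  with_seed_(seed, {
    truth <- draw_truth(cohort, cell_types, n_genes, spec, risk_cell_type,
                        prs_trait)
    baseline <- stats::rnorm(n_genes, spec$score_baseline_log2, 1)
    names(baseline) <- truth$gene_ids
    n_d <- nrow(cohort)
    blocks <- purrr::map(cell_types, function(ct) {
      sig <- planted_log2_signal(truth, cohort, ct, prs_trait)
      n_cells <- if (is.null(n_cells_matrix)) {
        sample(seq(cells_per_sample[1], cells_per_sample[2]), n_d,
               replace = TRUE)
      } else {
        as.integer(n_cells_matrix[cohort$donor_id, ct])
      }
      log2_score <- baseline + sig +
        matrix(stats::rnorm(n_genes * n_d, 0, spec$score_noise_sd),
               n_genes, n_d)
      vals <- 2^log2_score * rep(n_cells, each = n_genes)
      rownames(vals) <- truth$gene_ids
      list(values = vals,
           meta = tibble::tibble(
             sample_id = paste(cohort$donor_id, ct, sep = "."),
             donor_id = cohort$donor_id, cell_type = ct, n_cells = n_cells
           ))
    })
    assay <- pseudobulk_assay(
      do.call(cbind, purrr::map(blocks, "values")),
      dplyr::bind_rows(purrr::map(blocks, "meta")),
      modality = "atac_genescore"
    )
    truth_out <- structure(
      list(gene_effects = truth$gene_effects,
           batch_effects = truth$batch_effects,
           donor_factors = truth$donor_factors,
           baseline = tibble::tibble(gene_id = truth$gene_ids,
                                     log2_score = baseline),
           spec = unclass(spec), seed = seed, modality = "atac_genescore",
           risk_cell_type = risk_cell_type, prs_trait = prs_trait),
      class = "simulation_truth"
    )
    list(assay = assay, truth = truth_out)
  })
}

#' Simulate gene, peak, motif and gene-set annotations
#'
#' Genes are laid out on two toy chromosomes; every emitted peak has a fixed
#' width of 501 bp. Each gene receives at least one peak inside its promoter
#' window (while peaks last); remaining peaks are placed uniformly. Motif
#' presence is Bernoulli with a per-motif rate drawn from U(0.05, 0.3);
#' gene sets are sampled without replacement.
#'
#' @param n_genes,n_peaks,n_motifs,n_sets Component counts (>= 0).
#' @param seed Integer seed.
#' @param set_size Integer range of gene-set sizes.
#' @return List with `genes`, `peaks`, `motifs`, `gene_sets`.
#' @export
simulate_annotations <- function(n_genes, n_peaks, n_motifs, n_sets,
                                 seed = 1, set_size = c(10, 50)) {
  stopifnot(n_genes >= 0, n_peaks >= 0, n_motifs >= 0, n_sets >= 0)
  with_seed_(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    chrom <- rep(c("chr1", "chr2"), length.out = n_genes)
    idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
    start <- 10000L + (idx_on_chrom - 1L) * 25000L
    len <- sample(2000:10000, max(n_genes, 1), replace = TRUE)[seq_len(n_genes)]
    genes <- tibble::tibble(
      gene_id = gene_ids, chrom = chrom, start = start,
      end = start + len,
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    if (n_peaks < n_genes) {
      warning("fewer peaks than genes: some genes lack a promoter peak",
              call. = FALSE)
    }
    n_prom <- min(n_peaks, n_genes)
    prom <- if (n_prom > 0) {
      g <- genes[seq_len(n_prom), ]
      tss <- ifelse(g$strand == "+", g$start, g$end)
      center <- tss + ifelse(g$strand == "+", -1L, 1L) *
        sample(0:1200, n_prom, replace = TRUE)
      tibble::tibble(chrom = g$chrom,
                     start = pmax(0L, as.integer(center) - 250L))
    } else {
      tibble::tibble(chrom = character(), start = integer())
    }
    n_rand <- n_peaks - n_prom
    rand <- if (n_rand > 0) {
      extent <- max(genes$end, 1L) + 100000L
      tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n_rand, replace = TRUE),
        start = sample.int(extent, n_rand, replace = TRUE)
      )
    } else {
      tibble::tibble(chrom = character(), start = integer())
    }
    peaks <- dplyr::bind_rows(prom, rand)
    peaks <- tibble::tibble(
      peak_id = sprintf("peak%05d", seq_len(nrow(peaks))),
      chrom = peaks$chrom, start = as.integer(peaks$start),
      end = as.integer(peaks$start) + 501L
    )
    motif_rates <- stats::runif(n_motifs, 0.05, 0.3)
    motifs <- tibble::as_tibble(
      matrix(stats::rbinom(n_peaks * n_motifs, 1,
                           rep(motif_rates, each = n_peaks)),
             nrow = n_peaks,
             dimnames = list(NULL, sprintf("motif%03d", seq_len(n_motifs)))),
      .name_repair = "minimal"
    )
    motifs <- dplyr::bind_cols(tibble::tibble(peak_id = peaks$peak_id), motifs)
    sizes <- sample(seq(set_size[1], set_size[2]), max(n_sets, 1),
                    replace = TRUE)[seq_len(n_sets)]
    sizes <- pmin(sizes, max(n_genes, 1))
    gene_sets <- tibble::tibble(
      set_id = sprintf("SET%03d", seq_len(n_sets)),
      description = rep("synthetic gene set", n_sets),
      members = purrr::map(sizes, ~ sort(sample(gene_ids, .x)))
    )
    list(genes = genes, peaks = peaks, motifs = motifs,
         gene_sets = gene_sets)
  })
}

#' Simulate coupled per-donor cell-type compositions for two modalities
#'
#' Each donor gets one Dirichlet-distributed cell-type composition, shared
#' by both modalities; modality-specific totals and multiplicative noise
#' are applied on top. This reproduces the strong donor-wise correlation of
#' cell-type proportions between transcriptome and chromatin assays.
#'
#' @param cohort Cohort tibble.
#' @param cell_types Cell-type labels.
#' @param seed Integer seed.
#' @param rna_total,atac_total Ranges of total nuclei per donor and
#'   modality.
#' @param concentration Dirichlet concentration scale (larger = donors more
#'   similar).
#' @param noise_sd SD of the per-modality log-normal perturbation.
#' @return List of two integer matrices (`rna`, `atac`), donors x cell
#'   types, every entry >= 2.
#' @export
simulate_cell_composition <- function(cohort, cell_types, seed = 1,
                                      rna_total = c(600, 1600),
                                      atac_total = c(300, 900),
                                      concentration = 25, noise_sd = 0.15) {
  k <- length(cell_types)
  n_d <- nrow(cohort)
  with_seed_(seed, {
    alpha <- stats::rgamma(k, shape = 2, rate = 1) + 0.3
    alpha <- alpha / sum(alpha)
    props <- matrix(stats::rgamma(n_d * k, shape =
                                    rep(alpha * concentration, each = n_d)),
                    n_d, k)
    props <- props / rowSums(props)
    one <- function(total_range) {
      tot <- round(exp(stats::runif(n_d, log(total_range[1]),
                                    log(total_range[2]))))
      m <- round(props * tot *
                   exp(matrix(stats::rnorm(n_d * k, 0, noise_sd), n_d, k)))
      m <- pmax(m, 2L)
      dimnames(m) <- list(cohort$donor_id, cell_types)
      m
    }
    list(rna = one(rna_total), atac = one(atac_total))
  })
}

#' Simulate a complete multi-omic study
#'
#' Convenience wrapper tying the individual simulators together with
#' sub-seeds derived from one master seed: cohort, PRS for the requested
#' traits, pseudobulk expression counts and gene scores with shared planted
#' risk effects in one targeted cell type, and annotations.
#'
#' @param n_donors,cell_types,n_genes Study dimensions.
#' @param traits Character vector of PRS trait names.
#' @param spec A [truth_spec()].
#' @param seed Master integer seed.
#' @param n_peaks,n_motifs,n_sets Annotation dimensions.
#' @param liability_correlation PRS-liability correlation for the first
#'   trait (others get 0.1).
#' @return List with `cohort`, `rna`, `atac` (each `assay` + `truth`),
#'   `annotations`, and `risk_cell_type`.
#' @export
simulate_study <- function(n_donors = 90,
                           cell_types = paste0("ct", 1:4),
                           n_genes = 500, traits = "scz",
                           spec = truth_spec(), seed = 1,
                           n_peaks = 2000, n_motifs = 25, n_sets = 15,
                           liability_correlation = 0.3) {
  cohort <- simulate_cohort(n_donors, seed = seed)
  for (i in seq_along(traits)) {
    cohort <- simulate_prs(
      cohort, traits[i],
      liability_correlation = if (i == 1) liability_correlation else 0.1,
      seed = seed + 1000 + i
    )
  }
  risk_ct <- cell_types[1]
  comp <- simulate_cell_composition(cohort, cell_types, seed = seed + 5000)
  rna <- simulate_expression_counts(
    cohort, cell_types, n_genes, spec = spec, seed = seed + 2000,
    risk_cell_type = risk_ct, prs_trait = traits[1],
    n_cells_matrix = comp$rna
  )
  atac <- simulate_gene_scores(
    cohort, cell_types, n_genes, spec = spec, seed = seed + 3000,
    risk_cell_type = risk_ct, prs_trait = traits[1],
    n_cells_matrix = comp$atac
  )
  ann <- simulate_annotations(n_genes, n_peaks, n_motifs, n_sets,
                              seed = seed + 4000)
  list(cohort = cohort, rna = rna, atac = atac, annotations = ann,
       risk_cell_type = risk_ct)
}
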