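# Per-gene Wald tests: a negative-binomial GLM for pseudobulk counts and an
# ordinary linear model for cell-count-normalized gene scores, with BH FDR.

# One-gene NB IRLS with log link, fixed dispersion alpha and offset.
nb_irls_one <- function(y, x, offset, alpha, tol = 1e-8, maxit = 100) {
  p <- ncol(x)
  beta <- .lm.fit(x, log(y + 0.5) - offset)$coefficients
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- exp(pmin(eta + offset, 30))
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    beta_new <- .lm.fit(x * sw, z * sw)$coefficients
    if (any(!is.finite(beta_new))) break
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  mu <- exp(pmin(drop(x %*% beta) + offset, 30))
  w <- mu / (1 + alpha * mu)
  info <- crossprod(x * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
  list(beta = beta, se = se, converged = converged && !is.null(cov))
}

#' Negative-binomial GLM Wald test per gene
#'
#' Fits, for every gene, an NB GLM with log link and `log(size_factor)`
#' offset by iteratively reweighted least squares (relative tolerance 1e-8,
#' at most 100 iterations). The per-gene dispersion is estimated by the
#' method of moments on normalized counts, `(var - mean) / mean^2`, floored
#' at 1e-8 (the Poisson limit), unless supplied. Wald standard errors come
#' from the observed information matrix; the reported log2 fold change is
#' the variable-of-interest coefficient divided by `ln 2` and the p value
#' is two-sided normal. All-zero genes are skipped; non-converged fits are
#' reported with `NA` statistics and flagged.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design A `design_matrix` from [build_design()] (or a plain
#'   numeric matrix plus `voi`).
#' @param size_factors Positive numeric vector, one per sample.
#' @param dispersion Optional fixed dispersion (scalar or per-gene vector);
#'   default method-of-moments per gene.
#' @param voi Variable-of-interest column name when `design` is a plain
#'   matrix.
#' @return Tibble: `gene_id`, `log2FC`, `SE`, `wald_statistic`, `p_value`,
#'   `dispersion`, `converged`.
#' @export
fit_nb_glm_wald <- function(counts, design, size_factors,
                            dispersion = NULL, voi = NULL) {
  if (inherits(design, "design_matrix")) {
    x <- design$matrix
    voi <- design$voi
  } else {
    x <- as.matrix(design)
    if (is.null(voi)) stop("voi required with a plain design matrix",
                           call. = FALSE)
  }
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(x), length(size_factors) == nrow(x),
            all(size_factors > 0))
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient",
                                 call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  voi_idx <- match(voi, colnames(x))
  if (is.na(voi_idx)) stop("variable of interest '", voi,
                           "' not in design", call. = FALSE)
  offset <- log(size_factors)
  nz <- rowSums(counts) > 0
  counts <- counts[nz, , drop = FALSE]
  genes <- rownames(counts) %||% as.character(which(nz))
  g <- nrow(counts)
  if (is.null(dispersion)) {
    # method of moments on normalized counts, conditioned on the design:
    # residual variance (df-corrected) so that design-explained variation
    # (group effect, covariates) does not inflate the dispersion
    q <- sweep(counts, 2, size_factors, "/")
    m <- rowMeans(q)
    qr_x <- qr(x)
    resid <- t(qr.resid(qr_x, t(q)))
    v <- rowSums(resid^2) / (nrow(x) - ncol(x))
    alpha <- pmax((v - m) / m^2, 1e-8)
  } else {
    alpha <- pmax(rep_len(dispersion, g), 1e-8)
  }
  log2fc <- se <- rep(NA_real_, g)
  converged <- logical(g)
  for (i in seq_len(g)) {
    fit <- nb_irls_one(counts[i, ], x, offset, alpha[i])
    converged[i] <- fit$converged
    if (fit$converged) {
      log2fc[i] <- fit$beta[voi_idx] / log(2)
      se[i] <- fit$se[voi_idx] / log(2)
    }
  }
  wald <- log2fc / se
  tibble::tibble(
    gene_id = genes, log2FC = log2fc, SE = se,
    wald_statistic = wald,
    # t reference with n - p df: the plug-in dispersion makes the normal
    # reference anti-conservative at pseudobulk sample sizes
    p_value = 2 * stats::pt(-abs(wald), df = nrow(x) - ncol(x)),
    dispersion = alpha, converged = converged
  )
}

#' Linear-model Wald test per gene on normalized gene scores
#'
#' Response is `log2(score + pseudocount)` (set `log_transform = FALSE` to
#' model the values directly). Ordinary least squares is solved for all
#' genes at once from one QR decomposition; the Wald statistic is the
#' variable-of-interest coefficient over its standard error, referred to a
#' t distribution with `n - p` degrees of freedom (conservative at small
#' n). The log2 fold change is the variable-of-interest coefficient itself.
#'
#' @param scores Numeric matrix, genes x samples, cell-count normalized.
#' @param design A `design_matrix` or plain matrix (then supply `voi`).
#' @param pseudocount Added before the log2 transform (default 1).
#' @param log_transform Apply `log2(x + pseudocount)` to the response.
#' @param voi Variable-of-interest column for a plain design matrix.
#' @return Tibble: `gene_id`, `log2FC`, `SE`, `wald_statistic`, `p_value`,
#'   `df`.
#' @export
fit_lm_wald <- function(scores, design, pseudocount = 1,
                        log_transform = TRUE, voi = NULL) {
  if (inherits(design, "design_matrix")) {
    x <- design$matrix
    voi <- design$voi
  } else {
    x <- as.matrix(design)
    if (is.null(voi)) stop("voi required with a plain design matrix",
                           call. = FALSE)
  }
  scores <- as.matrix(scores)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(ncol(scores) == n)
  if (n <= p) stop("need more samples than design columns", call. = FALSE)
  voi_idx <- match(voi, colnames(x))
  if (is.na(voi_idx)) stop("variable of interest '", voi,
                           "' not in design", call. = FALSE)
  y <- if (log_transform) log2(scores + pseudocount) else scores
  qr_x <- qr(x)
  if (qr_x$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  coefs <- qr.coef(qr_x, t(y))              # p x genes
  resid <- t(y) - x %*% coefs               # n x genes
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[voi_idx, voi_idx])
  b <- coefs[voi_idx, ]
  tstat <- b / se
  tibble::tibble(
    gene_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
    log2FC = unname(b), SE = unname(se), wald_statistic = unname(tstat),
    p_value = unname(2 * stats::pt(-abs(tstat), df)), df = df
  )
}

#' Shapiro-Wilk screen of per-gene model residuals
#'
#' Advisory diagnostic for the linear gene-score model: tests each gene's
#' residual vector for normality and summarizes the rejection fraction at
#' `alpha`. Never gates results.
#'
#' @param residuals Numeric matrix, genes x samples.
#' @param alpha Rejection level (default 0.05).
#' @return List with `per_gene` tibble (`gene_id`, `statistic`, `p_value`)
#'   and `rejected_fraction`.
#' @export
check_residual_normality <- function(residuals, alpha = 0.05) {
  residuals <- as.matrix(residuals)
  n <- ncol(residuals)
  out <- apply(residuals, 1, function(r) {
    if (n < 3 || length(unique(r)) < 3) return(c(NA_real_, NA_real_))
    sw <- tryCatch(stats::shapiro.test(r), error = function(e) NULL)
    if (is.null(sw)) c(NA_real_, NA_real_) else c(sw$statistic, sw$p.value)
  })
  per_gene <- tibble::tibble(
    gene_id = rownames(residuals) %||% as.character(seq_len(nrow(residuals))),
    statistic = out[1, ], p_value = out[2, ]
  )
  if (all(is.na(per_gene$p_value))) {
    warning("residual normality could not be assessed", call. = FALSE)
  }
  list(per_gene = per_gene,
       rejected_fraction = mean(per_gene$p_value <= alpha, na.rm = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity; `NA` p values pass
#' through as `NA` and do not count toward the number of tests.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NAs allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the differential-testing pipeline for every cell type
#'
#' For each cell type: parametric feature filtering, normalization (size
#' factors for counts; cell-count normalization for gene scores), iterative
#' PC1 outlier removal, RIN imputation, design construction including the
#' hidden-noise PC, per-gene Wald fits, and BH adjustment within the cell
#' type. Cell types with fewer than `min_samples` samples after outlier
#' removal are skipped with a warning. Counts are tested with the NB GLM;
#' gene scores with the linear model on `log2(score + 1)`; following the
#' emulated study, RIN is dropped from the gene-score design.
#'
#' @param pb A [pseudobulk_assay()] covering one or more cell types.
#' @param sample_table Donor-level table with `donor_id`, the contrast
#'   column (`disease_status` or `risk_group`), `sex`, `lib_batch` and the
#'   continuous covariates. For risk contrasts, restrict it to the matched
#'   donors beforehand (see [define_risk_groups()]).
#' @param contrast `"diagnosis"` or `"risk:<trait>"`.
#' @param covariates Continuous covariates for the design.
#' @param min_value,min_fraction Feature-filter parameters (defaults 10 /
#'   0.75 for counts, 0.1 / 0.75 for scores).
#' @param fdr_threshold Significance threshold on the BH FDR (default 0.1).
#' @param min_samples Minimum samples per cell type after outlier removal.
#' @param sd_threshold Outlier threshold in PC1 standard deviations.
#' @return Object of class `differential_result`: list with `table`
#'   (tidy per-gene results), `contrast`, `modality`, `fdr_threshold`,
#'   `details` (per-cell-type design, size factors, outlier log, noise PC).
#' @export
run_differential <- function(pb, sample_table, contrast = "diagnosis",
                             covariates = c("age", "pH", "rin", "pmi"),
                             min_value = NULL, min_fraction = 0.75,
                             fdr_threshold = 0.1, min_samples = 6,
                             sd_threshold = 3) {
  stopifnot(inherits(pb, "pseudobulk_assay"))
  is_risk <- grepl("^risk:", contrast)
  voi <- if (is_risk) "risk_group" else "disease_status"
  if (!voi %in% names(sample_table)) {
    stop("sample_table lacks the contrast column '", voi, "'",
         call. = FALSE)
  }
  modality <- pb$modality
  if (is.null(min_value)) {
    min_value <- if (modality == "rna_counts") 10 else 0.1
  }
  use_covariates <- if (modality == "atac_genescore") {
    setdiff(covariates, "rin")
  } else {
    covariates
  }
  keep_donors <- sample_table$donor_id[!is.na(sample_table[[voi]])]
  pb <- pb_subset_samples(pb, pb$sample_meta$donor_id %in% keep_donors)
  cell_types <- sort(unique(pb$sample_meta$cell_type))
  results <- list()
  details <- list()
  for (ct in cell_types) {
    pct <- pb_subset_cell_type(pb, ct)
    pct <- filter_features(pct, min_value = min_value,
                           min_fraction = min_fraction)
    if (nrow(pct$values) == 0) {
      warning("cell type '", ct, "': no features pass filtering; skipped",
              call. = FALSE)
      next
    }
    if (ncol(pct$values) < max(min_samples, 3)) {
      warning("cell type '", ct, "': fewer than ", max(min_samples, 3),
              " samples; skipped", call. = FALSE)
      next
    }
    if (modality == "rna_counts") {
      tr <- transform_counts(pct)
      tm <- tr$matrix
      sf <- tr$size_factors
      norm_vals <- NULL
    } else {
      norm <- if (pct$normalized) pct else normalize_gene_scores(pct)
      norm_vals <- norm$values
      tm <- log2(norm_vals + 1)
      sf <- NULL
    }
    colnames(tm) <- pct$sample_meta$sample_id
    ol <- remove_outliers_iterative(tm, sd_threshold = sd_threshold)
    keep <- pct$sample_meta$sample_id %in% ol$kept
    if (sum(keep) < min_samples) {
      warning("cell type '", ct, "': fewer than ", min_samples,
              " samples after outlier removal; skipped", call. = FALSE)
      next
    }
    pct <- pb_subset_samples(pct, keep)
    tab <- dplyr::inner_join(pct$sample_meta, impute_rin(sample_table),
                             by = "donor_id")
    if (modality == "rna_counts") {
      tr <- transform_counts(pct)
      tm <- tr$matrix
      sf <- tr$size_factors
    } else {
      norm_vals <- norm_vals[, keep, drop = FALSE]
      tm <- log2(norm_vals + 1)
    }
    d0 <- build_design(tab, variable_of_interest = voi,
                       covariates = use_covariates,
                       include_batch = !is_risk)
    noise <- compute_noise_pc(tm, d0$matrix)
    design <- build_design(tab, variable_of_interest = voi,
                           covariates = use_covariates,
                           pc_noise = noise$pc_noise,
                           include_batch = !is_risk)
    fit <- if (modality == "rna_counts") {
      fit_nb_glm_wald(pct$values, design, size_factors = sf)
    } else {
      fit_lm_wald(norm_vals, design)
    }
    fit$fdr <- bh_adjust(fit$p_value)
    fit$n_samples_used <- ncol(pct$values)
    fit$cell_type <- ct
    fit$modality <- modality
    fit$contrast <- contrast
    results[[ct]] <- fit
    details[[ct]] <- list(design = design, size_factors = sf,
                          outliers = ol, noise_pc = noise$pc_noise,
                          sample_ids = pct$sample_meta$sample_id)
  }
  table <- dplyr::bind_rows(results)
  if (nrow(table)) {
    table <- dplyr::select(
      table, "gene_id", "log2FC", "SE", "wald_statistic", "p_value",
      "fdr", "n_samples_used", "cell_type", "modality", "contrast",
      dplyr::any_of(c("dispersion", "converged", "df"))
    )
  }
  structure(
    list(table = table, contrast = contrast, modality = modality,
         fdr_threshold = fdr_threshold, details = details),
    class = "differential_result"
  )
}

#' Significant genes of a differential result
#' @param x A `differential_result`.
#' @param fdr Threshold (defaults to the one stored in `x`).
#' @return Tibble of rows with `fdr <=` threshold.
#' @export
significant_genes <- function(x, fdr = x$fdr_threshold) {
  dplyr::filter(x$table, !is.na(.data$fdr), .data$fdr <= !!fdr)
}

#' @method print differential_result
#' @export
print.differential_result <- function(x, ...) {
  n_sig <- nrow(significant_genes(x))
  cat(sprintf(
    "<differential_result:%s> contrast %s: %d tests in %d cell types, %d at FDR<=%g\n",
    x$modality, x$contrast, nrow(x$table),
    dplyr::n_distinct(x$table$cell_type), n_sig, x$fdr_threshold
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.differential_result <- function(x, ...) x$table

#' @importFrom generics glance
#' @export
glance.differential_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, modality = x$modality,
    n_cell_types = dplyr::n_distinct(x$table$cell_type),
    n_tests = nrow(x$table),
    n_significant = nrow(significant_genes(x)),
    fdr_threshold = x$fdr_threshold
  )
}
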