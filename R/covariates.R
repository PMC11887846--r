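# Data-driven covariate selection, hidden-noise PC estimation, iterative
# PCA outlier removal, and design-matrix construction.

#' Variance-stabilizing transform for pseudobulk counts
#'
#' Size factors are computed by the median-of-ratios rule: for each sample,
#' the median over all-positive features of count / geometric feature mean.
#' The transformed value is `log2(count / size_factor + 1)`, a closed-form,
#' rank-preserving stabilization. When no feature is positive in every
#' sample, size factors fall back to total-count scaling with a warning.
#'
#' @param pb A [pseudobulk_assay()] with modality `"rna_counts"`.
#' @return List with `matrix` (features x samples, transformed) and
#'   `size_factors` (one per sample).
#' @export
transform_counts <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk_assay"))
  if (pb$modality != "rna_counts") {
    stop("transform_counts expects rna_counts", call. = FALSE)
  }
  m <- pb$values
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    log_geo <- rowMeans(log(m[all_pos, , drop = FALSE]))
    sf <- apply(m[all_pos, , drop = FALSE], 2, function(col) {
      stats::median(exp(log(col) - log_geo))
    })
  } else {
    warning("no feature positive in all samples; using total-count size factors",
            call. = FALSE)
    tot <- colSums(m)
    sf <- tot / mean(tot)
  }
  list(matrix = log2(sweep(m, 2, sf, "/") + 1), size_factors = sf)
}

#' Principal component scores with a fixed sign convention
#'
#' PCA of the row-observations of `x` (centered, unscaled by default). The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making results deterministic across platforms.
#'
#' @param x Numeric matrix, observations in rows.
#' @param n_pcs Number of components to return.
#' @param center,scale Passed to [stats::prcomp()].
#' @return List with `scores`, `loadings`, `explained_variance`
#'   (proportions), and `zero_variance` flag vector.
#' @export
pca_scores <- function(x, n_pcs = min(10, nrow(x) - 1), center = TRUE,
                       scale = FALSE) {
  if (nrow(x) < 2) stop("PCA needs at least 2 observations", call. = FALSE)
  n_pcs <- max(1, min(n_pcs, nrow(x) - 1, ncol(x)))
  p <- stats::prcomp(x, center = center, scale. = scale, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  total_var <- sum(p$sdev^2)
  ev <- if (total_var > 0) p$sdev[seq_len(ncol(scores))]^2 / total_var else
    rep(0, ncol(scores))
  list(scores = scores, loadings = loadings, explained_variance = ev,
       zero_variance = p$sdev[seq_len(ncol(scores))]^2 < 1e-12)
}

#' Associate donor covariates with principal components
#'
#' Continuous covariates are tested by Pearson correlation (t test) against
#' each of the first 10 PCs; categorical covariates by a one-way ANOVA F
#' test of the PC scores across levels (the univariate equivalent of a
#' canonical correlation screen). A covariate is selected when its minimum
#' p value across the examined PCs is at most `alpha`.
#'
#' @param scores PC score matrix (samples x PCs), e.g. from [pca_scores()].
#' @param sample_table Data frame aligned with the score rows holding the
#'   covariate columns.
#' @param covariates Covariate column names to screen.
#' @param alpha Selection threshold on the per-covariate minimum p value.
#' @param n_pcs Number of leading PCs examined (capped at what is
#'   available).
#' @return An object of class `covariate_report`: list with `table`
#'   (covariate x PC statistics), `selected`, `alpha`.
#' @export
associate_covariates_with_pcs <- function(scores, sample_table,
                                          covariates = c("age", "pH", "pmi",
                                                         "rin", "sex",
                                                         "lib_batch"),
                                          alpha = 0.05, n_pcs = 10) {
  if (nrow(scores) < 3) stop("need at least 3 samples", call. = FALSE)
  stopifnot(nrow(scores) == nrow(sample_table))
  n_pcs <- min(n_pcs, ncol(scores), nrow(scores) - 1)
  rows <- list()
  for (cv in covariates) {
    v <- sample_table[[cv]]
    if (is.null(v)) next
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("covariate '", cv, "' is constant; excluded", call. = FALSE)
      next
    }
    for (j in seq_len(n_pcs)) {
      s <- scores[, j]
      if (is.numeric(v)) {
        ok <- !is.na(v)
        ct <- suppressWarnings(stats::cor.test(v[ok], s[ok]))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          covariate = cv, pc = j, type = "continuous",
          statistic = unname(ct$estimate), p_value = ct$p.value
        )
      } else {
        fit <- stats::aov(s ~ factor(v))
        tab <- summary(fit)[[1]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          covariate = cv, pc = j, type = "categorical",
          statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1]
        )
      }
    }
  }
  table <- dplyr::bind_rows(rows)
  if (nrow(table)) {
    table <- table |>
      dplyr::group_by(.data$covariate) |>
      dplyr::mutate(selected = min(.data$p_value, na.rm = TRUE) <= alpha) |>
      dplyr::ungroup()
  } else {
    table <- tibble::tibble(covariate = character(), pc = integer(),
                            type = character(), statistic = numeric(),
                            p_value = numeric(), selected = logical())
  }
  structure(
    list(table = table,
         selected = unique(table$covariate[table$selected]),
         alpha = alpha, n_pcs = n_pcs),
    class = "covariate_report"
  )
}

#' @method print covariate_report
#' @export
print.covariate_report <- function(x, ...) {
  cat(sprintf("<covariate_report> %d covariates screened over %d PCs (alpha=%g)\n",
              dplyr::n_distinct(x$table$covariate), x$n_pcs, x$alpha))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Impute missing RIN values to the cohort median
#'
#' @param cohort Cohort tibble with an `rin` column.
#' @return The cohort with missing RIN replaced by the median of the
#'   observed values; all other fields untouched.
#' @export
impute_rin <- function(cohort) {
  if (all(is.na(cohort$rin))) {
    stop("all RIN values are missing; cannot impute", call. = FALSE)
  }
  med <- stats::median(cohort$rin, na.rm = TRUE)
  dplyr::mutate(cohort, rin = dplyr::coalesce(.data$rin, med))
}

#' Estimate the hidden-noise principal component
#'
#' Regresses every feature on the known design (covariates plus the
#' variable of interest), then takes the first principal component of the
#' residual matrix across samples as a surrogate for unmodeled structured
#' noise. The returned vector is standardized to unit variance and is
#' orthogonal to every design column by construction.
#'
#' @param mat Transformed data, features x samples.
#' @param design Numeric design matrix (samples x columns, including the
#'   intercept), without the noise PC.
#' @return List with `pc_noise` (length = samples), `explained_variance`
#'   of the residual PC, and `degenerate` flag (TRUE when residuals are
#'   numerically zero, in which case `pc_noise` is all zeros).
#' @export
compute_noise_pc <- function(mat, design) {
  n <- ncol(mat)
  stopifnot(nrow(design) == n)
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  if (n <= ncol(design) + 1) {
    stop("need more samples than design columns + 1", call. = FALSE)
  }
  resid <- t(qr.resid(qr_x, t(mat)))  # features x samples
  if (max(abs(resid)) < 1e-10) {
    warning("residual matrix is numerically zero; PC_noise set to zeros",
            call. = FALSE)
    return(list(pc_noise = rep(0, n), explained_variance = 0,
                degenerate = TRUE))
  }
  p <- pca_scores(t(resid), n_pcs = 1, center = TRUE)
  v <- p$scores[, 1]
  list(pc_noise = v / stats::sd(v), explained_variance =
         p$explained_variance[1], degenerate = FALSE)
}

#' Iteratively remove PC1 outlier samples
#'
#' Repeats: compute PC1 scores of the samples, drop every sample whose
#' score lies more than `sd_threshold` sample standard deviations from the
#' mean, and recompute; stops when no sample is removed or fewer than 3
#' samples remain. With zero PC1 variance nothing is removed.
#'
#' @param mat Transformed data, features x samples (columns named).
#' @param sd_threshold Distance threshold in SDs (default 3).
#' @return List with `kept` (sample ids), `removed` (tibble: iteration,
#'   sample_id, score), `n_iterations`.
#' @export
remove_outliers_iterative <- function(mat, sd_threshold = 3) {
  ids <- colnames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(mat)))
  if (ncol(mat) < 3) stop("need at least 3 samples", call. = FALSE)
  removed <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- pca_scores(t(mat), n_pcs = 1, center = TRUE)
    s <- p$scores[, 1]
    sdev <- stats::sd(s)
    if (!is.finite(sdev) || sdev == 0) break
    out <- abs(s - mean(s)) > sd_threshold * sdev
    if (!any(out)) break
    removed[[iter]] <- tibble::tibble(iteration = iter,
                                      sample_id = ids[out],
                                      score = unname(s[out]))
    mat <- mat[, !out, drop = FALSE]
    ids <- ids[!out]
    if (length(ids) < 3) break
  }
  list(kept = ids, removed = dplyr::bind_rows(removed), n_iterations = iter)
}

#' Build the differential-testing design matrix
#'
#' Columns, in order: intercept, variable of interest (0/1), sex (0/1,
#' M = 1), then the selected continuous covariates (centered), library
#' batch indicators (reference level dropped), and the noise PC. For risk
#' contrasts the library batch is excluded: the small matched groups do not
#' contain enough observations per batch to support a categorical
#' covariate.
#'
#' @param sample_table Data frame, one row per sample, holding the variable
#'   of interest and covariate columns (post RIN imputation).
#' @param variable_of_interest `"disease_status"` (case = 1) or
#'   `"risk_group"` (high = 1).
#' @param covariates Continuous covariate columns to include.
#' @param pc_noise Optional numeric vector (one per sample).
#' @param include_batch Include `lib_batch` indicators; forced off for risk
#'   contrasts.
#' @return Object of class `design_matrix`: list with `matrix`, `voi`
#'   (column name of the variable of interest), `provenance` tibble.
#' @export
build_design <- function(sample_table,
                         variable_of_interest = c("disease_status",
                                                  "risk_group"),
                         covariates = c("age", "pH", "rin", "pmi"),
                         pc_noise = NULL, include_batch = TRUE) {
  variable_of_interest <- match.arg(variable_of_interest)
  n <- nrow(sample_table)
  if (variable_of_interest == "disease_status") {
    voi <- as.numeric(sample_table$disease_status == "case")
    voi_name <- "disease_status"
  } else {
    voi <- as.numeric(sample_table$risk_group == "high")
    voi_name <- "risk_group"
    if (include_batch) {
      message("lib_batch excluded from the risk-group design ",
              "(too few observations per batch)")
      include_batch <- FALSE
    }
  }
  cols <- list(intercept = rep(1, n))
  cols[[voi_name]] <- voi
  prov <- tibble::tibble(column = c("intercept", voi_name),
                         source = c("intercept", "variable_of_interest"))
  if ("sex" %in% names(sample_table)) {
    cols$sex <- as.numeric(sample_table$sex == "M")
    prov <- dplyr::add_row(prov, column = "sex", source = "covariate")
  }
  for (cv in covariates) {
    if (cv == "sex") next
    v <- sample_table[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found", call. = FALSE)
    if (anyNA(v)) stop("covariate '", cv, "' has missing values; impute first",
                       call. = FALSE)
    cols[[cv]] <- v - mean(v)
    prov <- dplyr::add_row(prov, column = cv, source = "covariate")
  }
  if (include_batch && "lib_batch" %in% names(sample_table)) {
    lv <- sort(unique(sample_table$lib_batch))
    for (b in lv[-1]) {
      nm <- paste0("lib_batch", b)
      cols[[nm]] <- as.numeric(sample_table$lib_batch == b)
      prov <- dplyr::add_row(prov, column = nm, source = "lib_batch")
    }
  }
  if (!is.null(pc_noise)) {
    stopifnot(length(pc_noise) == n)
    cols$pc_noise <- pc_noise
    prov <- dplyr::add_row(prov, column = "pc_noise", source = "noise_pc")
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  if ("sample_id" %in% names(sample_table)) {
    rownames(x) <- sample_table$sample_id
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(matrix = x, voi = voi_name, provenance = prov),
            class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print design_matrix
#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d samples x %d columns (voi: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$voi))
  cat("columns:", paste(colnames(x$matrix), collapse = ", "), "\n")
  invisible(x)
}
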