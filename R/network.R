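# Multi-omic Spearman correlation networks: typed nodes (expression,
# accessibility, PRS, disease status) and signed, |rho|-weighted edges.

#' Spearman correlation network across multi-omic features
#'
#' Computes Spearman correlations (average ranks for ties) between every
#' pair of features and keeps edges with nominal `p <= p_threshold`; the p
#' value uses the t approximation with `n - 2` degrees of freedom. Before
#' correlating, expression and accessibility features are residualized
#' against the supplied covariates (sex, age, RIN, PMI, pH, library batch
#' when present); PRS and status features are used as-is. Edge weight is
#' `|rho|`; the sign is retained separately.
#'
#' @param feature_table Tibble with `donor_id` plus one numeric column per
#'   feature.
#' @param node_meta Tibble: `feature`, `modality` (one of `"expression"`,
#'   `"accessibility"`, `"prs"`, `"status"`), `cell_type` (or `NA`).
#' @param covariate_table Optional tibble aligned by `donor_id` with the
#'   correction covariates.
#' @param p_threshold Nominal p-value cutoff for retaining an edge.
#' @return Object of class `correlation_network`: list with `nodes`,
#'   `edges` (`from`, `to`, `rho`, `p_value`, `sign`, `weight`),
#'   `n_samples`, `p_threshold`.
#' @export
spearman_network <- function(feature_table, node_meta,
                             covariate_table = NULL, p_threshold = 0.05) {
  feats <- setdiff(names(feature_table), "donor_id")
  missing_meta <- setdiff(feats, node_meta$feature)
  if (length(missing_meta)) {
    stop("node_meta lacks features: ",
         paste(utils::head(missing_meta, 3), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(feature_table[feats])
  n <- nrow(m)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  constant <- apply(m, 2, function(x) stats::sd(x) == 0 || anyNA(x))
  if (any(constant)) {
    warning("excluding constant feature(s): ",
            paste(utils::head(feats[constant], 3), collapse = ", "),
            call. = FALSE)
    m <- m[, !constant, drop = FALSE]
    feats <- feats[!constant]
  }
  if (!is.null(covariate_table)) {
    stopifnot(nrow(covariate_table) == n)
    cv <- covariate_table
    cols <- intersect(c("sex", "age", "rin", "pmi", "pH", "lib_batch"),
                      names(cv))
    cols <- cols[vapply(cols, function(cl)
      length(unique(cv[[cl]])) > 1, logical(1))]
    if (length(cols)) {
      x <- stats::model.matrix(
        stats::reformulate(cols),
        data = as.data.frame(cv)
      )
      meta <- node_meta[match(feats, node_meta$feature), ]
      omic <- meta$modality %in% c("expression", "accessibility")
      if (any(omic)) {
        m[, omic] <- qr.resid(qr(x), m[, omic, drop = FALSE])
      }
    }
  }
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  pmat <- 2 * stats::pt(-abs(tstat), n - 2)
  pmat[abs(rho) >= 1 - 1e-12] <- 0
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = feats[idx[, 1]], to = feats[idx[, 2]],
    rho = rho[idx], p_value = pmat[idx]
  ) |>
    dplyr::filter(.data$p_value <= p_threshold) |>
    dplyr::mutate(sign = sign(.data$rho), weight = abs(.data$rho)) |>
    dplyr::arrange(.data$from, .data$to)
  nodes <- node_meta[match(feats, node_meta$feature), ]
  structure(
    list(nodes = nodes, edges = edges, n_samples = n,
         p_threshold = p_threshold),
    class = "correlation_network"
  )
}

#' @method print correlation_network
#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network> %d nodes, %d edges (p<=%g, n=%d)\n",
    nrow(x$nodes), nrow(x$edges), x$p_threshold, x$n_samples
  ))
  invisible(x)
}

#' @export
tidy.correlation_network <- function(x, ...) x$edges

#' @export
glance.correlation_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_samples = x$n_samples, p_threshold = x$p_threshold,
    mean_abs_rho = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_
  )
}

#' Convert a correlation network to an igraph object
#'
#' @param x A `correlation_network`.
#' @return An undirected [igraph::graph] with node attributes `modality`,
#'   `cell_type` and edge attributes `rho`, `p_value`, `sign`, `weight`.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "correlation_network"))
  vertices <- data.frame(
    name = x$nodes$feature,
    modality = x$nodes$modality,
    cell_type = ifelse(is.na(x$nodes$cell_type), "n/a", x$nodes$cell_type),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    as.data.frame(x$edges), directed = FALSE, vertices = vertices
  )
}
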