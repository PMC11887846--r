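test_that("nucleus QC applies the stated thresholds strictly", {
  counts <- Matrix::Matrix(matrix(1L, 5, 3), sparse = TRUE)
  meta <- tibble::tibble(
    nucleus_id = paste0("n", 1:5),
    donor_id = "d1", cell_type = "Exc",
    total_counts = c(499, 500, 500, 1000, 1000),
    n_features_detected = c(500, 300, 299, 400, 400),
    mito_fraction = c(0.01, 0.149, 0.01, 0.15, 0.02)
  )
  nm <- nucleus_matrix(counts, meta, paste0("g", 1:3))
  th <- qc_thresholds(min_nuclei = 1)
  kept <- qc_filter_nuclei(nm, th)$nucleus_meta$nucleus_id
  # n1: counts 499 < 500 out; n2: boundary kept; n3: genes 299 out;
  # n4: mito 0.15 out; n5: clean
  expect_identical(kept, c("n2", "n5"))
})

test_that("ATAC fragment and TSS thresholds filter nuclei", {
  counts <- Matrix::Matrix(matrix(1L, 4, 2), sparse = TRUE)
  meta <- tibble::tibble(
    nucleus_id = paste0("n", 1:4), donor_id = "d1", cell_type = "Exc",
    n_fragments = c(999, 1000, 100000, 100001),
    tss_enrichment = c(5, 4, 3.9, 5)
  )
  nm <- nucleus_matrix(counts, meta, c("gA", "gB"))
  kept <- qc_filter_nuclei(nm, qc_thresholds(min_nuclei = 1))$nucleus_meta
  expect_identical(kept$nucleus_id, "n2")
})

test_that("sparsely detected features are removed after nucleus QC", {
  counts <- Matrix::Matrix(cbind(rep(1L, 10), c(1L, rep(0L, 9))),
                           sparse = TRUE)
  meta <- tibble::tibble(nucleus_id = paste0("n", 1:10), donor_id = "d1",
                         cell_type = "Exc")
  nm <- nucleus_matrix(counts, meta, c("common", "rare"))
  out <- qc_filter_nuclei(nm, qc_thresholds(min_nuclei = 5))
  expect_identical(out$feature_ids, "common")
})

test_that("pseudobulk aggregation sums nuclei per group and conserves totals", {
  nm <- tiny_nucleus_fixture()  # rows [1,2],[3,4],[5,6]; d1/Exc, d1/Exc, d1/Ast
  pb <- aggregate_pseudobulk(nm, by = "donor_cell_type")
  expect_identical(pb$sample_meta$sample_id, c("d1.Ast", "d1.Exc"))
  expect_equal(unname(pb$values[, "d1.Exc"]), c(4, 6))
  expect_equal(unname(pb$values[, "d1.Ast"]), c(5, 6))
  expect_identical(pb$sample_meta$n_cells, c(1L, 2L))
  expect_equal(sum(pb$values), sum(nm$counts))

  # full pseudobulk equals the sum of per-cell-type pseudobulks
  full <- aggregate_pseudobulk(nm, by = "donor")
  expect_equal(unname(full$values[, "d1"]),
               unname(rowSums(pb$values)))
  expect_identical(full$sample_meta$n_cells, 3L)

  # one nucleus per group reproduces that nucleus
  nm1 <- nucleus_matrix(nm$counts[3, , drop = FALSE],
                        nm$nucleus_meta[3, ], nm$feature_ids)
  pb1 <- aggregate_pseudobulk(nm1)
  expect_equal(unname(pb1$values[, 1]), c(5, 6))
  expect_identical(pb1$sample_meta$n_cells, 1L)
})

test_that("gene scores use the exponential distance kernel within 100 kb", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 200000L, end = 210000L, strand = "+")
  mk_peak <- function(start) {
    tibble::tibble(peak_id = "p1", chrom = "chr1",
                   start = as.integer(start), end = as.integer(start + 501))
  }
  score_for <- function(peaks, count) {
    pc <- make_pb(matrix(count, 1, 1, dimnames = list("p1", NULL)))
    compute_gene_scores(pc, peaks, genes)$values[1, 1]
  }
  # peak overlapping the gene body: w(0) = 1
  expect_equal(score_for(mk_peak(205000), 7), 7)
  # peak ending exactly 5000 bp before the gene start: w = exp(-1)
  expect_equal(score_for(mk_peak(200000 - 5000 - 501), 1), exp(-1),
               tolerance = 1e-12)
  # peak 100001 bp away contributes nothing
  far <- mk_peak(200000 - 100001 - 501)
  pc <- make_pb(matrix(1, 1, 1, dimnames = list("p1", NULL)))
  out <- compute_gene_scores(pc, far, genes)
  expect_equal(out$values[1, 1], 0)
  expect_identical(attr(out, "no_peak_genes"), "g1")
})

test_that("gene scores are linear in peak counts", {
  set.seed(4)
  ann <- simulate_annotations(10, 50, 2, 2, seed = 4)
  pc <- make_pb(matrix(rpois(50 * 3, 5), 50, 3,
                       dimnames = list(ann$peaks$peak_id, NULL)))
  s1 <- compute_gene_scores(pc, ann$peaks, ann$genes)$values
  pc2 <- make_pb(pc$values * 2)
  s2 <- compute_gene_scores(pc2, ann$peaks, ann$genes)$values
  expect_equal(s2, s1 * 2)
})

test_that("cell-count normalization divides once and only once", {
  pb <- make_pb(matrix(c(10, 20), 1), cell_type = "Exc",
                n_cells = c(4L, 1L), modality = "atac_genescore")
  norm <- normalize_gene_scores(pb)
  expect_equal(unname(norm$values[1, ]), c(2.5, 20))
  expect_true(norm$normalized)
  expect_error(normalize_gene_scores(norm), "already")
  expect_error(normalize_gene_scores(make_pb(matrix(1, 1, 1))),
               "gene scores")
})

test_that("feature filtering follows the count and score rules at the boundary", {
  pb <- make_pb(matrix(c(10, 10, 10, 0,
                         9, 10, 10, 10), 2, byrow = TRUE))
  kept <- filter_features(pb, min_value = 10, min_fraction = 0.75)
  expect_equal(nrow(kept$values), 2)  # both have >= 3 samples at >= 10

  pb2 <- make_pb(matrix(c(10, 10, 0, 0), 1))
  expect_equal(nrow(filter_features(pb2, 10, 0.75)$values), 0)

  sc <- make_pb(matrix(c(0.2, 0.2, 0.05, 0.05,
                         0.2, 0.2, 0.2, 0.05), 2, byrow = TRUE),
                modality = "atac_genescore")
  kept_sc <- filter_features(sc, min_value = 0.1, min_fraction = 0.75)
  expect_equal(rownames(kept_sc$values), "g002")  # strict > for scores

  empty <- make_pb(matrix(numeric(), 0, 4))
  expect_equal(nrow(filter_features(empty, 10, 0.75)$values), 0)

  # idempotent
  expect_equal(filter_features(kept, 10, 0.75)$values, kept$values)
})
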