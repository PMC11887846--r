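test_that("cohort generation honors size, determinism and distributions", {
  expect_equal(nrow(simulate_cohort(0)), 0)
  expect_identical(simulate_cohort(30, seed = 5), simulate_cohort(30, seed = 5))
  expect_error(simulate_cohort(10, case_fraction = 1.5), "case_fraction")

  big <- simulate_cohort(10000, seed = 11)
  expect_lt(abs(mean(big$age) - 54.27), 3 * 13.64 / sqrt(10000))
  expect_lt(abs(mean(big$pmi) - 33.90), 4 * 14.82 / sqrt(10000))
  expect_lt(abs(mean(big$sex == "F") - 0.38), 3 * sqrt(0.38 * 0.62 / 10000))
  expect_true(all(big$pmi >= 0))
  expect_equal(sum(is.na(big$rin)), 1)
  expect_equal(sum(big$disease_status == "case"), round(10000 * 57 / 92))
  dx <- table(big$diagnosis[big$disease_status == "case"])
  expect_gt(dx[["schizophrenia"]] / sum(dx), 0.5)
})

test_that("simulated PRS is standardized and tracks the latent liability", {
  co <- simulate_cohort(10000, seed = 3)
  co0 <- simulate_prs(co, "null_trait", liability_correlation = 0, seed = 4)
  prs <- co0$prs_null_trait
  expect_equal(mean(prs), 0, tolerance = 1e-8)
  expect_equal(sd(prs), 1, tolerance = 1e-8)
  status <- as.numeric(co0$disease_status == "case")
  expect_lt(abs(cor(prs, status)), 0.05)

  co1 <- simulate_prs(co, "full", liability_correlation = 1, seed = 4)
  expect_gt(mean(co1$prs_full[co1$disease_status == "case"]),
            mean(co1$prs_full[co1$disease_status == "control"]))

  expect_identical(simulate_prs(co, "t", 0.3, seed = 9),
                   simulate_prs(co, "t", 0.3, seed = 9))
  expect_error(simulate_prs(co0, "null_trait", 0.3, 1), "already has")
  expect_error(simulate_prs(co, "x", 1.5, 1), "liability_correlation")
})

test_that("expression counts carry planted fold changes and are seeded", {
  co <- simulate_cohort(200, case_fraction = 0.5, seed = 21)
  spec1 <- truth_spec(status_frac = 1, status_log2fc = 1, dispersion = 0.05,
                      hidden_sd = 0, batch_sd = 0, covariate_sd = 0)
  sim <- simulate_expression_counts(co, "ct1", 50, spec = spec1, seed = 22)
  sf <- transform_counts(sim$assay)$size_factors
  q <- sweep(sim$assay$values, 2, sf, "/")
  case <- co$disease_status == "case"
  ratio <- rowMeans(q[, case]) / rowMeans(q[, !case])
  eff <- sim$truth$gene_effects
  expected <- 2^eff$status_log2fc
  expect_equal(median(ratio / expected), 1, tolerance = 0.1)

  spec0 <- truth_spec(status_frac = 0, hidden_sd = 0, batch_sd = 0,
                      covariate_sd = 0)
  sim0 <- simulate_expression_counts(co, "ct1", 100, spec = spec0, seed = 23)
  q0 <- sweep(sim0$assay$values, 2,
              transform_counts(sim0$assay)$size_factors, "/")
  ratio0 <- rowMeans(q0[, case]) / rowMeans(q0[, !case])
  expect_equal(median(ratio0), 1, tolerance = 0.1)

  expect_identical(
    simulate_expression_counts(co, "ct1", 20, seed = 5)$assay$values,
    simulate_expression_counts(co, "ct1", 20, seed = 5)$assay$values
  )
  expect_error(truth_spec(dispersion = -1), "dispersion")
})

test_that("library sizes span at least a 4-fold range by construction", {
  co <- simulate_cohort(60, seed = 2)
  sim <- simulate_expression_counts(co, "ct1", 300, seed = 2)
  tot <- colSums(sim$assay$values)
  expect_gt(max(tot) / min(tot), 2)  # realized spread of 4-fold factor range
})

test_that("nucleus-level mode aggregates to the emitted pseudobulk", {
  co <- simulate_cohort(4, seed = 7)
  sim <- simulate_expression_counts(co, c("Exc", "Ast"), 30, seed = 7,
                                    level = "nucleus",
                                    cells_per_sample = c(5, 10))
  agg <- aggregate_pseudobulk(sim$nuclei, by = "donor_cell_type")
  common <- intersect(agg$sample_meta$sample_id, sim$assay$sample_meta$sample_id)
  expect_setequal(agg$sample_meta$sample_id, sim$assay$sample_meta$sample_id)
  ord <- match(sim$assay$sample_meta$sample_id, agg$sample_meta$sample_id)
  expect_equal(unname(agg$values[, ord]), unname(sim$assay$values))
})

test_that("gene scores are positive, cell-count scaled, and seeded", {
  co <- simulate_cohort(20, seed = 31)
  sim <- simulate_gene_scores(co, "ct1", 40, seed = 32)
  expect_true(all(sim$assay$values > 0))
  expect_false(sim$assay$normalized)
  # doubled cell counts with the same signal leave normalized scores unchanged
  pb <- sim$assay
  doubled <- pseudobulk_assay(pb$values * 2,
                              dplyr::mutate(pb$sample_meta,
                                            n_cells = n_cells * 2L),
                              modality = pb$modality)
  expect_equal(normalize_gene_scores(doubled)$values,
               normalize_gene_scores(pb)$values)
  expect_identical(simulate_gene_scores(co, "ct1", 10, seed = 3)$assay$values,
                   simulate_gene_scores(co, "ct1", 10, seed = 3)$assay$values)
})

test_that("annotations: 501-bp peaks, promoter coverage, set-size bounds", {
  ann <- simulate_annotations(40, 120, 8, 6, seed = 41, set_size = c(5, 15))
  expect_true(all(ann$peaks$end - ann$peaks$start == 501))
  expect_equal(nrow(ann$peaks), 120)
  sizes <- lengths(ann$gene_sets$members)
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_true(all(unlist(ann$motifs[-1]) %in% 0:1))
  # every gene has a peak within its promoter window
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tss <- if (g$strand == "+") g$start else g$end
    win <- if (g$strand == "+") c(tss - 2000, tss + 500) else
      c(tss - 500, tss + 2000)
    hit <- any(ann$peaks$chrom == g$chrom & ann$peaks$start < win[2] &
                 ann$peaks$end > win[1])
    expect_true(hit, info = g$gene_id)
  }
  expect_identical(simulate_annotations(10, 20, 3, 2, seed = 1),
                   simulate_annotations(10, 20, 3, 2, seed = 1))
  expect_warning(simulate_annotations(10, 5, 2, 1, seed = 1),
                 "fewer peaks than genes")
})
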