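test_that("hypergeometric enrichment reproduces exact enumeration", {
  # worked example: N=20, K=5, n=5, k=4 -> 76/15504
  universe <- paste0("g", 1:20)
  sel <- paste0("g", 1:5)
  sets <- tibble::tibble(set_id = "S", members = list(paste0("g", c(1:4, 20))))
  res <- hypergeometric_enrichment(sel, universe, sets)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap_k, 4)

  # empty selection: p = 1
  r0 <- hypergeometric_enrichment(character(), universe, sets)
  expect_equal(r0$p_value, 1)
  # set = universe: p = 1 regardless of selection
  ru <- hypergeometric_enrichment(sel, universe,
                                  tibble::tibble(set_id = "U",
                                                 members = list(universe)))
  expect_equal(ru$p_value, 1)
  expect_error(hypergeometric_enrichment("zz", universe, sets), "subset")

  # random instances vs the enumeration oracle
  set.seed(21)
  for (i in 1:30) {
    N <- sample(5:25, 1)
    uni <- paste0("x", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    st <- tibble::tibble(set_id = "S", members = list(sample(uni, K)))
    slc <- sample(uni, n)
    r <- hypergeometric_enrichment(slc, uni, st)
    expect_equal(r$p_value, hyper_enum(r$overlap_k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("pathway enrichment ranks, truncates and tie-breaks deterministically", {
  set.seed(22)
  genes <- sprintf("g%03d", 1:120)
  tab <- tibble::tibble(
    gene_id = genes, cell_type = "Exc",
    log2FC = c(rep(1, 60), rep(-1, 60)),
    p_value = runif(120), fdr = NA
  )
  tab$fdr <- bh_adjust(tab$p_value)
  # plant: top up-regulated genes drawn from one set
  top_up <- tab |>
    dplyr::filter(log2FC > 0) |>
    dplyr::arrange(fdr, gene_id) |>
    head(15)
  sets <- tibble::tibble(
    set_id = c("planted", "random"),
    members = list(top_up$gene_id, sample(genes, 15))
  )
  res <- pathway_enrichment(tab, sets, top_n = 20)
  up <- dplyr::filter(res, direction == "up")
  expect_equal(up$set_id[which.min(up$p_value)], "planted")

  # permuting the input row order leaves the result unchanged
  res2 <- pathway_enrichment(tab[sample(120), ], sets, top_n = 20)
  expect_equal(dplyr::arrange(res, cell_type, direction, set_id),
               dplyr::arrange(res2, cell_type, direction, set_id))

  # one-sided inputs skip the empty direction
  up_only <- dplyr::mutate(tab, log2FC = abs(log2FC))
  expect_warning(r3 <- pathway_enrichment(up_only, sets, top_n = 20),
                 "down.*fewer than 10|fewer than 10")
  expect_identical(unique(r3$direction), "up")
})

test_that("motif enrichment tests promoter peaks against all peaks", {
  # 2 promoter peaks, both carrying a motif present in only those 2 of 100
  peaks <- tibble::tibble(
    peak_id = sprintf("p%03d", 1:100), chrom = "chr1",
    start = c(9000L, 9600L, seq(50000L, by = 1000L, length.out = 98)),
    end = c(9501L, 10101L, seq(50501L, by = 1000L, length.out = 98))
  )
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000L,
                          end = 15000L, strand = "+")
  motifs <- tibble::tibble(peak_id = peaks$peak_id,
                           rare = c(1, 1, rep(0, 98)),
                           everywhere = rep(1, 100))
  res <- motif_enrichment("g1", genes, peaks, motifs)
  expect_equal(res$p_value[res$set_id == "rare"], 1 / 4950,
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set_id == "everywhere"], 1)

  # strand-aware window: gene on the minus strand uses its end as TSS
  genes2 <- tibble::tibble(gene_id = "g2", chrom = "chr1", start = 1000L,
                           end = 51000L, strand = "-")
  res2 <- motif_enrichment("g2", genes2, peaks, motifs)
  expect_gt(res2$selection_n[1], 0)

  # no promoter peaks -> flagged empty result
  far_gene <- tibble::tibble(gene_id = "g3", chrom = "chr2", start = 1000L,
                             end = 2000L, strand = "+")
  r3 <- motif_enrichment("g3", far_gene, peaks, motifs)
  expect_equal(nrow(r3), 0)
  expect_true(attr(r3, "no_promoter_peaks"))
})

test_that("the signed-rank test equals full sign enumeration for small n", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), 1)         # rounding creates ties and zeros
    got <- signed_rank_test(d)
    expect_equal(got$p_value, wilcox_enum(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
  z <- signed_rank_test(rep(0, 5))
  expect_equal(z$p_value, 1)
  expect_true(z$all_zero)
  # large n switches to the corrected normal approximation
  big <- signed_rank_test(rnorm(40) + 0.5)
  expect_identical(big$method, "normal_approx")
  expect_lt(big$p_value, 0.05)
})

test_that("proportion comparison is calibrated on identical tables and has power", {
  set.seed(24)
  donors <- sprintf("d%02d", 1:40)
  base <- tidyr::expand_grid(donor_id = donors,
                             cell_type = c("Exc", "Inh", "Ast", "Oli"))
  base$proportion <- as.vector(apply(
    matrix(rgamma(40 * 4, 5), 40), 1, function(x) x / sum(x)
  ))
  a <- dplyr::mutate(base, modality = "rna")
  ident <- compare_proportions(dplyr::bind_rows(
    a, dplyr::mutate(base, modality = "atac")
  ))
  expect_true(all(ident$tests$p_value == 1))
  expect_equal(ident$median_r, 1)

  # shift one cell type in one modality
  shifted <- base
  exc <- shifted$cell_type == "Exc"
  shifted$proportion[exc] <- shifted$proportion[exc] + 0.05
  shifted <- shifted |>
    dplyr::group_by(donor_id) |>
    dplyr::mutate(proportion = proportion / sum(proportion)) |>
    dplyr::ungroup()
  res <- compare_proportions(dplyr::bind_rows(
    a, dplyr::mutate(shifted, modality = "atac")
  ))
  expect_true(res$tests$significant[res$tests$cell_type == "Exc"])
})

test_that("cross-study effect-size correlation handles self, fixtures and disjoint genes", {
  set.seed(25)
  fc <- tibble::tibble(
    gene_id = rep(sprintf("g%d", 1:30), 2),
    cell_type = rep(c("Exc", "Inh"), each = 30),
    log2FC = rnorm(60)
  )
  self <- cross_study_fc_correlation(fc, fc)
  expect_equal(self$r[self$cell_type_a == self$cell_type_b], c(1, 1))

  a <- tibble::tibble(gene_id = paste0("g", 1:5), cell_type = "Exc",
                      log2FC = c(1, 2, 3, 4, 5))
  b <- tibble::tibble(gene_id = paste0("g", 1:5), cell_type = "Exc",
                      log2FC = c(2, 1, 4, 3, 6))
  hand <- cov(a$log2FC, b$log2FC) / (sd(a$log2FC) * sd(b$log2FC))
  expect_equal(cross_study_fc_correlation(a, b)$r, hand)

  dis <- tibble::tibble(gene_id = paste0("h", 1:5), cell_type = "Exc",
                        log2FC = 1:5)
  expect_true(is.na(cross_study_fc_correlation(a, dis)$r))
})
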