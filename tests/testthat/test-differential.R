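test_that("the linear Wald engine equals closed-form OLS on random fixtures", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    p <- sample(2:4, 1)
    x <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(x) <- c("intercept", paste0("v", seq_len(p - 1)))
    y <- matrix(rnorm(3 * n), 3, n)
    fit <- fit_lm_wald(y, x, log_transform = FALSE, voi = "v1")
    for (g in 1:3) {
      or <- ols_oracle(x, y[g, ])
      expect_equal(fit$log2FC[g], or$beta[2], tolerance = 1e-10)
      expect_equal(fit$SE[g], or$se[2], tolerance = 1e-10)
      expect_equal(fit$p_value[g], or$p[2], tolerance = 1e-10)
    }
  }
})

test_that("a response equal to the group indicator gives coefficient 1, p ~ 0", {
  x <- cbind(intercept = 1, group = rep(0:1, each = 5))
  y <- matrix(x[, "group"], 1)
  fit <- fit_lm_wald(y, x, log_transform = FALSE, voi = "group")
  expect_equal(fit$log2FC, 1)
  expect_equal(fit$p_value, 0)
  expect_error(fit_lm_wald(y[, 1:2, drop = FALSE], x[1:2, ], voi = "group"),
               "more samples")
})

test_that("the NB engine matches a Poisson GLM oracle at the dispersion floor", {
  set.seed(32)
  n <- 30
  x <- cbind(intercept = 1, group = rep(0:1, each = n / 2), cov = rnorm(n))
  sf <- exp(runif(n, -0.5, 0.5))
  counts <- matrix(rpois(20 * n, lambda = 50 * sf), 20, n, byrow = FALSE)
  counts <- t(t(counts))  # genes x samples
  rownames(counts) <- paste0("g", 1:20)
  fit <- fit_nb_glm_wald(counts, x, sf, dispersion = 1e-8, voi = "group")
  for (g in 1:20) {
    or <- poisson_oracle(counts[g, ], x, log(sf))
    expect_equal(fit$log2FC[g] * log(2), or$beta[2], tolerance = 1e-3)
    expect_equal(fit$SE[g] * log(2), or$se[2], tolerance = 1e-3)
  }
})

test_that("the NB engine recovers a planted log2 fold change", {
  set.seed(33)
  n <- 40
  x <- cbind(intercept = 1, group = rep(0:1, each = n / 2))
  mu <- outer(rep(100, 200), 2^x[, "group"])
  counts <- matrix(rnbinom(200 * n, mu = mu, size = 10), 200, n)
  rownames(counts) <- paste0("g", 1:200)
  fit <- fit_nb_glm_wald(counts, x, rep(1, n), voi = "group")
  expect_lt(abs(mean(fit$log2FC) - 1), 0.1)
  fdr <- bh_adjust(fit$p_value)
  expect_gt(mean(fdr <= 0.1), 0.8)
})

test_that("all-zero genes are skipped and degenerate fits flagged", {
  x <- cbind(intercept = 1, group = rep(0:1, each = 4))
  counts <- rbind(g1 = rep(0L, 8), g2 = c(1, 2, 1, 2, 3, 1, 2, 2))
  fit <- fit_nb_glm_wald(counts, x, rep(1, 8), voi = "group")
  expect_identical(fit$gene_id, "g2")
  expect_error(fit_nb_glm_wald(rbind(c(-1, 1, 1, 1, 1, 1, 1, 1)), x,
                               rep(1, 8), voi = "group"),
               "non-negative")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(34)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  # NAs pass through and do not count toward m
  p <- c(0.01, NA, 0.04)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_brute(c(0.01, 0.04)))
  # monotone in sorted p
  p <- sort(runif(30))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("residual normality screen is calibrated and has power", {
  set.seed(35)
  norm_res <- matrix(rnorm(400 * 30), 400, 30)
  out <- check_residual_normality(norm_res)
  expect_lt(abs(out$rejected_fraction - 0.05), 0.04)
  expo <- matrix(rexp(200 * 30), 200, 30)
  expect_gt(check_residual_normality(expo)$rejected_fraction, 0.5)
  expect_warning(cr <- check_residual_normality(matrix(1, 2, 10)),
                 "could not")
  expect_true(all(is.na(cr$per_gene$p_value)))
})

test_that("run_differential is deterministic and respects the skip rule", {
  co <- simulate_cohort(24, seed = 51)
  sim <- simulate_expression_counts(co, c("Exc", "Ast"), 120,
                                    spec = truth_spec(), seed = 52)
  r1 <- suppressWarnings(run_differential(sim$assay, co,
                                          covariates = c("age", "pH")))
  r2 <- suppressWarnings(run_differential(sim$assay, co,
                                          covariates = c("age", "pH")))
  expect_identical(r1$table, r2$table)
  expect_s3_class(tidy(r1), "tbl_df")
  expect_identical(glance(r1)$n_tests, nrow(r1$table))
  expect_true(all(r1$table$fdr >= 0 & r1$table$fdr <= 1, na.rm = TRUE))
  expect_true(all(r1$table$SE > 0, na.rm = TRUE))
  expect_true(all(r1$table$p_value >= 0 & r1$table$p_value <= 1,
                  na.rm = TRUE))

  tiny <- pb_subset_samples(sim$assay, 1:5)
  expect_warning(
    r3 <- run_differential(tiny, co, covariates = character(0)),
    "fewer than"
  )
  expect_equal(nrow(r3$table), 0)
})

test_that("gene-score differential testing uses the linear engine end-to-end", {
  co <- simulate_cohort(30, seed = 61)
  sim <- simulate_gene_scores(co, "Exc", 150,
                              spec = truth_spec(status_frac = 0.2,
                                                status_log2fc = 2),
                              seed = 62)
  res <- suppressWarnings(run_differential(sim$assay, co,
                                           covariates = c("age", "pH")))
  expect_identical(unique(res$table$modality), "atac_genescore")
  expect_true("df" %in% names(res$table))
  truth <- sim$truth$gene_effects
  hit <- significant_genes(res)
  affected <- truth$gene_id[truth$status_log2fc != 0]
  # planted strong effects are recovered
  expect_gt(mean(affected %in% hit$gene_id), 0.8)
})
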