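test_that("median-of-ratios size factors behave on hand fixtures", {
  m <- matrix(c(10, 10,
                20, 20,
                30, 30), 3, byrow = TRUE)
  pb <- make_pb(m)
  tr <- transform_counts(pb)
  expect_equal(unname(tr$size_factors), c(1, 1))
  expect_equal(tr$matrix, log2(m + 1), ignore_attr = TRUE)

  # one sample's counts exactly doubled: size factor doubles
  m2 <- cbind(c(10, 20, 30), c(20, 40, 60))
  tr2 <- transform_counts(make_pb(m2))
  expect_equal(unname(tr2$size_factors[2] / tr2$size_factors[1]), 2)

  # monotone within a sample
  ord <- order(m2[, 1])
  expect_true(all(diff(tr2$matrix[ord, 1]) > 0))

  # fallback when no feature is always positive
  m3 <- cbind(c(5, 0), c(0, 5))
  expect_warning(tr3 <- transform_counts(make_pb(m3)), "total-count")
  expect_equal(unname(tr3$size_factors), c(1, 1))
})

test_that("pca_scores matches an eigendecomposition oracle with fixed signs", {
  set.seed(10)
  x <- matrix(rnorm(12), 4, 3)
  p <- pca_scores(x, n_pcs = 3)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(cov(xc))
  for (j in 1:3) {
    s_or <- drop(xc %*% eig$vectors[, j])
    # orientation-free comparison, then check the package's convention
    expect_equal(abs(unname(p$scores[, j])), abs(s_or), tolerance = 1e-8)
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_equal(p$explained_variance,
               eig$values / sum(eig$values), tolerance = 1e-8)

  # rank-1 matrix: PC1 explains everything
  r1 <- outer(1:4, c(1, 2, 3))
  p1 <- pca_scores(r1, n_pcs = 2)
  expect_equal(p1$explained_variance[1], 1)

  # duplicated observations share scores
  xd <- rbind(x, x[1, ])
  pd <- pca_scores(xd, n_pcs = 2)
  expect_equal(pd$scores[1, ], pd$scores[5, ])
})

test_that("covariates aligned with PCs are selected, constants excluded", {
  set.seed(2)
  scores <- matrix(rnorm(30 * 5), 30, 5,
                   dimnames = list(NULL, paste0("PC", 1:5)))
  tab <- tibble::tibble(
    age = scores[, 1],                      # perfectly correlated with PC1
    pmi = rnorm(30),
    grp = ifelse(scores[, 1] > median(scores[, 1]), "a", "b"),
    flat = rep(1, 30)
  )
  expect_warning(
    rep <- associate_covariates_with_pcs(scores, tab,
                                         covariates = c("age", "pmi",
                                                        "grp", "flat")),
    "constant"
  )
  expect_true("age" %in% rep$selected)
  expect_true("grp" %in% rep$selected)
  expect_false("flat" %in% unique(rep$table$covariate))
  age_p1 <- rep$table$p_value[rep$table$covariate == "age" & rep$table$pc == 1]
  expect_lt(age_p1, 1e-20)
})

test_that("null covariates are selected at the 10-PC familywise rate", {
  set.seed(77)
  n_sim <- 400
  hits <- 0
  for (i in seq_len(n_sim)) {
    scores <- matrix(rnorm(20 * 10), 20, 10)
    tab <- data.frame(age = rnorm(20))
    rep <- associate_covariates_with_pcs(scores, tab, covariates = "age",
                                         alpha = 0.05, n_pcs = 10)
    hits <- hits + ("age" %in% rep$selected)
  }
  expected <- 1 - (1 - 0.05)^10  # 0.401
  se <- sqrt(expected * (1 - expected) / n_sim)
  expect_lt(abs(hits / n_sim - expected), 4 * se)
})

test_that("RIN imputation uses the observed median and touches nothing else", {
  co <- tibble::tibble(donor_id = c("a", "b", "c"), rin = c(7, 8, NA),
                       age = 1:3)
  out <- impute_rin(co)
  expect_equal(out$rin, c(7, 8, 7.5))
  expect_identical(out$age, co$age)
  expect_identical(impute_rin(out), out)
  co2 <- tibble::tibble(rin = c(6, NA, NA))
  expect_equal(impute_rin(co2)$rin, c(6, 6, 6))
  expect_error(impute_rin(tibble::tibble(rin = c(NA_real_, NA_real_))),
               "all RIN")
})

test_that("the noise PC is orthogonal to the design and flags degeneracy", {
  set.seed(5)
  n <- 30
  x <- cbind(1, rep(0:1, each = n / 2), rnorm(n))
  # data exactly in the design column space -> degenerate
  mat0 <- t(x %*% matrix(rnorm(3 * 50), 3))
  expect_warning(out0 <- compute_noise_pc(mat0, x), "numerically zero")
  expect_true(out0$degenerate)
  expect_equal(out0$pc_noise, rep(0, n))

  mat <- mat0 + matrix(rnorm(50 * n, sd = 1), 50, n)
  out <- compute_noise_pc(mat, x)
  expect_equal(sd(out$pc_noise), 1)
  expect_lt(max(abs(crossprod(x, out$pc_noise))), 1e-8)
})

test_that("the noise PC recovers a planted hidden factor", {
  set.seed(6)
  ok <- 0
  for (s in 1:10) {
    n <- 40
    h <- rnorm(n)
    x <- cbind(1, rep(0:1, each = n / 2), rnorm(n))
    load <- rnorm(100, sd = 2)           # SNR 2 vs unit noise
    mat <- outer(load, h) + matrix(rnorm(100 * n), 100, n)
    out <- compute_noise_pc(mat, x)
    # compare against the part of h the design cannot absorb
    h_res <- qr.resid(qr(x), h)
    if (abs(cor(out$pc_noise, h_res)) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("iterative outlier removal removes planted outliers and terminates", {
  set.seed(8)
  n <- 21
  mat <- matrix(rnorm(100 * n), 100, n)
  mat[, n] <- mat[, n] + 10        # +10 SD on every feature
  colnames(mat) <- paste0("s", 1:n)
  out <- remove_outliers_iterative(mat)
  expect_identical(setdiff(paste0("s", 1:n), out$kept), "s21")
  expect_lte(out$n_iterations, 2 + 1)  # removal pass + clean pass
  # direct PCA oracle: the removed sample is the PC1 extreme
  p <- prcomp(t(mat))
  expect_equal(which.max(abs(p$x[, 1] - mean(p$x[, 1]))), c(s21 = 21L))

  # all-identical samples: nothing to remove (zero-variance guard)
  same <- matrix(1, 10, 5, dimnames = list(NULL, paste0("s", 1:5)))
  out2 <- remove_outliers_iterative(same)
  expect_identical(out2$kept, paste0("s", 1:5))
  expect_equal(nrow(out2$removed), 0)

  expect_error(remove_outliers_iterative(mat[, 1:2]), "at least 3")
})

test_that("design construction encodes, centers, and catches collinearity", {
  tab <- make_sample_table(6)
  d <- build_design(tab, "disease_status", covariates = c("age", "pmi"))
  expect_identical(colnames(d$matrix),
                   c("intercept", "disease_status", "sex", "age", "pmi",
                     "lib_batchb2"))
  expect_equal(unname(colSums(d$matrix[, c("age", "pmi")])), c(0, 0))
  expect_equal(qr(d$matrix)$rank, ncol(d$matrix))

  tab$risk_group <- rep(c("high", "low", "low", "high"), length.out = 6)
  expect_message(dr <- build_design(tab, "risk_group",
                                    covariates = c("age", "pmi")),
                 "lib_batch excluded")
  expect_false(any(grepl("lib_batch", colnames(dr$matrix))))

  tab2 <- tab
  tab2$pmi <- 2 * tab2$age + 1   # collinear after centering
  expect_error(build_design(tab2, "disease_status",
                            covariates = c("age", "pmi")),
               "collinear")
})
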