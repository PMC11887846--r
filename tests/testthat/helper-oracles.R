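# Independent reference implementations used as test oracles. These stay
# deliberately naive (closed forms, enumeration, brute force) and share no
# code with the package.

# closed-form OLS: beta = (X'X)^-1 X'y, SE from sigma^2 (X'X)^-1
ols_oracle <- function(x, y) {
  xtx_inv <- solve(t(x) %*% x)
  beta <- unname(drop(xtx_inv %*% t(x) %*% y))
  res <- y - drop(x %*% beta)
  df <- nrow(x) - ncol(x)
  sigma2 <- sum(res^2) / df
  se <- unname(sqrt(sigma2 * diag(xtx_inv)))
  list(beta = beta, se = se, t = beta / se,
       p = 2 * pt(-abs(beta / se), df))
}

# Poisson GLM via stats::glm (C-based IRLS, independent of the package NB
# engine)
poisson_oracle <- function(y, x, offset) {
  fit <- glm(y ~ x - 1 + offset(offset), family = poisson())
  s <- summary(fit)$coefficients
  list(beta = unname(coef(fit)), se = unname(s[, "Std. Error"]))
}

# literal BH definition: q_i = min over j with p_(j) >= p_(i)... computed as
# min_{j >= rank(i)} p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- sapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact upper-tail hypergeometric by direct summation of binomial products
hyper_enum <- function(k, K, N, n) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# two-sided signed-rank p by full enumeration over all sign assignments of
# the observed (average-tied) ranks; zeros dropped
wilcox_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# logistic MLE by plain Newton-Raphson
logistic_newton <- function(x, y, maxit = 50, tol = 1e-10) {
  beta <- rep(0, ncol(x))
  for (i in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    grad <- t(x) %*% (y - p)
    hess <- t(x) %*% (x * w)
    step <- solve(hess, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, fitted = plogis(drop(x %*% beta)))
}

# hand-rolled Matrix Market reader (text parsing only)
mtx_read_naive <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^%", lines)]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  m <- matrix(0, hdr[1], hdr[2])
  for (l in lines[-1]) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    m[v[1], v[2]] <- v[3]
  }
  m
}

# a small hand-built nucleus matrix fixture
tiny_nucleus_fixture <- function() {
  counts <- Matrix::Matrix(
    matrix(c(
      1, 2,
      3, 4,
      5, 6
    ), nrow = 3, byrow = TRUE),
    sparse = TRUE
  )
  meta <- tibble::tibble(
    nucleus_id = c("n1", "n2", "n3"),
    donor_id = c("d1", "d1", "d1"),
    cell_type = c("Exc", "Exc", "Ast")
  )
  nucleus_matrix(counts, meta, feature_ids = c("gA", "gB"))
}

# pseudobulk assay builder for fixtures
make_pb <- function(values, cell_type = "ct1", n_cells = NULL,
                    modality = "rna_counts", normalized = FALSE,
                    donor_ids = NULL) {
  values <- as.matrix(values)
  ns <- ncol(values)
  if (is.null(n_cells)) n_cells <- rep(1L, ns)
  if (is.null(donor_ids)) donor_ids <- sprintf("d%02d", seq_len(ns))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  cell_type <- rep_len(cell_type, ns)
  pseudobulk_assay(
    values,
    tibble::tibble(sample_id = paste(donor_ids, cell_type, sep = "."),
                   donor_id = donor_ids, cell_type = cell_type,
                   n_cells = n_cells),
    modality = modality, normalized = normalized
  )
}

# cohort-like sample table for design/differential fixtures
make_sample_table <- function(n, seed = 1, n_batches = 2) {
  set.seed(seed)
  tibble::tibble(
    donor_id = sprintf("d%02d", seq_len(n)),
    disease_status = rep(c("case", "control"), each = ceiling(n / 2))[1:n],
    sex = rep(c("F", "M"), length.out = n),
    age = rnorm(n, 54, 13),
    pH = rnorm(n, 6.6, 0.24),
    pmi = rnorm(n, 34, 14),
    rin = rnorm(n, 7, 1),
    lib_batch = paste0("b", rep(c(1, 2, 2, 1), length.out = n))
  )
}
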