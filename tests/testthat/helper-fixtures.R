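# Shared fixtures and independent oracles for the suite.

# small labeled expression matrix (genes x samples)
make_matrix <- function(m = 3L, n = 4L, seed = 42L) {
  set.seed(seed)
  mat <- matrix(round(abs(rnorm(m * n, 5, 2)), 3), m, n,
                dimnames = list(sprintf("g%d", seq_len(m)),
                                sprintf("s%d", seq_len(n))))
  mat
}

write_dense_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_map_tsv <- function(map, path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(names(map), unname(map)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  path
}

# a 2-stage set with n samples per stage over m genes
make_staged_set <- function(m = 5L, n = 5L, stages = c("d0", "d5"),
                            seed = 7L) {
  set.seed(seed)
  total <- n * length(stages)
  mat <- matrix(abs(rnorm(m * total, 5, 2)), m, total,
                dimnames = list(sprintf("g%d", seq_len(m)),
                                sprintf("s%d", seq_len(total))))
  map <- setNames(rep(stages, each = n), colnames(mat))
  build_staged_set(mat, map)
}

# quadrature oracle for the zero-truncated Gaussian CDF
quad_truncated_cdf <- function(mu, sigma, x) {
  stats::integrate(function(u) dnorm(u, mu, sigma), 0, x,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# 2-D quadrature oracle for the bivariate-normal rectangle probability
quad_joint_probability <- function(mu_i, mu_j, s_i, s_j, rho, gi, gj) {
  inner <- function(v) {
    vapply(v, function(vv) {
      stats::integrate(function(u) {
        z <- ((u - mu_i) / s_i)^2 -
          2 * rho * ((u - mu_i) / s_i) * ((vv - mu_j) / s_j) +
          ((vv - mu_j) / s_j)^2
        exp(-z / (2 * (1 - rho^2))) /
          (2 * pi * s_i * s_j * sqrt(1 - rho^2))
      }, 0, gi, rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1L))
  }
  stats::integrate(inner, 0, gj, rel.tol = 1e-9, abs.tol = 1e-11)$value
}

# quadrature oracle for the truncated differential entropy
quad_truncated_entropy <- function(mu, sigma) {
  stats::integrate(function(x) {
    f <- dnorm(x, mu, sigma)
    ifelse(f > 0, -f * log(f), 0)
  }, 0, mu, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Fixture with an engineered correlation jump: gene "dark" keeps a constant
# mean but becomes strongly coupled to two (differentially expressed) hub
# genes in the final stage, so only its score dynamics mark it.
make_dark_fixture <- function(n = 40L, seed = 5L) {
  set.seed(seed)
  stages <- c("S1", "S2", "S3")
  genes <- c("dark", "de8", "hub1", "hub2", sprintf("b%d", 1:6))
  cols <- sprintf("%s_%02d", rep(stages, each = n), rep(seq_len(n), 3))
  mat <- matrix(0, length(genes), 3 * n,
                dimnames = list(genes, cols))
  for (s in 1:3) {
    idx <- (s - 1) * n + seq_len(n)
    if (s < 3) {
      mat["dark", idx] <- rnorm(n, 5, 1)
      mat["hub1", idx] <- rnorm(n, 2, 1)
      mat["hub2", idx] <- rnorm(n, 2, 1)
      mat["de8", idx] <- rnorm(n, 1, 0.2)
    } else {
      L1 <- rnorm(n); L2 <- rnorm(n)
      mat["dark", idx] <- 5 + (L1 + L2) / sqrt(2)
      mat["hub1", idx] <- 10 + L1
      mat["hub2", idx] <- 8 + L2
      mat["de8", idx] <- rnorm(n, 8, 0.5)
    }
    for (b in sprintf("b%d", 1:6)) mat[b, idx] <- rnorm(n, 3, 1)
  }
  mat <- abs(mat)
  build_staged_set(mat, setNames(rep(stages, each = n), cols))
}

# score series + detection on a simulated sweep
run_sweep_pipeline <- function(sw, quantile = 0.9) {
  fit <- miwe(sw$set, quantile = quantile, run_gof = FALSE)
  list(fit = fit,
       detected_p = if (is.na(fit$detection$critical_stage)) NA_real_
       else unname(sw$p_values[fit$detection$critical_stage]))
}
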