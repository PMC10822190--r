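test_that("truncated differential entropy matches quadrature across scales", {
  expect_identical(
    truncated_differential_entropy(list(mu = 0, sigma = 1,
                                        mean_expression = 0)), 0)
  for (mu in c(0.5, 2, 5)) {
    for (sigma in c(0.05, 0.5, 1, 5)) {
      fit <- list(mu = mu, sigma = sigma, mean_expression = mu)
      expect_equal(truncated_differential_entropy(fit),
                   quad_truncated_entropy(mu, sigma), tolerance = 1e-8,
                   label = sprintf("DE(mu=%g, sigma=%g)", mu, sigma))
    }
  }
  # a tight density exceeds 1 over the range, so the entropy is negative
  expect_lt(truncated_differential_entropy(
    list(mu = 2, sigma = 0.05, mean_expression = 2)), 0)
})

test_that("local and global scores combine weights and entropies", {
  fits <- list(a = list(mu = 2, sigma = 1, mean_expression = 2),
               b = list(mu = 3, sigma = 0.5, mean_expression = 3))
  # isolated center
  expect_identical(local_weighted_entropy(
    list(center = "c", neighbors = character(0), weights = numeric(0)),
    fits), 0)
  # identity weight returns the neighbor's entropy
  one <- list(center = "c", neighbors = "a", weights = c(a = 1))
  expect_equal(local_weighted_entropy(one, fits),
               truncated_differential_entropy(fits$a))
  # hand arithmetic with synthetic entropies
  fake <- list(a = list(mu = 10, sigma = 1, mean_expression = 10),
               b = list(mu = 10, sigma = 1, mean_expression = 10))
  de <- truncated_differential_entropy(fake$a)
  two <- list(center = "c", neighbors = c("a", "b"),
              weights = c(a = 0.5, b = 2))
  expect_equal(local_weighted_entropy(two, fake), 2.5 * de)
  expect_error(local_weighted_entropy(
    list(center = "c", neighbors = "zz", weights = c(zz = 1)), fits),
    "missing")

  expect_equal(global_miwe(c(1, 2, 3)), 2)
  expect_equal(global_miwe(5), 5)
  expect_equal(global_miwe(rep(0, 4)), 0)
})

test_that("critical-stage detection flags a unique jump and ignores flat series", {
  s <- setNames(c(1, 1, 1, 5, 5), paste0("t", 1:5))
  det <- detect_critical_stage(s)
  expect_identical(det$critical_stage, "t4")
  expect_identical(det$index, 4L)

  flat <- setNames(rep(1, 3), paste0("t", 1:3))
  expect_true(is.na(detect_critical_stage(flat)$critical_stage))
  expect_error(detect_critical_stage(c(a = 1)), "2 stages")
  # diagnostics cover every transition even without a flag
  expect_identical(nrow(detect_critical_stage(flat)$diagnostics), 2L)
})

test_that("signaling-gene selection applies the ceiling and breaks ties lexicographically", {
  local100 <- setNames(seq_len(100) / 10, sprintf("g%03d", 1:100))
  sel <- select_signaling_genes(local100)
  expect_identical(length(sel), 5L)
  expect_setequal(sel, sprintf("g%03d", 96:100))

  local10 <- setNames(1:10, sprintf("g%02d", 1:10))
  expect_identical(length(select_signaling_genes(local10)), 1L)

  # tie spanning the cut: all equal scores -> lexicographically first
  tied <- setNames(rep(1, 10), sprintf("g%02d", 10:1))
  expect_identical(select_signaling_genes(tied), "g01")
})

test_that("stage scoring is invariant to sample and gene ordering", {
  set <- make_staged_set(m = 6L, n = 6L, seed = 19L)
  base <- score_all_stages(set, run_gof = FALSE)

  # permute samples within each stage
  perm <- set
  set.seed(1)
  for (st in set$stages) {
    own <- names(set$sample_stage)[set$sample_stage == st]
    shuffled <- sample(own)
    perm$values[, own] <- perm$values[, shuffled]
    colnames(perm$values)[match(own, colnames(perm$values))] <- shuffled
    perm$sample_stage <- perm$sample_stage[colnames(perm$values)]
  }
  perm2 <- build_staged_set(perm$values, perm$sample_stage)
  res_perm <- score_all_stages(perm2, run_gof = FALSE)
  for (i in seq_along(base)) {
    expect_equal(res_perm[[i]]$global, base[[i]]$global, tolerance = 1e-12)
    expect_equal(res_perm[[i]]$local[names(base[[i]]$local)],
                 base[[i]]$local, tolerance = 1e-12)
  }

  # permute gene order
  g_ord <- rev(set$genes)
  reord <- build_staged_set(set$values[g_ord, ], set$sample_stage)
  res_g <- score_all_stages(reord, run_gof = FALSE)
  for (i in seq_along(base)) {
    expect_equal(res_g[[i]]$global, base[[i]]$global, tolerance = 1e-12)
  }

  # determinism: identical inputs give identical output
  again <- score_all_stages(set, run_gof = FALSE)
  expect_identical(vapply(again, `[[`, numeric(1L), "global"),
                   vapply(base, `[[`, numeric(1L), "global"))
})

test_that("dark-gene screen finds the engineered non-DE gene and excludes the DE gene", {
  set <- make_dark_fixture()
  res <- score_all_stages(set, run_gof = FALSE)
  dark <- dark_gene_screen(set, res, critical_stage = "S3")
  expect_true("dark" %in% dark$gene)
  expect_false("de8" %in% dark$gene)
  expect_false("hub1" %in% dark$gene)
  expect_error(dark_gene_screen(set, res, NA_character_), "critical stage")
})

test_that("dark-gene screen returns nothing when nothing moves", {
  set.seed(9)
  stages <- rep(c("a", "b"), each = 5L)
  cols <- sprintf("s%02d", 1:10)
  mat <- matrix(abs(rnorm(60, 5, 1)), 6, 10,
                dimnames = list(sprintf("g%d", 1:6), cols))
  # same draws in both stages: identical expression and identical scores
  mat[, 6:10] <- mat[, 1:5]
  set <- build_staged_set(mat, setNames(stages, cols))
  res <- score_all_stages(set, run_gof = FALSE)
  out <- dark_gene_screen(set, res, critical_stage = "b")
  expect_identical(nrow(out), 0L)
})
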