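test_that("dense TSV round-trips bit-identically and CSV parses too", {
  mat <- make_matrix()
  path <- write_dense_tsv(mat)
  back <- read_expression(path, format = "dense_tsv")
  expect_identical(dimnames(back), dimnames(mat))
  expect_identical(back, mat)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(gene = rownames(mat), mat, check.names = FALSE),
            csv, quote = FALSE, row.names = FALSE)
  expect_identical(read_expression(csv), mat)
})

test_that("MTX triplet reads with sparse-zero semantics", {
  dir <- tempfile(); dir.create(dir)
  mat <- make_matrix(3L, 4L)
  mat[2L, 3L] <- 0  # omitted from the triplet file
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                  file.path(dir, "m.mtx"))
  writeLines(rownames(mat), file.path(dir, "genes.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  back <- read_expression(file.path(dir, "m.mtx"), format = "mtx_triplet")
  expect_equal(back, mat)
  expect_identical(back[2L, 3L], 0)
})

test_that("reader rejects bad cells, duplicates and negatives", {
  mat <- make_matrix()
  bad <- mat
  storage.mode(bad) <- "character"
  bad[2L, 2L] <- "NA"
  df <- data.frame(gene = rownames(bad), bad, check.names = FALSE)
  p <- tempfile(); write.table(df, p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
  expect_error(read_expression(p, format = "dense_tsv"), "g2.*s2")

  dup <- mat; rownames(dup) <- c("g1", "g1", "g3")
  expect_error(read_expression(write_dense_tsv(dup), format = "dense_tsv"),
               "duplicate")

  neg <- mat; neg[1L, 1L] <- -2
  pn <- write_dense_tsv(neg)
  expect_error(read_expression(pn, format = "dense_tsv"), "nonnegative")
  shifted <- read_expression(pn, format = "dense_tsv",
                             shift_to_zero = TRUE)
  expect_identical(min(shifted), 0)
})

test_that("stage map keeps first-appearance order and validates", {
  map <- c(s1 = "d0", s2 = "d0", s3 = "d5", s4 = "d5")
  sm <- read_stage_map(write_map_tsv(map))
  expect_identical(sm$stages, c("d0", "d5"))
  expect_identical(sm$sample_stage, map)

  # explicit order file wins
  ord <- tempfile(); writeLines(c("d5", "d0"), ord)
  expect_identical(read_stage_map(write_map_tsv(map), ord)$stages,
                   c("d5", "d0"))

  # conflicting duplicate is an error
  p <- tempfile()
  writeLines(c("s1\td0", "s1\td5"), p)
  expect_error(read_stage_map(p), "more than one stage")
})

test_that("staged set enforces its invariants", {
  mat <- make_matrix(4L, 10L)
  map <- setNames(rep(c("a", "b"), each = 5L), colnames(mat))
  set <- build_staged_set(mat, map)
  expect_identical(ncol(stage_view(set, "a")), 5L)

  # sample in map but not matrix
  expect_error(build_staged_set(mat[, 1:9], map), "absent from the matrix")
  # unmapped matrix sample
  expect_error(build_staged_set(mat, map[1:9]), "missing from the stage map")
  # stage with < 3 samples
  small <- setNames(c(rep("a", 8L), "b", "b"), colnames(mat))
  expect_error(build_staged_set(mat, small), "at least 3")
})

test_that("reference samples augment every stage view and leave others alone", {
  mat <- make_matrix(4L, 14L)
  map <- setNames(rep(c("I", "II"), each = 5L), colnames(mat)[1:10])
  ref <- colnames(mat)[11:14]
  plain <- build_staged_set(mat[, 1:10], map)
  with_ref <- build_staged_set(mat, map, reference_ids = ref)
  for (st in c("I", "II")) {
    v <- stage_view(with_ref, st)
    expect_identical(ncol(v), 9L)  # 5 own + 4 reference
    expect_identical(v[, 1:5], stage_view(plain, st))
    expect_identical(colnames(v)[6:9], ref)
  }
  # reference ids may not also be staged
  expect_error(build_staged_set(mat, map, reference_ids = colnames(mat)[1]),
               "stage map")
})

test_that("gene filtering removes degenerate genes and is idempotent", {
  set <- make_staged_set(m = 6L, n = 5L)
  set$values[1L, ] <- 3            # constant everywhere
  set$values[2L, ] <- 0            # all-zero
  set$values[2L, 1L] <- 0.5        # nonzero in 1/10 samples
  f1 <- suppressMessages(filter_genes(set, min_sd = 1e-8,
                                      min_nonzero_fraction = 0.2))
  expect_false("g1" %in% f1$genes)
  expect_false("g2" %in% f1$genes)
  expect_identical(length(f1$genes), 4L)
  f2 <- filter_genes(f1, min_sd = 1e-8, min_nonzero_fraction = 0.2)
  expect_identical(f2$values, f1$values)
  # no-op thresholds keep everything
  expect_identical(filter_genes(set, 0, 0)$values, set$values)
  # removing every gene is an error
  one <- make_staged_set(m = 2L, n = 4L)
  one$values[] <- 1
  expect_error(filter_genes(one, min_sd = 1e-8), "every gene")
})

test_that("write_staged_set round-trips through the readers", {
  set <- make_staged_set(m = 4L, n = 4L)
  mp <- tempfile(); sp <- tempfile()
  write_staged_set(set, mp, sp)
  back <- build_staged_set(read_expression(mp, format = "dense_tsv"),
                           read_stage_map(sp))
  expect_identical(back$values[, colnames(set$values)], set$values)
  expect_identical(back$stages, set$stages)
})
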