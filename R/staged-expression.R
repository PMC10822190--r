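#' Read an expression matrix
#'
#' Reads a genes x samples nonnegative expression matrix from a dense
#' TSV/CSV file (gene identifiers in the first column, sample identifiers in
#' the header row) or from a MatrixMarket triplet with `genes.tsv` /
#' `barcodes.tsv` sidecar files in the same directory.
#'
#' @param matrix_path path to the matrix file (`.mtx` for triplet format).
#' @param format one of `"dense_tsv"`, `"dense_csv"`, `"mtx_triplet"`.
#'   Defaults to a guess from the file extension.
#' @param shift_to_zero if `TRUE`, subtract the global minimum so the
#'   smallest value becomes 0. Off by default: negative input (e.g. already
#'   log-centred data) is rejected instead, because every downstream
#'   probability integrates from 0.
#' @return a numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(matrix_path,
                            format = c("auto", "dense_tsv", "dense_csv",
                                       "mtx_triplet"),
                            shift_to_zero = FALSE) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) {
    stop("expression matrix file not found: ", matrix_path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(matrix_path))
    format <- switch(ext,
                     mtx = "mtx_triplet",
                     csv = "dense_csv",
                     "dense_tsv")
  }
  if (format == "mtx_triplet") {
    mat <- .read_mtx_triplet(matrix_path)
  } else {
    sep <- if (format == "dense_csv") "," else "\t"
    mat <- .read_dense(matrix_path, sep)
  }
  .validate_expression(mat, shift_to_zero = shift_to_zero)
}

.read_dense <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("dense matrix needs a gene-ID column plus >= 1 sample column")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("unparseable or non-finite value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

.read_mtx_triplet <- function(mtx_path) {
  dir <- dirname(mtx_path)
  gene_file <- file.path(dir, "genes.tsv")
  sample_file <- file.path(dir, "barcodes.tsv")
  if (!file.exists(gene_file) || !file.exists(sample_file)) {
    stop("mtx_triplet format requires genes.tsv and barcodes.tsv next to ", mtx_path)
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- utils::read.table(gene_file, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  samples <- utils::read.table(sample_file, sep = "\t",
                               stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m) || length(samples) != ncol(m)) {
    stop("sidecar label counts do not match matrix dimensions")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  dimnames(m) <- list(genes, samples)
  m
}

.validate_expression <- function(mat, shift_to_zero = FALSE) {
  if (!all(is.finite(mat))) stop("expression matrix contains non-finite values")
  if (any(mat < 0)) {
    if (shift_to_zero) {
      mat <- mat - min(mat)
    } else {
      stop("negative expression values found; this method integrates ",
           "probabilities from 0, so input must be nonnegative ",
           "(use shift_to_zero = TRUE to subtract the global minimum)")
    }
  }
  mat
}

#' Read a sample-to-stage map
#'
#' Two-column TSV (sample, stage), no header by default. Stage order is
#' first-appearance order unless `order_path` gives an explicit one-per-line
#' stage ordering.
#'
#' @param map_path path to the two-column TSV.
#' @param order_path optional path to a file listing the stage labels, one
#'   per line, in chronological order.
#' @return list with `sample_stage` (named character vector, names are
#'   samples) and `stages` (ordered unique stage labels).
#' @export
read_stage_map <- function(map_path, order_path = NULL) {
  df <- utils::read.table(map_path, sep = "\t", header = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("stage map must have two columns: sample, stage")
  samples <- df[[1L]]
  stages <- df[[2L]]
  dup <- duplicated(samples)
  if (any(dup)) {
    conflicting <- vapply(unique(samples[dup]), function(s) {
      length(unique(stages[samples == s])) > 1L
    }, logical(1L))
    if (any(conflicting)) {
      stop("sample(s) mapped to more than one stage: ",
           paste(unique(samples[dup])[conflicting], collapse = ", "))
    }
    keep <- !dup
    samples <- samples[keep]
    stages <- stages[keep]
  }
  map <- stats::setNames(stages, samples)
  order <- unique(stages)
  if (!is.null(order_path)) {
    order <- readLines(order_path)
    order <- trimws(order[nzchar(trimws(order))])
    if (!setequal(order, unique(stages))) {
      stop("explicit stage order must list exactly the stages in the map")
    }
  }
  list(sample_stage = map, stages = order)
}

#' Assemble a staged expression set
#'
#' Bundles an expression matrix with its stage partition and an optional
#' reference-sample group. Reference samples (e.g. healthy controls in a
#' cancer staging analysis) are not assigned to any stage; instead they are
#' appended to every stage's sample set when stage views are taken, so that
#' entropy at each stage is computed against a common baseline.
#'
#' @param matrix numeric genes x samples matrix (rownames = genes,
#'   colnames = samples), values finite and nonnegative.
#' @param stage_map result of [read_stage_map()], or a named character
#'   vector sample -> stage (stage order = first appearance).
#' @param reference_ids optional character vector of matrix samples acting
#'   as the reference group; must not appear in the stage map.
#' @return an object of class `staged_expression_set`.
#' @export
build_staged_set <- function(matrix, stage_map, reference_ids = NULL) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) stop("gene identifiers must be unique")
  matrix <- .validate_expression(matrix)
  if (is.list(stage_map) && !is.null(stage_map$sample_stage)) {
    map <- stage_map$sample_stage
    stages <- stage_map$stages
  } else {
    map <- stage_map
    stages <- unique(unname(map))
  }
  missing_in_matrix <- setdiff(names(map), colnames(matrix))
  if (length(missing_in_matrix) > 0L) {
    stop("stage map lists samples absent from the matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  }
  reference_ids <- as.character(reference_ids %||% character(0L))
  if (length(reference_ids) > 0L) {
    if (!all(reference_ids %in% colnames(matrix))) {
      stop("reference samples absent from the matrix: ",
           paste(setdiff(reference_ids, colnames(matrix)), collapse = ", "))
    }
    clash <- intersect(reference_ids, names(map))
    if (length(clash) > 0L) {
      stop("reference samples may not also appear in the stage map: ",
           paste(clash, collapse = ", "))
    }
  }
  unmapped <- setdiff(colnames(matrix), c(names(map), reference_ids))
  if (length(unmapped) > 0L) {
    stop("matrix samples missing from the stage map: ",
         paste(unmapped, collapse = ", "))
  }
  n_ref <- length(reference_ids)
  for (st in stages) {
    n_st <- sum(map == st) + n_ref
    if (n_st < 3L) {
      stop(sprintf(
        "stage '%s' has %d samples (including reference); at least 3 are needed for correlation and SD",
        st, n_st))
    }
  }
  structure(list(values = matrix,
                 genes = rownames(matrix),
                 stages = stages,
                 sample_stage = map,
                 reference_samples = reference_ids),
            class = "staged_expression_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.staged_expression_set <- function(x, ...) {
  cat(sprintf("staged_expression_set: %d genes, %d samples, %d stages\n",
              length(x$genes), ncol(x$values), length(x$stages)))
  counts <- vapply(x$stages, function(s) sum(x$sample_stage == s), integer(1L))
  cat("  stages: ",
      paste(sprintf("%s (n=%d)", x$stages, counts), collapse = ", "), "\n",
      sep = "")
  if (length(x$reference_samples) > 0L) {
    cat(sprintf("  reference group: %d samples appended to every stage\n",
                length(x$reference_samples)))
  }
  invisible(x)
}

#' Extract one stage's sample slice
#'
#' Returns the genes x samples submatrix for a stage. Reference samples,
#' when present in the set, are appended after the stage's own samples.
#'
#' @param set a `staged_expression_set`.
#' @param stage one stage label.
#' @return numeric matrix (genes x n_T samples).
#' @export
stage_view <- function(set, stage) {
  stopifnot(inherits(set, "staged_expression_set"))
  if (!stage %in% set$stages) stop("unknown stage: ", stage)
  own <- names(set$sample_stage)[set$sample_stage == stage]
  set$values[, c(own, set$reference_samples), drop = FALSE]
}

#' Filter uninformative genes
#'
#' Removes genes whose within-stage standard deviation is below `min_sd` in
#' every stage, or whose overall nonzero fraction is below
#' `min_nonzero_fraction`. Zero-variance genes break the correlation and the
#' Gaussian model downstream, so the default `min_sd` removes exactly those.
#'
#' @param set a `staged_expression_set`.
#' @param min_sd minimum within-stage SD a gene must reach in at least one
#'   stage (default `1e-8`).
#' @param min_nonzero_fraction minimum fraction of samples in which a gene
#'   must be nonzero (default 0, off).
#' @param verbose log the removal count (default `TRUE`).
#' @return the filtered `staged_expression_set`.
#' @export
filter_genes <- function(set, min_sd = 1e-8, min_nonzero_fraction = 0,
                         verbose = TRUE) {
  stopifnot(inherits(set, "staged_expression_set"),
            min_sd >= 0, min_nonzero_fraction >= 0)
  sds <- sapply(set$stages, function(st) {
    apply(stage_view(set, st), 1L, stats::sd)
  })
  sds <- matrix(sds, nrow = length(set$genes))
  low_sd <- apply(sds, 1L, function(s) all(s < min_sd))
  nz_frac <- rowMeans(set$values != 0)
  sparse <- nz_frac < min_nonzero_fraction
  drop <- low_sd | sparse
  if (all(drop)) stop("gene filtering removed every gene; lower the thresholds")
  if (verbose && any(drop)) {
    message(sprintf("filter_genes: removed %d of %d genes (%d low-SD, %d sparse)",
                    sum(drop), length(drop), sum(low_sd), sum(sparse)))
  }
  set$values <- set$values[!drop, , drop = FALSE]
  set$genes <- rownames(set$values)
  set
}

#' Write stage views as a dense TSV plus stage map
#'
#' Inverse of [read_expression()] + [read_stage_map()]: writes the full
#' matrix (stage samples in stage order, then reference samples) and the
#' two-column stage map so the set round-trips losslessly.
#'
#' @param set a `staged_expression_set`.
#' @param matrix_path output TSV path.
#' @param map_path output stage-map TSV path.
#' @return invisibly, the paths written.
#' @export
write_staged_set <- function(set, matrix_path, map_path) {
  stopifnot(inherits(set, "staged_expression_set"))
  ord <- unlist(lapply(set$stages, function(st) {
    names(set$sample_stage)[set$sample_stage == st]
  }))
  ord <- c(ord, set$reference_samples)
  mat <- set$values[, ord, drop = FALSE]
  # full "%.17g" precision so the round trip through text is bit-exact
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  df <- data.frame(gene = rownames(mat), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage_of <- set$sample_stage[setdiff(ord, set$reference_samples)]
  utils::write.table(data.frame(names(stage_of), unname(stage_of)),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, map_path))
}
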