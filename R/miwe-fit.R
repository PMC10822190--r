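#' Fit the mutual-information-weighted entropy model
#'
#' The main entry point: scores every stage of a staged expression set,
#' detects the critical stage from the score series and selects the
#' signaling genes. The per-stage procedure is: (1) fit a Gaussian per
#' gene; (2) map expression values to zero-truncated cumulative
#' probabilities and build the mutual-information network over gene pairs;
#' (3) extract every gene's first-order neighborhood; (4) compute the
#' truncated differential entropy of each neighbor; (5) combine entropies
#' with MI edge weights into per-gene local scores whose mean is the
#' global stage score. A sharp increase of the global score flags the
#' critical stage.
#'
#' @param x a `staged_expression_set` (see [build_staged_set()]), or a
#'   genes x samples matrix if `stages` is given.
#' @param stages named character vector sample -> stage (or a
#'   [read_stage_map()] result); ignored when `x` is already staged.
#' @param reference optional reference sample ids (appended to every
#'   stage).
#' @param quantile MI-network retention quantile (default 0.9: top 10
#'   percent of edges by `|MI|`).
#' @param edge_list optional reference edge list fixing the network
#'   topology.
#' @param abs_weights use `|MI|` as edge weights (default `FALSE`).
#' @param min_fold,z_threshold critical-stage detection gates (see
#'   [detect_critical_stage()]).
#' @param signaling_fraction fraction of genes reported as signaling
#'   genes (default 0.05).
#' @param min_sd,min_nonzero_fraction gene prefilter thresholds (see
#'   [filter_genes()]).
#' @param gof_alpha significance level of the per-gene normality test.
#' @param drop_gof_failures drop genes failing the normality test.
#' @param run_gof run the normality test at all (default `TRUE`).
#' @param sigma_floor,prob_floor numerical floors.
#' @return an object of class `miwe` with components `series` (global
#'   score per stage), `local` (genes x stages matrix of local scores),
#'   `detection`, `signaling_genes`, `results` (per-stage detail), `set`,
#'   `settings`, `call`.
#' @examples
#' sw <- sweep_parameter(n = 20, seed = 1, grid = (-5:1) / 10)
#' fit <- miwe(sw$set)
#' print(fit)
#' @export
miwe <- function(x, stages = NULL, reference = NULL, quantile = 0.9,
                 edge_list = NULL, abs_weights = FALSE, min_fold = 1.5,
                 z_threshold = 2, signaling_fraction = 0.05,
                 min_sd = 1e-8, min_nonzero_fraction = 0,
                 gof_alpha = 0.05, drop_gof_failures = FALSE,
                 run_gof = TRUE, sigma_floor = 1e-8, prob_floor = 1e-12) {
  cl <- match.call()
  set <- if (inherits(x, "staged_expression_set")) {
    x
  } else {
    build_staged_set(as.matrix(x), stages, reference_ids = reference)
  }
  set <- filter_genes(set, min_sd = min_sd,
                      min_nonzero_fraction = min_nonzero_fraction,
                      verbose = FALSE)
  results <- score_all_stages(set, quantile = quantile,
                              edge_list = edge_list,
                              abs_weights = abs_weights,
                              sigma_floor = sigma_floor,
                              gof_alpha = gof_alpha,
                              prob_floor = prob_floor,
                              drop_gof_failures = drop_gof_failures,
                              run_gof = run_gof)
  stage_labels <- vapply(results, `[[`, character(1L), "stage")
  series <- stats::setNames(vapply(results, `[[`, numeric(1L), "global"),
                            stage_labels)
  genes <- names(results[[1L]]$local)
  local <- vapply(results, function(r) r$local[genes],
                  numeric(length(genes)))
  local <- matrix(local, nrow = length(genes),
                  dimnames = list(genes, stage_labels))
  detection <- detect_critical_stage(series, min_fold = min_fold,
                                     z_threshold = z_threshold)
  signaling <- if (!is.na(detection$critical_stage)) {
    select_signaling_genes(local[, detection$critical_stage],
                           fraction = signaling_fraction)
  } else {
    character(0L)
  }
  structure(list(series = series, local = local, detection = detection,
                 signaling_genes = signaling, results = results, set = set,
                 settings = list(quantile = quantile,
                                 abs_weights = abs_weights,
                                 min_fold = min_fold,
                                 z_threshold = z_threshold,
                                 signaling_fraction = signaling_fraction,
                                 gof_alpha = gof_alpha,
                                 sigma_floor = sigma_floor,
                                 prob_floor = prob_floor,
                                 edge_list_mode = !is.null(edge_list)),
                 call = cl),
            class = "miwe")
}

#' @export
print.miwe <- function(x, digits = 4L, ...) {
  cat("Mutual-information-weighted entropy fit\n\n")
  cat("Global score by stage:\n")
  print(round(x$series, digits))
  if (!is.na(x$detection$critical_stage)) {
    cat(sprintf("\nCritical stage: %s\n", x$detection$critical_stage))
    cat(sprintf("Signaling genes (top %g%%): %s\n",
                100 * x$settings$signaling_fraction,
                paste(x$signaling_genes, collapse = ", ")))
  } else {
    cat(sprintf("\nNo critical stage detected (largest increase at %s did not pass the gates)\n",
                x$detection$candidate))
  }
  invisible(x)
}

#' @export
summary.miwe <- function(object, ...) {
  gof <- vapply(object$results, function(r) {
    as.integer(r$gof_failures %||% NA_integer_)
  }, integer(1L))
  edges <- vapply(object$results, function(r) nrow(r$network$edges),
                  integer(1L))
  out <- list(series = object$series,
              detection = object$detection,
              signaling_genes = object$signaling_genes,
              n_genes = nrow(object$local),
              stage_table = data.frame(
                stage = names(object$series),
                miwe = unname(object$series),
                delta = c(NA, diff(object$series)),
                edges = edges,
                gof_failures = gof,
                stringsAsFactors = FALSE),
              settings = object$settings)
  class(out) <- "summary.miwe"
  out
}

#' @export
print.summary.miwe <- function(x, digits = 4L, ...) {
  cat(sprintf("MIWE fit over %d stages, %d genes\n\n",
              nrow(x$stage_table), x$n_genes))
  tab <- x$stage_table
  tab$miwe <- round(tab$miwe, digits)
  tab$delta <- round(tab$delta, digits)
  print(tab, row.names = FALSE)
  if (!is.na(x$detection$critical_stage)) {
    cat(sprintf("\nCritical stage: %s (fold gate %g, z gate %g)\n",
                x$detection$critical_stage, x$settings$min_fold,
                x$settings$z_threshold))
    cat("Signaling genes:", paste(x$signaling_genes, collapse = ", "), "\n")
  } else {
    cat("\nNo critical stage detected\n")
  }
  invisible(x)
}

#' @export
coef.miwe <- function(object, ...) {
  object$series
}

#' Plot the global score series
#'
#' @param x a `miwe` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.miwe <- function(x, ...) {
  n <- length(x$series)
  graphics::plot(seq_len(n), x$series, type = "b", xaxt = "n",
                 xlab = "stage", ylab = "global MIWE score", ...)
  graphics::axis(1L, at = seq_len(n), labels = names(x$series), las = 2L)
  if (!is.na(x$detection$index)) {
    graphics::abline(v = x$detection$index, lty = 2L, col = "red")
  }
  invisible(x)
}

#' Run the end-to-end pipeline and write its outputs
#'
#' Reads the inputs named in `config`, fits the model and writes the
#' standard output files: `miwe_scores.tsv` (stage, global score),
#' `local_scores.tsv` (genes x stages local-score landscape),
#' `signaling_genes.txt`, optionally `dark_genes.tsv`, `report.json`
#' (detection result, thresholds, provenance) and `config.yaml` (the
#' resolved configuration). On error, partial outputs are removed.
#'
#' @param config list with `matrix` (path), `stages` (path), optional
#'   `reference` (path, one id per line), `order` (stage-order path),
#'   `edge_list` (path), `out_dir`, plus any [miwe()] settings and the
#'   dark-gene thresholds `de_fdr`, `de_lfc`, `miwe_quantile`,
#'   `dark_genes` (logical).
#' @return the `miwe` fit, invisibly.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% "miwe_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0L)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    mat <- read_expression(config$matrix,
                           shift_to_zero = isTRUE(config$shift_to_zero))
    sm <- read_stage_map(config$stages, order_path = config$order)
    ref <- if (!is.null(config$reference)) {
      trimws(readLines(config$reference))
    } else NULL
    el <- if (!is.null(config$edge_list)) {
      utils::read.table(config$edge_list, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)
    } else NULL
    set <- build_staged_set(mat, sm, reference_ids = ref)
    fit <- miwe(set,
                quantile = config$quantile %||% 0.9,
                edge_list = el,
                abs_weights = isTRUE(config$abs_weights),
                min_fold = config$min_fold %||% 1.5,
                z_threshold = config$z_threshold %||% 2,
                signaling_fraction = config$signaling_fraction %||% 0.05,
                min_sd = config$min_sd %||% 1e-8,
                min_nonzero_fraction = config$min_nonzero_fraction %||% 0,
                gof_alpha = config$gof_alpha %||% 0.05,
                drop_gof_failures = isTRUE(config$drop_gof_failures))
    f <- function(name) {
      p <- file.path(out_dir, name)
      written <<- c(written, p)
      p
    }
    utils::write.table(
      data.frame(stage = names(fit$series), miwe = unname(fit$series)),
      f("miwe_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = rownames(fit$local), fit$local,
                 check.names = FALSE),
      f("local_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(fit$signaling_genes, f("signaling_genes.txt"))
    dark <- NULL
    if (isTRUE(config$dark_genes) && !is.na(fit$detection$critical_stage)) {
      dark <- dark_gene_screen(fit$set, fit$results,
                               fit$detection$critical_stage,
                               de_fdr = config$de_fdr %||% 0.05,
                               de_lfc = config$de_lfc %||% 0.5,
                               miwe_quantile = config$miwe_quantile %||% 0.9)
      utils::write.table(dark, f("dark_genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    gof <- vapply(fit$results, function(r) {
      as.integer(r$gof_failures %||% NA_integer_)
    }, integer(1L))
    report <- list(
      critical_stage = fit$detection$critical_stage,
      candidate_stage = fit$detection$candidate,
      series = as.list(fit$series),
      signaling_genes = fit$signaling_genes,
      n_genes = nrow(fit$local),
      gof_failures_per_stage = stats::setNames(as.list(gof),
                                               names(fit$series)),
      dark_genes = if (!is.null(dark)) dark$gene else NULL,
      settings = fit$settings)
    jsonlite::write_json(report, f("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    yaml::write_yaml(config, f("config.yaml"))
    invisible(fit)
  }, error = on_fail)
}
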