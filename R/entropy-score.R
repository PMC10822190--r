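#' Truncated differential entropy of a fitted Gaussian
#'
#' `DE = -integral_0^{g} f(x) ln f(x) dx` with `f` the gene's stage Gaussian
#' density and the upper limit `g` the stage mean. In standardized
#' coordinates `z = (x - mu)/sigma` the closed form is
#' `ln(sigma * sqrt(2*pi)) * (Phi(z_b) - Phi(z_a)) +
#'  1/2 * [Phi(z) - z*phi(z)]_{z_a}^{z_b}` with `z_a = -mu/sigma`,
#' `z_b = 0`. The value is negative when `sigma` is small enough that the
#' density exceeds 1 over the integration range.
#'
#' @param fit a fit from [fit_gene_gaussian()].
#' @return the (possibly negative) entropy contribution.
#' @export
truncated_differential_entropy <- function(fit) {
  g <- fit$mean_expression
  if (g < 0) stop("upper integration limit (stage mean) must be >= 0")
  if (g == 0) return(0)
  mu <- fit$mu
  sigma <- fit$sigma
  z_a <- -mu / sigma
  z_b <- (g - mu) / sigma  # equals 0 when the limit is the mean
  mass <- stats::pnorm(z_b) - stats::pnorm(z_a)
  second <- (stats::pnorm(z_b) - z_b * stats::dnorm(z_b)) -
    (stats::pnorm(z_a) - z_a * stats::dnorm(z_a))
  log(sigma * sqrt(2 * pi)) * mass + 0.5 * second
}

#' Local weighted entropy of one center gene
#'
#' Sum over the center's first-order neighbors of edge weight times the
#' neighbor's truncated differential entropy. An isolated center scores 0.
#'
#' @param local a local network from [extract_local_network()].
#' @param fits list of per-gene fits for the stage (named by gene); must
#'   cover every neighbor.
#' @return the local score.
#' @export
local_weighted_entropy <- function(local, fits) {
  if (length(local$neighbors) == 0L) return(0)
  missing <- setdiff(local$neighbors, names(fits))
  if (length(missing) > 0L) {
    stop("missing Gaussian fit for neighbor(s): ",
         paste(missing, collapse = ", "))
  }
  de <- vapply(local$neighbors,
               function(g) truncated_differential_entropy(fits[[g]]),
               numeric(1L))
  sum(local$weights * de)
}

#' Global stage score
#'
#' Arithmetic mean of the per-gene local scores of one stage.
#'
#' @param locals numeric vector of the m local scores.
#' @return the mean.
#' @export
global_miwe <- function(locals) {
  if (length(locals) < 1L) stop("need at least one local score")
  mean(locals)
}

#' Score every stage of a staged expression set
#'
#' For each stage in order: fit the per-gene Gaussians, build the
#' mutual-information network, extract every gene's local network and
#' compute the local and global weighted-entropy scores. Deterministic
#' given the input and settings.
#'
#' @param set a `staged_expression_set`.
#' @param quantile network retention quantile (default 0.9).
#' @param edge_list optional reference edge list (see
#'   [build_global_network()]).
#' @param abs_weights use absolute MI weights (default `FALSE`).
#' @param sigma_floor,gof_alpha,prob_floor numerical settings passed down.
#' @param drop_gof_failures drop genes failing the normality test in any
#'   stage before scoring (default `FALSE`; failures are counted either
#'   way).
#' @param run_gof run the goodness-of-fit test (default `TRUE`).
#' @return list of per-stage results, each with `stage`, `local` (named
#'   numeric, per center gene), `global`, `network`, `gof_failures`.
#' @export
score_all_stages <- function(set, quantile = 0.9, edge_list = NULL,
                             abs_weights = FALSE, sigma_floor = 1e-8,
                             gof_alpha = 0.05, prob_floor = 1e-12,
                             drop_gof_failures = FALSE, run_gof = TRUE) {
  stopifnot(inherits(set, "staged_expression_set"))
  if (drop_gof_failures && run_gof) {
    fail <- Reduce(`|`, lapply(set$stages, function(st) {
      v <- stage_view(set, st)
      vapply(rownames(v), function(g) {
        !goodness_of_fit(v[g, ], alpha = gof_alpha)$pass
      }, logical(1L))
    }))
    if (all(fail)) stop("every gene fails the goodness-of-fit test")
    set$values <- set$values[!fail, , drop = FALSE]
    set$genes <- rownames(set$values)
  }
  lapply(set$stages, function(st) {
    view <- stage_view(set, st)
    fits <- .fit_stage(view, sigma_floor = sigma_floor,
                       gof_alpha = gof_alpha, run_gof = run_gof)
    net <- build_global_network(view, fits, quantile = quantile,
                                edge_list = edge_list,
                                abs_weights = abs_weights,
                                prob_floor = prob_floor)
    locals <- vapply(set$genes, function(g) {
      local_weighted_entropy(extract_local_network(net, g), fits)
    }, numeric(1L))
    list(stage = st, local = locals, global = global_miwe(locals),
         network = net, gof_failures = attr(fits, "gof_failures"))
  })
}

#' Detect the critical stage from a score series
#'
#' The candidate is the stage with the largest forward increase
#' `Delta_T = MIWE_T - MIWE_{T-1}`. It is flagged as critical only if the
#' increase is sharp: either `MIWE_T >= min_fold * MIWE_{T-1}` (evaluated
#' when the previous score is positive) or the z-score of `Delta_T`
#' against all other transitions exceeds `z_threshold`. Because the
#' baseline SD is estimated from the other transitions, the gate is
#' calibrated on the t-scale: the score must exceed
#' `qt(pnorm(z_threshold), df)` with `df = (number of other transitions)
#' - 1`, which equals `z_threshold` for long series and guards short
#' series against the small-sample inflation of the z-score. Otherwise no
#' stage is flagged. The first stage can never be critical (its increase
#' is undefined).
#'
#' @param series numeric vector of global scores, named by stage label,
#'   in chronological order; length >= 2.
#' @param min_fold fold-change gate (default 1.5).
#' @param z_threshold z-score gate (default 2).
#' @return list with `critical_stage` (label or `NA`), `index` (or `NA`),
#'   and `diagnostics` (data.frame of per-transition increase and z-score).
#' @export
detect_critical_stage <- function(series, min_fold = 1.5, z_threshold = 2) {
  if (length(series) < 2L) stop("need scores for at least 2 stages")
  labels <- names(series) %||% as.character(seq_along(series))
  delta <- diff(series)
  cand <- unname(which.max(delta)) + 1L   # stage index of the largest jump
  d_star <- delta[cand - 1L]
  others <- delta[-(cand - 1L)]
  z <- if (length(others) >= 2L && stats::sd(others) > 0) {
    (d_star - mean(others)) / stats::sd(others)
  } else {
    NA_real_
  }
  prev <- series[cand - 1L]
  fold_ok <- is.finite(prev) && prev > 0 && series[cand] >= min_fold * prev
  z_crit <- if (length(others) >= 2L) {
    stats::qt(stats::pnorm(z_threshold), df = length(others) - 1L)
  } else {
    Inf
  }
  z_ok <- is.finite(z) && z > z_crit
  flagged <- d_star > 0 && (fold_ok || z_ok)
  diagnostics <- data.frame(
    from = labels[-length(labels)], to = labels[-1L],
    delta = unname(delta),
    z = vapply(seq_along(delta), function(i) {
      oth <- delta[-i]
      if (length(oth) >= 2L && stats::sd(oth) > 0) {
        (delta[i] - mean(oth)) / stats::sd(oth)
      } else NA_real_
    }, numeric(1L)),
    stringsAsFactors = FALSE)
  list(critical_stage = if (flagged) labels[cand] else NA_character_,
       index = if (flagged) cand else NA_integer_,
       candidate = labels[cand],
       diagnostics = diagnostics,
       thresholds = list(min_fold = min_fold, z_threshold = z_threshold))
}

#' Select signaling genes at the critical stage
#'
#' The `ceiling(fraction * m)` genes with the largest local scores at the
#' critical stage; ties at the cut are broken by lexicographic gene
#' identifier.
#'
#' @param local named numeric vector of local scores at the critical stage.
#' @param fraction fraction of genes to keep (default 0.05).
#' @return character vector of selected gene identifiers.
#' @export
select_signaling_genes <- function(local, fraction = 0.05) {
  m <- length(local)
  k <- ceiling(fraction * m)
  ord <- order(-local, names(local))
  names(local)[ord][seq_len(k)]
}

#' Screen for dark genes
#'
#' Dark genes show no differential expression between the first stage and
#' the critical stage yet large local-score dynamics across stages. A gene
#' qualifies when (a) its two-sided Wilcoxon rank-sum test (BH-adjusted
#' across genes) gives FDR >= `de_fdr` AND the absolute log2 fold change of
#' stage means (pseudocount 1) is below `de_lfc`, and (b) the range of its
#' local score across stages lies in the top `1 - miwe_quantile` fraction
#' of genes.
#'
#' @param set the scored `staged_expression_set`.
#' @param results output of [score_all_stages()].
#' @param critical_stage the detected critical stage label.
#' @param de_fdr FDR threshold below which a gene counts as differentially
#'   expressed (default 0.05).
#' @param de_lfc absolute log2-fold-change threshold (default 0.5).
#' @param miwe_quantile quantile of the local-score range a dark gene must
#'   exceed (default 0.9).
#' @return data.frame with gene, de_fdr, log2fc, miwe_range for the genes
#'   selected (possibly zero rows).
#' @export
dark_gene_screen <- function(set, results, critical_stage, de_fdr = 0.05,
                             de_lfc = 0.5, miwe_quantile = 0.9) {
  stopifnot(inherits(set, "staged_expression_set"))
  stages <- vapply(results, `[[`, character(1L), "stage")
  if (is.na(critical_stage) || !critical_stage %in% stages) {
    stop("dark-gene screen requires a detected critical stage")
  }
  first_v <- stage_view(set, stages[1L])
  crit_v <- stage_view(set, critical_stage)
  genes <- set$genes
  pvals <- vapply(genes, function(g) {
    suppressWarnings(
      stats::wilcox.test(first_v[g, ], crit_v[g, ], exact = FALSE)$p.value)
  }, numeric(1L))
  pvals[!is.finite(pvals)] <- 1
  fdr <- stats::p.adjust(pvals, method = "BH")
  lfc <- vapply(genes, function(g) {
    log2((mean(crit_v[g, ]) + 1) / (mean(first_v[g, ]) + 1))
  }, numeric(1L))
  local_mat <- vapply(results, function(r) r$local[genes],
                      numeric(length(genes)))
  local_mat <- matrix(local_mat, nrow = length(genes),
                      dimnames = list(genes, stages))
  rng <- apply(local_mat, 1L, function(x) diff(range(x)))
  cut <- stats::quantile(rng, miwe_quantile, names = FALSE)
  not_de <- fdr >= de_fdr & abs(lfc) < de_lfc
  sensitive <- rng >= cut & rng > 0
  sel <- not_de & sensitive
  data.frame(gene = genes[sel], de_fdr = fdr[sel], log2fc = lfc[sel],
             miwe_range = rng[sel], row.names = NULL,
             stringsAsFactors = FALSE)[order(-rng[sel]), , drop = FALSE]
}
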