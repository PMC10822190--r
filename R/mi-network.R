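#' Mutual-information edge weight of a gene pair
#'
#' The stage-level joint probability `Q` of the pair is combined with the
#' per-sample truncated marginal probabilities:
#' `MI = sum_r Q * ln( Q / (P_i(x_ir) * P_j(x_jr)) )`.
#' `Q` and each marginal product are floored at `prob_floor` inside the
#' logarithm, so the value is always finite. It can be negative (the
#' samplewise marginal product can exceed the stage-level `Q`); negative
#' weights are kept unless the caller takes absolute values.
#'
#' @param Q joint probability in `[0, 1]` (from [joint_probability()]).
#' @param P_i_vals,P_j_vals equal-length vectors of per-sample truncated
#'   cumulative probabilities (from [truncated_cdf()]).
#' @param prob_floor floor applied to `Q` and to each marginal product
#'   inside the log (default `1e-12`).
#' @return finite MI value.
#' @export
pair_mutual_information <- function(Q, P_i_vals, P_j_vals,
                                    prob_floor = 1e-12) {
  if (length(P_i_vals) != length(P_j_vals)) {
    stop("marginal probability vectors differ in length")
  }
  Qf <- max(Q, prob_floor)
  denom <- pmax(P_i_vals * P_j_vals, prob_floor)
  sum(Qf * log(Qf / denom))
}

#' Build the stage mutual-information network
#'
#' Computes the MI edge weight for every unordered gene pair of one stage
#' (or only the pairs of a user-supplied reference edge list), then
#' sparsifies: edges whose `|MI|` falls in the top `1 - quantile` fraction
#' are retained, and any node left isolated is rescued by keeping its single
#' largest-`|MI|` edge. With a reference edge list the list defines the
#' topology and MI provides the weights (no quantile filtering).
#'
#' @param view genes x samples stage matrix (from [stage_view()]).
#' @param fits per-gene fits for this stage (list named by gene).
#' @param quantile retention quantile `q` in `[0, 1)`; edges with `|MI|` at
#'   or above the `q`-quantile are kept (default 0.9, i.e. top 10 percent).
#' @param edge_list optional two-column character matrix/data.frame of gene
#'   pairs defining the topology.
#' @param abs_weights take absolute MI values as weights (default `FALSE`).
#' @param prob_floor probability floor passed to
#'   [pair_mutual_information()].
#' @return object of class `mi_network`: list with `nodes`, `edges`
#'   (data.frame gene_i, gene_j, weight) and a `retention` record.
#' @export
build_global_network <- function(view, fits, quantile = 0.9,
                                 edge_list = NULL, abs_weights = FALSE,
                                 prob_floor = 1e-12) {
  genes <- rownames(view)
  if (length(genes) < 2L) stop("need at least 2 genes to build a network")
  # per-sample truncated marginals, one row per gene
  P <- t(vapply(genes, function(g) truncated_cdf(fits[[g]], view[g, ]),
                numeric(ncol(view))))
  if (is.null(edge_list)) {
    pairs <- utils::combn(genes, 2L)
  } else {
    el <- as.matrix(edge_list)[, 1:2, drop = FALSE]
    keep <- el[, 1L] %in% genes & el[, 2L] %in% genes & el[, 1L] != el[, 2L]
    el <- el[keep, , drop = FALSE]
    if (nrow(el) == 0L) stop("reference edge list has no usable edges")
    # canonical order, drop duplicates
    el <- t(apply(el, 1L, sort))
    el <- el[!duplicated(el), , drop = FALSE]
    pairs <- t(el)
  }
  w <- numeric(ncol(pairs))
  for (e in seq_len(ncol(pairs))) {
    gi <- pairs[1L, e]; gj <- pairs[2L, e]
    rho <- pair_correlation(view[gi, ], view[gj, ])
    Q <- joint_probability(fits[[gi]], fits[[gj]], rho)
    w[e] <- pair_mutual_information(Q, P[gi, ], P[gj, ],
                                    prob_floor = prob_floor)
  }
  edges <- data.frame(gene_i = pairs[1L, ], gene_j = pairs[2L, ],
                      weight = w, stringsAsFactors = FALSE)
  if (is.null(edge_list)) {
    n_keep <- max(1L, ceiling((1 - quantile) * nrow(edges)))
    ord <- order(abs(edges$weight), decreasing = TRUE)
    keep <- rep(FALSE, nrow(edges))
    keep[ord[seq_len(n_keep)]] <- TRUE
    # rescue isolated nodes with their strongest edge
    for (g in genes) {
      touch <- which(edges$gene_i == g | edges$gene_j == g)
      if (!any(keep[touch])) {
        keep[touch[which.max(abs(edges$weight[touch]))]] <- TRUE
      }
    }
    edges <- edges[keep, , drop = FALSE]
    retention <- list(mode = "quantile", quantile = quantile)
  } else {
    retention <- list(mode = "edge_list", n_edges = nrow(edges))
  }
  if (nrow(edges) == 0L) stop("no edges retained; lower the retention quantile")
  if (abs_weights) edges$weight <- abs(edges$weight)
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, retention = retention),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d nodes, %d retained edges (%s mode)\n",
              length(x$nodes), nrow(x$edges), x$retention$mode))
  invisible(x)
}

#' Extract the local network of a center gene
#'
#' The local network is the center plus its first-order neighbors in the
#' retained stage network, with the global edge weights copied.
#'
#' @param network an `mi_network`.
#' @param center one node identifier.
#' @return list with `center`, `neighbors` (character, may be empty) and
#'   `weights` (named numeric, one per neighbor).
#' @export
extract_local_network <- function(network, center) {
  stopifnot(inherits(network, "mi_network"))
  if (!center %in% network$nodes) stop("unknown center gene: ", center)
  e <- network$edges
  at_i <- e$gene_i == center
  at_j <- e$gene_j == center
  neighbors <- c(e$gene_j[at_i], e$gene_i[at_j])
  weights <- stats::setNames(c(e$weight[at_i], e$weight[at_j]), neighbors)
  list(center = center, neighbors = neighbors, weights = weights)
}

#' Export a network as a weighted edge-list TSV
#'
#' @param network an `mi_network`.
#' @param path output path.
#' @param stage stage label recorded in the `stage` column.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path, stage = NA_character_) {
  df <- network$edges
  df$stage <- stage
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
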