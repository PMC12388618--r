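#' Filter OTUs by mean relative abundance
#'
#' Network construction uses only OTUs whose mean relative abundance across
#' the group's samples is strictly greater than the threshold (default 0.1%).
#'
#' @param table a [community_table()]; counts are converted to relative
#'   abundances for the filter, but the returned table keeps the input scale.
#' @param min_mean_relative_abundance strict lower threshold.
#' @return The filtered `community_table`.
#' @export
filter_abundant_otus <- function(table, min_mean_relative_abundance = 0.001) {
  table <- as_community_table(table)
  rel <- count_matrix(to_relative(table))
  keep <- colMeans(rel) > min_mean_relative_abundance
  if (!any(keep)) {
    stop_value("no OTU exceeds mean relative abundance %g", min_mean_relative_abundance)
  }
  m <- count_matrix(table)[, keep, drop = FALSE]
  community_table(if (is_relative(table)) m / rowSums(m) else m,
                  is_relative = is_relative(table))
}

#' Build a Spearman co-occurrence network
#'
#' All pairwise Spearman rank correlations among OTUs; p-values from the
#' t approximation (rank correlations use midranks, so ties are handled by
#' the statistic itself) or from the exact permutation distribution for small
#' sample counts; p-values adjusted across all tested pairs
#' (Benjamini-Hochberg by default). An edge is kept when `|rho| >=
#' rho_threshold` and adjusted p `< alpha`; isolated OTUs are not nodes.
#' Construction is deterministic.
#'
#' @param table a [community_table()] for one group of samples (typically one
#'   salinity level), already filtered with [filter_abundant_otus()].
#' @param rho_threshold minimum absolute Spearman correlation.
#' @param alpha significance level on adjusted p-values.
#' @param p_adjust method passed to [stats::p.adjust()].
#' @param min_samples minimum number of samples required.
#' @param p_method `"t_approx"` (default) or `"exact"` (feasible for
#'   < 10 samples, via [stats::cor.test()]).
#' @return Object of class `cooccurrence_network`: list with `graph` (an
#'   igraph object whose edges carry `rho`, `p_adjusted`, `sign`), `edges`
#'   (data.frame), `nodes`, and `params`.
#' @export
build_network <- function(table, rho_threshold = 0.6, alpha = 0.05,
                          p_adjust = "BH", min_samples = 5L,
                          p_method = c("t_approx", "exact")) {
  p_method <- match.arg(p_method)
  m <- count_matrix(as_community_table(table))
  n <- nrow(m)
  if (n < min_samples) stop_value("need at least %d samples, got %d", min_samples, n)
  if (ncol(m) < 3L) stop_value("need at least 3 OTUs to build a network")
  const <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning(sprintf("skipping constant (zero-variance) OTU(s): %s",
                    paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 3L) stop_value("fewer than 3 variable OTUs remain")
  }
  rho <- cor(m, method = "spearman")
  pr <- upper.tri(rho)
  r <- rho[pr]
  if (p_method == "t_approx") {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
  } else {
    ij <- which(pr, arr.ind = TRUE)
    p <- vapply(seq_len(nrow(ij)), function(k) {
      suppressWarnings(stats::cor.test(m[, ij[k, 1L]], m[, ij[k, 2L]],
                                       method = "spearman", exact = TRUE)$p.value)
    }, numeric(1))
  }
  p_adj <- p.adjust(p, method = p_adjust)
  ij <- which(pr, arr.ind = TRUE)
  keep <- abs(r) >= rho_threshold & p_adj < alpha
  edges <- data.frame(otu_a = colnames(m)[ij[keep, 1L]],
                      otu_b = colnames(m)[ij[keep, 2L]],
                      rho = r[keep], p_adjusted = p_adj[keep],
                      sign = ifelse(r[keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, edges = edges,
                 nodes = sort(unique(c(edges$otu_a, edges$otu_b))),
                 params = list(rho_threshold = rho_threshold, alpha = alpha,
                               p_adjust = p_adjust, p_method = p_method,
                               n_samples = n, n_otus_tested = ncol(m))),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%.0f%% positive); |rho| >= %g, %s p < %g\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) 100 * mean(x$edges$sign == "+") else NA_real_,
              x$params$rho_threshold, x$params$p_adjust, x$params$alpha))
  invisible(x)
}

#' Topological properties of a co-occurrence network
#'
#' @param net a [build_network()] result (or an igraph graph).
#' @return Named list: `n_nodes`, `n_edges`, `positive_edge_fraction`,
#'   `mean_degree`, `density`, `clustering_coefficient`, `modularity`
#'   (greedy community detection), `average_path_length` (largest component).
#' @export
topological_properties <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  pos <- if (ne > 0 && "sign" %in% igraph::edge_attr_names(g)) {
    mean(igraph::E(g)$sign == "+")
  } else NA_real_
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  list(n_nodes = nv,
       n_edges = ne,
       positive_edge_fraction = pos,
       mean_degree = if (nv > 0) 2 * ne / nv else NA_real_,
       density = igraph::edge_density(g),
       clustering_coefficient = igraph::transitivity(g, type = "global"),
       modularity = if (ne > 0) {
         igraph::modularity(igraph::cluster_fast_greedy(g))
       } else NA_real_,
       average_path_length = igraph::mean_distance(big, directed = FALSE))
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net a [build_network()] result.
#' @param edge_list_path,graphml_path output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, edge_list_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!is.null(edge_list_path)) {
    write.table(net$edges, edge_list_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(c(edge_list_path, graphml_path))
}
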