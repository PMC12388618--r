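#' Network robustness under node removal
#'
#' Removes a fraction of nodes and counts the proportion of the original
#' nodes that remain in the network, where a surviving node "remains" if it
#' retains at least one edge to another survivor. Random removal repeats
#' `n_repetitions` times (mean and sd reported); targeted removal deletes the
#' highest-degree nodes (ties broken by node id) and is deterministic, so it
#' collapses to a single repetition.
#'
#' @param net a [build_network()] result or igraph graph (>= 4 nodes).
#' @param removal_fraction fraction of nodes to remove, in (0, 1); the count
#'   removed is `floor(removal_fraction * n)`.
#' @param n_repetitions repetitions for random removal.
#' @param mode `"random"` or `"targeted_by_degree"`.
#' @param seed integer seed (random mode).
#' @return list: `robustness_mean`, `robustness_sd`, `removal_fraction`,
#'   `n_repetitions`, `mode`.
#' @export
robustness <- function(net, removal_fraction = 0.5, n_repetitions = 100L,
                       mode = c("random", "targeted_by_degree"), seed = NULL) {
  mode <- match.arg(mode)
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 4L) stop_value("robustness needs a network with at least 4 nodes")
  if (removal_fraction <= 0 || removal_fraction >= 1) {
    stop_value("removal_fraction must be in (0, 1)")
  }
  n_remove <- floor(removal_fraction * n)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- adj > 0
  remaining_frac <- function(keep_idx) {
    sub <- adj[keep_idx, keep_idx, drop = FALSE]
    sum(rowSums(sub) > 0) / n
  }
  if (mode == "targeted_by_degree") {
    deg <- igraph::degree(g)
    ord <- order(-deg, igraph::V(g)$name %||% seq_len(n))
    keep <- setdiff(seq_len(n), ord[seq_len(n_remove)])
    vals <- remaining_frac(keep)
    reps <- 1L
  } else {
    if (is.null(seed)) stop_value("`seed` is required for random removal")
    reps <- as.integer(n_repetitions)
    if (reps < 1L) stop_value("n_repetitions must be >= 1")
    vals <- with_seed(seed, {
      vapply(seq_len(reps), function(k) {
        remaining_frac(setdiff(seq_len(n), sample.int(n, n_remove)))
      }, numeric(1))
    })
  }
  list(robustness_mean = mean(vals),
       robustness_sd = if (reps > 1L) sd(vals) else 0,
       removal_fraction = removal_fraction,
       n_repetitions = reps,
       mode = mode)
}

# Global efficiency: mean over unordered node pairs of 1/shortest-path
# length, unweighted, 0 for disconnected pairs.
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  sp <- igraph::distances(g)
  inv <- 1 / sp[upper.tri(sp)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Network vulnerability via global efficiency
#'
#' Global efficiency \eqn{E} is the mean inverse shortest-path length over
#' all unordered node pairs (disconnected pairs contribute 0; paths are
#' unweighted). Each node's vulnerability is the relative efficiency drop
#' caused by deleting it, \eqn{V_i = (E - E_i)/E} with \eqn{E_i} computed
#' over the remaining nodes, and the network's vulnerability is
#' \eqn{\max_i V_i} (at most 1; negative values mean deleting the node
#' raises efficiency).
#'
#' @param net a [build_network()] result or igraph graph (>= 3 nodes).
#' @return The network vulnerability, with attribute `per_node` (named
#'   vector of \eqn{V_i}) and `efficiency` (\eqn{E}).
#' @export
vulnerability <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 3L) stop_value("vulnerability needs at least 3 nodes")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  E <- global_efficiency(adj)
  if (E == 0) stop_value("edgeless network has zero efficiency")
  v <- vapply(seq_len(n), function(i) {
    (E - global_efficiency(adj[-i, -i, drop = FALSE])) / E
  }, numeric(1))
  names(v) <- igraph::V(g)$name %||% as.character(seq_len(n))
  structure(max(v), per_node = v, efficiency = E)
}

#' Community cohesion and network complexity
#'
#' Cohesion summarises, per sample, how strongly the community's taxa
#' covary. Pairwise Pearson correlations between OTUs are corrected by a
#' taxa-shuffle null (each OTU's abundances independently permuted across
#' samples, `n_null` times; the null mean correlation is subtracted).
#' Each OTU's positive connectedness is the sum of its positive corrected
#' correlations divided by the number of other OTUs (negative connectedness
#' analogously), and a sample's positive (negative) cohesion is the
#' abundance-weighted sum of positive (negative) connectedness over its OTUs.
#' Complexity is `positive_cohesion + |negative_cohesion|`.
#'
#' @param table a [community_table()] (converted to relative abundances);
#'   at least 5 samples. Constant OTUs are dropped with a warning.
#' @param n_null number of taxa-shuffle null iterations.
#' @param seed integer seed.
#' @return Object of class `cohesion_result`: list with `samples`
#'   (data.frame: `sample_id`, `positive_cohesion`, `negative_cohesion`,
#'   `complexity`) and `otus` (data.frame: `otu_id`, `connectedness_pos`,
#'   `connectedness_neg`).
#' @export
cohesion <- function(table, n_null = 200L, seed) {
  rel <- count_matrix(to_relative(as_community_table(table)))
  if (nrow(rel) < 5L) stop_value("cohesion needs at least 5 samples")
  if (missing(seed)) stop_value("`seed` is required")
  const <- apply(rel, 2L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warning(sprintf("dropping constant OTU(s): %s",
                    paste(colnames(rel)[const], collapse = ", ")))
    rel <- rel[, !const, drop = FALSE]
  }
  S <- ncol(rel)
  if (S < 2L) stop_value("need at least 2 variable OTUs")
  obs <- cor(rel)
  null_mean <- with_seed(seed, {
    acc <- matrix(0, S, S)
    for (k in seq_len(n_null)) {
      perm <- apply(rel, 2L, sample)
      acc <- acc + cor(perm)
    }
    acc / n_null
  })
  corrected <- obs - null_mean
  diag(corrected) <- 0
  conn_pos <- colSums(pmax(corrected, 0)) / (S - 1)
  conn_neg <- colSums(pmin(corrected, 0)) / (S - 1)
  pos <- as.numeric(rel %*% conn_pos)
  neg <- as.numeric(rel %*% conn_neg)
  structure(list(
    samples = data.frame(sample_id = rownames(rel),
                         positive_cohesion = pos, negative_cohesion = neg,
                         complexity = pos + abs(neg),
                         row.names = NULL, stringsAsFactors = FALSE),
    otus = data.frame(otu_id = colnames(rel),
                      connectedness_pos = unname(conn_pos),
                      connectedness_neg = unname(conn_neg),
                      row.names = NULL, stringsAsFactors = FALSE),
    n_null = as.integer(n_null)
  ), class = "cohesion_result")
}

#' Per-salinity-level network stability report
#'
#' Convenience wrapper running the full network arm for one group of
#' samples: abundance filter, network construction, robustness (random
#' removal), vulnerability, cohesion and topological properties.
#'
#' @param table a [community_table()] restricted to one group's samples.
#' @param seed integer seed.
#' @param min_mean_relative_abundance,rho_threshold,alpha,removal_fraction,n_repetitions,n_null
#'   passed to the respective steps.
#' @return list: `network`, `robustness`, `vulnerability`, `cohesion`
#'   (summarised as mean positive/negative cohesion and complexity over
#'   samples plus the full `cohesion_result`), `topology`.
#' @export
network_stability_report <- function(table, seed,
                                     min_mean_relative_abundance = 0.001,
                                     rho_threshold = 0.6, alpha = 0.05,
                                     removal_fraction = 0.5,
                                     n_repetitions = 100L, n_null = 200L) {
  filt <- filter_abundant_otus(table, min_mean_relative_abundance)
  net <- build_network(filt, rho_threshold = rho_threshold, alpha = alpha)
  coh <- cohesion(filt, n_null = n_null, seed = seed + 1L)
  rob <- if (length(net$nodes) >= 4L) {
    robustness(net, removal_fraction = removal_fraction,
               n_repetitions = n_repetitions, seed = seed)
  } else NULL
  vul <- if (length(net$nodes) >= 3L) vulnerability(net) else NULL
  list(network = net,
       robustness = rob,
       vulnerability = if (!is.null(vul)) as.numeric(vul) else NA_real_,
       cohesion = list(positive = mean(coh$samples$positive_cohesion),
                       negative = mean(coh$samples$negative_cohesion),
                       complexity = mean(coh$samples$complexity),
                       detail = coh),
       topology = topological_properties(net))
}
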