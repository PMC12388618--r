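# Small in-code fixtures shared across tests.

toy_table <- function(m, samples = NULL, otus = NULL, relative = FALSE) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% rownames(m) %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- otus %||% colnames(m) %||% paste0("OTU_", seq_len(ncol(m)))
  community_table(m, is_relative = relative)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

balanced4_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# star phylogeny: every tip at distance `h` from the root (tip-tip = 2h)
star_tree <- function(n, h = 1) {
  ape::read.tree(text = paste0("(", paste0(sprintf("t%d:%g", seq_len(n), h),
                                           collapse = ","), ");"))
}

# random count table + random tree over the same OTUs
random_instance <- function(n_samples, n_otus, seed, depth = 100) {
  set.seed(seed)
  tr <- ape::rphylo(n_otus, 1, 0)
  tr$tip.label <- sprintf("OTU_%03d", seq_len(n_otus))
  m <- t(vapply(seq_len(n_samples), function(i) {
    rmultinom(1, depth, prob = rexp(n_otus))[, 1L]
  }, integer(n_otus)))
  rownames(m) <- paste0("S", seq_len(n_samples))
  colnames(m) <- tr$tip.label
  list(table = community_table(m), tree = tr,
       dist = ape::cophenetic.phylo(tr))
}

# Nested-loop betaMNTD oracle, independent of the package's kernel.
bmntd_oracle <- function(m, d, a, b, weighted = TRUE) {
  ia <- which(m[a, ] > 0); ib <- which(m[b, ] > 0)
  wa <- if (weighted) m[a, ia] / sum(m[a, ia]) else rep(1 / length(ia), length(ia))
  wb <- if (weighted) m[b, ib] / sum(m[b, ib]) else rep(1 / length(ib), length(ib))
  s1 <- 0
  for (k in seq_along(ia)) {
    best <- Inf
    for (l in seq_along(ib)) {
      v <- d[colnames(m)[ia[k]], colnames(m)[ib[l]]]
      if (v < best) best <- v
    }
    s1 <- s1 + wa[k] * best
  }
  s2 <- 0
  for (l in seq_along(ib)) {
    best <- Inf
    for (k in seq_along(ia)) {
      v <- d[colnames(m)[ib[l]], colnames(m)[ia[k]]]
      if (v < best) best <- v
    }
    s2 <- s2 + wb[l] * best
  }
  as.numeric(0.5 * (s1 + s2))
}

raw_counts <- function(tab) {
  x <- unclass(tab); attr(x, "is_relative") <- NULL; x
}

# igraph builders for closed-form stability checks
complete_graph <- function(n) igraph::make_full_graph(n)
path_graph <- function(n) igraph::make_ring(n, circular = FALSE)
star_graph <- function(n_leaves) igraph::make_star(n_leaves + 1, mode = "undirected")
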