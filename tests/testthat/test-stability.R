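test_that("robustness closed forms: complete graph and enumeration oracles", {
  # complete graph on 10 nodes, remove 5: every survivor keeps an edge
  r <- robustness(complete_graph(10), removal_fraction = 0.5,
                  n_repetitions = 50, seed = 1)
  expect_equal(r$robustness_mean, 0.5)
  expect_equal(r$robustness_sd, 0)

  # star on 11 nodes (hub + 10 leaves): exact expectation over all C(11,5)
  # removal sets vs simulation at large repetition count
  g <- star_graph(10)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  sets <- combn(11, 5)
  exact <- mean(apply(sets, 2, function(rm) {
    keep <- setdiff(1:11, rm)
    sub <- adj[keep, keep, drop = FALSE]
    sum(rowSums(sub) > 0) / 11
  }))
  sim <- robustness(g, removal_fraction = 0.5, n_repetitions = 4000, seed = 2)
  expect_lt(abs(sim$robustness_mean - exact), 0.01)

  # two disjoint edges, remove 2: enumeration over all 6 removal sets
  g2 <- igraph::graph_from_literal(a - b, c - d)
  adj2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE) > 0
  exact2 <- mean(apply(combn(4, 2), 2, function(rm) {
    keep <- setdiff(1:4, rm)
    sub <- adj2[keep, keep, drop = FALSE]
    sum(rowSums(sub) > 0) / 4
  }))
  sim2 <- robustness(g2, removal_fraction = 0.5, n_repetitions = 6000, seed = 3)
  expect_lt(abs(sim2$robustness_mean - exact2), 0.01)

  # mean bounded by 1 - removal_fraction; targeted mode is deterministic
  expect_lte(sim$robustness_mean, 0.5 + 1e-12)
  t1 <- robustness(g, mode = "targeted_by_degree")
  expect_equal(t1$n_repetitions, 1L)
  expect_equal(t1$robustness_mean, 0)  # removing the hub first strands leaves
  expect_error(robustness(g, removal_fraction = 1.2, seed = 1), "removal_fraction")
})

test_that("vulnerability matches hand-derived efficiencies", {
  # complete graph: deleting any node leaves a complete graph -> 0
  expect_equal(as.numeric(vulnerability(complete_graph(6))), 0)

  # path A-B-C: E = 5/6; deleting B -> 0, deleting an end raises E
  v <- vulnerability(path_graph(3))
  expect_equal(as.numeric(v), 1)
  expect_equal(attr(v, "efficiency"), 5 / 6)
  expect_equal(sort(unname(attr(v, "per_node"))), c(-0.2, -0.2, 1))

  # vertex-transitive graphs: all nodes share one vulnerability value
  ring <- igraph::make_ring(6)
  vr <- attr(vulnerability(ring), "per_node")
  expect_lt(diff(range(vr)), 1e-12)

  # oracle: independent all-pairs-shortest-path efficiency on a random graph
  set.seed(7)
  g <- igraph::sample_gnp(12, 0.3)
  while (min(igraph::degree(g)) == 0) g <- igraph::sample_gnp(12, 0.3)
  eff <- function(gr) {
    sp <- igraph::distances(gr)
    iv <- 1 / sp[upper.tri(sp)]
    mean(ifelse(is.finite(iv), iv, 0))
  }
  E <- eff(g)
  per <- vapply(1:12, function(i) (E - eff(igraph::delete_vertices(g, i))) / E,
                numeric(1))
  expect_equal(as.numeric(vulnerability(g)), max(per), tolerance = 1e-12)
  expect_lte(as.numeric(vulnerability(g)), 1)
})

test_that("cohesion: definitional complexity, sign structure, noise calibration", {
  # a perfectly positively correlated 8-OTU block, balanced by one
  # compensating OTU so rows still close to 1 (closure forbids *all* pairs
  # being positive); positive cohesion dominates, negative stays small
  n <- 80
  set.seed(99)
  u <- rep(c(-0.1, 0.1), length.out = n)
  w <- c(rep(0.08, 8), 0.05, rep(0.31 / 25, 25))
  a <- c(rep(0.5, 8), -6.4, rep(0, 25))  # balancer offsets the block exactly
  m <- t(vapply(seq_len(n), function(i) {
    x <- w * (1 + a * u[i])
    x[10:34] <- x[10:34] * exp(0.2 * rnorm(25))  # keep background variable
    x / sum(x)
  }, numeric(34)))
  tab <- toy_table(m, otus = paste0("o", 1:34), relative = TRUE)
  ch <- cohesion(tab, n_null = 100, seed = 2)
  expect_true(all(abs(ch$samples$negative_cohesion) < 0.1))
  expect_gt(mean(ch$samples$positive_cohesion),
            1.5 * mean(abs(ch$samples$negative_cohesion)))
  expect_gt(mean(ch$samples$positive_cohesion), 0.1)
  # complexity is definitional for every sample
  expect_equal(ch$samples$complexity,
               ch$samples$positive_cohesion + abs(ch$samples$negative_cohesion))
  expect_true(all(ch$otus$connectedness_pos <= 1 & ch$otus$connectedness_pos >= -1))

  # direct-loop oracle for the null-corrected connectedness
  rel <- raw_counts(to_relative(tab))
  obs <- cor(rel)
  set.seed(2)  # cohesion() seeds identically via with_seed
  acc <- matrix(0, 34, 34)
  for (k in 1:100) acc <- acc + cor(apply(rel, 2, sample))
  corrected <- obs - acc / 100; diag(corrected) <- 0
  expect_equal(ch$otus$connectedness_pos,
               unname(colSums(pmax(corrected, 0)) / 33), tolerance = 1e-12)

  # invariance to sample and OTU reordering (up to the Monte-Carlo error of
  # the finite taxa-shuffle null, whose draws attach to column positions)
  perm <- raw_counts(tab)[c(5, 1, 3, 2, 4, 6:80), c(9, 2, 34, 1, 3:8, 10:33)]
  ch2 <- cohesion(community_table(perm), n_null = 100, seed = 2)
  expect_equal(sort(ch2$otus$connectedness_pos), sort(ch$otus$connectedness_pos),
               tolerance = 0.05)

  # independent noise: both cohesions near zero
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    mm <- matrix(rpois(30 * 40, 30), 30, 40,
                 dimnames = list(paste0("S", 1:30), sprintf("o%02d", 1:40)))
    cc <- cohesion(community_table(mm), n_null = 60, seed = s)
    abs(mean(cc$samples$positive_cohesion)) < 0.1 &&
      abs(mean(cc$samples$negative_cohesion)) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  expect_error(cohesion(toy_table(matrix(1:8, 2)), seed = 1), "5 samples")
})
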