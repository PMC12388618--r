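test_that("simulated trees are valid, metric and reproducible", {
  t1 <- simulate_tree(3, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(t1$newick, f)
  d <- read_phylogeny(f, sprintf("OTU_%04d", 1:3))
  expect_equal(d, t1$distances[rownames(d), colnames(d)])

  t2 <- simulate_tree(40, seed = 9)
  expect_identical(t2$newick, simulate_tree(40, seed = 9)$newick)
  # triangle inequality on random triples
  set.seed(1)
  for (k in 1:100) {
    ijk <- sample(40, 3)
    expect_lte(t2$distances[ijk[1], ijk[2]],
               t2$distances[ijk[1], ijk[3]] + t2$distances[ijk[3], ijk[2]] + 1e-9)
  }
  expect_error(simulate_tree(2, seed = 1), ">= 3")
})

test_that("generators are seed-reproducible and pass table validation", {
  for (sc in c("neutral", "selection", "dispersal_limited",
               "planted_generalist", "mid_salinity_coupling")) {
    cfg <- scenario_config(sc, seed = 5, n_samples = 20, n_otus = 320,
                           reads_per_sample = 500)
    s1 <- simulate_scenario(cfg)
    s2 <- simulate_scenario(cfg)
    expect_identical(raw_counts(s1$table), raw_counts(s2$table))
    expect_s3_class(s1$table, "community_table")
    expect_identical(unname(rowSums(s1$table)), rep(500, 20))
    expect_identical(nrow(s1$metadata), 20L)
    expect_true(all(s1$metadata$salinity >= 0 & s1$metadata$salinity <= 11))
  }
  expect_error(scenario_config("neutral", seed = 1, m = 0), "migration")
  expect_error(scenario_config("neutral"), "seed")
})

test_that("neutral generator couples occupancy to metacommunity abundance", {
  sim <- simulate_scenario(scenario_config("neutral", seed = 3, n_otus = 300,
                                           n_samples = 40,
                                           reads_per_sample = 3000))
  occ <- colMeans(raw_counts(sim$table) > 0)
  expect_gt(cor(occ, sim$truth$metacommunity_p, method = "spearman"), 0.8)
})

test_that("selection generator plants phylogenetically conserved niches", {
  sim <- simulate_scenario(scenario_config("selection", seed = 2, n_otus = 150,
                                           n_samples = 30,
                                           reads_per_sample = 3000))
  # cross-extreme pairs show variable selection; same-end pairs do not
  sal <- setNames(sim$metadata$salinity, sim$metadata$sample_id)
  lo <- names(sort(sal))[1:4]
  hi <- names(sort(sal, decreasing = TRUE))[1:4]
  cross <- t(combn(c(lo[1:2], hi[1:2]), 2))
  cross <- cross[xor(cross[, 1] %in% lo, cross[, 2] %in% lo), , drop = FALSE]
  z_cross <- vapply(seq_len(nrow(cross)), function(k) {
    as.numeric(bnti(sim$table, sim$distances, cross[k, ], n_null = 199,
                    seed = 30 + k))
  }, numeric(1))
  expect_gte(mean(z_cross > 2), 0.7)
  z_same <- vapply(list(lo[1:2], lo[3:4], hi[1:2], hi[3:4]), function(pr) {
    as.numeric(bnti(sim$table, sim$distances, pr, n_null = 199, seed = 77))
  }, numeric(1))
  # pairs sharing a salinity end show far less phylogenetic turnover than
  # cross-extreme pairs
  expect_lt(median(z_same), median(z_cross))

  # the planted optima carry phylogenetic signal detectable by the correlogram
  opt <- setNames(sim$truth$optima, colnames(sim$table))
  mc <- phylo_mantel_correlogram(sim$distances, opt, n_classes = 5,
                                 n_permutations = 199, seed = 4)
  expect_gt(mc$mantel_r[1], 0)
  expect_lt(mc$p_corrected[1], 0.05)
})

test_that("dispersal generator yields disjoint sites without phylogenetic or
           niche structure", {
  sim <- simulate_scenario(scenario_config("dispersal_limited", seed = 4,
                                           pool_overlap = 0))
  meta <- sim$metadata
  site <- setNames(meta$site_id, meta$sample_id)
  prs <- t(combn(meta$sample_id, 2))
  between <- prs[site[prs[, 1]] != site[prs[, 2]], , drop = FALSE]
  set.seed(8)
  bsel <- between[sample(nrow(between), 12), , drop = FALSE]
  lab <- vapply(seq_len(nrow(bsel)), function(k) {
    z <- as.numeric(bnti(sim$table, sim$distances, bsel[k, ], n_null = 199,
                         seed = 200 + k))
    rc <- as.numeric(rc_bray(sim$table, bsel[k, ], n_null = 199, seed = 200 + k))
    if (is.nan(z)) NA_character_ else partition_processes(z, rc)
  }, character(1))
  expect_gte(mean(lab == "dispersal_limitation", na.rm = TRUE), 0.5)

  # pooled over sites no endemic OTU attains a generalist-scale niche: every
  # observed breadth stays near its site's sample count, far below the 33
  # samples a true generalist would approach. (The swap null can still flag
  # a minority of evenly-sampled endemics, a known property of
  # abundance-based margin-preserving nulls.)
  small <- simulate_scenario(scenario_config("dispersal_limited", seed = 4,
                                             n_samples = 33, n_otus = 150,
                                             reads_per_sample = 2000))
  cls <- suppressWarnings(
    classify_generalists_specialists(small$table, n_permutations = 150,
                                     seed = 5))
  expect_lt(max(cls$breadth_observed), 8)
  expect_lte(mean(cls$label == "generalist"), 0.2)
})

test_that("written simulations are readable by the io layer", {
  sim <- simulate_scenario(scenario_config("neutral", seed = 7, n_samples = 10,
                                           n_otus = 40, reads_per_sample = 200))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  tab <- read_community_table(file.path(dir, "otu_table.tsv"))
  expect_identical(raw_counts(tab), raw_counts(sim$table))
  d <- read_phylogeny(file.path(dir, "tree.nwk"), colnames(tab))
  expect_equal(d, sim$distances[colnames(tab), colnames(tab)], tolerance = 1e-8)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta$sample_id, sim$metadata$sample_id)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(sort(tax$otu_id), sort(colnames(tab)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$scenario, "neutral")
})
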