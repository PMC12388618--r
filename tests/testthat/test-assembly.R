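test_that("betaMNTD matches closed forms, the brute-force oracle and picante", {
  # identical communities share every OTU -> 0
  tr <- balanced4_tree()
  d <- read_phylogeny(tr, tr$tip.label)
  m <- toy_table(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)), otus = tr$tip.label)
  expect_equal(bmntd(m, d, c("S1", "S2")), 0)

  # star phylogeny, disjoint communities: every nearest distance = 2h
  st <- star_tree(6, h = 1.5)
  ds <- read_phylogeny(st, st$tip.label)
  ms <- toy_table(rbind(c(2, 1, 0, 0, 0, 0), c(0, 0, 5, 1, 1, 0)),
                  otus = st$tip.label)
  expect_equal(bmntd(ms, ds, c("S1", "S2")), 3)

  # worked 4-OTU instance: disjoint cherries, all cross distances 4
  m2 <- toy_table(rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)),
                  otus = tr$tip.label, relative = TRUE)
  expect_equal(bmntd(m2, d, c("S1", "S2")), 4)

  # random instances vs nested-loop oracle (and symmetry/non-negativity)
  for (s in 1:20) {
    inst <- random_instance(2, 6, seed = s, depth = 40)
    m <- raw_counts(inst$table)
    got <- bmntd(inst$table, inst$dist, c("S1", "S2"))
    expect_equal(got, bmntd_oracle(m, inst$dist, "S1", "S2"), tolerance = 1e-12)
    expect_equal(got, bmntd(inst$table, inst$dist, c("S2", "S1")))
    expect_gte(got, 0)
  }

  # independent cross-check against picante's implementation
  skip_if_not_installed("picante")
  inst <- random_instance(4, 10, seed = 42)
  pc <- as.matrix(picante::comdistnt(raw_counts(inst$table),
                                     inst$dist, abundance.weighted = TRUE))
  for (pr in list(c("S1", "S2"), c("S2", "S4"), c("S3", "S4"))) {
    expect_equal(bmntd(inst$table, inst$dist, pr), pc[pr[1], pr[2]],
                 tolerance = 1e-10)
  }
})

test_that("betaNTI sampled null agrees with the exhaustive permutation z-score", {
  tr <- balanced4_tree()
  d <- read_phylogeny(tr, tr$tip.label)
  m <- toy_table(rbind(c(3, 1, 0, 0), c(0, 0, 2, 2)), otus = tr$tip.label)

  z_ex <- bnti(m, d, c("S1", "S2"), exhaustive = TRUE)

  # oracle: enumerate the 24 tip relabelings by hand, nested-loop betaMNTD
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- as.matrix(perms[apply(perms, 1, function(x) length(unique(x)) == 4), ])
  nulls <- apply(perms, 1, function(p) {
    dp <- d[p, p]; dimnames(dp) <- dimnames(d)
    bmntd_oracle(raw_counts(m), dp, "S1", "S2")
  })
  z_oracle <- (attr(z_ex, "bmntd_obs") - mean(nulls)) / sd(nulls)
  expect_equal(as.numeric(z_ex), z_oracle, tolerance = 1e-12)

  # a large sampled null approximates the exhaustive z
  z_mc <- bnti(m, d, c("S1", "S2"), n_null = 999, seed = 5)
  expect_lt(abs(as.numeric(z_mc) - z_oracle), 0.35)

  # star phylogeny: all relabelings identical -> flagged NaN
  st <- star_tree(5)
  ds <- read_phylogeny(st, st$tip.label)
  ms <- toy_table(rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 0)), otus = st$tip.label)
  z0 <- bnti(ms, ds, c("S1", "S2"), n_null = 99, seed = 1)
  expect_true(is.nan(as.numeric(z0)))
  expect_match(attr(z0, "flag"), "zero-variance")
})

test_that("RC-Bray respects bounds, limits and the ties rule", {
  set.seed(10)
  m <- matrix(rpois(12 * 30, 40), 12, 30,
              dimnames = list(paste0("S", 1:12), sprintf("o%02d", 1:30)))
  m[2, ] <- m[1, ]  # identical abundant pair
  tab <- community_table(m)
  expect_lte(as.numeric(rc_bray(tab, c("S1", "S2"), n_null = 299, seed = 3)), -0.9)

  # bounds on assorted random pairs
  for (s in 1:10) {
    pr <- paste0("S", sample(12, 2))
    rc <- as.numeric(rc_bray(tab, pr, n_null = 99, seed = s))
    expect_gte(rc, -1); expect_lte(rc, 1)
  }

  # fully disjoint communities made of the pool's rarest OTUs
  m2 <- matrix(0, 22, 54, dimnames = list(paste0("S", 1:22), sprintf("o%02d", 1:54)))
  m2[1:20, 1:30] <- rpois(20 * 30, 25)
  m2[21, 31:42] <- rpois(12, 20) + 1
  m2[22, 43:54] <- rpois(12, 20) + 1
  expect_gte(as.numeric(rc_bray(community_table(m2), c("S21", "S22"),
                                n_null = 299, seed = 8)), 0.9)

  # degenerate single-OTU pool: every null equals the observed value
  m3 <- matrix(c(10, 10), 2, 1, dimnames = list(c("S1", "S2"), "only"))
  expect_equal(as.numeric(rc_bray(community_table(m3), c("S1", "S2"),
                                  n_null = 99, seed = 1)), 0)

  # order independence
  expect_equal(as.numeric(rc_bray(tab, c("S3", "S4"), n_null = 199, seed = 2)),
               as.numeric(rc_bray(tab, c("S4", "S3"), n_null = 199, seed = 2)))
})

test_that("process partition follows the betaNTI/RC thresholds strictly", {
  expect_identical(partition_processes(2.5, 0.1), "variable_selection")
  expect_identical(partition_processes(-1.0, 0.97), "dispersal_limitation")
  expect_identical(partition_processes(1.0, 0.5), "undominated")
  expect_identical(partition_processes(-2.5, 0.99), "homogeneous_selection")
  expect_identical(partition_processes(0, -0.97), "homogenizing_dispersal")
  # boundaries fall to the stochastic / undominated side
  expect_identical(partition_processes(c(2, -2), c(0, 0)),
                   c("undominated", "undominated"))
  expect_identical(partition_processes(c(0, 0), c(0.95, -0.95)),
                   c("undominated", "undominated"))
  expect_error(partition_processes(NaN, 0.5), "NaN")
})

test_that("assembly summaries count processes and flag exclusions", {
  pairs <- data.frame(process = c(rep("undominated", 7),
                                  rep("dispersal_limitation", 2),
                                  "variable_selection"))
  s <- summarize_assembly(pairs)
  expect_equal(s$stochastic_fraction, 0.9)
  expect_equal(sum(s$fractions), 1)
  expect_equal(s$n_pairs, 10L)

  s2 <- summarize_assembly(data.frame(process = rep("variable_selection", 4)))
  expect_equal(s2$stochastic_fraction, 0)

  s3 <- summarize_assembly(data.frame(process = c("undominated", NA)))
  expect_equal(s3$n_pairs, 1L); expect_equal(s3$n_excluded, 1L)
  expect_error(summarize_assembly(data.frame(process = character(0))), "no pairs")
})

test_that("assembly_pairs table is reproducible and group-annotated", {
  inst <- random_instance(6, 12, seed = 2, depth = 200)
  groups <- setNames(rep(c("lo", "hi"), each = 3), paste0("S", 1:6))
  a <- assembly_pairs(inst$table, inst$dist, n_null = 99, seed = 7, groups = groups)
  b <- assembly_pairs(inst$table, inst$dist, n_null = 99, seed = 7, groups = groups)
  expect_identical(a, b)
  expect_equal(nrow(a), choose(6, 2))
  expect_true(all(is.na(a$group) | a$group %in% c("lo", "hi")))
  within <- a[!is.na(a$group), ]
  expect_equal(nrow(within), 2 * choose(3, 2))
})

test_that("phylogenetic Mantel correlogram finds Brownian signal and stays
           quiet on permuted tips", {
  hits <- 0L
  for (s in 1:20) {
    tr <- simulate_tree(60, seed = s)
    set.seed(s)
    z <- ape::rTraitCont(tr$tree, sigma = 1)
    mc <- phylo_mantel_correlogram(tr$distances, z[tr$tree$tip.label],
                                   n_classes = 5, n_permutations = 199,
                                   seed = s + 50)
    hits <- hits + (mc$mantel_r[1] > 0 && mc$p_corrected[1] < 0.05)
  }
  expect_gte(hits, 16L)  # >= 80% recovery

  fp <- 0L
  for (s in 1:12) {
    tr <- simulate_tree(60, seed = s)
    set.seed(s + 99)
    z <- setNames(rnorm(60), sample(tr$tree$tip.label))
    mc <- phylo_mantel_correlogram(tr$distances, z, n_classes = 5,
                                   n_permutations = 199, seed = s + 70)
    fp <- fp + (mc$p_corrected[1] < 0.05)
  }
  expect_lte(fp, 2L)

  expect_error(phylo_mantel_correlogram(diag(0, 3), setNames(1:3, letters[1:3]),
                                        seed = 1), "10 OTUs")
})
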