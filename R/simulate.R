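#' Scenario configuration for the synthetic-data generator
#'
#' Bundles the design of a simulated study emulating an AM-fungal survey
#' along a salinity gradient: 54 samples in 11 sites, 428 OTUs in 12 genera,
#' 10,000 reads per sample, salinity spanning 0-11 mS/cm. Each scenario
#' plants a known community structure so pipeline inferences can be checked
#' against ground truth.
#'
#' @param scenario one of `"neutral"`, `"selection"`, `"dispersal_limited"`,
#'   `"planted_generalist"`, `"planted_specialist"`,
#'   `"mid_salinity_coupling"`.
#' @param seed integer seed (mandatory; every generator is bit-reproducible
#'   given the seed).
#' @param n_samples,n_sites,n_otus,n_genera,reads_per_sample study design.
#' @param salinity_range numeric length-2, mS/cm.
#' @param fisher_alpha Fisher's alpha of the log-series metacommunity
#'   rank-abundance distribution.
#' @param m neutral-scenario migration rate in (0, 1].
#' @param niche_sigma selection-scenario Gaussian niche breadth (mS/cm).
#' @param pool_overlap dispersal-scenario fraction of foreign OTUs admitted
#'   into each site's endemic pool.
#' @param planted_fraction per-sample relative abundance of the planted
#'   generalist/specialist OTU.
#' @param coupling per-salinity-bin strength of the shared latent factor in
#'   the `mid_salinity_coupling` scenario (length 5).
#' @param architecture per-bin mixing weight between clique-structured
#'   (0) and pair-structured (1) co-occurrence modules (length 5).
#' @param bin_edges salinity-level edges the coupling scenario plants its
#'   per-bin structure in; defaults to the analysis default
#'   [salinity_binning()] edges so planted structure and stratified analysis
#'   agree.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario, seed,
                            n_samples = 54L, n_sites = 11L, n_otus = 428L,
                            n_genera = 12L, reads_per_sample = 10000L,
                            salinity_range = c(0, 11),
                            fisher_alpha = 60,
                            m = 0.1,
                            niche_sigma = 1.5,
                            pool_overlap = 0.05,
                            planted_fraction = 0.05,
                            coupling = c(0, 0.25, 0.6, 0.25, 0),
                            architecture = c(0, 0.5, 1, 0.5, 0),
                            bin_edges = c(0, 1, 2, 4, 7, 11)) {
  scenario <- match.arg(scenario, c("neutral", "selection", "dispersal_limited",
                                    "planted_generalist", "planted_specialist",
                                    "mid_salinity_coupling"))
  if (missing(seed)) stop_value("`seed` is mandatory in a scenario_config")
  stopifnot(n_samples >= 2, n_sites >= 1, n_otus >= 3, reads_per_sample >= 1,
            diff(salinity_range) > 0)
  if (m <= 0 || m > 1) stop_value("migration rate m must be in (0, 1]")
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate a birth-death phylogeny over the OTU pool
#'
#' @param n_otus number of tips (>= 3).
#' @param seed integer seed.
#' @return list: `tree` (ape `phylo`, tips `OTU_0001`...), `newick` (string),
#'   `distances` (patristic matrix).
#' @export
simulate_tree <- function(n_otus, seed) {
  with_seed(seed, sim_tree_impl(n_otus))
}

sim_tree_impl <- function(n_otus) {
  if (n_otus < 3L) stop_value("n_otus must be >= 3")
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- sprintf("OTU_%04d", seq_len(n_otus))
  list(tree = tree,
       newick = ape::write.tree(tree),
       distances = ape::cophenetic.phylo(tree))
}

# Log-series metacommunity relative abundances: draw per-OTU abundances from
# the log-series distribution with x implied by Fisher's alpha and the
# metacommunity size alpha*(exp(S/alpha) - 1), via Kemp's inversion sampler.
rlogseries_relab <- function(n_otus, fisher_alpha) {
  N <- fisher_alpha * (exp(n_otus / fisher_alpha) - 1)
  x <- N / (N + fisher_alpha)
  v <- runif(n_otus); u <- runif(n_otus)
  counts <- floor(1 + log(v) / log(1 - (1 - x)^u))
  counts <- pmax(pmin(counts, 1e9), 1)
  counts / sum(counts)
}

# Samples in sites-as-blocks along the gradient: per-sample salinity, sites
# as contiguous blocks of the sorted gradient (sites have local salinity).
make_metadata <- function(n_samples, n_sites, salinity_range, stratified_bins = NULL) {
  if (is.null(stratified_bins)) {
    sal <- sort(runif(n_samples, salinity_range[1L], salinity_range[2L]))
  } else {
    # equal allocation over bins, uniform within each bin
    nb <- length(stratified_bins) - 1L
    per <- diff(round(seq(0, n_samples, length.out = nb + 1L)))
    sal <- sort(unlist(lapply(seq_len(nb), function(b) {
      runif(per[b], stratified_bins[b], stratified_bins[b + 1L])
    })))
  }
  site_of <- as.integer(cut(seq_len(n_samples), breaks = n_sites, labels = FALSE))
  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             site_id = sprintf("site_%02d", site_of),
             salinity = sal, stringsAsFactors = FALSE)
}

# Synthetic taxonomy: genera are clades cut from the tree, grouped into 4
# families and 3 orders.
make_taxonomy <- function(distances, n_genera) {
  hc <- stats::hclust(stats::as.dist(distances), method = "average")
  gen <- stats::cutree(hc, k = min(n_genera, nrow(distances)))
  fam <- (gen - 1L) %% 4L + 1L
  ord <- (gen - 1L) %% 3L + 1L
  data.frame(otu_id = names(gen),
             genus = sprintf("Genus_%02d", gen),
             family = sprintf("Family_%d", fam),
             order = sprintf("Order_%d", ord),
             stringsAsFactors = FALSE)
}

finish_sim <- function(config, counts, meta, treeinfo, truth) {
  rownames(counts) <- meta$sample_id
  colnames(counts) <- sprintf("OTU_%04d", seq_len(ncol(counts)))
  sim <- list(table = community_table(counts),
              metadata = meta,
              tree = treeinfo$tree %||% NULL,
              newick = treeinfo$newick %||% NULL,
              distances = treeinfo$distances %||% NULL,
              taxonomy = if (!is.null(treeinfo$distances)) {
                make_taxonomy(treeinfo$distances, config$n_genera)
              } else NULL,
              truth = truth,
              config = config)
  class(sim) <- "amf_simulation"
  sim
}

#' Simulate a scenario
#'
#' Dispatches on `config$scenario`; all randomness is governed by
#' `config$seed`, so a config fully reproduces its dataset.
#'
#' **neutral** — metacommunity relative abundances from a log-series; each
#' local community is a Dirichlet draw with concentrations
#' \eqn{N m p_i} (the stationary Sloan community distribution, giving each
#' OTU the Beta(\eqn{Nmp, Nm(1-p)}) marginal), multinomially sampled to the
#' read depth. Truth: `m`.
#'
#' **selection** — niche optima evolve on the simulated tree by Brownian
#' motion, rescaled to span the salinity range; expected abundance of OTU j
#' in sample i is its metacommunity weight times a Gaussian kernel of
#' `|salinity_i - optimum_j| / niche_sigma`. Phylogenetically conserved
#' optima make selection detectable as betaNTI > 2 between salinity
#' extremes. Truth: `optima`, `niche_sigma`.
#'
#' **dispersal_limited** — per-site endemic OTU pools with `pool_overlap`
#' admixture and site-specific lognormal abundance ranks; no
#' salinity-abundance coupling. Between-site pairs are taxonomically
#' disjoint (RC-Bray toward +1) without phylogenetic structure
#' (|betaNTI| < 2). Truth: `site_pools`.
#'
#' **planted_generalist / planted_specialist** — a background of
#' patchily-occupied OTUs plus one planted OTU holding `planted_fraction` of
#' each sample's reads: spread perfectly evenly over all samples
#' (generalist) or evenly over the samples of a single site (specialist).
#' Truth: `planted_otu`, `planted_label`.
#'
#' **mid_salinity_coupling** — five salinity bins with bin-specific
#' co-occurrence architecture: a shared latent factor of strength
#' `coupling[b]` (peaking mid-gradient, raising cohesion-based complexity)
#' and correlation modules that grade from one tight 6-OTU clique at the
#' gradient extremes (`architecture = 0`; robust) to independent
#' near-duplicate OTU pairs mid-gradient (`architecture = 1`; fragile
#' 2-node components). Truth: per-bin architecture and coupling.
#'
#' @param config a [scenario_config()].
#' @return list of class `amf_simulation`: `table`, `metadata`, `tree`,
#'   `newick`, `distances`, `taxonomy`, `truth`, `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    switch(config$scenario,
           neutral = sim_neutral(config),
           selection = sim_selection(config),
           dispersal_limited = sim_dispersal(config),
           planted_generalist = sim_planted(config, "generalist"),
           planted_specialist = sim_planted(config, "specialist"),
           mid_salinity_coupling = sim_network_scenario(config))
  })
}

sim_neutral <- function(config) {
  S <- config$n_otus
  p <- rlogseries_relab(S, config$fisher_alpha)
  meta <- make_metadata(config$n_samples, config$n_sites, config$salinity_range)
  conc <- config$reads_per_sample * config$m * p
  counts <- t(vapply(seq_len(config$n_samples), function(i) {
    g <- rgamma(S, shape = conc, rate = 1)
    if (sum(g) == 0) g[which.max(p)] <- 1
    rmultinom(1, config$reads_per_sample, prob = g / sum(g))[, 1L]
  }, integer(S)))
  treeinfo <- sim_tree_impl(S)
  finish_sim(config, counts, meta, treeinfo,
             truth = list(scenario = "neutral", m = config$m,
                          metacommunity_p = p))
}

sim_selection <- function(config) {
  S <- config$n_otus
  treeinfo <- sim_tree_impl(S)
  z <- ape::rTraitCont(treeinfo$tree, model = "BM", sigma = 1)
  rng <- config$salinity_range
  opt <- (z - min(z)) / (max(z) - min(z)) * diff(rng) + rng[1L]
  opt <- opt[treeinfo$tree$tip.label]
  base <- rlogseries_relab(S, config$fisher_alpha)
  meta <- make_metadata(config$n_samples, config$n_sites, rng)
  counts <- t(vapply(seq_len(config$n_samples), function(i) {
    w <- base * exp(-((meta$salinity[i] - opt)^2) / (2 * config$niche_sigma^2))
    if (sum(w) == 0) w <- base
    rmultinom(1, config$reads_per_sample, prob = w / sum(w))[, 1L]
  }, integer(S)))
  finish_sim(config, counts, meta, treeinfo,
             truth = list(scenario = "selection", optima = unname(opt),
                          niche_sigma = config$niche_sigma))
}

sim_dispersal <- function(config) {
  S <- config$n_otus
  meta <- make_metadata(config$n_samples, config$n_sites, config$salinity_range)
  # salinity decoupled from sites: shuffle it across samples
  meta$salinity <- sample(meta$salinity)
  home <- sample(rep_len(seq_len(config$n_sites), S))
  pools <- lapply(seq_len(config$n_sites), function(s) {
    own <- which(home == s)
    foreign <- which(home != s)
    extra <- sample(foreign, size = max(0L, round(config$pool_overlap * length(own))))
    sort(c(own, extra))
  })
  # site-specific abundance ranks over its pool, with per-sample lognormal
  # heterogeneity so within-site communities are similar but not identical
  site_w <- lapply(pools, function(pl) {
    w <- numeric(S)
    w[pl] <- rlnorm(length(pl), meanlog = 0, sdlog = 1.5)
    w / sum(w)
  })
  site_idx <- as.integer(factor(meta$site_id, levels = unique(meta$site_id)))
  counts <- t(vapply(seq_len(config$n_samples), function(i) {
    w <- site_w[[site_idx[i]]] * exp(rnorm(S, 0, 1))
    rmultinom(1, config$reads_per_sample, prob = w / sum(w))[, 1L]
  }, integer(S)))
  treeinfo <- sim_tree_impl(S)
  finish_sim(config, counts, meta, treeinfo,
             truth = list(scenario = "dispersal_limited", site_pools = pools))
}

sim_planted <- function(config, label) {
  S <- config$n_otus
  n <- config$n_samples
  reads <- config$reads_per_sample
  meta <- make_metadata(n, config$n_sites, config$salinity_range)
  planted <- 1L
  planted_reads <- round(config$planted_fraction * reads)
  # background: patchy occupancy, each OTU present in 20-60% of samples
  # (uneven enough to contrast with the planted profiles)
  bg <- matrix(0, n, S)
  occ_range <- max(3L, round(0.2 * n)):max(4L, round(0.6 * n))
  for (j in 2:S) {
    occ <- sample(n, size = sample(occ_range, 1L))
    bg[occ, j] <- rlnorm(length(occ), 0, 1)
  }
  counts <- matrix(0L, n, S)
  if (label == "generalist") {
    counts[, planted] <- planted_reads          # perfectly even occupancy
    host_rows <- seq_len(n)
  } else {
    host_rows <- which(meta$site_id == meta$site_id[1L])
    counts[host_rows, planted] <- round(planted_reads * n / length(host_rows))
  }
  for (i in seq_len(n)) {
    left <- reads - counts[i, planted]
    w <- bg[i, ]
    if (sum(w) == 0) w[sample(2:S, 1L)] <- 1
    counts[i, -planted] <- rmultinom(1, left, prob = w[-planted] / sum(w[-planted]))[, 1L]
  }
  treeinfo <- sim_tree_impl(S)
  finish_sim(config, counts, meta, treeinfo,
             truth = list(scenario = paste0("planted_", label),
                          planted_otu = "OTU_0001", planted_label = label))
}

sim_network_scenario <- function(config) {
  S <- config$n_otus
  reads <- config$reads_per_sample
  edges <- config$bin_edges
  if (length(edges) != 6L) stop_value("the coupling scenario needs 5 salinity bins")
  meta <- make_metadata(config$n_samples, config$n_sites, config$salinity_range,
                        stratified_bins = edges)
  bin_of <- findInterval(meta$salinity, edges, rightmost.closed = TRUE)
  n_active <- 60L
  if (S < 5L * n_active + 10L) stop_value("n_otus too small for the coupling scenario")
  active_sets <- lapply(1:5, function(b) ((b - 1L) * n_active + 1L):(b * n_active))
  background <- (5L * n_active + 1L):S
  mu <- rnorm(S, 0, 0.5)  # per-OTU baseline log-abundance
  sigma_z <- 1.2
  clique_l <- 0.997   # within-clique loading (rho ~ l^2)
  pair_l <- 0.999     # within-pair loading
  # extra log-abundance for module members: enough reads that rank
  # correlations survive multinomial noise; the clique gets less so it does
  # not dominate its bin's abundance-weighted cohesion
  pair_boost <- 1.5
  clique_boost <- 0.8
  counts <- matrix(0L, config$n_samples, S)
  modules <- vector("list", 5L)
  for (b in 1:5) {
    rows <- which(bin_of == b)
    act <- active_sets[[b]]
    arch <- config$architecture[b]
    coup <- config$coupling[b]
    # module layout: one 6-OTU clique unless fully pair-structured; pairs
    # fill `arch` of the remaining actives; the rest are singletons
    members <- act
    mods <- list()
    if (arch < 1) {
      mods$clique <- members[1:6]
      members <- members[-(1:6)]
    }
    n_pairs <- floor(arch * length(members) / 2)
    if (n_pairs > 0) {
      mods$pairs <- matrix(members[seq_len(2 * n_pairs)], ncol = 2L, byrow = TRUE)
      members <- members[-seq_len(2 * n_pairs)]
    }
    mods$singletons <- members
    modules[[b]] <- mods
    mu_b <- mu
    if (!is.null(mods$clique)) mu_b[mods$clique] <- mu_b[mods$clique] + clique_boost
    if (!is.null(mods$pairs)) {
      mu_b[as.vector(mods$pairs)] <- mu_b[as.vector(mods$pairs)] + pair_boost
    }
    responders <- act[seq_len(n_active %/% 2L)]  # latent factor loads on half
    for (i in rows) {
      z <- rnorm(S)  # idiosyncratic
      if (!is.null(mods$clique)) {
        g <- rnorm(1)
        z[mods$clique] <- clique_l * g + sqrt(1 - clique_l^2) * rnorm(6)
      }
      if (!is.null(mods$pairs)) {
        for (k in seq_len(nrow(mods$pairs))) {
          g <- rnorm(1)
          z[mods$pairs[k, ]] <- pair_l * g + sqrt(1 - pair_l^2) * rnorm(2)
        }
      }
      if (coup > 0) {
        f <- rnorm(1)
        z[responders] <- sqrt(coup) * f + sqrt(1 - coup) * z[responders]
      }
      w <- numeric(S)
      w[act] <- exp(mu_b[act] + sigma_z * z[act])
      w[act] <- 0.95 * w[act] / sum(w[act])
      w[background] <- exp(mu_b[background] + 0.3 * z[background])
      w[background] <- 0.05 * w[background] / sum(w[background])
      counts[i, ] <- rmultinom(1, reads, prob = w)[, 1L]
    }
  }
  treeinfo <- sim_tree_impl(S)
  finish_sim(config, counts, meta, treeinfo,
             truth = list(scenario = "mid_salinity_coupling",
                          bin_edges = edges, bin_of = bin_of,
                          coupling = config$coupling,
                          architecture = config$architecture,
                          modules = modules))
}

#' Write a simulated dataset to a directory
#'
#' Writes `otu_table.tsv`, `tree.nwk`, `taxonomy.tsv`, `metadata.tsv` and
#' `truth.json` (ground-truth parameters; matrices and trees omitted).
#'
#' @param sim an `amf_simulation` from [simulate_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "amf_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_community_table(sim$table, file.path(dir, "otu_table.tsv"))
  if (!is.null(sim$newick)) writeLines(sim$newick, file.path(dir, "tree.nwk"))
  if (!is.null(sim$taxonomy)) {
    write.table(sim$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth <- truth[!vapply(truth, function(x) is.matrix(x) || is.list(x), logical(1))]
  truth$seed <- sim$config$seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
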