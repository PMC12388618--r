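#' Between-community mean nearest taxon distance
#'
#' \eqn{\beta}MNTD between two samples is the abundance-weighted mean
#' phylogenetic distance from each OTU present in one sample to its nearest
#' relative present in the other:
#' \deqn{\beta MNTD = 0.5 \left[\sum_{i \in A} f_{iA} \min_{j \in B} d_{ij} +
#'   \sum_{j \in B} f_{jB} \min_{i \in A} d_{ij}\right]}
#' where \eqn{f} are within-sample relative abundances over present OTUs.
#' A shared OTU contributes 0 through \eqn{d_{ii} = 0}.
#'
#' @param table a [community_table()] or samples x OTUs matrix.
#' @param dist patristic distance matrix covering the table's OTUs
#'   (see [read_phylogeny()]).
#' @param pair character vector of two sample ids.
#' @param abundance_weighted if `FALSE`, presence/absence weights
#'   (each present OTU weighted 1/richness).
#' @return A single non-negative distance.
#' @export
bmntd <- function(table, dist, pair, abundance_weighted = TRUE) {
  m <- count_matrix(as_community_table(table))
  d <- match_distances(m, dist)
  pr <- pair_rows(m, pair)
  pw <- pair_weights(m, pr[1L], pr[2L], abundance_weighted)
  cpp_bmntd(d, pw$idxA - 1L, pw$wA, pw$idxB - 1L, pw$wB)
}

match_distances <- function(m, dist) {
  miss <- setdiff(colnames(m), rownames(dist))
  if (length(miss)) {
    stop_value("distance matrix missing OTU(s): %s", paste(miss, collapse = ", "))
  }
  d <- dist[colnames(m), colnames(m), drop = FALSE]
  validate_distance_matrix(d)
  d
}

pair_rows <- function(m, pair) {
  if (length(pair) != 2L) stop_value("`pair` must name exactly two samples")
  r <- match(pair, rownames(m))
  if (anyNA(r)) stop_value("unknown sample(s): %s", paste(pair[is.na(r)], collapse = ", "))
  r
}

pair_weights <- function(m, ra, rb, abundance_weighted) {
  idxA <- which(m[ra, ] > 0)
  idxB <- which(m[rb, ] > 0)
  if (!length(idxA) || !length(idxB)) {
    stop_value("empty sample in pair (%s, %s)", rownames(m)[ra], rownames(m)[rb])
  }
  if (abundance_weighted) {
    wA <- m[ra, idxA] / sum(m[ra, idxA])
    wB <- m[rb, idxB] / sum(m[rb, idxB])
  } else {
    wA <- rep(1 / length(idxA), length(idxA))
    wB <- rep(1 / length(idxB), length(idxB))
  }
  list(idxA = unname(idxA), wA = unname(wA), idxB = unname(idxB), wB = unname(wB))
}

# All permutations of 1..n as an n! x n matrix (exhaustive betaNTI nulls).
all_permutations <- function(n) {
  if (n > 8L) stop_value("exhaustive enumeration limited to 8 OTUs (%d requested)", n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Beta nearest taxon index for one sample pair
#'
#' z-score of the observed [bmntd()] against a null built by shuffling tip
#' identities on the distance matrix across the whole OTU pool of the table
#' ("taxa labels" randomization), with abundances held fixed:
#' \eqn{\beta NTI = (\beta MNTD_{obs} - \mu_{null}) / \sigma_{null}}.
#' \eqn{|\beta NTI| > 2} indicates deterministic selection (variable if
#' > 2, homogeneous if < -2).
#'
#' @inheritParams bmntd
#' @param n_null number of tip-shuffle null draws (>= 99).
#' @param seed integer seed (required unless `exhaustive`).
#' @param exhaustive if `TRUE`, the null is the complete set of tip-label
#'   permutations (only feasible for <= 8 OTUs); `n_null` and `seed` are then
#'   ignored.
#' @return The z-score, with attributes `bmntd_obs`, `null_mean`, `null_sd`.
#'   If the null has zero spread (e.g. a star phylogeny) the value is `NaN`
#'   and attribute `flag` gives the reason; such pairs are excluded from
#'   partition counts downstream.
#' @export
bnti <- function(table, dist, pair, n_null = 999L, seed,
                 abundance_weighted = TRUE, exhaustive = FALSE) {
  m <- count_matrix(as_community_table(table))
  d <- match_distances(m, dist)
  pr <- pair_rows(m, pair)
  pw <- pair_weights(m, pr[1L], pr[2L], abundance_weighted)
  if (length(union(pw$idxA, pw$idxB)) < 2L) {
    stop_value("need at least 2 OTUs present in the union of the pair")
  }
  n_pool <- ncol(m)
  if (exhaustive) {
    perms <- all_permutations(n_pool)
  } else {
    if (n_null < 99L) stop_value("n_null must be >= 99")
    if (missing(seed)) stop_value("`seed` is required for a reproducible null")
    perms <- with_seed(seed, {
      t(vapply(seq_len(n_null), function(k) sample.int(n_pool), integer(n_pool)))
    })
  }
  obs <- cpp_bmntd(d, pw$idxA - 1L, pw$wA, pw$idxB - 1L, pw$wB)
  nulls <- cpp_bmntd_perm_null(d, pw$idxA - 1L, pw$wA, pw$idxB - 1L, pw$wB,
                               perms - 1L)
  mu <- mean(nulls)
  sg <- sd(nulls)
  z <- if (sg > 0) (obs - mu) / sg else NaN
  structure(z, bmntd_obs = obs, null_mean = mu, null_sd = sg,
            flag = if (is.nan(z)) "zero-variance null (degenerate phylogeny)" else NULL)
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' Compares the observed Bray-Curtis dissimilarity of a sample pair with a
#' null distribution in which both communities are probabilistically
#' reassembled: each null community draws its observed richness worth of OTUs
#' without replacement with probability proportional to occupancy frequency
#' across all samples, then allocates its observed total abundance among the
#' drawn OTUs with probability proportional to pool mean relative abundance.
#' The result is rescaled to \eqn{[-1, 1]}:
#' \deqn{RC = 2\,\frac{\#\{null < obs\} + 0.5\,\#\{null = obs\}}{n_{null}} - 1}
#' RC > 0.95 indicates dispersal limitation; RC < -0.95 homogenizing
#' dispersal.
#'
#' @inheritParams bmntd
#' @param n_null number of null assemblies (>= 99).
#' @param seed integer seed.
#' @return RC value in \eqn{[-1, 1]} with attribute `bray_obs`.
#' @export
rc_bray <- function(table, pair, n_null = 999L, seed) {
  m <- count_matrix(as_community_table(table))
  if (max(abs(m - round(m))) > 1e-8) {
    stop_value("rc_bray requires (integerizable) counts, not relative abundances")
  }
  m <- round(m)
  if (n_null < 99L) stop_value("n_null must be >= 99")
  if (missing(seed)) stop_value("`seed` is required for a reproducible null")
  pr <- sort(pair_rows(m, pair))  # canonical order: result is order-independent
  xa <- m[pr[1L], ]
  xb <- m[pr[2L], ]
  if (sum(xa) == 0 || sum(xb) == 0) stop_value("empty sample in pair")
  occ_freq <- colMeans(m > 0)
  mean_relab <- colMeans(m / rowSums(m))
  richA <- sum(xa > 0); richB <- sum(xb > 0)
  if (richA > ncol(m) || richB > ncol(m)) stop_value("richness exceeds OTU pool")
  obs <- sum(abs(xa - xb)) / sum(xa + xb)
  nulls <- with_seed(seed, {
    cpp_rc_bray_null(occ_freq, mean_relab, richA, richB,
                     as.integer(sum(xa)), as.integer(sum(xb)), as.integer(n_null))
  })
  eps <- 1e-10
  rc <- 2 * (sum(nulls < obs - eps) + 0.5 * sum(abs(nulls - obs) <= eps)) / n_null - 1
  structure(rc, bray_obs = obs)
}

#' Assign an assembly process from betaNTI and RC-Bray
#'
#' Five-way partition: betaNTI > 2 is variable selection, betaNTI < -2
#' homogeneous selection; otherwise RC > 0.95 is dispersal limitation,
#' RC < -0.95 homogenizing dispersal, and the remainder is undominated.
#' Boundary values (betaNTI of exactly +/-2, RC of exactly +/-0.95) fall on
#' the stochastic/undominated side: the selection and dispersal calls require
#' strict exceedance. Vectorized over pairs.
#'
#' @param bnti numeric vector of betaNTI z-scores.
#' @param rc numeric vector of RC-Bray values, same length.
#' @return character vector of process labels.
#' @examples
#' partition_processes(c(2.5, -1.0, 1.0), c(0.1, 0.97, 0.5))
#' @export
partition_processes <- function(bnti, rc) {
  if (length(bnti) != length(rc)) stop_value("bnti and rc must have equal length")
  if (anyNA(bnti) || anyNA(rc)) {
    stop_value("NaN/NA input to partition_processes; exclude flagged pairs first")
  }
  ifelse(bnti > 2, "variable_selection",
    ifelse(bnti < -2, "homogeneous_selection",
      ifelse(rc > 0.95, "dispersal_limitation",
        ifelse(rc < -0.95, "homogenizing_dispersal", "undominated"))))
}

assembly_process_levels <- c("variable_selection", "homogeneous_selection",
                             "dispersal_limitation", "homogenizing_dispersal",
                             "undominated")
stochastic_processes <- c("dispersal_limitation", "homogenizing_dispersal",
                          "undominated")

#' Pairwise assembly analysis over a community table
#'
#' Computes [bmntd()], [bnti()], [rc_bray()] and the process assignment for
#' sample pairs. Pairs whose betaNTI null is degenerate are kept in the output
#' with `NA` process and a `flag`, and are excluded from [summarize_assembly()]
#' counts.
#'
#' @inheritParams bnti
#' @param pairs optional two-column character matrix of sample pairs to
#'   evaluate; default all unordered pairs.
#' @param groups optional named vector (sample_id -> label, e.g. from
#'   [assign_salinity_levels()]); adds a `group` column labelling pairs whose
#'   two samples share a level (pairs across levels get `NA`).
#' @return data.frame: `sample_a`, `sample_b`, `bmntd_obs`, `bnti`, `rc_bray`,
#'   `process`, `flag` (and `group` when `groups` given).
#' @export
assembly_pairs <- function(table, dist, n_null = 999L, seed, pairs = NULL,
                           groups = NULL, abundance_weighted = TRUE) {
  table <- as_community_table(table)
  m <- count_matrix(table)
  if (is.null(pairs)) {
    cmb <- t(combn(rownames(m), 2L))
  } else {
    cmb <- matrix(as.character(pairs), ncol = 2L)
  }
  if (missing(seed)) stop_value("`seed` is required")
  res <- lapply(seq_len(nrow(cmb)), function(k) {
    pr <- cmb[k, ]
    z <- bnti(table, dist, pr, n_null = n_null, seed = seed + k,
              abundance_weighted = abundance_weighted)
    rc <- rc_bray(table, pr, n_null = n_null, seed = seed + k)
    data.frame(sample_a = pr[1L], sample_b = pr[2L],
               bmntd_obs = attr(z, "bmntd_obs"),
               bnti = as.numeric(z), rc_bray = as.numeric(rc),
               process = if (is.nan(z)) NA_character_ else
                 partition_processes(as.numeric(z), as.numeric(rc)),
               flag = attr(z, "flag") %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(groups)) {
    ga <- unname(groups[out$sample_a])
    gb <- unname(groups[out$sample_b])
    out$group <- ifelse(!is.na(ga) & !is.na(gb) & ga == gb, ga, NA_character_)
  }
  out
}

#' Summarize assembly-process fractions
#'
#' @param pairs data.frame from [assembly_pairs()] (or any data.frame with a
#'   `process` column). Rows with `NA` process (flagged pairs) are dropped and
#'   reported through `n_excluded`.
#' @return list with `fractions` (named over the five processes, summing
#'   to 1), `stochastic_fraction` (dispersal limitation + homogenizing
#'   dispersal + undominated), `n_pairs`, `n_excluded`.
#' @export
summarize_assembly <- function(pairs) {
  if (NROW(pairs) == 0L) stop_value("no pairs to summarize")
  proc <- pairs$process
  n_exc <- sum(is.na(proc))
  proc <- proc[!is.na(proc)]
  if (!length(proc)) stop_value("no valid (unflagged) pairs to summarize")
  bad <- setdiff(unique(proc), assembly_process_levels)
  if (length(bad)) stop_value("unknown process label(s): %s", paste(bad, collapse = ", "))
  counts <- table(factor(proc, levels = assembly_process_levels))
  fr <- as.numeric(counts) / length(proc)
  names(fr) <- assembly_process_levels
  list(fractions = fr,
       stochastic_fraction = sum(fr[stochastic_processes]),
       n_pairs = length(proc),
       n_excluded = n_exc)
}

#' Abundance-weighted niche optimum per OTU
#'
#' The default niche variable for the phylogenetic-signal test: each OTU's
#' abundance-weighted mean of an environmental variable (typically salinity)
#' over the samples it occupies.
#'
#' @param table a [community_table()].
#' @param env numeric vector of the environmental variable, one value per
#'   sample (named, or in the table's sample order).
#' @return Named numeric vector over OTUs with positive total abundance.
#' @export
otu_niche_optima <- function(table, env) {
  m <- count_matrix(as_community_table(table))
  if (!is.null(names(env))) {
    miss <- setdiff(rownames(m), names(env))
    if (length(miss)) stop_value("env missing sample(s): %s", paste(miss, collapse = ", "))
    env <- env[rownames(m)]
  }
  if (length(env) != nrow(m)) stop_value("env must have one value per sample")
  tot <- colSums(m)
  keep <- tot > 0
  setNames(colSums(m[, keep, drop = FALSE] * env) / tot[keep],
           colnames(m)[keep])
}

#' Phylogenetic Mantel correlogram
#'
#' Tests for phylogenetic signal in a niche variable: patristic distances are
#' binned into equal-frequency classes and, per class, the Mantel correlation
#' between the within-class membership indicator and pairwise niche
#' differences is evaluated by permutation with progressive Holm correction
#' (via [vegan::mantel.correlog()]). A positive correlation in the shortest
#' distance classes indicates that close relatives have similar niches.
#'
#' @param dist patristic distance matrix.
#' @param niche_values named numeric vector (otu_id -> niche value, e.g. from
#'   [otu_niche_optima()]); at least 10 OTUs.
#' @param n_classes number of equal-frequency distance classes.
#' @param n_permutations permutations per class.
#' @param seed integer seed.
#' @return data.frame: `class_index`, `d_center`, `n_pairs`, `mantel_r`,
#'   `p_value`, `p_corrected`. Classes with too few pairs are dropped by the
#'   underlying routine with a warning.
#' @export
phylo_mantel_correlogram <- function(dist, niche_values, n_classes = 5L,
                                     n_permutations = 999L, seed) {
  ids <- names(niche_values)
  if (is.null(ids)) stop_value("niche_values must be named by OTU id")
  if (length(ids) < 10L) stop_value("need at least 10 OTUs with niche values")
  miss <- setdiff(ids, rownames(dist))
  if (length(miss)) stop_value("distance matrix missing OTU(s): %s",
                               paste(miss, collapse = ", "))
  if (missing(seed)) stop_value("`seed` is required")
  d <- dist[ids, ids]
  dn <- as.matrix(stats::dist(niche_values))
  v <- upper_tri_values(d)
  brk <- unique(quantile(v, probs = seq(0, 1, length.out = n_classes + 1L),
                         names = FALSE))
  if (length(brk) < 3L) stop_value("phylogenetic distances too tied for %d classes", n_classes)
  brk[1L] <- brk[1L] - 1e-9  # include the minimum in the first class
  mc <- with_seed(seed, {
    vegan::mantel.correlog(D.eco = stats::as.dist(dn), D.geo = stats::as.dist(d),
                           break.pts = brk, cutoff = FALSE,
                           nperm = n_permutations, mult = "holm",
                           progressive = TRUE)
  })
  tab <- as.data.frame(mc$mantel.res)
  out <- data.frame(class_index = seq_len(nrow(tab)),
                    d_center = tab[["class.index"]],
                    n_pairs = tab[["n.dist"]],
                    mantel_r = tab[["Mantel.cor"]],
                    p_value = tab[["Pr(Mantel)"]],
                    p_corrected = tab[["Pr(corrected)"]],
                    row.names = NULL)
  out[!is.na(out$mantel_r), , drop = FALSE]
}
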