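#' Bray-Curtis community dissimilarity
#'
#' Default community distance for the association tests: Bray-Curtis on
#' per-sample relative abundances (via [vegan::vegdist()]).
#'
#' @param table a [community_table()].
#' @return A symmetric distance matrix over samples.
#' @export
bray_curtis_distance <- function(table) {
  rel <- count_matrix(to_relative(as_community_table(table)))
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' Euclidean distance on standardized covariates
#'
#' @param meta data.frame with a `sample_id` column and numeric covariates.
#' @param vars covariate column names to use.
#' @return Symmetric distance matrix keyed by sample_id.
#' @export
environment_distance <- function(meta, vars) {
  miss <- setdiff(vars, colnames(meta))
  if (length(miss)) stop_value("metadata missing covariate(s): %s", paste(miss, collapse = ", "))
  x <- scale(as.matrix(meta[, vars, drop = FALSE]))
  rownames(x) <- meta$sample_id
  as.matrix(stats::dist(x))
}

check_matching_distance <- function(dx, dy) {
  validate_distance_matrix(dx)
  validate_distance_matrix(dy)
  if (is.null(rownames(dx)) || is.null(rownames(dy)) ||
      !identical(rownames(dx), rownames(dy))) {
    stop_value("distance matrices must share identical ids in identical order")
  }
}

#' Mantel test
#'
#' Correlation between two distance matrices over the same samples, with a
#' one-sided permutation p-value (rows and columns of the second matrix
#' permuted jointly), computed with [vegan::mantel()]:
#' p = (1 + number of permuted r >= observed r) / (1 + n_permutations).
#'
#' @param dx,dy symmetric distance matrices with matching row/column names.
#' @param n_permutations number of permutations.
#' @param method `"pearson"` or `"spearman"`.
#' @param seed integer seed.
#' @return list: `r`, `p_value`, `n_permutations`, `method`.
#' @export
mantel_test <- function(dx, dy, n_permutations = 999L,
                        method = c("pearson", "spearman"), seed) {
  method <- match.arg(method)
  check_matching_distance(dx, dy)
  if (nrow(dx) < 4L) stop_value("mantel test needs at least 4 samples")
  if (sd(upper_tri_values(dx)) == 0 || sd(upper_tri_values(dy)) == 0) {
    stop_value("zero variance in a distance matrix")
  }
  if (missing(seed)) stop_value("`seed` is required")
  fit <- with_seed(seed, {
    vegan::mantel(stats::as.dist(dx), stats::as.dist(dy), method = method,
                  permutations = n_permutations)
  })
  list(r = unname(fit$statistic), p_value = fit$signif,
       n_permutations = n_permutations, method = method)
}

#' PERMANOVA for group differences
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F), via [vegan::adonis2()].
#'
#' @param d symmetric distance matrix with sample ids.
#' @param groups named vector (sample_id -> group label) or vector in the
#'   matrix's sample order; at least 2 groups with >= 2 members each.
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return list: `pseudo_F`, `p_value`, `r_squared`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed) {
  validate_distance_matrix(d)
  ids <- rownames(d)
  if (!is.null(names(groups))) {
    miss <- setdiff(ids, names(groups))
    if (length(miss)) stop_value("groups missing for sample(s): %s", paste(miss, collapse = ", "))
    groups <- groups[ids]
  }
  if (length(groups) != nrow(d)) stop_value("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L) stop_value("need at least 2 groups")
  if (any(tab < 2L)) {
    stop_value("singleton group(s): %s", paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (all(upper_tri_values(d) == 0)) stop_value("zero total sum of squares")
  if (missing(seed)) stop_value("`seed` is required")
  df <- data.frame(group = factor(unname(groups)))
  fit <- with_seed(seed, {
    vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                   permutations = n_permutations)
  })
  list(pseudo_F = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
       r_squared = fit$R2[1L], n_permutations = n_permutations)
}
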