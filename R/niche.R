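#' Levins niche breadth per OTU
#'
#' For OTU j with per-sample proportions \eqn{P_{ij} = x_{ij} / \sum_i x_{ij}},
#' Levins breadth is \eqn{B_j = 1 / \sum_i P_{ij}^2}: the effective number of
#' samples (habitats) the OTU occupies, between 1 (a point niche) and the
#' number of samples (perfectly even occupancy). Breadth is invariant to
#' rescaling an OTU's abundance vector, so counts and relative abundances
#' give identical values.
#'
#' @param table a [community_table()] or samples x OTUs matrix.
#' @return Named numeric vector of breadths. OTUs with zero total abundance
#'   are dropped with a warning.
#' @examples
#' m <- matrix(c(1, 1, 1, 1,  2, 2, 0, 0), ncol = 2,
#'             dimnames = list(paste0("S", 1:4), c("even", "half")))
#' levins_breadth(m)  # 4 and 2
#' @export
levins_breadth <- function(table) {
  m <- count_matrix(as_community_table(table))
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning(sprintf("dropping OTU(s) with zero total abundance: %s",
                    paste(colnames(m)[tot == 0], collapse = ", ")))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (ncol(m) == 0L) return(setNames(numeric(0), character(0)))
  p <- sweep(m, 2L, tot, "/")
  setNames(1 / colSums(p^2), colnames(m))
}

#' Classify OTUs as habitat generalists or specialists
#'
#' Builds, for every OTU, a null distribution of Levins breadths from
#' randomized community matrices and labels the OTU `generalist` if its
#' observed breadth exceeds the null's upper 95% bound, `specialist` if it
#' falls below the lower bound, and `neutral` otherwise (ties on a bound are
#' neutral: the labels require strict exceedance). Bounds are the 2.5th and
#' 97.5th percentiles of the null breadths (for `alpha = 0.05`), taken from
#' the permutation distribution directly with no normality assumption.
#'
#' Two null schemes are available. `"quasiswap"` (default) randomizes the
#' count matrix while conserving every per-sample total, per-OTU total and the
#' matrix fill exactly (vegan's `quasiswap_count` algorithm), the standard
#' marginal-preserving null for occupancy tests; it requires integer counts.
#' `"shuffle"` permutes each sample's abundances across OTUs (a row shuffle),
#' preserving sample totals while breaking OTU identity; it works for
#' non-integer data. (Permuting an OTU's abundances across samples would
#' leave Levins breadth unchanged — breadth depends only on the multiset of
#' abundances — so that variant is not offered.)
#'
#' @param table a [community_table()] of counts (quasiswap null) or any
#'   non-negative abundances (shuffle null).
#' @param n_permutations number of null matrices (>= 100).
#' @param alpha two-sided size of the null interval.
#' @param seed integer seed; output is reproducible given the seed.
#' @param null one of `"quasiswap"`, `"shuffle"`.
#' @return data.frame with one row per retained OTU: `otu_id`,
#'   `breadth_observed`, `null_lower_95`, `null_upper_95`, `label`,
#'   `n_permutations`.
#' @export
classify_generalists_specialists <- function(table, n_permutations = 1000L,
                                             alpha = 0.05, seed,
                                             null = c("quasiswap", "shuffle")) {
  null <- match.arg(null)
  table <- as_community_table(table)
  m <- count_matrix(table)
  if (nrow(m) < 2L) stop_value("need at least 2 samples to classify niche breadth")
  if (n_permutations < 100L) stop_value("n_permutations must be >= 100")
  if (missing(seed)) stop_value("`seed` is required for a reproducible null")
  keep <- colSums(m) > 0
  if (!all(keep)) {
    warning(sprintf("dropping OTU(s) with zero total abundance: %s",
                    paste(colnames(m)[!keep], collapse = ", ")))
    m <- m[, keep, drop = FALSE]
  }
  if (null == "quasiswap" && any(m != round(m))) {
    stop_value(paste0("quasiswap null requires integer counts; ",
                      "use null = \"shuffle\" for non-integer abundances"))
  }

  obs <- levins_breadth(m)
  null_b <- with_seed(seed, {
    if (null == "quasiswap") {
      nm <- vegan::nullmodel(m, "quasiswap_count")
      sims <- stats::simulate(nm, nsim = n_permutations)
      apply(sims, 3L, breadth_no_check)
    } else {
      vapply(seq_len(n_permutations), function(k) {
        breadth_no_check(t(apply(m, 1L, sample)))
      }, numeric(ncol(m)))
    }
  })
  # null_b: OTUs x permutations
  null_b <- matrix(null_b, nrow = ncol(m))
  lo <- apply(null_b, 1L, quantile, probs = alpha / 2, names = FALSE,
              na.rm = TRUE)
  hi <- apply(null_b, 1L, quantile, probs = 1 - alpha / 2, names = FALSE,
              na.rm = TRUE)
  label <- ifelse(obs > hi, "generalist", ifelse(obs < lo, "specialist", "neutral"))
  data.frame(otu_id = colnames(m), breadth_observed = unname(obs),
             null_lower_95 = lo, null_upper_95 = hi, label = label,
             n_permutations = as.integer(n_permutations),
             row.names = NULL, stringsAsFactors = FALSE)
}

# levins_breadth without validation/warnings, for hot permutation loops;
# a null draw that zeroes out an OTU entirely yields NA (row shuffles can,
# margin-preserving swaps cannot).
breadth_no_check <- function(m) {
  tot <- colSums(m)
  tot[tot == 0] <- NA_real_
  p <- sweep(m, 2L, tot, "/")
  1 / colSums(p^2)
}
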