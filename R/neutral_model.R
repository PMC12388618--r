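#' Fit the Sloan neutral community model
#'
#' Relates each OTU's occurrence frequency across samples to its mean
#' relative abundance \eqn{p}. Under the neutral model with metacommunity
#' migration rate \eqn{m} and local community size \eqn{N} (reads), the local
#' relative abundance of an OTU is Beta-distributed with shape parameters
#' \eqn{(Nmp,\; Nm(1-p))}, so the predicted probability of detecting it above
#' a detection limit \eqn{\delta} is the upper Beta tail
#' \eqn{P(x > \delta)}. \eqn{m} is estimated by bounded least squares of
#' predicted against observed frequencies over OTUs; the fit is deterministic.
#'
#' @param table a [community_table()] of counts (relative tables are accepted
#'   only with an explicit numeric `detection_limit`).
#' @param detection_limit relative-abundance detection threshold, or `"auto"`
#'   for 1 / (mean per-sample read total).
#' @param N local community size; defaults to the mean per-sample total.
#' @return An object of class `ncm_fit`: list with `m`, `Nm`, `r_squared`,
#'   `detection_limit`, `N`, `n_samples`, and `otu` (per-OTU data.frame with
#'   `mean_abundance`, `observed_frequency`, `predicted_frequency`,
#'   `ci_lower`, `ci_upper` — a 95% Wilson binomial band around the
#'   prediction at n = number of samples — and `partition` in
#'   above/within/below).
#' @export
fit_ncm <- function(table, detection_limit = "auto", N = NULL) {
  table <- as_community_table(table)
  m0 <- count_matrix(table)
  if (nrow(m0) < 5L || ncol(m0) < 10L) {
    stop_value("fit_ncm needs at least 5 samples and 10 OTUs")
  }
  counts_like <- !is_relative(table) && max(abs(m0 - round(m0))) < 1e-8
  if (identical(detection_limit, "auto")) {
    if (!counts_like) {
      stop_value("detection_limit=\"auto\" needs count data; supply an explicit limit")
    }
    detection_limit <- 1 / mean(rowSums(m0))
  }
  if (!is.numeric(detection_limit) || detection_limit <= 0 || detection_limit >= 1) {
    stop_value("detection_limit must be in (0, 1)")
  }
  N <- N %||% (if (counts_like) mean(rowSums(m0)) else 1 / detection_limit)

  rel <- count_matrix(to_relative(table))
  p <- colMeans(rel)
  keep <- p > 0
  p <- p[keep]
  # occurrence = detected at or above the limit (with auto = 1/N this is
  # presence: a single read already counts as an occurrence)
  obs_freq <- colMeans(rel[, keep, drop = FALSE] >= detection_limit - 1e-12)
  n_samp <- nrow(rel)

  pred_fun <- function(m) {
    stats::pbeta(detection_limit, N * m * p, N * m * (1 - p), lower.tail = FALSE)
  }
  sse <- function(m) sum((obs_freq - pred_fun(m))^2)
  opt <- optimise(sse, interval = c(1e-6, 1))
  m_hat <- opt$minimum
  pred <- pred_fun(m_hat)
  sst <- sum((obs_freq - mean(obs_freq))^2)
  if (sst == 0) stop_value("observed frequencies have zero variance; cannot fit")
  r2 <- 1 - opt$objective / sst

  ci <- wilson_interval(pred, n_samp)
  partition <- ifelse(obs_freq > ci$upper, "above",
                      ifelse(obs_freq < ci$lower, "below", "within"))
  structure(list(
    m = m_hat, Nm = N * m_hat, r_squared = r2,
    detection_limit = detection_limit, N = N, n_samples = n_samp,
    otu = data.frame(otu_id = names(p), mean_abundance = unname(p),
                     observed_frequency = unname(obs_freq),
                     predicted_frequency = unname(pred),
                     ci_lower = ci$lower, ci_upper = ci$upper,
                     partition = partition,
                     row.names = NULL, stringsAsFactors = FALSE)
  ), class = "ncm_fit")
}

# 95% Wilson score interval for a binomial proportion `p` at size `n`,
# vectorized over p; clamped so the band always contains the prediction.
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmin(pmax(center - half, 0), p),
       upper = pmax(pmin(center + half, 1), p))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf(paste0("Sloan neutral community model fit\n",
                     "  m = %.4g  (Nm = %.4g)\n  R^2 = %.3f\n",
                     "  detection limit = %.3g, N = %.4g, %d samples, %d OTUs\n"),
              x$m, x$Nm, x$r_squared, x$detection_limit, x$N,
              x$n_samples, nrow(x$otu)))
  invisible(x)
}
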