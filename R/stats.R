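#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return A value in `[-1, 1]`; an error if any denominator factor is zero
#'   (the metric is undefined).
#' @export
mcc <- function(tp, tn, fp, fn) {
  cnt <- c(tp, tn, fp, fn)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    sf_input_error("confusion counts must be non-negative integers")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) sf_input_error("MCC undefined: a denominator factor is zero")
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Rank-based computation: the probability that a random positive outranks
#' a random negative, with tied scores counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) sf_input_error("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    sf_input_error("both classes must be present")
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

new_test_result <- function(Z, n, method, ties) {
  structure(list(Z = Z, n = n, method = method, tie_corrected = ties),
            class = "sf_test")
}

#' @export
print.sf_test <- function(x, ...) {
  cat(sprintf("%s: Z = %.4f (n = %s)%s\n", x$method, x$Z,
              paste(x$n, collapse = ", "),
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

# shared binned core: values with per-group counts
rank_sum_core <- function(values, count_a, count_b) {
  o <- order(values)
  values <- values[o]; ca <- as.numeric(count_a[o]); cb <- as.numeric(count_b[o])
  t_ab <- ca + cb
  n_a <- sum(ca); n_b <- sum(cb); n <- n_a + n_b
  hi <- cumsum(t_ab)
  midrank <- hi - (t_ab - 1) / 2
  Ra <- sum(midrank * ca)
  mu <- n_a * (n + 1) / 2
  tie_term <- sum(t_ab^3 - t_ab)
  v <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  list(Z = (Ra - mu) / sqrt(v), n_a = n_a, n_b = n_b,
       U = Ra - n_a * (n_a + 1) / 2, ties = tie_term > 0)
}

#' Wilcoxon rank-sum Z statistic (large-sample, streaming-capable)
#'
#' Normal approximation with mid-ranks and tie-corrected variance. Besides
#' two raw samples, the test accepts pre-binned input (`values` with
#' per-group counts), so samples of tens of millions of values can be
#' tested with memory proportional to the number of distinct bins; the
#' binned path is algebraically identical to the in-memory path. The sign
#' convention is positive when the first group tends to be larger. No
#' continuity correction is applied.
#'
#' @param a,b Numeric samples, or for binned input pass `a` as a data frame
#'   with columns `value`, `count_a`, `count_b` and leave `b` missing.
#' @return An `sf_test` with fields `Z`, `n`, `U`.
#' @export
rank_sum_z <- function(a, b = NULL) {
  if (is.data.frame(a)) {
    if (!is.null(b)) sf_input_error("binned input takes a single data frame")
    core <- rank_sum_core(a$value, a$count_a, a$count_b)
  } else {
    if (length(a) < 1L || length(b) < 1L)
      sf_input_error("both samples must be non-empty")
    vals <- sort(unique(c(a, b)))
    core <- rank_sum_core(vals,
                          tabulate(match(a, vals), length(vals)),
                          tabulate(match(b, vals), length(vals)))
  }
  res <- new_test_result(core$Z, c(core$n_a, core$n_b),
                         "Wilcoxon rank-sum (normal approximation)",
                         core$ties)
  res$U <- core$U
  res
}

#' Wilcoxon signed-rank Z statistic
#'
#' Zero differences are dropped; ranks of `|d|` use mid-ranks and the
#' variance carries the tie correction `sum(t^3 - t)/48`. Positive Z means
#' positive differences dominate.
#'
#' @param d Numeric vector of paired differences.
#' @return An `sf_test` with fields `Z`, `n`, `W` (sum of positive ranks).
#' @export
signed_rank_z <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0L)
    sf_input_error("signed-rank test undefined: all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tt <- table(abs(d))
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  res <- new_test_result((W - mu) / sqrt(v), n,
                         "Wilcoxon signed-rank (normal approximation)",
                         any(tt > 1))
  res$W <- W
  res
}

#' One-sided Bonferroni threshold on the Z scale
#'
#' The Z value above which a one-sided test remains significant at family
#' level `alpha` after Bonferroni correction over `m` comparisons.
#'
#' @param alpha Family-wise error rate.
#' @param m Number of comparisons.
#' @return The corrected Z threshold.
#' @export
bonferroni_z_threshold <- function(alpha = 0.05, m = 1L) {
  stats::qnorm(alpha / m, lower.tail = FALSE)
}

#' Positional mean profile across aligned series
#'
#' Averages several per-position series after aligning them on a common
#' anchor (e.g. a splice site at offset 0). Offsets with no coverage are
#' reported as `NA`.
#'
#' @param series A list of numeric vectors.
#' @param anchors Integer vector: the 1-based anchor position within each
#'   series.
#' @param offsets Integer offsets (relative positions) to report.
#' @return Data frame with `offset`, `mu` (positional mean) and `n_cov`
#'   (number of series covering the offset).
#' @export
positional_profile <- function(series, anchors, offsets = -300:300) {
  if (length(series) != length(anchors)) sf_input_error("length mismatch")
  mu <- numeric(length(offsets)); cov <- integer(length(offsets))
  for (t in seq_along(offsets)) {
    vals <- unlist(lapply(seq_along(series), function(s) {
      p <- anchors[s] + offsets[t]
      if (p >= 1L && p <= length(series[[s]])) series[[s]][p] else NULL
    }))
    cov[t] <- length(vals)
    mu[t] <- if (length(vals)) mean(vals) else NA_real_
  }
  data.frame(offset = offsets, mu = mu, n_cov = cov)
}

#' Normalised log-ratio of a positional profile
#'
#' `log(mu(i) / mu_bar)` with `mu_bar` the mean of `mu` across the
#' `+/- half_span` offsets around the anchor (offsets without coverage are
#' ignored).
#'
#' @param profile Output of [positional_profile()].
#' @param half_span Half-width of the normalisation span (default 300 nt).
#' @return The profile with an extra `log_ratio` column.
#' @export
log_relative <- function(profile, half_span = 300L) {
  sel <- abs(profile$offset) <= half_span & !is.na(profile$mu)
  mu_bar <- mean(profile$mu[sel])
  profile$log_ratio <- log(profile$mu / mu_bar)
  profile
}

#' Binned density log-ratio of two samples
#'
#' Histogram densities on shared breaks with an add-half pseudocount per
#' bin (so empty bins stay finite), then `log(f_a(x) / f_b(x))` per bin.
#'
#' @param a,b Numeric samples.
#' @param bins Number of equal-width bins over the pooled range.
#' @return Data frame with `mid`, `f_a`, `f_b`, `log_ratio`.
#' @export
density_log_ratio <- function(a, b, bins = 50L) {
  if (length(a) == 0L || length(b) == 0L)
    sf_input_error("both samples must be non-empty")
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  w <- diff(breaks)[1]
  ca <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE), bins)
  cb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE), bins)
  fa <- (ca + 0.5) / (length(a) + 0.5 * bins) / w
  fb <- (cb + 0.5) / (length(b) + 0.5 * bins) / w
  data.frame(mid = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
             f_a = fa, f_b = fb, log_ratio = log(fa / fb))
}
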