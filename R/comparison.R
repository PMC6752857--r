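# Difference statistics between the bound and the unbound condition.
#
# All statistics pool frames over replicas; significance resamples whole
# replicas (frames within a replica are time-correlated and move together).

.check_units <- function(bound, unbound) {
  if (inherits(bound, "descriptor_series") && inherits(unbound, "descriptor_series") &&
      !identical(bound$units, unbound$units))
    stop_ensdiff("ensdiff_unit_error", sprintf(
      "unit mismatch: '%s' vs '%s'", bound$units, unbound$units))
}

#' Mean difference d between two conditions
#'
#' `d = mean(bound) - mean(unbound)`, each mean taken over all frames and
#' replicas pooled.  Signed, in descriptor units.
#'
#' @param bound,unbound [descriptor_series()] objects (or lists of per-replica
#'   numeric vectors) of the same descriptor.
#' @return signed scalar.
#' @export
stat_d <- function(bound, unbound) {
  .check_units(bound, unbound)
  mean(pooled_values(bound)) - mean(pooled_values(unbound))
}

#' Range-normalised difference d/r
#'
#' `d` divided by the range `r` of the union of the two trimmed
#' distributions, where each condition's pooled values are first trimmed to
#' their own 2.5th-97.5th percentile interval (linear-interpolation
#' percentiles).  Dimensionless and scale-invariant.
#'
#' @inheritParams stat_d
#' @param trim lower tail fraction trimmed from each side (default 0.025).
#' @return signed dimensionless scalar.
#' @export
stat_d_over_r <- function(bound, unbound, trim = 0.025) {
  .check_units(bound, unbound)
  vb <- pooled_values(bound)
  vu <- pooled_values(unbound)
  if (length(vb) + length(vu) < 40L)
    stop_ensdiff("ensdiff_insufficient_data_error",
                 "d/r needs a pooled sample of >= 40 values for stable tail percentiles")
  r <- .trimmed_union_range(vb, vu, trim)
  if (r <= 0)
    stop_ensdiff("ensdiff_degenerate_range_error",
                 "combined trimmed range is zero (all values identical)")
  (mean(vb) - mean(vu)) / r
}

.trimmed_union_range <- function(vb, vu, trim = 0.025) {
  qb <- quantile(vb, c(trim, 1 - trim), names = FALSE, type = 7)
  qu <- quantile(vu, c(trim, 1 - trim), names = FALSE, type = 7)
  max(qb[2], qu[2]) - min(qb[1], qu[1])
}

#' Total variation distance between two pooled descriptor distributions
#'
#' Histograms with `bins` shared equal-width bins spanning the pooled
#' min-max of both conditions are normalised to probability mass one;
#' `tvd = 0.5 * sum |p_bound - p_unbound|`.  0 means perfect overlap, 1 no
#' overlap.  Always non-negative (no sign).
#'
#' @inheritParams stat_d
#' @param bins number of shared histogram bins.
#' @param warn_sensitivity emit a note when halving the bin count moves the
#'   value by more than 0.05 (binning-sensitive distributions).
#' @return scalar in `[0, 1]`.
#' @export
stat_tvd <- function(bound, unbound, bins = 100, warn_sensitivity = TRUE) {
  .check_units(bound, unbound)
  vb <- pooled_values(bound)
  vu <- pooled_values(unbound)
  out <- .tvd_values(vb, vu, bins)
  if (is.na(out)) {
    warning("fewer than 2 distinct pooled values; tvd set to 0")
    return(0)
  }
  if (warn_sensitivity && bins >= 4) {
    half <- .tvd_values(vb, vu, max(2L, bins %/% 2L))
    if (!is.na(half) && abs(half - out) > 0.05)
      message(sprintf(
        "tvd is binning-sensitive here: %.3f with %d bins vs %.3f with %d bins",
        out, bins, half, bins %/% 2L))
  }
  out
}

.tvd_values <- function(vb, vu, bins) {
  pooled <- c(vb, vu)
  lo <- min(pooled); hi <- max(pooled)
  if (hi <= lo) return(NA_real_)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  0.5 * sum(abs(.bin_fracs(vb, breaks) - .bin_fracs(vu, breaks)))
}

.bin_counts <- function(v, breaks) {
  nb <- length(breaks) - 1L
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = nb)
}

.bin_fracs <- function(v, breaks) .bin_counts(v, breaks) / length(v)

#' Cohen's d between two conditions
#'
#' Difference of pooled means divided by the pooled standard deviation.
#'
#' @inheritParams stat_d
#' @return signed dimensionless scalar.
#' @export
cohen_d <- function(bound, unbound) {
  .check_units(bound, unbound)
  vb <- pooled_values(bound)
  vu <- pooled_values(unbound)
  if (length(vb) < 2L || length(vu) < 2L)
    stop_ensdiff("ensdiff_insufficient_data_error", "Cohen's d needs >= 2 values per condition")
  sp2 <- ((length(vb) - 1) * stats::var(vb) + (length(vu) - 1) * stats::var(vu)) /
    (length(vb) + length(vu) - 2)
  if (sp2 <= 0)
    stop_ensdiff("ensdiff_degenerate_range_error", "pooled standard deviation is zero")
  (mean(vb) - mean(vu)) / sqrt(sp2)
}

# ---- replica-level resampling ------------------------------------------------

# Shared engine.  Merges the 2n replicas; each of n_perm draws picks two
# groups of n replicas with repetition and recomputes the statistics.
# q = fraction of null draws strictly smaller than the observed value.
.resample_engine <- function(bound, unbound, statistics, n_perm, bins, seed,
                             trim = 0.025) {
  vb <- replica_values(bound)
  vu <- replica_values(unbound)
  if (length(vb) < 2L || length(vu) < 2L)
    stop_ensdiff("ensdiff_insufficient_replicas_error",
                 "resampling needs >= 2 replicas per condition")
  if (!is.null(seed)) set.seed(seed)
  reps <- c(vb, vu)
  nn <- length(vb)
  total <- length(reps)
  len <- lengths(reps)
  sums <- vapply(reps, sum, numeric(1))
  sumsq <- vapply(reps, function(v) sum(v^2), numeric(1))
  pooled_all <- unlist(reps, use.names = FALSE)
  lo <- min(pooled_all); hi <- max(pooled_all)
  degenerate <- hi <= lo
  if (!degenerate) {
    breaks <- seq(lo, hi, length.out = bins + 1L)
    counts <- t(vapply(reps, .bin_counts, integer(bins), breaks = breaks))
  }

  can_dr <- "d_over_r" %in% statistics &&
    (sum(len) >= 40L) && !degenerate
  observed <- list()
  pv_b <- unlist(vb, use.names = FALSE); pv_u <- unlist(vu, use.names = FALSE)
  if ("d" %in% statistics) observed$d <- mean(pv_b) - mean(pv_u)
  if ("d_over_r" %in% statistics)
    observed$d_over_r <- if (can_dr)
      (mean(pv_b) - mean(pv_u)) / .trimmed_union_range(pv_b, pv_u, trim) else NA_real_
  if ("tvd" %in% statistics)
    observed$tvd <- if (degenerate) 0 else
      0.5 * sum(abs(colSums(counts[seq_len(nn), , drop = FALSE]) / sum(len[seq_len(nn)]) -
                    colSums(counts[nn + seq_len(length(vu)), , drop = FALSE]) /
                      sum(len[nn + seq_len(length(vu))])))
  if ("cohen" %in% statistics) observed$cohen <- cohen_d(replica_values(bound),
                                                         replica_values(unbound))

  null_mat <- matrix(NA_real_, n_perm, length(statistics),
                     dimnames = list(NULL, statistics))
  g1 <- matrix(sample.int(total, nn * n_perm, replace = TRUE), n_perm, nn)
  g2 <- matrix(sample.int(total, nn * n_perm, replace = TRUE), n_perm, nn)
  for (p in seq_len(n_perm)) {
    i1 <- g1[p, ]; i2 <- g2[p, ]
    n1 <- sum(len[i1]); n2 <- sum(len[i2])
    m1 <- sum(sums[i1]) / n1; m2 <- sum(sums[i2]) / n2
    if ("d" %in% statistics) null_mat[p, "d"] <- m1 - m2
    if ("tvd" %in% statistics)
      null_mat[p, "tvd"] <- if (degenerate) 0 else
        0.5 * sum(abs(colSums(counts[i1, , drop = FALSE]) / n1 -
                      colSums(counts[i2, , drop = FALSE]) / n2))
    if ("cohen" %in% statistics) {
      ss1 <- sum(sumsq[i1]); ss2 <- sum(sumsq[i2])
      v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
      v2 <- (ss2 - n2 * m2^2) / (n2 - 1)
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      null_mat[p, "cohen"] <- if (sp2 > 0) (m1 - m2) / sqrt(sp2) else 0
    }
    if ("d_over_r" %in% statistics && can_dr) {
      x1 <- unlist(reps[i1], use.names = FALSE)
      x2 <- unlist(reps[i2], use.names = FALSE)
      r <- .trimmed_union_range(x1, x2, trim)
      null_mat[p, "d_over_r"] <- if (r > 0) (m1 - m2) / r else 0
    }
  }
  q <- vapply(statistics, function(s) {
    if (is.na(observed[[s]])) return(NA_real_)
    mean(null_mat[, s] < observed[[s]])
  }, numeric(1))
  list(observed = observed, q = q, null = null_mat)
}

#' Replica-level resampling significance (quartile q)
#'
#' Merges the n bound and n unbound replicas into one pool of 2n; 1000 times
#' (by default) two groups of n replicas are drawn with repetition and the
#' statistic recomputed between them.  The resampling unit is the whole
#' replica: all its frames move together, which makes the null robust to
#' within-replica time correlation.  `q` is the fraction of resampled
#' statistics strictly smaller than the observed one (ties count as not
#' smaller); `q = 1` means no random split produced a larger value.
#'
#' @inheritParams stat_tvd
#' @param statistic one of `"d"`, `"d_over_r"`, `"tvd"`, `"cohen"`.
#' @param n_perm number of resampling draws.
#' @param seed RNG seed (integer) for reproducibility.
#' @return `q` in `[0, 1]`.
#' @export
permutation_test <- function(bound, unbound, statistic = c("d", "d_over_r", "tvd", "cohen"),
                             n_perm = 1000, bins = 100, seed = NULL) {
  statistic <- match.arg(statistic)
  .check_units(bound, unbound)
  eng <- .resample_engine(bound, unbound, statistic, n_perm, bins, seed)
  unname(eng$q[statistic])
}

#' Compare one descriptor between conditions: d, d/r, tvd + significance
#'
#' Computes the three difference statistics (plus, optionally, Cohen's d),
#' their resampling quartiles `q`, and the masked variants in one pass over a
#' shared set of resampling draws.
#'
#' @inheritParams permutation_test
#' @param statistics which statistics to compute.
#' @param lower,upper mask thresholds: signed statistics are kept when
#'   `q <= lower` or `q >= upper`; sign-free tvd when `q >= upper`.
#' @return object of class `comparison_result` with fields `descriptor_name`,
#'   `d`, `d_over_r`, `tvd`, (`cohen`), `q_d`, `q_dr`, `q_tvd`, (`q_cohen`),
#'   and `masked_*` counterparts.
#' @export
compare_conditions <- function(bound, unbound,
                               statistics = c("d", "d_over_r", "tvd"),
                               n_perm = 1000, bins = 100, seed = NULL,
                               lower = 0.05, upper = 0.95) {
  .check_units(bound, unbound)
  eng <- .resample_engine(bound, unbound, statistics, n_perm, bins, seed)
  res <- list(
    descriptor_name = if (inherits(bound, "descriptor_series"))
      bound$descriptor else "descriptor",
    units = if (inherits(bound, "descriptor_series")) bound$units else "",
    d = eng$observed$d, d_over_r = eng$observed$d_over_r,
    tvd = eng$observed$tvd, cohen = eng$observed$cohen,
    q_d = unname(eng$q["d"]), q_dr = unname(eng$q["d_over_r"]),
    q_tvd = unname(eng$q["tvd"]), q_cohen = unname(eng$q["cohen"]),
    n_perm = n_perm, bins = bins, seed = seed)
  class(res) <- "comparison_result"
  significance_mask(res, lower = lower, upper = upper)
}

#' Mask non-significant statistics to zero
#'
#' Signed statistics (d, d/r, Cohen's d) are kept only when their observed
#' value falls in the top or bottom 5% of the resampling null (`q >= upper`
#' or `q <= lower`); the sign-free tvd only in the top 5% (`q >= upper`).
#' Everything else is set to zero, as in masked summary tables.
#'
#' @param result a `comparison_result`.
#' @param lower,upper mask thresholds.
#' @return the `comparison_result` with `masked_d`, `masked_dr`,
#'   `masked_tvd` (and `masked_cohen` when present) filled in.
#' @export
significance_mask <- function(result, lower = 0.05, upper = 0.95) {
  keep2 <- function(value, q) {
    if (is.null(value) || is.na(value)) return(NA_real_)
    if (!is.na(q) && (q >= upper || q <= lower)) value else 0
  }
  keep1 <- function(value, q) {
    if (is.null(value) || is.na(value)) return(NA_real_)
    if (!is.na(q) && q >= upper) value else 0
  }
  result$masked_d <- keep2(result$d, result$q_d)
  result$masked_dr <- keep2(result$d_over_r, result$q_dr)
  result$masked_tvd <- keep1(result$tvd, result$q_tvd)
  if (!is.null(result$cohen)) result$masked_cohen <- keep2(result$cohen, result$q_cohen)
  result
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result: %s>\n", x$descriptor_name))
  cat(sprintf("  d      = %8.4g (q = %.3f, masked %.4g) %s\n",
              x$d, x$q_d, x$masked_d, x$units))
  if (!is.null(x$d_over_r))
    cat(sprintf("  d/r    = %8.4g (q = %s, masked %s)\n", x$d_over_r,
                format(x$q_dr), format(x$masked_dr)))
  if (!is.null(x$tvd))
    cat(sprintf("  tvd    = %8.4g (q = %.3f, masked %.4g)\n", x$tvd, x$q_tvd, x$masked_tvd))
  if (!is.null(x$cohen) && !is.na(x$cohen))
    cat(sprintf("  cohen  = %8.4g (q = %.3f, masked %.4g)\n", x$cohen, x$q_cohen,
                x$masked_cohen))
  invisible(x)
}

#' Replica-variance bootstrap curve
#'
#' How much does averaging over n replicas stabilise a descriptor?  For each
#' group size n, two groups of n replicas are drawn with repetition from the
#' replica pool `n_boot` times (default 10 000); the curve records the mean
#' and SD of the absolute difference between the two group means, plus the
#' percent reduction of that mean relative to group size 1.  For iid replica
#' means the curve follows a `1/sqrt(n)` law (about 68% reduction at n = 10,
#' 80% at n = 25).
#'
#' @param series a [descriptor_series()], a list of per-replica value vectors,
#'   or a numeric vector of per-replica means.
#' @param group_sizes integer vector of group sizes n (must include 1 for the
#'   reduction column to be defined).
#' @param n_boot number of resamples per group size.
#' @param seed RNG seed.
#' @return data frame of class `bootstrap_curve`: `n`, `mean_abs_diff`,
#'   `sd_abs_diff`, `pct_reduction`.
#' @export
bootstrap_replica_variance <- function(series, group_sizes, n_boot = 10000, seed = NULL) {
  if (any(group_sizes < 1L))
    stop_ensdiff("ensdiff_argument_error", "group sizes must be >= 1")
  means <- if (is.numeric(series) && !is.list(series)) as.numeric(series)
           else vapply(replica_values(series), mean, numeric(1))
  if (length(means) < 2L)
    stop_ensdiff("ensdiff_insufficient_replicas_error", "need >= 2 replicas")
  if (any(group_sizes > length(means)))
    stop_ensdiff("ensdiff_argument_error", "group size exceeds replica count")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(group_sizes, function(n) {
    d1 <- rowMeans(matrix(means[sample.int(length(means), n * n_boot, replace = TRUE)],
                          n_boot, n))
    d2 <- rowMeans(matrix(means[sample.int(length(means), n * n_boot, replace = TRUE)],
                          n_boot, n))
    ad <- abs(d1 - d2)
    data.frame(n = n, mean_abs_diff = mean(ad), sd_abs_diff = sd(ad))
  })
  out <- do.call(rbind, rows)
  base <- out$mean_abs_diff[out$n == 1L]
  out$pct_reduction <- if (length(base) && base > 0)
    100 * (1 - out$mean_abs_diff / base) else NA_real_
  class(out) <- c("bootstrap_curve", "data.frame")
  attr(out, "n_boot") <- n_boot
  out
}
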