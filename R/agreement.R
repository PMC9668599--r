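#' Bland-Altman test-retest agreement
#'
#' For paired measurements, computes the mean difference (bias), the sample
#' SD of differences and the 95 percent limits of agreement
#' \eqn{\bar d \pm 1.96\, s_d} — the range expected to contain 95 percent of
#' repeat-measurement differences — plus the per-subject (average,
#' difference) pairs used for the classic plot.
#'
#' @param x1,x2 paired measurements (first / second session), length >= 2.
#' @return An object of class \code{bland_altman}: list with \code{n},
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_half_width},
#'   \code{loa_low}, \code{loa_high} and data.frame \code{pairs}
#'   (columns \code{average}, \code{difference}).
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(1.1, 2.1, 2.9))
#' c(ba$loa_low, ba$loa_high)
#' @export
bland_altman <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("'x1' and 'x2' must be paired")
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- x2 - x1
  md <- mean(d)
  sdd <- sd(d)
  structure(list(
    n = n, mean_diff = md, sd_diff = sdd,
    loa_half_width = 1.96 * sdd,
    loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
    pairs = data.frame(average = (x1 + x2) / 2, difference = d)
  ), class = "bland_altman")
}

#' @exportS3Method base::print
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.4g, limits [%.4g, %.4g]\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Exact two-sided sign test for paired data
#'
#' Tests whether paired differences are symmetric about zero using the exact
#' binomial distribution of the number of positive differences among the
#' non-tied pairs: \eqn{p = \min(1,\, 2 \min(P(X \le k), P(X \ge k)))} with
#' \eqn{X \sim Bin(m, 1/2)}. Zero differences are dropped (the standard
#' convention); small samples make the exact form essential.
#'
#' @param x1 first-session values, or (if \code{x2} is NULL) the differences.
#' @param x2 optional second-session values.
#' @return List: \code{n_pairs} (non-tied m), \code{n_positive} (k),
#'   \code{p}.
#' @examples
#' sign_test_counts(7, 11)$p   # 0.549
#' sign_test_counts(6, 9)$p    # 0.508
#' @export
sign_test <- function(x1, x2 = NULL) {
  d <- if (is.null(x2)) x1 else {
    if (length(x1) != length(x2)) stop("'x1' and 'x2' must be paired")
    x2 - x1
  }
  d <- d[is.finite(d)]
  if (length(d) < 1L) stop("need at least one pair")
  nz <- d != 0
  if (sum(!nz) > 0)
    message(sum(!nz), " zero difference(s) dropped from the sign test")
  if (!any(nz)) {
    warning("all differences are zero; sign test is uninformative (p = 1)")
    return(list(n_pairs = 0L, n_positive = 0L, p = 1))
  }
  sign_test_counts(sum(d > 0), sum(nz))
}

#' @rdname sign_test
#' @param k number of positive differences.
#' @param m number of non-tied pairs.
#' @export
sign_test_counts <- function(k, m) {
  stopifnot(m >= 1, k >= 0, k <= m)
  p <- min(1, 2 * min(pbinom(k, m, 0.5),
                      pbinom(k - 1, m, 0.5, lower.tail = FALSE)))
  list(n_pairs = as.integer(m), n_positive = as.integer(k), p = p)
}

#' Test-retest agreement table for one cohort arm
#'
#' For each metric x region combination present in a long-format ROI table,
#' pairs the two timepoints per subject and reports session means,
#' Bland-Altman statistics and the exact sign-test p-value — the layout used
#' to report healthy-control scan-rescan agreement.
#'
#' @param cohort_table long-format table from
#'   \code{\link{build_cohort_table}}.
#' @param arm which arm to analyse (default "control").
#' @param value which ROI statistic enters the analysis ("mean" or
#'   "median").
#' @return data.frame: metric, region, n, mean_t1, mean_t2, mean_diff,
#'   sd_diff, loa_low, loa_high, sign_test_p.
#' @export
agreement_table <- function(cohort_table, arm = "control", value = "mean") {
  tab <- cohort_table[cohort_table$arm == arm, ]
  if (nrow(tab) == 0L) stop("no rows for arm '", arm, "'")
  tps <- unique(tab$timepoint)
  if (length(tps) != 2L) stop("agreement requires exactly two timepoints")
  out <- list()
  for (metric in unique(tab$metric)) {
    for (region in unique(tab$region)) {
      sub <- tab[tab$metric == metric & tab$region == region, ]
      if (nrow(sub) == 0L) next
      w <- reshape_pairs(sub, tps, value)
      if (nrow(w) < 2L) next
      ba <- bland_altman(w$t1, w$t2)
      st <- suppressMessages(sign_test(w$t1, w$t2))
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, region = region, n = ba$n,
        mean_t1 = mean(w$t1), mean_t2 = mean(w$t2),
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        sign_test_p = st$p)
    }
  }
  do.call(rbind, out)
}

reshape_pairs <- function(sub, tps, value = "mean") {
  a <- sub[sub$timepoint == tps[1], c("subject", value)]
  b <- sub[sub$timepoint == tps[2], c("subject", value)]
  m <- merge(a, b, by = "subject", suffixes = c("_1", "_2"))
  data.frame(subject = m$subject, t1 = m[[2]], t2 = m[[3]])
}
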