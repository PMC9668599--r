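#' Paired t-test for longitudinal ROI means
#'
#' Two-sided paired t-test, \eqn{t = \bar d / (s_d / \sqrt n)} on n - 1
#' degrees of freedom. A zero-variance difference with non-zero mean is
#' flagged (infinite t) rather than silently dropped.
#'
#' @param x1,x2 paired per-subject values (baseline, follow-up).
#' @return data.frame: n, mean_diff, sd_diff, t, df, p.
#' @export
paired_t <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("'x1' and 'x2' must be paired")
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- x2 - x1
  if (sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    warning("zero variance of differences; t is ",
            if (is.finite(t)) "0" else "infinite")
    p <- if (is.finite(t)) 1 else 0
    return(data.frame(n = n, mean_diff = mean(d), sd_diff = 0,
                      t = t, df = n - 1, p = p))
  }
  tt <- t.test(x2, x1, paired = TRUE)
  data.frame(n = n, mean_diff = mean(d), sd_diff = sd(d),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Paired t statistic from summary statistics
#'
#' Recomputes a paired t-test from a reported mean difference, SD of
#' differences and sample size — useful for checking published tables.
#'
#' @param mean_diff mean of paired differences.
#' @param sd_diff sample SD of the differences.
#' @param n number of pairs.
#' @return data.frame: n, mean_diff, sd_diff, t, df, p.
#' @examples
#' paired_t_from_summary(0.47, 1.05, 62)$t  # 3.52
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n) {
  stopifnot(n >= 2, sd_diff > 0)
  t <- mean_diff / (sd_diff / sqrt(n))
  data.frame(n = n, mean_diff = mean_diff, sd_diff = sd_diff,
             t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

#' Covariate-adjusted linear mixed model for a longitudinal metric
#'
#' Fits \code{value ~ time + age + sex + lesion_load + dmt + (1 | subject)}
#' by maximum likelihood (not REML) and reports the fixed effect of time with
#' Satterthwaite degrees of freedom, the variance components, and Nakagawa's
#' marginal R-squared
#' \eqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)} where
#' \eqn{\sigma^2_f} is the variance of the fixed-effect predictions.
#' Covariates that are constant in the data (e.g. one sex only) are dropped
#' from the formula automatically; optional interaction terms with time can
#' be added. Non-convergence is raised as an error, not swallowed.
#'
#' @param data data.frame with columns \code{value}, \code{time} (numeric,
#'   e.g. 0/1 years), \code{subject}, and the covariates.
#' @param covariates character vector of covariate column names.
#' @param interactions character vector of covariates that additionally
#'   interact with time (default none).
#' @return data.frame: beta_time, se, t, df, p, sigma2_fixed,
#'   sigma2_random, sigma2_resid, marginal_r2, converged.
#' @export
fit_lmm <- function(data,
                    covariates = c("age", "sex", "lesion_load", "dmt"),
                    interactions = character()) {
  stopifnot(all(c("value", "time", "subject") %in% names(data)))
  keep <- covariates[vapply(covariates, function(v) {
    x <- data[[v]]
    !is.null(x) && length(unique(x[!is.na(x)])) > 1L
  }, logical(1))]
  rhs <- c("time", keep, paste0("time:", intersect(interactions, keep)))
  f <- as.formula(paste("value ~", paste(rhs, collapse = " + "),
                        "+ (1 | subject)"))
  fit <- lmerTest::lmer(f, data = data, REML = FALSE)
  msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(msgs) && any(grepl("failed to converge", msgs)))
    stop("mixed model failed to converge: ", paste(msgs, collapse = "; "))
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_r <- sum(vc$vcov[vc$grp != "Residual"])
  s2_e <- vc$vcov[vc$grp == "Residual"]
  s2_f <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  data.frame(beta_time = co["time", "Estimate"],
             se = co["time", "Std. Error"],
             t = co["time", "t value"],
             df = co["time", "df"],
             p = co["time", "Pr(>|t|)"],
             sigma2_fixed = s2_f, sigma2_random = s2_r,
             sigma2_resid = s2_e,
             marginal_r2 = nakagawa_r2(s2_f, s2_r, s2_e),
             converged = TRUE)
}

#' Nakagawa marginal R-squared from variance components
#'
#' @param var_fixed variance of the fixed-effect predictions.
#' @param var_random summed random-effect variances.
#' @param var_resid residual variance.
#' @return Marginal R-squared in [0, 1].
#' @examples
#' nakagawa_r2(1, 1, 2)  # 0.25
#' @export
nakagawa_r2 <- function(var_fixed, var_random, var_resid) {
  stopifnot(var_fixed >= 0, var_random >= 0, var_resid >= 0)
  var_fixed / (var_fixed + var_random + var_resid)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' q-values are never smaller than the raw p-values.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values, same length/order as \code{p}.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation between longitudinal changes of two metrics
#'
#' @param delta_a,delta_b per-subject changes of two metrics (paired).
#' @return data.frame: n, r, r2, p.
#' @export
change_correlation <- function(delta_a, delta_b) {
  if (length(delta_a) != length(delta_b)) stop("inputs must be paired")
  ok <- is.finite(delta_a) & is.finite(delta_b)
  a <- delta_a[ok]; b <- delta_b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance input")
  ct <- cor.test(a, b, method = "pearson")
  data.frame(n = length(a), r = unname(ct$estimate),
             r2 = unname(ct$estimate)^2, p = ct$p.value)
}

#' Welch two-sample comparison of longitudinal change between subgroups
#'
#' Welch's unequal-variance t-test with Satterthwaite degrees of freedom,
#' e.g. to compare change in patients with versus without new lesions at
#' follow-up.
#'
#' @param values per-subject change values.
#' @param groups two-level grouping vector (factor/logical/character).
#' @return data.frame: n1, n2, mean1, mean2, t, df, p.
#' @export
subgroup_welch <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("'groups' must have exactly two levels")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need at least 2 values")
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    return(data.frame(n1 = length(x), n2 = length(y), mean1 = mean(x),
                      mean2 = mean(y), t = 0, df = length(x) + length(y) - 2,
                      p = 1))
  tt <- t.test(x, y, var.equal = FALSE)
  data.frame(n1 = length(x), n2 = length(y),
             mean1 = mean(x), mean2 = mean(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Longitudinal group statistics over a cohort table
#'
#' For the patient arm: per metric x region, a paired t-test of follow-up
#' versus baseline ROI values; a covariate-adjusted linear mixed model with
#' BH-FDR correction applied across metrics within each region; Pearson
#' correlations between per-subject changes of every metric pair within each
#' region; and, when both subgroups are populated, Welch comparisons of
#' change between patients with and without new lesions.
#'
#' @param cohort_table long-format table from
#'   \code{\link{build_cohort_table}}.
#' @param meta subject metadata (needs subject, age, sex, dmt_initiated,
#'   lesion_load_pct_icv, and optionally new_lesions).
#' @param arm which arm to analyse (default "patient").
#' @param value which ROI statistic to model ("mean" or "median").
#' @param covariates,interactions passed to \code{\link{fit_lmm}}.
#' @return List of data.frames: \code{paired}, \code{lmm} (with q-values),
#'   \code{correlations}, \code{subgroup} (NULL if not estimable).
#' @export
longitudinal_table <- function(cohort_table, meta, arm = "patient",
                               value = "mean",
                               covariates = c("age", "sex", "lesion_load",
                                              "dmt"),
                               interactions = character()) {
  tab <- cohort_table[cohort_table$arm == arm, ]
  if (nrow(tab) == 0L) stop("no rows for arm '", arm, "'")
  tps <- unique(tab$timepoint)
  if (length(tps) != 2L) stop("need exactly two timepoints")

  paired <- list(); lmm <- list(); deltas <- list()
  for (region in unique(tab$region)) {
    for (metric in unique(tab$metric)) {
      sub <- tab[tab$metric == metric & tab$region == region, ]
      if (nrow(sub) == 0L) next
      w <- reshape_pairs(sub, tps, value)
      if (nrow(w) < 2L) next
      pt_row <- paired_t(w$t1, w$t2)
      paired[[length(paired) + 1L]] <-
        cbind(data.frame(metric = metric, region = region), pt_row)
      deltas[[region]][[metric]] <-
        setNames(w$t2 - w$t1, w$subject)

      long <- data.frame(
        subject = rep(w$subject, 2L),
        time = rep(c(0, 1), each = nrow(w)),
        value = c(w$t1, w$t2))
      mi <- match(long$subject, meta$subject)
      long$age <- meta$age[mi]
      long$sex <- meta$sex[mi]
      long$dmt <- meta$dmt_initiated[mi]
      long$lesion_load <- meta$lesion_load_pct_icv[mi]
      lr <- fit_lmm(long, covariates = covariates,
                    interactions = interactions)
      lmm[[length(lmm) + 1L]] <-
        cbind(data.frame(metric = metric, region = region), lr)
    }
  }
  paired <- do.call(rbind, paired)
  lmm <- do.call(rbind, lmm)
  # FDR family: the per-metric time-effect p-values within each region
  lmm$q <- NA_real_
  for (region in unique(lmm$region)) {
    i <- lmm$region == region
    lmm$q[i] <- fdr_adjust(lmm$p[i])
  }

  cors <- list()
  for (region in names(deltas)) {
    ms <- names(deltas[[region]])
    if (length(ms) < 2L) next
    for (i in seq_len(length(ms) - 1L)) for (j in (i + 1L):length(ms)) {
      da <- deltas[[region]][[ms[i]]]
      db <- deltas[[region]][[ms[j]]]
      common <- intersect(names(da), names(db))
      if (length(common) < 3L) next
      cr <- change_correlation(da[common], db[common])
      cors[[length(cors) + 1L]] <- cbind(
        data.frame(metric_a = ms[i], metric_b = ms[j], region = region), cr)
    }
  }

  subgroup <- NULL
  if ("new_lesions" %in% names(meta) &&
      length(unique(meta$new_lesions[meta$arm == arm])) == 2L) {
    sg <- list()
    for (region in names(deltas)) for (metric in names(deltas[[region]])) {
      d <- deltas[[region]][[metric]]
      grp <- meta$new_lesions[match(names(d), meta$subject)]
      if (sum(grp) >= 2L && sum(!grp) >= 2L) {
        sg[[length(sg) + 1L]] <- cbind(
          data.frame(metric = metric, region = region),
          subgroup_welch(d, grp))
      }
    }
    if (length(sg)) {
      subgroup <- do.call(rbind, sg)
      subgroup$q <- fdr_adjust(subgroup$p)
    }
  }

  list(paired = paired, lmm = lmm,
       correlations = if (length(cors)) do.call(rbind, cors) else NULL,
       subgroup = subgroup)
}

#' Running tally of cohort exclusions
#'
#' Bookkeeping helper: starting from the number of enrolled subjects, applies
#' a sequence of exclusion counts and reports the remaining sample after each
#' step.
#'
#' @param n_enrolled subjects enrolled.
#' @param exclusions named numeric vector of subjects removed at each step.
#' @return data.frame: step, removed, remaining; attribute aside, the final
#'   sample is \code{tail(result$remaining, 1)}.
#' @examples
#' exclusion_tally(100, c(screen_fail = 5, withdrew = 3))
#' @export
exclusion_tally <- function(n_enrolled, exclusions) {
  stopifnot(n_enrolled >= 0, all(exclusions >= 0))
  rem <- n_enrolled - cumsum(as.numeric(exclusions))
  if (any(rem < 0)) stop("exclusions exceed the enrolled sample")
  data.frame(step = names(exclusions) %||% seq_along(exclusions),
             removed = as.numeric(exclusions), remaining = rem)
}
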