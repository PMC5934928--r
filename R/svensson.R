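#' Percentage agreement
#'
#' Proportion of identical paired ratings, optionally relaxed to agreement
#' within a number of scale steps.
#'
#' @param table a [paired_table()].
#' @param within_steps non-negative integer; pairs whose categories differ by
#'   at most this many steps count as agreeing. `0` (default) is exact
#'   agreement, i.e. the diagonal proportion.
#' @return proportion in \[0, 1\].
#' @export
percentage_agreement <- function(table, within_steps = 0) {
  stopifnot(inherits(table, "paired_table"))
  if (table$n < 1) stop("table is empty")
  if (within_steps < 0 || within_steps != round(within_steps))
    stop("'within_steps' must be a non-negative integer")
  C <- length(table$categories)
  if (within_steps >= C) {
    warning("'within_steps' spans the whole scale; agreement is 1 by construction")
    return(1)
  }
  m <- table$counts
  sum(m[abs(row(m) - col(m)) <= within_steps]) / table$n
}

#' Relative position (RP)
#'
#' Systematic change in position between the two occasions: the difference
#' between the probability that an independent draw from the occasion-2
#' marginal exceeds one from the occasion-1 marginal and the probability of
#' the reverse. Positive values mean a shift toward higher (better)
#' categories at the second occasion; range -1 to +1. RP depends on the
#' marginals only (rank-invariant).
#'
#' @param table a [paired_table()].
#' @return value in \[-1, 1\].
#' @export
#' @examples
#' # P(improve) = 0.70, P(deteriorate) = 0.27 gives RP = 0.43
#' tab <- paired_table(rbind(0, c(27, 3, 70), 0), categories = 1:3)
#' relative_position(tab)
relative_position <- function(table) {
  m <- marginal_distributions(table)
  C <- length(m$p1)
  F1lag <- c(0, m$F1[-C])
  sum(m$p2 * F1lag) - sum(m$p2 * (1 - m$F1))
}

#' Relative concentration (RC)
#'
#' Systematic shift in the concentration of ratings toward the centre of the
#' scale. With `c21` the probability that an occasion-2 draw lies strictly
#' between two independent occasion-1 draws (taken in order) and `c12` its
#' mirror image, RC is `kappa * (c21 - c12)`. A positive value means the
#' second-occasion ratings are more concentrated in the centre; range -1 to
#' +1 under the default normalisation.
#'
#' @param table a [paired_table()].
#' @param kappa positive normalising constant. The default 4 makes RC reach
#'   +1 in the maximally concentrated configuration (all occasion-2 mass
#'   strictly between a half/half split of occasion-1 mass).
#' @return value in \[-1, 1\].
#' @export
relative_concentration <- function(table, kappa = 4) {
  if (kappa <= 0) stop("'kappa' must be positive")
  m <- marginal_distributions(table)
  C <- length(m$p1)
  F1lag <- c(0, m$F1[-C])
  F2lag <- c(0, m$F2[-C])
  c21 <- sum(m$p2 * F1lag * (1 - m$F1))
  c12 <- sum(m$p1 * F2lag * (1 - m$F2))
  kappa * (c21 - c12)
}

#' Augmented mean ranks
#'
#' Mean ranks of the subjects in each cell under the augmented ranking:
#' subjects are ordered primarily by one occasion's category with ties broken
#' by the other occasion's category, and subjects sharing a cell receive the
#' cell's mid-rank. `rbar1` ranks with respect to occasion 1 (ties by
#' occasion 2), `rbar2` the reverse. Defined only for non-empty cells (NA
#' elsewhere).
#'
#' @param table a [paired_table()].
#' @return object of class `augmented_ranks`: list of two `C x C` matrices
#'   `rbar1`, `rbar2`.
#' @export
augmented_mean_ranks <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  if (table$n < 1) stop("table is empty")
  cnt <- table$counts
  C <- nrow(cnt)
  rowcum <- c(0, cumsum(rowSums(cnt)))[seq_len(C)]       # subjects in rows < i
  colcum <- c(0, cumsum(colSums(cnt)))[seq_len(C)]       # subjects in cols < j
  within_row <- t(apply(cnt, 1, function(x) c(0, cumsum(x))[seq_len(C)]))
  within_col <- apply(cnt, 2, function(x) c(0, cumsum(x))[seq_len(C)])
  rbar1 <- matrix(rowcum, C, C) + within_row + (cnt + 1) / 2
  rbar2 <- matrix(colcum, C, C, byrow = TRUE) + within_col + (cnt + 1) / 2
  rbar1[cnt == 0] <- NA_real_
  rbar2[cnt == 0] <- NA_real_
  structure(list(rbar1 = rbar1, rbar2 = rbar2), class = "augmented_ranks")
}

#' Relative rank variance (RV)
#'
#' Individual variability in ranks between the two occasions:
#' `RV = (6 / n^3) * sum counts[i,j] * (rbar1[i,j] - rbar2[i,j])^2` over
#' non-empty cells. RV is 0 exactly for rank-transformable patterns (all
#' paired change explained by a common monotone shift, including purely
#' diagonal tables); values above about 0.2 indicate individual departures
#' from a common pattern of change.
#'
#' @param table a [paired_table()].
#' @param warn_threshold warn when RV exceeds this value (default 0.20, the
#'   conventional heterogeneity flag); `NULL` disables the warning.
#' @return non-negative value. The nominal range is 0 to 1; values above 1
#'   (extreme reversal patterns) are reported unclipped with a warning.
#' @export
relative_rank_variance <- function(table, warn_threshold = 0.20) {
  ar <- augmented_mean_ranks(table)
  cnt <- table$counts
  n <- table$n
  rv <- 6 / n^3 * sum(cnt * (ar$rbar1 - ar$rbar2)^2, na.rm = TRUE)
  if (!is.null(warn_threshold) && rv > warn_threshold)
    warning(sprintf(paste0("RV = %.3f exceeds %.2f: indication of individual ",
                           "departures from a common pattern of change"),
                    rv, warn_threshold))
  if (rv > 1)
    warning("RV exceeds 1 (extreme reversal pattern)")
  rv
}

# Evaluate one Svensson statistic on a raw count matrix, warnings off.
svensson_stat <- function(counts, categories, statistic,
                          kappa = 4, within_steps = 0) {
  tb <- paired_table(counts, categories)
  switch(statistic,
         PA = percentage_agreement(tb, within_steps),
         RP = relative_position(tb),
         RC = relative_concentration(tb, kappa),
         RV = relative_rank_variance(tb, warn_threshold = NULL),
         stop("unknown statistic: ", statistic))
}

#' Leave-one-pair-out jackknife standard error
#'
#' For each observed pair the statistic is recomputed on the table with that
#' pair removed; all pairs in a cell give the same leave-one-out value, so
#' the loop runs over non-empty cells weighted by their counts.
#' `SE = sqrt((n - 1)/n * sum_pairs (theta_(-i) - mean theta_(-.))^2)`.
#'
#' @param table a [paired_table()] with `n >= 2`.
#' @param statistic one of `"RP"`, `"RC"`, `"RV"`, `"PA"`.
#' @param kappa,within_steps passed to the underlying statistic.
#' @return non-negative standard error.
#' @export
jackknife_se <- function(table, statistic = c("RP", "RC", "RV", "PA"),
                         kappa = 4, within_steps = 0) {
  stopifnot(inherits(table, "paired_table"))
  statistic <- match.arg(statistic)
  n <- table$n
  if (n < 2) stop("SE undefined: need at least two pairs")
  cnt <- table$counts
  cells <- which(cnt > 0, arr.ind = TRUE)
  theta <- numeric(nrow(cells))
  w <- cnt[cells]
  for (k in seq_len(nrow(cells))) {
    m <- cnt
    m[cells[k, 1], cells[k, 2]] <- m[cells[k, 1], cells[k, 2]] - 1
    theta[k] <- svensson_stat(m, table$categories, statistic,
                              kappa = kappa, within_steps = within_steps)
  }
  tbar <- sum(w * theta) / n
  sqrt((n - 1) / n * sum(w * (theta - tbar)^2))
}

#' Normal-approximation confidence interval
#'
#' `estimate +/- z(level) * se`, with optional clipping to a parameter's
#' natural range. The interval drives the significance rule: an effect is
#' significant exactly when 0 lies strictly outside the interval.
#'
#' @param estimate point estimate.
#' @param se non-negative standard error.
#' @param level confidence level in (0, 1); 0.95 gives z = 1.959964.
#' @param lower_bound,upper_bound clip the interval to a natural range
#'   (e.g. 0 for RV); defaults leave it unclipped.
#' @return numeric vector `c(low, high)`.
#' @export
confidence_interval <- function(estimate, se, level = 0.95,
                                lower_bound = -Inf, upper_bound = Inf) {
  if (level <= 0 || level >= 1) stop("confidence level must be in (0, 1)")
  if (is.na(se) || se < 0) stop("'se' must be non-negative")
  z <- stats::qnorm((1 + level) / 2)
  lo <- max(estimate - z * se, lower_bound)
  hi <- min(estimate + z * se, upper_bound)
  c(lo, hi)
}

#' Analysis configuration for Svensson summaries
#'
#' @param confidence_level level for all confidence intervals (default 0.95).
#' @param kappa relative-concentration normaliser (default 4).
#' @param within_steps agreement tolerance in scale steps for PA (default 0).
#' @param rv_warning_threshold flag RV values above this (default 0.20).
#' @param min_n_warning warn when a table has fewer pairs than this
#'   (default 12; the method remains usable down to ten-twelve subjects).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(confidence_level = 0.95, kappa = 4,
                            within_steps = 0, rv_warning_threshold = 0.20,
                            min_n_warning = 12) {
  if (confidence_level <= 0 || confidence_level >= 1)
    stop("confidence level must be in (0, 1)")
  if (kappa <= 0) stop("'kappa' must be positive")
  if (within_steps < 0 || within_steps != round(within_steps))
    stop("'within_steps' must be a non-negative integer")
  structure(list(confidence_level = confidence_level, kappa = kappa,
                 within_steps = within_steps,
                 rv_warning_threshold = rv_warning_threshold,
                 min_n_warning = min_n_warning),
            class = "analysis_config")
}

#' Full Svensson analysis of one paired table
#'
#' Computes PA, RP, RC and RV with jackknife standard errors,
#' normal-approximation confidence intervals and significance flags (0
#' strictly outside the interval). The RV interval is clipped below at 0.
#'
#' @param table a [paired_table()] with `n >= 2`.
#' @param config an [analysis_config()].
#' @return object of class `svensson_result`.
#' @export
svensson_analysis <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "paired_table"))
  n <- table$n
  if (n < 2) stop("need at least two pairs")
  if (n < config$min_n_warning)
    warning(sprintf("only %d pairs: below the recommended minimum of %d subjects",
                    as.integer(n), config$min_n_warning))
  pa <- percentage_agreement(table, config$within_steps)
  rp <- relative_position(table)
  rc <- relative_concentration(table, config$kappa)
  rv <- relative_rank_variance(table, config$rv_warning_threshold)
  se_rp <- jackknife_se(table, "RP")
  se_rc <- jackknife_se(table, "RC", kappa = config$kappa)
  se_rv <- jackknife_se(table, "RV")
  lvl <- config$confidence_level
  ci_rp <- confidence_interval(rp, se_rp, lvl)
  ci_rc <- confidence_interval(rc, se_rc, lvl)
  ci_rv <- confidence_interval(rv, se_rv, lvl, lower_bound = 0)
  sig <- function(ci) ci[1] > 0 || ci[2] < 0
  structure(list(n = n, pa = pa,
                 rp = rp, se_rp = se_rp, ci_rp = ci_rp, significant_rp = sig(ci_rp),
                 rc = rc, se_rc = se_rc, ci_rc = ci_rc, significant_rc = sig(ci_rc),
                 rv = rv, se_rv = se_rv, ci_rv = ci_rv, significant_rv = sig(ci_rv),
                 level = lvl),
            class = "svensson_result")
}

#' @export
print.svensson_result <- function(x, digits = 3, ...) {
  cat(sprintf("Svensson analysis of paired ordinal data (n = %d pairs)\n",
              as.integer(x$n)))
  cat(sprintf("  PA  %.0f%%\n", 100 * x$pa))
  fmt <- function(name, est, se, ci, sig)
    cat(sprintf("  %-3s %+.*f  SE %.*f  %d%% CI (%+.*f, %+.*f)%s\n",
                name, digits, est, digits, se, round(100 * x$level),
                digits, ci[1], digits, ci[2], if (sig) "  *" else ""))
  fmt("RP", x$rp, x$se_rp, x$ci_rp, x$significant_rp)
  fmt("RC", x$rc, x$se_rc, x$ci_rc, x$significant_rc)
  fmt("RV", x$rv, x$se_rv, x$ci_rv, x$significant_rv)
  if (x$significant_rp || x$significant_rc || x$significant_rv)
    cat("  * interval excludes zero\n")
  invisible(x)
}

#' One-row data frame view of a Svensson result
#'
#' Column layout mirrors the reliability/responsiveness report tables:
#' PA, then estimate/SE/CI triplets for RP, RC and RV with significance
#' flag columns.
#'
#' @param result a [svensson_analysis()] result.
#' @return one-row data frame.
#' @export
svensson_row <- function(result) {
  stopifnot(inherits(result, "svensson_result"))
  data.frame(n = as.integer(result$n),
             PA = result$pa,
             RP = result$rp, RP_SE = result$se_rp,
             RP_CI_low = result$ci_rp[1], RP_CI_high = result$ci_rp[2],
             RP_significant = result$significant_rp,
             RC = result$rc, RC_SE = result$se_rc,
             RC_CI_low = result$ci_rc[1], RC_CI_high = result$ci_rc[2],
             RC_significant = result$significant_rc,
             RV = result$rv, RV_SE = result$se_rv,
             RV_CI_low = result$ci_rv[1], RV_CI_high = result$ci_rv[2],
             RV_significant = result$significant_rv,
             stringsAsFactors = FALSE)
}
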