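#' Study configuration
#'
#' Bundles the eligibility window, scoring options and analysis settings for
#' one cohort analysis. The mode only switches the default window and the
#' hypothesis label; the computations are identical.
#'
#' @param mode `"reliability"` (default window 7-17 days) or
#'   `"responsiveness"` (default window 50-70 days).
#' @param window_days inclusive `c(min, max)` day window between occasions;
#'   NULL takes the mode default.
#' @param aggregator,missing_policy passed to [score_cohort()].
#' @param analysis an [analysis_config()].
#' @return list of class `study_config`.
#' @export
study_config <- function(mode = c("reliability", "responsiveness"),
                         window_days = NULL,
                         aggregator = "mean",
                         missing_policy = "complete_only",
                         analysis = analysis_config()) {
  mode <- match.arg(mode)
  if (is.null(window_days))
    window_days <- switch(mode, reliability = c(7, 17),
                          responsiveness = c(50, 70))
  if (window_days[1] > window_days[2]) stop("window min must not exceed max")
  structure(list(mode = mode, window_days = as.integer(window_days),
                 aggregator = aggregator, missing_policy = missing_policy,
                 analysis = analysis),
            class = "study_config")
}

#' Eligibility filtering by completion-date window
#'
#' Keeps patients whose day difference between the two occasions lies in the
#' inclusive window and logs each exclusion with its day count.
#'
#' @param cohort wide cohort data frame with `patient_id`, `occasion`
#'   (`baseline`/`followup`) and `date`; exactly one record per occasion per
#'   patient.
#' @param window inclusive `c(min, max)` in days.
#' @return list with `eligible` (cohort rows of eligible patients),
#'   `exclusions` (data frame `patient_id`, `days`) and `days` (named day
#'   difference per patient).
#' @export
filter_by_window <- function(cohort, window) {
  need <- c("patient_id", "occasion", "date")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  cohort$date <- as.Date(cohort$date)
  tab <- table(cohort$patient_id, factor(cohort$occasion,
                                         levels = c("baseline", "followup")))
  if (any(tab != 1))
    stop("each patient must have exactly one baseline and one followup record")
  base <- cohort[cohort$occasion == "baseline", ]
  foll <- cohort[cohort$occasion == "followup", ]
  foll <- foll[match(base$patient_id, foll$patient_id), ]
  days <- as.integer(foll$date - base$date)
  names(days) <- base$patient_id
  if (any(days < 0))
    stop("negative day difference: occasions appear mislabeled")
  ok <- days >= window[1] & days <= window[2]
  list(eligible = cohort[cohort$patient_id %in% base$patient_id[ok], ],
       exclusions = data.frame(patient_id = base$patient_id[!ok],
                               days = days[!ok], row.names = NULL,
                               stringsAsFactors = FALSE),
       days = days)
}

#' Triangle summary of a paired table
#'
#' Counts and whole-rounded percents of pairs on the diagonal (same rating),
#' in the upper triangle (follow-up category higher: improved, since higher
#' = better) and in the lower triangle (worsened).
#'
#' @param table a [paired_table()].
#' @return data frame with columns `outcome`, `n`, `percent`.
#' @export
triangle_summary <- function(table) {
  m <- table$counts
  same <- sum(diag(m))
  improved <- sum(m[row(m) < col(m)])
  worsened <- sum(m[row(m) > col(m)])
  data.frame(outcome = c("same", "improved", "worsened"),
             n = c(same, improved, worsened),
             percent = round(100 * c(same, improved, worsened) / table$n),
             stringsAsFactors = FALSE)
}

#' Build a paired table from triangle totals
#'
#' Places given numbers of agreeing, improved and worsened pairs into a
#' `C x C` table (diagonal, first superdiagonal and first subdiagonal,
#' distributed round-robin). The placement within each triangle is
#' arbitrary, but percentage agreement and the triangle summary depend only
#' on the triangle totals.
#'
#' @param n_same,n_improved,n_worsened pair counts.
#' @param n_categories scale size (default 5).
#' @return a [paired_table()].
#' @export
table_from_triangle_counts <- function(n_same, n_improved, n_worsened,
                                       n_categories = 5) {
  C <- n_categories
  m <- matrix(0, C, C)
  spread <- function(total, cells) {
    k <- nrow(cells)
    each <- total %/% k
    extra <- total %% k
    cnt <- rep(each, k) + (seq_len(k) <= extra)
    cbind(cells, cnt)
  }
  put <- function(m, placed) {
    m[placed[, 1:2, drop = FALSE]] <- m[placed[, 1:2, drop = FALSE]] + placed[, 3]
    m
  }
  m <- put(m, spread(n_same, cbind(1:C, 1:C)))
  m <- put(m, spread(n_improved, cbind(1:(C - 1), 2:C)))
  m <- put(m, spread(n_worsened, cbind(2:C, 1:(C - 1))))
  paired_table(m, categories = seq_len(C))
}

#' Health-change cross-tabulation of a scored cohort
#'
#' Builds the 5x5 paired table of the ordinal Health-change item
#' (reverse-recoded, higher = better) over patients with the item present at
#' both occasions, plus the same/improved/worsened triangle summary.
#'
#' @param scored output of [score_cohort()] holding both occasions.
#' @return list with `table` (a [paired_table()] over categories 1..5),
#'   `summary` (see [triangle_summary()]) and `n` complete pairs.
#' @export
health_change_crosstab <- function(scored) {
  base <- scored[scored$occasion == "baseline", ]
  foll <- scored[scored$occasion == "followup", ]
  foll <- foll[match(base$patient_id, foll$patient_id), ]
  tab <- build_paired_table(base$health_change, foll$health_change,
                            categories = 1:5)
  list(table = tab, summary = triangle_summary(tab), n = tab$n)
}

#' Paired table from paired subscale scores
#'
#' The ordered category set is the pooled sorted unique score values across
#' both occasions (rank-invariance of the Svensson measures makes the
#' fineness of the category set harmless).
#'
#' @param score1,score2 numeric score vectors, pairwise by patient; pairs
#'   with a missing value are dropped.
#' @return a [paired_table()].
#' @export
scores_to_paired_table <- function(score1, score2) {
  keep <- !(is.na(score1) | is.na(score2))
  if (!any(keep)) stop("no complete pairs")
  cats <- sort(unique(c(score1[keep], score2[keep])))
  if (length(cats) < 2) cats <- c(cats, cats + 1)   # degenerate: pad scale
  build_paired_table(score1[keep], score2[keep], categories = cats)
}

# Subscale score means with normal-approximation CIs, per occasion.
subscale_means <- function(scored, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  subscales <- names(rand36_subscales())
  res <- list()
  for (occ in c("baseline", "followup")) {
    sub <- scored[scored$occasion == occ, ]
    for (s in subscales) {
      v <- sub[[s]]
      v <- v[!is.na(v)]
      m <- mean(v)
      half <- z * stats::sd(v) / sqrt(length(v))
      res[[length(res) + 1]] <- data.frame(
        subscale = s, occasion = occ, n = length(v), mean = m,
        ci_low = m - half, ci_high = m + half, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Ordinal alpha per subscale
#'
#' Items are recoded to the common higher-is-better orientation before
#' estimation (a strictly monotone relabelling per item, so only the
#' orientation of reverse-scored items is affected).
#'
#' @param cohort wide cohort data frame with raw items `q1`..`q36`.
#' @param occasion occasion(s) whose responses enter the estimation
#'   (default baseline only; pass both to pool occasions).
#' @return data frame `subscale`, `n_items`, `n`, `alpha`, `mean_rho`;
#'   subscales whose estimation fails get NA with a warning.
#' @export
subscale_alphas <- function(cohort, occasion = "baseline") {
  sub <- cohort[cohort$occasion %in% occasion, ]
  map <- rand36_subscales()
  recode <- rand36_recode_table()
  res <- lapply(names(map), function(s) {
    X <- sub[paste0("q", map[[s]])]
    for (j in seq_along(map[[s]]))
      X[[j]] <- recode_item(map[[s]][j], X[[j]], recode)
    a <- tryCatch(suppressWarnings(ordinal_alpha(X)), error = function(e) e)
    if (inherits(a, "error")) {
      warning(sprintf("alpha for %s failed: %s", s, conditionMessage(a)))
      data.frame(subscale = s, n_items = length(map[[s]]), n = NA_integer_,
                 alpha = NA_real_, mean_rho = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(subscale = s, n_items = a$k, n = a$n, alpha = a$alpha,
                 mean_rho = a$mean_offdiag, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Run a full cohort analysis
#'
#' End-to-end reproduction of the study's analysis products for one cohort:
#' eligibility filtering, completeness, subscale score means, ordinal
#' alphas, the Health-change cross-tabulation with its Svensson analysis,
#' per-subscale Svensson tables on paired subscale scores, and ROC point
#' exports, all written as CSV under `out_dir` together with a JSON run
#' manifest. Output is deterministic for a given cohort and configuration.
#'
#' @param cohort wide cohort data frame (both occasions).
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param compute_alpha set FALSE to skip the (slower) per-subscale alpha
#'   estimation.
#' @return invisible list with all computed tables: `eligibility`,
#'   `completeness`, `means`, `alphas`, `health_change` (table, summary and
#'   `svensson` result row), `svensson` (per-subscale rows), `roc` (named
#'   list of ROC point frames) and `manifest`.
#' @export
run_study <- function(cohort, config = study_config(), out_dir = NULL,
                      compute_alpha = TRUE) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("empty input cohort")
  stopifnot(inherits(config, "study_config"))
  flt <- filter_by_window(cohort, config$window_days)
  if (nrow(flt$eligible) == 0) stop("no patients inside the eligibility window")
  scored <- score_cohort(flt$eligible, aggregator = config$aggregator,
                         missing_policy = config$missing_policy)
  completeness <- completeness_summary(flt$eligible)
  means <- subscale_means(scored, level = config$analysis$confidence_level)
  alphas <- if (compute_alpha) subscale_alphas(flt$eligible) else NULL
  hc <- health_change_crosstab(scored)
  hc_sv <- suppressWarnings(svensson_analysis(hc$table, config$analysis))
  base <- scored[scored$occasion == "baseline", ]
  foll <- scored[scored$occasion == "followup", ]
  foll <- foll[match(base$patient_id, foll$patient_id), ]
  roc <- list(health_change = roc_points(hc$table))
  sv_rows <- list()
  for (s in names(rand36_subscales())) {
    tab <- scores_to_paired_table(base[[s]], foll[[s]])
    res <- suppressWarnings(svensson_analysis(tab, config$analysis))
    sv_rows[[s]] <- cbind(data.frame(subscale = s, stringsAsFactors = FALSE),
                          svensson_row(res))
    roc[[s]] <- roc_points(tab)
  }
  svensson <- do.call(rbind, c(sv_rows, list(make.row.names = FALSE)))
  manifest <- list(
    package = "svensson36",
    version = as.character(utils::packageVersion("svensson36")),
    mode = config$mode,
    window_days = config$window_days,
    aggregator = config$aggregator,
    missing_policy = config$missing_policy,
    confidence_level = config$analysis$confidence_level,
    n_input_patients = length(flt$days),
    n_eligible = length(flt$days) - nrow(flt$exclusions),
    n_excluded = nrow(flt$exclusions),
    n_health_change_pairs = as.integer(hc$n))
  out <- list(eligibility = flt, scored = scored, completeness = completeness,
              means = means, alphas = alphas,
              health_change = list(table = hc$table, summary = hc$summary,
                                   svensson = hc_sv),
              svensson = svensson, roc = roc, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    w(flt$exclusions, "exclusions.csv")
    w(completeness, "completeness.csv")
    w(means, "subscale_means.csv")
    if (!is.null(alphas)) w(alphas, "alpha.csv")
    utils::write.csv(as.data.frame(hc$table$counts),
                     file.path(out_dir, "health_change_table.csv"))
    w(hc$summary, "health_change_summary.csv")
    w(cbind(data.frame(variable = "health_change"), svensson_row(hc_sv)),
      "health_change_svensson.csv")
    w(svensson, "svensson_subscales.csv")
    for (v in names(roc)) w(roc[[v]], sprintf("roc_%s.csv", v))
    manifest$config_hash <- unname(config_hash(config))
    manifest$files <- sort(setdiff(list.files(out_dir), "manifest.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest <- manifest
  }
  invisible(out)
}

# md5 of the deparsed configuration (stable across sessions)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(lapply(unclass(config), unclass)), tmp)
  tools::md5sum(tmp)
}
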