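#' RAND-36 item recode table
#'
#' The standard RAND scoring recode: every raw response (on the item's native
#' 2, 3, 5 or 6 point scale) maps to a value in 0..100 with higher = better
#' health. Shipped as an editable CSV configuration (columns `item`, `raw`,
#' `score`) so scoring dialects can be swapped without code changes.
#'
#' @param file path to an alternative recode CSV; default is the packaged
#'   RAND-standard table.
#' @return data frame with columns `item`, `raw`, `score`.
#' @export
rand36_recode_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "rand36_recode.csv", package = "svensson36",
                        mustWork = TRUE)
  df <- utils::read.csv(file)
  if (!all(c("item", "raw", "score") %in% names(df)))
    stop("recode table needs columns item, raw, score")
  if (!setequal(unique(df$item), 1:36))
    stop("recode table must cover items 1..36")
  df
}

# item -> number of response choices, derived from the recode table
rand36_choice_counts <- function(recode = rand36_recode_table()) {
  vapply(1:36, function(i) max(recode$raw[recode$item == i]), numeric(1))
}

# items whose raw scale runs best-to-worst (raw 1 recodes highest)
rand36_reverse_items <- function(recode = rand36_recode_table()) {
  which(vapply(1:36, function(i) {
    s <- recode[recode$item == i, ]
    s$score[s$raw == 1] > s$score[s$raw == max(s$raw)]
  }, logical(1)))
}

#' RAND-36 subscale map
#'
#' The eight subscales and their member items. Item 2 (Health change) belongs
#' to no subscale; it is carried separately as an ordinal single item.
#'
#' @return named list of item-number vectors.
#' @export
rand36_subscales <- function() {
  list(physical_functioning = 3:12,
       role_physical        = 13:16,
       pain                 = c(21, 22),
       general_health       = c(1, 33, 34, 35, 36),
       energy_fatigue       = c(23, 27, 29, 31),
       social_functioning   = c(20, 32),
       role_emotional       = 17:19,
       emotional_wellbeing  = c(24, 25, 26, 28, 30))
}

#' Recode raw item responses to the 0-100 scale
#'
#' @param item item number(s) in 1..36 (recycled against `raw`).
#' @param raw raw response(s) on the item's native scale; NA passes through.
#' @param recode recode table, see [rand36_recode_table()].
#' @return recoded value(s) in 0..100, higher = better health.
#' @export
#' @examples
#' recode_item(3, 1:3)   # 0, 50, 100
#' recode_item(21, 1)    # 100 (reverse-scored item)
recode_item <- function(item, raw, recode = rand36_recode_table()) {
  k <- max(length(item), length(raw))
  item <- rep_len(item, k)
  raw <- rep_len(raw, k)
  map <- stats::setNames(recode$score, paste(recode$item, recode$raw))
  out <- unname(map[paste(item, raw)])
  bad <- which(is.na(out) & !is.na(raw))
  if (length(bad))
    stop(sprintf("invalid response %s for item %s", raw[bad[1]], item[bad[1]]))
  out
}

# Recode a subjects x 36 raw response matrix and aggregate to subscales.
# Returns a data.frame with the eight subscale scores and health_change.
score_matrix <- function(raw, aggregator = c("mean", "median"),
                         missing_policy = c("complete_only", "half_rule"),
                         recode = rand36_recode_table()) {
  aggregator <- match.arg(aggregator)
  missing_policy <- match.arg(missing_policy)
  raw <- as.matrix(raw)
  if (ncol(raw) != 36) stop("expected 36 item columns")
  nmax <- rand36_choice_counts(recode)
  rec <- matrix(NA_real_, nrow(raw), 36)
  for (i in 1:36) {
    v <- raw[, i]
    ok <- is.na(v) | (v %in% recode$raw[recode$item == i])
    if (!all(ok))
      stop(sprintf("invalid response %s for item %d (scale 1..%d)",
                   v[!ok][1], i, nmax[i]))
    rec[, i] <- recode_item(rep(i, length(v)), v, recode)
  }
  map <- rand36_subscales()
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (s in names(map)) {
    sub <- rec[, map[[s]], drop = FALSE]
    agg <- if (aggregator == "mean") rowMeans(sub, na.rm = TRUE)
           else apply(sub, 1, stats::median, na.rm = TRUE)
    n_answered <- rowSums(!is.na(sub))
    agg[is.nan(agg)] <- NA
    if (missing_policy == "complete_only") {
      agg[n_answered < ncol(sub)] <- NA
    } else {
      agg[n_answered < ncol(sub) / 2] <- NA
    }
    out[[s]] <- agg
  }
  # Health change kept as an ordinal category, reverse-recoded so higher = better
  hc <- raw[, 2]
  out$health_change <- ifelse(is.na(hc), NA_real_, 6 - hc)
  out
}

#' Score one subscale for a single record
#'
#' @param responses numeric vector of 36 raw item responses (NA = missing).
#' @param subscale one of the names in [rand36_subscales()].
#' @param aggregator `"mean"` (the standard RAND rule) or `"median"`.
#' @param missing_policy `"complete_only"` (default: the score is missing if
#'   any member item is missing) or `"half_rule"` (score over answered items
#'   when at least half are answered, for RAND compatibility).
#' @param recode recode table.
#' @return score in \[0, 100\] or NA.
#' @export
score_subscale <- function(responses, subscale,
                           aggregator = c("mean", "median"),
                           missing_policy = c("complete_only", "half_rule"),
                           recode = rand36_recode_table()) {
  subscale <- match.arg(subscale, names(rand36_subscales()))
  scores <- score_matrix(matrix(responses, 1, 36), aggregator = aggregator,
                         missing_policy = missing_policy, recode = recode)
  scores[[subscale]][1]
}

#' Score all subscales plus the Health-change item for a single record
#'
#' @inheritParams score_subscale
#' @return named numeric vector: eight subscale scores in \[0, 100\] and
#'   `health_change`, the reverse-recoded ordinal item 2 (1..5, higher =
#'   better), kept as a category rather than a 0-100 score.
#' @export
score_all <- function(responses, aggregator = c("mean", "median"),
                      missing_policy = c("complete_only", "half_rule"),
                      recode = rand36_recode_table()) {
  scores <- score_matrix(matrix(responses, 1, 36), aggregator = aggregator,
                         missing_policy = missing_policy, recode = recode)
  unlist(scores[1, ])
}

#' Score a wide cohort table
#'
#' @param cohort data frame with columns `patient_id`, `group`, `occasion`,
#'   `date` and `q1`..`q36` (NA or blank = missing).
#' @inheritParams score_subscale
#' @return data frame with the identifier columns followed by the eight
#'   subscale scores and `health_change`.
#' @export
score_cohort <- function(cohort, aggregator = c("mean", "median"),
                         missing_policy = c("complete_only", "half_rule"),
                         recode = rand36_recode_table()) {
  qcols <- paste0("q", 1:36)
  if (!all(qcols %in% names(cohort)))
    stop("cohort must have columns q1..q36")
  idcols <- intersect(c("patient_id", "group", "occasion", "date"), names(cohort))
  scores <- score_matrix(cohort[qcols], aggregator = aggregator,
                         missing_policy = missing_policy, recode = recode)
  cbind(cohort[idcols], scores)
}

#' Per-subscale completeness of a paired cohort
#'
#' Number and percent of patients with no missing member item at both
#' occasions, per subscale and for the Health-change item. Patients without
#' exactly one record per occasion are excluded with a warning.
#'
#' @param cohort wide cohort data frame (see [score_cohort()]) holding both
#'   occasions.
#' @return data frame with columns `subscale`, `n_items`, `n_complete`,
#'   `percent` (whole-percent rounding).
#' @export
completeness_summary <- function(cohort) {
  qcols <- paste0("q", 1:36)
  if (!all(qcols %in% names(cohort)))
    stop("cohort must have columns q1..q36")
  tab <- table(cohort$patient_id, cohort$occasion)
  paired_ids <- rownames(tab)[rowSums(tab == 1) == 2 & rowSums(tab) == 2]
  dropped <- setdiff(unique(cohort$patient_id), paired_ids)
  if (length(dropped))
    warning("excluding ", length(dropped), " unpaired patient(s): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  sub <- cohort[cohort$patient_id %in% paired_ids, ]
  miss <- is.na(as.matrix(sub[qcols]))
  map <- c(rand36_subscales(), list(health_change = 2))
  n_pairs <- length(paired_ids)
  res <- lapply(names(map), function(s) {
    items <- map[[s]]
    any_miss <- rowSums(miss[, items, drop = FALSE]) > 0
    complete_by_patient <- tapply(any_miss, sub$patient_id, function(x) !any(x))
    n_complete <- sum(complete_by_patient[paired_ids])
    data.frame(subscale = s, n_items = length(items),
               n_complete = n_complete,
               percent = round(100 * n_complete / n_pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_pairs") <- n_pairs
  out
}
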