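#' Generate paired ordinal ratings from a latent test-retest model
#'
#' Each subject carries a standard-normal trait `theta`; the occasion-`t`
#' latent is `z_t = sqrt(r) * theta + sqrt(1 - r) * eps_t + delta * 1(t = 2)`
#' and is cut at the supplied thresholds into categories `1..C`. `r` is the
#' latent test-retest correlation; `delta` a second-occasion improvement
#' shift in latent (standard-deviation) units.
#'
#' @param n number of subjects.
#' @param thresholds strictly increasing cut points (length C - 1).
#' @param r latent test-retest correlation in \[0, 1\].
#' @param delta second-occasion latent shift (0 for a stable reliability
#'   design, > 0 for an improving responsiveness design).
#' @param seed optional integer seed (set before drawing when given).
#' @return data frame with integer columns `occasion1`, `occasion2`.
#' @export
#' @examples
#' generate_paired_item(5, thresholds = c(-1, 0, 1), r = 1, seed = 1)
generate_paired_item <- function(n, thresholds, r, delta = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing")
  if (r < 0 || r > 1) stop("'r' must be in [0, 1]")
  theta <- stats::rnorm(n)
  z1 <- sqrt(r) * theta + sqrt(1 - r) * stats::rnorm(n)
  z2 <- sqrt(r) * theta + sqrt(1 - r) * stats::rnorm(n) + delta
  data.frame(occasion1 = findInterval(z1, thresholds) + 1L,
             occasion2 = findInterval(z2, thresholds) + 1L)
}

#' Configuration of a synthetic two-occasion RAND-36 cohort
#'
#' Describes a latent-trait cohort: one subject-occasion factor per subscale
#' (and one for the Health-change item), item responses generated by loading
#' the factor onto each member item and thresholding to the item's native
#' RAND-36 category count, item-level MCAR missingness, and completion-date
#' offsets with optional out-of-window late returns.
#'
#' @param n_subjects number of subjects with in-window follow-up dates.
#' @param seed integer seed; mandatory for reproducibility.
#' @param retest_r latent test-retest correlation in \[0, 1\].
#' @param shift second-occasion latent improvement shift (0 = stable design).
#' @param loading factor loading of each item on its subscale factor, in
#'   \[0, 1\]; pairwise latent inter-item correlation is `loading^2`.
#' @param missing_rate item-level MCAR missingness probability in \[0, 1).
#' @param followup_offset inclusive integer day range for in-window
#'   follow-up completion dates.
#' @param n_late additional subjects whose follow-up date falls in
#'   `late_offset` (out-of-window contamination to exercise the eligibility
#'   filter).
#' @param late_offset inclusive day range for late returns.
#' @param baseline_date calendar date of the baseline occasion.
#' @param group cohort label carried into the output.
#' @param thresholds optional named list (`q1`..`q36`) of strictly increasing
#'   item threshold vectors; default equiprobable categories per item.
#' @return list of class `latent_cohort_config`.
#' @export
latent_cohort_config <- function(n_subjects, seed,
                                 retest_r = 0.8, shift = 0, loading = 0.85,
                                 missing_rate = 0.008,
                                 followup_offset = c(7, 17),
                                 n_late = 0, late_offset = c(75, 120),
                                 baseline_date = as.Date("2016-01-11"),
                                 group = "reliability",
                                 thresholds = NULL) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  if (retest_r < 0 || retest_r > 1) stop("'retest_r' must be in [0, 1]")
  if (loading < 0 || loading > 1) stop("'loading' must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  if (followup_offset[1] > followup_offset[2]) stop("invalid 'followup_offset'")
  nmax <- rand36_choice_counts()
  if (is.null(thresholds)) {
    thresholds <- lapply(nmax, function(C) stats::qnorm(seq_len(C - 1) / C))
    names(thresholds) <- paste0("q", 1:36)
  }
  for (i in 1:36) {
    tau <- thresholds[[paste0("q", i)]]
    if (length(tau) != nmax[i] - 1 || is.unsorted(tau, strictly = TRUE))
      stop(sprintf("thresholds for item %d must be %d strictly increasing values",
                   i, nmax[i] - 1))
  }
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 retest_r = retest_r, shift = shift, loading = loading,
                 missing_rate = missing_rate,
                 followup_offset = as.integer(followup_offset),
                 n_late = n_late, late_offset = as.integer(late_offset),
                 baseline_date = as.Date(baseline_date), group = group,
                 thresholds = thresholds),
            class = "latent_cohort_config")
}

#' Stable reliability-design cohort configuration
#'
#' Defaults emulate a clinically stable dialysis cohort: 84 subjects, no
#' latent shift, retest within 7-17 days.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size (default 84).
#' @param ... overrides passed to [latent_cohort_config()].
#' @export
reliability_cohort_config <- function(seed, n_subjects = 84, ...) {
  latent_cohort_config(n_subjects = n_subjects, seed = seed,
                       retest_r = 0.8, shift = 0,
                       followup_offset = c(7, 17), n_late = 0,
                       group = "reliability", ...)
}

#' Improving responsiveness-design cohort configuration
#'
#' Defaults emulate a cardiac rehabilitation cohort expected to improve over
#' 2-3 months: 97 in-window subjects, latent improvement shift 0.5, follow-up
#' within 50-70 days, plus 12 late returns (75-120 days) that the eligibility
#' window must filter out.
#'
#' @param seed integer seed.
#' @param n_subjects in-window cohort size (default 97).
#' @param ... overrides passed to [latent_cohort_config()].
#' @export
responsiveness_cohort_config <- function(seed, n_subjects = 97, ...) {
  latent_cohort_config(n_subjects = n_subjects, seed = seed,
                       retest_r = 0.6, shift = 0.5,
                       followup_offset = c(50, 70),
                       n_late = 12, late_offset = c(75, 120),
                       group = "responsiveness", ...)
}

#' Generate a wide two-occasion RAND-36 cohort
#'
#' Per latent block (each of the eight subscales plus the Health-change
#' item), the subject-occasion factor follows the test-retest model of
#' [generate_paired_item()]; each member item's latent is
#' `loading * factor + sqrt(1 - loading^2) * noise`, thresholded to the
#' item's native categories and mapped onto the raw response scale in the
#' item's documented orientation (reverse-scored items get low raw values
#' for high latent health). Deterministic given the config seed.
#'
#' @param config a [latent_cohort_config()].
#' @return wide data frame, two rows per subject (`occasion` in
#'   `baseline`/`followup`), columns `patient_id`, `group`, `occasion`,
#'   `date`, `q1`..`q36`.
#' @export
generate_rand36_cohort <- function(config) {
  stopifnot(inherits(config, "latent_cohort_config"))
  set.seed(config$seed)
  ntot <- config$n_subjects + config$n_late
  nmax <- rand36_choice_counts()
  reverse <- rand36_reverse_items()
  blocks <- c(rand36_subscales(), list(health_change = 2))
  raw <- array(NA_real_, dim = c(ntot, 36, 2))
  r <- config$retest_r
  for (b in blocks) {
    theta <- stats::rnorm(ntot)
    for (t in 1:2) {
      eta <- sqrt(r) * theta + sqrt(1 - r) * stats::rnorm(ntot) +
        config$shift * (t == 2)
      for (i in b) {
        y <- config$loading * eta +
          sqrt(1 - config$loading^2) * stats::rnorm(ntot)
        cat_good <- findInterval(y, config$thresholds[[paste0("q", i)]]) + 1L
        raw[, i, t] <- if (i %in% reverse) nmax[i] + 1L - cat_good else cat_good
      }
    }
  }
  if (config$missing_rate > 0) {
    drop <- array(stats::runif(ntot * 36 * 2) < config$missing_rate,
                  dim = dim(raw))
    raw[drop] <- NA_real_
  }
  draw_days <- function(range, n) {
    v <- seq(range[1], range[2])
    if (length(v) == 1) rep(v, n) else sample(v, n, replace = TRUE)
  }
  offsets <- c(draw_days(config$followup_offset, config$n_subjects),
               if (config$n_late > 0) draw_days(config$late_offset, config$n_late))
  ids <- sprintf("P%04d", seq_len(ntot))
  one_occ <- function(t) {
    df <- data.frame(patient_id = ids, group = config$group,
                     occasion = c("baseline", "followup")[t],
                     date = if (t == 1) rep(config$baseline_date, ntot)
                            else config$baseline_date + offsets,
                     stringsAsFactors = FALSE)
    items <- as.data.frame(raw[, , t])
    names(items) <- paste0("q", 1:36)
    cbind(df, items)
  }
  out <- rbind(one_occ(1), one_occ(2))
  out[order(out$patient_id, out$occasion), , drop = FALSE]
}

#' Read a scenario configuration from YAML or JSON
#'
#' Scenario files hold the arguments of [latent_cohort_config()] (dates as
#' ISO strings); the format is chosen by file extension.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [latent_cohort_config()].
#' @export
scenario_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  args <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path)
          else stop("unsupported scenario format: ", ext)
  if (!is.null(args$baseline_date)) args$baseline_date <- as.Date(args$baseline_date)
  do.call(latent_cohort_config, args)
}
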