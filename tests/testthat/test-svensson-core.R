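test_that("percentage agreement counts the diagonal band", {
  tab <- table_from_triangle_counts(53, 14, 16)
  expect_equal(percentage_agreement(tab), 53 / 83)
  tab2 <- table_from_triangle_counts(31, 43, 18)
  expect_equal(percentage_agreement(tab2), 31 / 92)

  all_on <- paired_table(diag(c(2, 3)), 1:2)
  expect_equal(percentage_agreement(all_on), 1)
  all_off <- paired_table(matrix(c(0, 4, 6, 0), 2, 2), 1:2)
  expect_equal(percentage_agreement(all_off), 0)
  expect_equal(percentage_agreement(all_off, within_steps = 1) |>
                 suppressWarnings(), 1)
  expect_warning(percentage_agreement(all_off, within_steps = 2),
                 "whole scale")
})

test_that("relative position reproduces the probability-difference definition", {
  # occasion 1 degenerate at category 2; occasion 2 = (0.27, 0.03, 0.70)
  tab <- paired_table(rbind(0, c(27, 3, 70), 0), categories = 1:3)
  expect_equal(relative_position(tab), 0.43)

  diag_tab <- paired_table(diag(c(3, 2, 5)), 1:3)
  expect_equal(relative_position(diag_tab), 0)

  extreme <- paired_table(matrix(c(0, 0, 5, 0), 2, 2), 1:2)
  expect_equal(relative_position(extreme), 1)

  set.seed(21)
  for (rep in 1:50) {
    tab <- random_table(C = 5)
    expect_equal(relative_position(tab), rp_oracle(tab), tolerance = 1e-12)
  }
})

test_that("relative concentration detects central concentration with the kappa = 4 norm", {
  diag_tab <- paired_table(diag(c(3, 2, 5)), 1:3)
  expect_equal(relative_concentration(diag_tab), 0)

  # half/half extremes at occasion 1, all central at occasion 2
  conc <- build_paired_table(c(1, 3), c(2, 2), categories = 1:3)
  expect_equal(relative_concentration(conc), 1)
  # and the mirrored table gives -1 (antisymmetry of the definition)
  deconc <- build_paired_table(c(2, 2), c(1, 3), categories = 1:3)
  expect_equal(relative_concentration(deconc), -1)
})

test_that("augmented mean ranks follow the mid-rank convention", {
  one_cell <- paired_table(matrix(c(0, 0, 0, 5), 2, 2), 1:2)
  ar <- augmented_mean_ranks(one_cell)
  expect_equal(ar$rbar1[2, 2], 3)
  expect_equal(ar$rbar2[2, 2], 3)

  stair <- paired_table(rbind(c(0, 2, 0), c(0, 0, 3), c(0, 0, 0)), 1:3)
  ars <- augmented_mean_ranks(stair)
  nonempty <- !is.na(ars$rbar1)
  expect_equal(ars$rbar1[nonempty], ars$rbar2[nonempty])

  set.seed(22)
  for (rep in 1:50) {
    tab <- random_table()
    ar <- augmented_mean_ranks(tab)
    o <- rank_oracle(tab)
    idx <- which(tab$counts > 0, arr.ind = TRUE)
    key <- paste(idx[, 1], idx[, 2])
    expect_equal(unname(ar$rbar1[idx]), as.numeric(o$rbar1[key]))
    expect_equal(unname(ar$rbar2[idx]), as.numeric(o$rbar2[key]))
    # count-weighted mean of mean ranks is (n + 1) / 2 on both occasions
    w <- tab$counts[idx]
    expect_equal(sum(w * ar$rbar1[idx]) / tab$n, (tab$n + 1) / 2)
    expect_equal(sum(w * ar$rbar2[idx]) / tab$n, (tab$n + 1) / 2)
  }
})

test_that("relative rank variance vanishes exactly on rank-transformable patterns", {
  expect_equal(relative_rank_variance(paired_table(diag(c(3, 1, 4)), 1:3)), 0)
  stair <- paired_table(rbind(c(0, 2, 0), c(0, 0, 3), c(0, 0, 0)), 1:3)
  expect_equal(relative_rank_variance(stair), 0)

  cross <- paired_table(matrix(c(2, 1, 1, 2), 2, 2), 1:2)
  expect_equal(relative_rank_variance(cross), 12 / 216)

  set.seed(23)
  for (rep in 1:50) {
    tab <- random_table()
    expect_equal(suppressWarnings(relative_rank_variance(tab)),
                 rv_oracle(tab), tolerance = 1e-9)
  }
})

test_that("RV above the heterogeneity threshold triggers a warning", {
  mixed <- paired_table(matrix(c(2, 3, 3, 2), 2, 2), 1:2)   # RV = 0.324
  expect_warning(relative_rank_variance(mixed), "departures")
  expect_silent(relative_rank_variance(mixed, warn_threshold = NULL))
  # full reversal exceeds the nominal 0-1 range and is reported unclipped
  reversal <- paired_table(matrix(c(0, 10, 10, 0), 2, 2), 1:2)
  expect_warning(
    expect_equal(relative_rank_variance(reversal, warn_threshold = NULL), 1.5),
    "exceeds 1")
})

test_that("jackknife SE is zero for a constant statistic", {
  one_cell <- paired_table(matrix(c(0, 0, 0, 5), 2, 2), 1:2)
  expect_equal(jackknife_se(one_cell, "PA"), 0)
  expect_error(jackknife_se(paired_table(matrix(c(1, 0, 0, 0), 2, 2), 1:2), "PA"),
               "SE undefined")
})

test_that("jackknife SE of PA equals the closed-form proportion jackknife", {
  set.seed(24)
  for (rep in 1:10) {
    tab <- random_table(n = sample(20:60, 1))
    p <- percentage_agreement(tab)
    expect_equal(jackknife_se(tab, "PA"),
                 sqrt(p * (1 - p) / (tab$n - 1)), tolerance = 1e-12)
  }
})

test_that("confidence intervals use the normal quantile and drive significance", {
  expect_equal(confidence_interval(0.5, 0, 0.95), c(0.5, 0.5))
  ci <- confidence_interval(0, 1, 0.95)
  expect_equal(ci[2] - ci[1], 2 * qnorm(0.975))
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  ci90 <- confidence_interval(0, 1, 0.90)
  expect_equal(ci90[2], 1.6449, tolerance = 1e-4)
  expect_error(confidence_interval(0, 1, 1.2), "level")
  expect_error(confidence_interval(0, -1), "non-negative")
})

test_that("svensson_analysis composes the individual measures", {
  diag_tab <- paired_table(diag(c(10, 10, 10)), 1:3)
  res <- svensson_analysis(diag_tab)
  expect_equal(res$pa, 1)
  expect_equal(res$rp, 0)
  expect_equal(res$rc, 0)
  expect_equal(res$rv, 0)
  expect_false(res$significant_rp || res$significant_rc || res$significant_rv)

  rp_tab <- paired_table(rbind(0, c(27, 3, 70), 0), categories = 1:3)
  expect_equal(suppressWarnings(svensson_analysis(rp_tab))$rp, 0.43)

  set.seed(25)
  tab <- random_table(C = 4, n = 40)
  res <- suppressWarnings(svensson_analysis(tab))
  expect_equal(res$pa, percentage_agreement(tab))
  expect_equal(res$rp, relative_position(tab))
  expect_equal(res$rc, relative_concentration(tab))
  expect_equal(res$rv, suppressWarnings(relative_rank_variance(tab)))
  expect_equal(res$se_rp, jackknife_se(tab, "RP"))
  expect_equal(res$ci_rp,
               confidence_interval(res$rp, res$se_rp, 0.95))
  # significance flag is exactly "0 outside the interval"
  for (x in c("rp", "rc", "rv")) {
    ci <- res[[paste0("ci_", x)]]
    expect_identical(res[[paste0("significant_", x)]], ci[1] > 0 || ci[2] < 0)
  }
  expect_warning(svensson_analysis(paired_table(matrix(c(2, 1, 1, 2), 2, 2), 1:2)),
                 "below the recommended minimum")
})

test_that("measures are antisymmetric or invariant under occasion swap", {
  set.seed(26)
  for (rep in 1:30) {
    tab <- random_table()
    swapped <- paired_table(t(tab$counts), tab$categories)
    expect_equal(relative_position(swapped), -relative_position(tab),
                 tolerance = 1e-12)
    expect_equal(relative_concentration(swapped), -relative_concentration(tab),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(relative_rank_variance(swapped)),
                 suppressWarnings(relative_rank_variance(tab)), tolerance = 1e-12)
    expect_equal(percentage_agreement(swapped), percentage_agreement(tab))
  }
})

test_that("measures are rank-invariant under monotone relabelling", {
  set.seed(27)
  tab <- random_table(C = 4, n = 40)
  relabeled <- paired_table(tab$counts, categories = c(10, 25, 31, 99))
  for (f in list(percentage_agreement, relative_position,
                 relative_concentration))
    expect_equal(f(relabeled), f(tab))
  expect_equal(suppressWarnings(relative_rank_variance(relabeled)),
               suppressWarnings(relative_rank_variance(tab)))
})

test_that("merging adjacent categories never increases RV", {
  set.seed(28)
  for (rep in 1:50) {
    tab <- random_table(C = sample(3:6, 1))
    rv <- suppressWarnings(relative_rank_variance(tab))
    c <- sample(length(tab$categories) - 1, 1)
    rv_merged <- suppressWarnings(relative_rank_variance(merge_categories(tab, c)))
    expect_lte(rv_merged, rv + 1e-12)
  }
})
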