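test_that("exclusion filter reproduces the planned cohort attrition", {
  sim <- simulate_cohort()
  tb <- apply_exclusions(sim)
  counts <- attr(tb, "counts")
  expect_identical(sum(counts$included), 16L)       # 18 prepared - 2 low glucose
  expect_identical(counts$analyzed[counts$group == "diabetic"], 6L)
  expect_identical(counts$analyzed[counts$group == "control"], 9L)
  # removed fish carry no rows; retained rows are unaltered
  expect_false(any(tb$status != "ok"))
  keep <- sim$table$status == "ok"
  expect_equal(tb$vad, sim$table$vad[keep])
  # with no flags the filter is the identity
  clean <- sim$table[sim$table$status == "ok", ]
  again <- apply_exclusions(clean, glucose_floor = sim$config$glucose_floor)
  expect_equal(nrow(again), nrow(clean))
  expect_equal(again$vad, clean$vad)
})

test_that("group summary computes mean and SEM", {
  tb <- tibble::tibble(group = factor(rep("control", 2)),
                       timepoint_dpw = c(4, 4), vad = c(0.2, 0.4))
  s <- group_summary(tb)
  expect_equal(s$mean, 0.3)
  expect_equal(s$sem, stats::sd(c(0.2, 0.4)) / sqrt(2))
  expect_equal(s$sem, 0.1, tolerance = 1e-3)
  # identical values -> SEM 0; single value -> flagged
  s2 <- group_summary(tibble::tibble(group = "a", timepoint_dpw = 1,
                                     vad = c(0.3, 0.3, 0.3)))
  expect_equal(s2$sem, 0)
  s3 <- group_summary(tibble::tibble(group = "a", timepoint_dpw = 1, vad = 0.3))
  expect_true(is.na(s3$sem) && !s3$sem_defined)
})

test_that("two-way ANOVA matches the textbook balanced decomposition", {
  # balanced 2 groups x 2 timepoints x 2 replicates
  tb <- tibble::tibble(
    group = factor(rep(c("control", "diabetic"), each = 4)),
    timepoint_dpw = rep(c(1, 1, 4, 4), 2),
    vad = c(0.30, 0.34, 0.50, 0.46, 0.20, 0.24, 0.28, 0.24))
  res <- two_way_anova(tb)
  y <- tb$vad
  ga <- tapply(y, tb$group, mean)                 # factor A marginal means
  gb <- tapply(y, tb$timepoint_dpw, mean)         # factor B marginal means
  cell <- tapply(y, list(tb$group, tb$timepoint_dpw), mean)
  gm <- mean(y)
  ss_a <- 4 * sum((ga - gm)^2)
  ss_b <- 4 * sum((gb - gm)^2)
  ss_ab <- 2 * sum((cell - outer(ga - gm, gb - gm, "+") - gm)^2)
  ss_e <- sum((y - cell[cbind(as.character(tb$group),
                              as.character(tb$timepoint_dpw))])^2)
  a <- res$anova
  expect_equal(a$sumsq[a$term == "group"], ss_a, tolerance = 1e-10)
  expect_equal(a$sumsq[a$term == "timepoint"], ss_b, tolerance = 1e-10)
  expect_equal(a$sumsq[a$term == "group:timepoint"], ss_ab, tolerance = 1e-10)
  expect_equal(a$sumsq[a$term == "Residuals"], ss_e, tolerance = 1e-10)
  expect_equal(sum(a$sumsq), sum((y - gm)^2), tolerance = 1e-10)  # exact split
  expect_equal(a$df, c(1, 1, 1, 4))
})

test_that("identical groups produce a null group effect", {
  vals <- c(0.2, 0.3, 0.25, 0.35)
  tb <- tibble::tibble(
    group = factor(rep(c("control", "diabetic"), each = 4)),
    timepoint_dpw = rep(c(1, 1, 4, 4), 2),
    vad = c(vals, vals))
  res <- two_way_anova(tb)
  expect_lt(res$anova$statistic[res$anova$term == "group"], 1e-20)
})

test_that("simulated cohorts detect the diabetic group effect reliably", {
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_cohort(cohort_config(seed = s))
    tb <- apply_exclusions(sim)
    res <- two_way_anova(tb)
    p <- res$anova$p_value[res$anova$term == "group"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("Bonferroni adjustment multiplies, clips and never shrinks", {
  withr::with_seed(91, {
    tb <- tibble::tibble(
      group = factor(rep(rep(c("control", "diabetic"), each = 4), 6)),
      timepoint_dpw = rep(c(0.125, 1, 4, 7, 10, 15), each = 8),
      vad = stats::runif(48, 0.1, 0.3))
  })
  pw <- bonferroni_pairwise(tb)
  expect_identical(nrow(pw), 6L)
  expect_equal(pw$p_adj, pmin(1, 6 * pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))
  # explicit family size
  pw2 <- bonferroni_pairwise(tb, m = 7)
  expect_equal(pw2$p_adj, pmin(1, 7 * pw2$p_raw))
  # identical groups -> adjusted p = 1
  tb2 <- tb; tb2$vad <- rep(rep(c(0.1, 0.2, 0.3, 0.4), 2), 6)
  expect_true(all(bonferroni_pairwise(tb2)$p_adj == 1))
  # under-replicated timepoint is skipped and flagged
  tb3 <- dplyr::filter(tb, !(timepoint_dpw == 15 & group == "diabetic")) |>
    dplyr::bind_rows(tibble::tibble(group = factor("diabetic"),
                                    timepoint_dpw = 15, vad = 0.2))
  pw3 <- bonferroni_pairwise(tb3)
  expect_false(pw3$tested[pw3$timepoint_dpw == 15])
  expect_true(is.na(pw3$p_raw[pw3$timepoint_dpw == 15]))
})

test_that("significance stars follow the three-level convention", {
  expect_identical(significance_stars(c(0.0005, 0.001, 0.002, 0.02, 0.03, 0.2)),
                   c("***", "***", "**", "*", "*", "n.s."))
  expect_true(is.na(significance_stars(NA)))
})

test_that("healing report summarizes peak, reduction and comparisons", {
  sim <- simulate_cohort()
  tb <- apply_exclusions(sim)
  rep_ <- healing_report(tb)
  expect_equal(rep_$peak$peak_dpw[rep_$peak$group == "control"], 4)
  expect_equal(rep_$peak$peak_dpw[rep_$peak$group == "diabetic"], 4)
  red <- rep_$reduction
  expect_true(all(red$reduction_pct[red$timepoint_dpw %in% c(4, 7, 10)] > 50))
  expect_s3_class(rep_$plot, "ggplot")
  expect_output(print(rep_), "Two-way ANOVA")
  # control-only cohort degenerates gracefully
  solo <- dplyr::filter(tb, group == "control")
  rep2 <- healing_report(solo)
  expect_null(rep2$reduction)
  expect_null(rep2$anova)
})
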