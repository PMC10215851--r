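#' @importFrom rlang .data
NULL

.cohort_table <- function(table) {
  if (inherits(table, "fish_cohort")) table$table else table
}

#' Apply attrition exclusion rules to a cohort table
#'
#' Removes all rows of fish that died during handling and of fish whose
#' induction-check glucose lies below the exclusion floor (failed diabetic
#' induction). Retained rows are never altered. Per-group attrition counts
#' are attached as the `"counts"` attribute: `prepared`, `excluded_low_glucose`,
#' `included` (prepared minus low-glucose exclusions), `died`, `analyzed`.
#'
#' @param table A `fish_cohort` or its tibble (columns `fish_id`, `group`,
#'   `glucose`, `status`).
#' @param glucose_floor Exclusion floor; defaults to the cohort's configured
#'   floor when a `fish_cohort` is given.
#' @return The filtered tibble with a `"counts"` attribute.
#' @export
apply_exclusions <- function(table, glucose_floor = NULL) {
  if (inherits(table, "fish_cohort") && is.null(glucose_floor))
    glucose_floor <- table$config$glucose_floor
  tb <- .cohort_table(table)
  if (is.null(glucose_floor)) stop("glucose_floor required")
  fish <- dplyr::distinct(tb, .data$fish_id, .data$group, .data$glucose, .data$status)
  fish$low <- fish$glucose < glucose_floor
  fish$dead <- fish$status == "died"
  counts <- fish |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(prepared = dplyr::n(),
                     excluded_low_glucose = sum(.data$low),
                     included = sum(!.data$low),
                     died = sum(.data$dead & !.data$low),
                     analyzed = sum(!.data$low & !.data$dead),
                     .groups = "drop")
  keep_ids <- fish$fish_id[!fish$low & !fish$dead]
  out <- dplyr::filter(tb, .data$fish_id %in% keep_ids)
  attr(out, "counts") <- counts
  out
}

#' Per-group, per-timepoint summary (mean, SEM, n)
#'
#' SEM is the sample SD divided by the square root of n; cells with a single
#' observation get `NA` SEM and are flagged.
#'
#' @param table A `fish_cohort` or tibble with `group`, `timepoint_dpw`, `vad`.
#' @return Tibble with `group`, `timepoint_dpw`, `mean`, `sem`, `n`,
#'   `sem_defined`.
#' @export
group_summary <- function(table) {
  tb <- dplyr::filter(.cohort_table(table), !is.na(.data$vad))
  if (!nrow(tb)) stop("no observations")
  tb |>
    dplyr::group_by(.data$group, .data$timepoint_dpw) |>
    dplyr::summarise(mean = mean(.data$vad),
                     sem = stats::sd(.data$vad) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sem_defined = .data$n > 1)
}

#' Two-way ANOVA of VAD on group and timepoint
#'
#' Fits `vad ~ group * timepoint` (timepoint as a factor) and computes Type II
#' sums of squares, which handle the unbalanced design that attrition
#' produces; on balanced designs Type II coincides with the textbook
#' decomposition. If the interaction leaves no residual degrees of freedom it
#' is dropped with a warning.
#'
#' @param table A `fish_cohort` or tibble with `group`, `timepoint_dpw`, `vad`.
#' @return An `anova_result`: list with `anova` (tibble: term, sumsq, df,
#'   statistic, p_value), `means` ([group_summary()]), `pairwise`
#'   ([bonferroni_pairwise()] when both groups are present), `ss_type`.
#' @export
two_way_anova <- function(table) {
  tb <- dplyr::filter(.cohort_table(table), !is.na(.data$vad))
  tb$timepoint <- factor(tb$timepoint_dpw)
  tb$group <- droplevels(factor(tb$group))
  if (nlevels(tb$group) < 2 || nlevels(tb$timepoint) < 2)
    stop("need >= 2 groups and >= 2 timepoints")
  fit <- stats::lm(vad ~ group * timepoint, data = tb)
  if (stats::df.residual(fit) == 0) {
    warning("no residual degrees of freedom for the interaction; dropping it")
    fit <- stats::lm(vad ~ group + timepoint, data = tb)
  }
  a2 <- car::Anova(fit, type = 2)
  tbl <- tibble::tibble(term = rownames(a2),
                        sumsq = a2[["Sum Sq"]],
                        df = a2[["Df"]],
                        statistic = a2[["F value"]],
                        p_value = a2[["Pr(>F)"]])
  pw <- if (nlevels(tb$group) == 2) bonferroni_pairwise(tb) else NULL
  structure(list(anova = tbl, means = group_summary(tb), pairwise = pw,
                 ss_type = "II"), class = "anova_result")
}

#' Per-timepoint Welch comparisons with Bonferroni correction
#'
#' Welch's unequal-variance two-sample t test of control vs diabetic at every
#' timepoint; adjusted p = min(1, m * p_raw) with family size m = number of
#' timepoints compared (configurable). Timepoints with fewer than two values
#' in either group are skipped and flagged.
#'
#' @param table A `fish_cohort` or tibble with `group`, `timepoint_dpw`, `vad`.
#' @param m Bonferroni family size; default the number of timepoints at which
#'   both groups have data.
#' @return Tibble: `timepoint_dpw`, `n_control`, `n_diabetic`, `mean_control`,
#'   `mean_diabetic`, `p_raw`, `p_adj`, `stars`, `tested`.
#' @export
bonferroni_pairwise <- function(table, m = NULL) {
  tb <- dplyr::filter(.cohort_table(table), !is.na(.data$vad))
  tps <- sort(unique(tb$timepoint_dpw))
  rows <- lapply(tps, function(tp) {
    a <- tb$vad[tb$timepoint_dpw == tp & tb$group == "control"]
    b <- tb$vad[tb$timepoint_dpw == tp & tb$group == "diabetic"]
    ok <- length(a) >= 2 && length(b) >= 2
    p <- if (!ok) NA_real_
    else if (stats::sd(c(a, b)) == 0 || (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                                         mean(a) == mean(b))) 1
    else tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    tibble::tibble(timepoint_dpw = tp,
                   n_control = length(a), n_diabetic = length(b),
                   mean_control = if (length(a)) mean(a) else NA_real_,
                   mean_diabetic = if (length(b)) mean(b) else NA_real_,
                   p_raw = p, tested = ok && !is.na(p))
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(m)) m <- sum(out$tested)
  out$p_adj <- pmin(1, m * out$p_raw)
  out$stars <- significance_stars(out$p_adj)
  out[, c("timepoint_dpw", "n_control", "n_diabetic", "mean_control",
          "mean_diabetic", "p_raw", "p_adj", "stars", "tested")]
}

#' Three-level significance labels
#'
#' `***` for p <= 0.001, `**` for p <= 0.003, `*` for p <= 0.03,
#' `n.s.` otherwise.
#'
#' @param p_adj Adjusted p value(s) in `[0, 1]` (NA allowed).
#' @return Character vector of labels.
#' @export
significance_stars <- function(p_adj) {
  ifelse(is.na(p_adj), NA_character_,
         ifelse(p_adj <= 0.001, "***",
                ifelse(p_adj <= 0.003, "**",
                       ifelse(p_adj <= 0.03, "*", "n.s."))))
}

#' Longitudinal wound-healing report
#'
#' Summarizes the cohort: per-group mean +/- SEM time course, the post-wound
#' timepoint of peak mean VAD per group, the percent reduction of the
#' diabetic versus control mean per timepoint, and (when both groups are
#' present) the two-way ANOVA with Bonferroni pairwise comparisons. A ggplot
#' of the time course is included. Deterministic given the table.
#'
#' @param table A `fish_cohort` or tibble with `group`, `timepoint_dpw`, `vad`.
#' @return A `healing_report`: list with `summary`, `peak`, `reduction`,
#'   `anova` (or `NULL` for a single group), `plot`.
#' @export
healing_report <- function(table) {
  tb <- dplyr::filter(.cohort_table(table), !is.na(.data$vad))
  smry <- group_summary(tb)
  post <- dplyr::filter(smry, .data$timepoint_dpw >= 0)
  peak <- post |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(group = "group", peak_dpw = "timepoint_dpw",
                  peak_mean = "mean")
  both <- nlevels(droplevels(factor(tb$group))) == 2
  reduction <- if (both) {
    tidyr::pivot_wider(post[, c("group", "timepoint_dpw", "mean")],
                       names_from = "group", values_from = "mean") |>
      dplyr::filter(!is.na(.data$control), !is.na(.data$diabetic),
                    .data$control > 0) |>
      dplyr::mutate(reduction_pct = 100 * (1 - .data$diabetic / .data$control)) |>
      dplyr::select("timepoint_dpw", "control", "diabetic", "reduction_pct")
  } else NULL
  anova <- if (both && length(unique(tb$timepoint_dpw)) >= 2)
    two_way_anova(tb) else NULL
  plot <- ggplot2::ggplot(
    smry, ggplot2::aes(x = .data$timepoint_dpw, y = .data$mean,
                       color = .data$group, group = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = "days post-wounding (-1 = pre-wound)",
                  y = "wound VAD (mean ± SEM)", color = NULL) +
    ggplot2::theme_minimal()
  structure(list(summary = smry, peak = peak, reduction = reduction,
                 anova = anova, plot = plot), class = "healing_report")
}

#' @export
print.healing_report <- function(x, ...) {
  cat("Wound-healing VAD report\n\nGroup means (mean ± SEM):\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("\nPeak of the mean VAD time course:\n")
  print(as.data.frame(x$peak), row.names = FALSE)
  if (!is.null(x$reduction)) {
    cat("\nDiabetic vs control reduction (%):\n")
    print(as.data.frame(x$reduction), row.names = FALSE)
  }
  if (!is.null(x$anova)) {
    cat(sprintf("\nTwo-way ANOVA (Type %s SS):\n", x$anova$ss_type))
    print(as.data.frame(x$anova$anova), row.names = FALSE)
    cat("\nPer-timepoint Bonferroni comparisons:\n")
    print(as.data.frame(x$anova$pairwise), row.names = FALSE)
  }
  invisible(x)
}
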