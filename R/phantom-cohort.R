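#' Cohort-simulation configuration
#'
#' Defines the simulated study: group sizes, imaging timepoints, the blood
#' glucose model used for the diabetic-induction check, and the planned
#' attrition (failed-induction low-glucose fish, handling mortality). Glucose
#' units are arbitrary (normal mean 60, hyperglycemic mean 300, SD 15); only
#' the ordering and the recovery-to-normal pattern are contractual.
#'
#' @param n_control,n_diabetic Fish prepared per group.
#' @param timepoints Imaging timepoints in dpw (`-1` = pre-wound baseline,
#'   0.125 = 3 hpw), strictly increasing.
#' @param seed Integer RNG seed.
#' @param glucose_normal_mean,glucose_normal_sd Normoglycemic distribution.
#' @param glucose_hyper_mean,glucose_hyper_sd Hyperglycemic distribution.
#' @param glucose_recovery_day Day post-injection by which diabetic glucose
#'   returns to normal.
#' @param glucose_dpi Days post-injection at which glucose is measured.
#' @param n_low_glucose Planned failed-induction (low-glucose) diabetic fish.
#' @param n_died Planned handling deaths among included diabetic fish.
#' @param glucose_floor Exclusion floor; defaults to the normal mean minus
#'   2 SD.
#' @param fish_effect_sd SD of the per-fish log-normal angiogenic effect.
#' @param measurement_sd SD of the Gaussian VAD measurement noise used when
#'   the cohort is simulated at the table level (no rendering).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_control = 9L, n_diabetic = 9L,
                          timepoints = c(-1, 0.125, 1, 4, 7, 10, 15),
                          seed = 1L,
                          glucose_normal_mean = 60, glucose_normal_sd = 15,
                          glucose_hyper_mean = 300, glucose_hyper_sd = 15,
                          glucose_recovery_day = 14,
                          glucose_dpi = c(4, 8, 14),
                          n_low_glucose = 2L, n_died = 1L,
                          glucose_floor = glucose_normal_mean - 2 * glucose_normal_sd,
                          fish_effect_sd = 0.1, measurement_sd = 0.015) {
  stopifnot(n_control >= 0, n_diabetic >= 0,
            !is.unsorted(timepoints, strictly = TRUE),
            n_low_glucose + n_died <= n_diabetic)
  structure(as.list(environment()), class = "cohort_config")
}

# draw from N(mean, sd) conditioned above `floor` (keeps the planned
# exclusion arithmetic seed-stable)
.rnorm_above <- function(n, mean, sd, floor) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= floor)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Simulate a longitudinal wound-healing cohort
#'
#' Generates the per-fish, per-timepoint cohort table with ground-truth wound
#' vessel fractions from [healing_vad_curve()], a simulated blood-glucose
#' trace per fish (hyperglycemic in successfully induced diabetic fish until
#' the recovery day, normal afterwards, with the configured number of
#' failed-induction low-glucose outliers), and the planned mortality.
#' Excluded and dead fish carry no VAD observations.
#'
#' With `render = FALSE` (default) the observed VAD is the ground truth times
#' a per-fish log-normal effect plus Gaussian measurement noise — the fast
#' table-level mode used for statistics work. With `render = TRUE` every
#' retained fish-timepoint is rendered as a phantom cube and pushed through
#' the full reconstruction pipeline ([measure_scene()]), which is tractable
#' only on small grids.
#'
#' @param config A [cohort_config()].
#' @param optics Acquisition grid for rendered scenes.
#' @param healing A [healing_params()] object.
#' @param render Render cubes and measure VAD through the pipeline.
#' @param ... Passed to [measure_scene()] when rendering.
#' @return A `fish_cohort`: list with `table` (tibble: fish_id, group,
#'   timepoint_dpw, vad_true, vad, glucose, status, scene_seed), `glucose`
#'   (tibble: fish_id, group, dpi, level), `config`, `healing`, and `enface`
#'   (named list of en face maps when rendered).
#' @export
simulate_cohort <- function(config = cohort_config(), optics = phantom_optics(),
                            healing = healing_params(), render = FALSE, ...) {
  cf <- config
  fish <- tibble::tibble(
    fish_id = c(sprintf("C%02d", seq_len(cf$n_control)),
                sprintf("D%02d", seq_len(cf$n_diabetic))),
    group = factor(rep(c("control", "diabetic"), c(cf$n_control, cf$n_diabetic)),
                   levels = c("control", "diabetic")))

  sim <- with_seed(as.integer(cf$seed), {
    di <- which(fish$group == "diabetic")
    low <- sample(di, cf$n_low_glucose)
    died <- sample(setdiff(di, low), cf$n_died)
    gl <- lapply(seq_len(nrow(fish)), function(i) {
      if (i %in% low) {
        pmax(stats::rnorm(length(cf$glucose_dpi), 20, 4), 5)
      } else if (fish$group[i] == "diabetic") {
        ifelse(cf$glucose_dpi < cf$glucose_recovery_day,
               .rnorm_above(length(cf$glucose_dpi), cf$glucose_hyper_mean,
                            cf$glucose_hyper_sd, cf$glucose_floor),
               .rnorm_above(length(cf$glucose_dpi), cf$glucose_normal_mean,
                            cf$glucose_normal_sd, cf$glucose_floor))
      } else {
        .rnorm_above(length(cf$glucose_dpi), cf$glucose_normal_mean,
                     cf$glucose_normal_sd, cf$glucose_floor)
      }
    })
    effect <- exp(stats::rnorm(nrow(fish), 0, cf$fish_effect_sd))
    noise <- matrix(stats::rnorm(nrow(fish) * length(cf$timepoints),
                                 0, cf$measurement_sd),
                    nrow(fish), length(cf$timepoints))
    list(low = low, died = died, glucose = gl, effect = effect, noise = noise)
  })

  status <- rep("ok", nrow(fish))
  status[sim$low] <- "excluded_low_glucose"
  status[sim$died] <- "died"
  glucose4 <- vapply(sim$glucose, function(g) g[which(cf$glucose_dpi == 4)[1]],
                     numeric(1))

  glucose_tbl <- tibble::tibble(
    fish_id = rep(fish$fish_id, each = length(cf$glucose_dpi)),
    group = rep(fish$group, each = length(cf$glucose_dpi)),
    dpi = rep(cf$glucose_dpi, nrow(fish)),
    level = unlist(sim$glucose))

  rows <- expand.grid(fi = seq_len(nrow(fish)), ti = seq_along(cf$timepoints))
  t_dpw <- cf$timepoints[rows$ti]
  grp <- as.character(fish$group[rows$fi])
  vad_true <- vapply(seq_len(nrow(rows)), function(r)
    healing_vad_curve(t_dpw[r], healing, grp[r]), numeric(1))
  vad_obs <- pmin(pmax(vad_true * sim$effect[rows$fi] +
                         sim$noise[cbind(rows$fi, rows$ti)], 0), 1)
  has_data <- status[rows$fi] == "ok"
  base_seed <- (as.integer(cf$seed) %% 1000L) * 1000000L
  table <- tibble::tibble(
    fish_id = fish$fish_id[rows$fi],
    group = fish$group[rows$fi],
    timepoint_dpw = t_dpw,
    vad_true = ifelse(has_data, vad_true, NA_real_),
    vad = ifelse(has_data, vad_obs, NA_real_),
    glucose = glucose4[rows$fi],
    status = status[rows$fi],
    scene_seed = base_seed + rows$fi * 1000L + rows$ti * 10L)
  table <- dplyr::arrange(table, .data$fish_id, .data$timepoint_dpw)

  out <- structure(list(table = table, glucose = glucose_tbl,
                        config = cf, healing = healing, enface = NULL),
                   class = "fish_cohort")
  if (render) {
    keep <- table$status == "ok"
    maps <- list()
    measured <- table$vad
    for (r in which(keep)) {
      ms <- measure_scene(as.character(table$group[r]), table$timepoint_dpw[r],
                          seed = table$scene_seed[r], optics = optics,
                          healing = healing, ...)
      measured[r] <- ms$vad
      maps[[paste(table$fish_id[r], table$timepoint_dpw[r], sep = "_")]] <- ms$enface
    }
    out$table$vad <- measured
    out$enface <- maps
  }
  out
}
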