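#' Generate differentiation dose-response conditions over level and duration
#'
#' Emulates the signaling-control experiments: signaling is an idealized step
#' of a given level (baseline-subtracted N:C units) held for a given duration
#' (hours), so the signaling integral of a condition is `level x duration`.
#' Each condition's differentiated fraction is a binomial sample of
#' `n_per_condition` cells whose single-cell differentiation probability
#' follows the chosen fate model:
#'
#' * `"integral"`: logistic threshold on the integral (width
#'   `logistic_width`), the integral-control model;
#' * `"level_duration"`: the classic alternative -- differentiation requires
#'   the level to exceed a level threshold AND the duration to exceed a
#'   duration threshold (both as logistics), with no integral dependence.
#'
#' @param levels signaling levels of the conditions.
#' @param durations signaling durations (hours); the full grid
#'   `levels x durations` is generated.
#' @param n_per_condition cells per condition.
#' @param model `"integral"` or `"level_duration"`.
#' @param integral_threshold,logistic_width integral model parameters.
#' @param level_threshold,level_width,duration_threshold,duration_width
#'   level+duration model parameters.
#' @param seed integer seed.
#' @return data.frame with one row per condition: `level`, `duration`,
#'   `sigma` (integral), `fraction` differentiated, `n`.
#' @export
gen_dose_response <- function(levels = c(1, 0.7),
                              durations = seq(18, 42, length.out = 6),
                              n_per_condition = 200L,
                              model = c("integral", "level_duration"),
                              integral_threshold = 26, logistic_width = 2,
                              level_threshold = 0.5, level_width = 0.05,
                              duration_threshold = 26, duration_width = 2,
                              seed = 1L) {
  model <- match.arg(model)
  set.seed(substream_seed(seed, paste0("dose_response_", model)))
  grid <- expand.grid(level = levels, duration = durations)
  grid$sigma <- grid$level * grid$duration
  p <- switch(model,
    integral = stats::plogis((grid$sigma - integral_threshold) /
                               logistic_width),
    level_duration = stats::plogis((grid$level - level_threshold) /
                                     level_width) *
      stats::plogis((grid$duration - duration_threshold) / duration_width))
  grid$fraction <- stats::rbinom(nrow(grid), n_per_condition, p) /
    n_per_condition
  grid$n <- as.integer(n_per_condition)
  grid
}
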