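#' Parameters for the fate and marker-expression generator
#'
#' Fate is a noisy threshold on the signaling integral: the probability of
#' amnion differentiation is logistic in `(integral - integral_threshold) /
#' logistic_width`. Differentiated cells draw amnion markers (ISL1, GATA3,
#' TFAP2C, HAND1) from the "on" log-normal component and pluripotency markers
#' (SOX2, NANOG, OCT4) from the "off" component, and vice versa.
#'
#' Defaults place the threshold at 26 ratio x hours, matching the observed
#' sharp duration threshold near 26 h at unit high-low amplitude, with on/off
#' log-means separated by 5 marker SDs (clearly bimodal).
#'
#' @param integral_threshold integral at 50% differentiation (ratio x hours).
#' @param logistic_width width of the probabilistic threshold (ratio x hours),
#'   >= 0; 0 gives a hard threshold.
#' @param marker_names the 7 markers; must contain ISL1 and NANOG.
#' @param on_mean,off_mean log-intensity means of expressed / silent markers.
#' @param marker_sd log-intensity SD of both components.
#' @param seed integer seed.
#' @return A list of class `fate_gen_params`.
#' @export
fate_gen_params <- function(integral_threshold = 26, logistic_width = 2,
                            marker_names = c("ISL1", "GATA3", "TFAP2C",
                                             "HAND1", "SOX2", "NANOG",
                                             "OCT4"),
                            on_mean = 6, off_mean = 4, marker_sd = 0.4,
                            seed = 1L) {
  if (logistic_width < 0) stop("logistic_width must be >= 0")
  if (!all(c("ISL1", "NANOG") %in% marker_names))
    stop("marker_names must contain ISL1 and NANOG")
  if (marker_sd <= 0) stop("marker_sd must be positive")
  p <- as.list(environment())
  class(p) <- "fate_gen_params"
  p
}

AMNION_MARKERS <- c("ISL1", "GATA3", "TFAP2C", "HAND1")
PLURI_MARKERS <- c("SOX2", "NANOG", "OCT4")

#' Generate fates and marker intensities from signaling features
#'
#' @param features data.frame with one row per cell containing at least an
#'   `integral` column (and optionally `cell_id`).
#' @param params a [fate_gen_params()] object.
#' @return A data.frame (FateTable): `cell_id`, `true_fate` ("amnion" or
#'   "pluripotent"), and one raw-intensity column per marker.
#' @export
gen_fates <- function(features, params) {
  stopifnot(inherits(params, "fate_gen_params"))
  if (!"integral" %in% names(features)) stop("features must have an 'integral' column")
  set.seed(substream_seed(params$seed, "fates"))
  n <- nrow(features)
  sig <- features$integral
  p_diff <- if (params$logistic_width == 0) {
    ifelse(sig > params$integral_threshold, 1,
           ifelse(sig < params$integral_threshold, 0, 0.5))
  } else {
    stats::plogis((sig - params$integral_threshold) / params$logistic_width)
  }
  diff <- stats::rbinom(n, 1L, p_diff) == 1L
  out <- data.frame(
    cell_id = features$cell_id %||% sprintf("cell_%04d", seq_len(n)),
    true_fate = ifelse(diff, "amnion", "pluripotent"),
    stringsAsFactors = FALSE
  )
  for (m in params$marker_names) {
    on <- if (m %in% AMNION_MARKERS) diff else !diff
    mu <- ifelse(on, params$on_mean, params$off_mean)
    out[[m]] <- exp(stats::rnorm(n, mu, params$marker_sd))
  }
  out
}
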