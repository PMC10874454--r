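#' Parameters for the signaling-history generator
#'
#' Defaults emulate the study conditions: 42 h of imaging at a 10-minute
#' interval, histories descending from a high plateau near 2 (N:C ratio) to a
#' low plateau near the unstimulated baseline of 1, heterogeneous durations
#' centered on the 26 h fate threshold, and i.i.d. Gaussian measurement noise
#' of SD 0.1 on the unit high-low amplitude.
#'
#' @param n_cells number of cells.
#' @param t_start,t_end,dt time grid (hours); default 0 to 42 h at 10 min.
#' @param high_mean,high_sd high-plateau distribution (ratio units).
#' @param low_mean,low_sd low-plateau distribution.
#' @param duration_mean,duration_sd duration (sigmoid midpoint) distribution
#'   (hours).
#' @param rate_tau transition timescale (hours), shared across cells.
#' @param noise_sd i.i.d. Gaussian measurement noise SD per timepoint.
#' @param noise_ar optional AR(1) coefficient in `[0, 1)` for temporally
#'   autocorrelated noise; 0 (default) gives i.i.d. noise.
#' @param baseline reference level used for ground-truth integrals.
#' @param seed integer seed.
#' @return A list of class `history_gen_params`.
#' @export
history_gen_params <- function(n_cells = 500L, t_start = 0, t_end = 42,
                               dt = 1 / 6,
                               high_mean = 2, high_sd = 0.1,
                               low_mean = 1, low_sd = 0.05,
                               duration_mean = 26, duration_sd = 6,
                               rate_tau = 2, noise_sd = 0.1, noise_ar = 0,
                               baseline = 1, seed = 1L) {
  if (n_cells < 1) stop("n_cells must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (high_sd < 0 || low_sd < 0 || duration_sd < 0 || noise_sd < 0)
    stop("standard deviations must be non-negative")
  if (low_mean >= high_mean) stop("low_mean must be below high_mean")
  if (rate_tau <= 0) stop("rate_tau must be positive")
  if (noise_ar < 0 || noise_ar >= 1) stop("noise_ar must be in [0, 1)")
  p <- as.list(environment())
  class(p) <- "history_gen_params"
  p
}

#' Generate synthetic signaling histories with ground truth
#'
#' Each history is a descending sigmoid ([sigmoid_response()]) with per-cell
#' high level, low level and duration drawn from the generator distributions,
#' plus Gaussian measurement noise. The true per-cell sigmoid features and
#' baseline-referenced integrals are recorded.
#'
#' @param params a [history_gen_params()] object.
#' @return A list of class `history_set`: `histories` (cells x timepoints
#'   matrix, rownames cell ids, colnames times), `time` (grid, hours), and
#'   `truth` (data.frame cell_id, H, L, d, tau, integral).
#' @export
gen_histories <- function(params) {
  stopifnot(inherits(params, "history_gen_params"))
  set.seed(substream_seed(params$seed, "histories"))
  tgrid <- seq(params$t_start, params$t_end, by = params$dt)
  n <- as.integer(params$n_cells)
  H <- stats::rnorm(n, params$high_mean, params$high_sd)
  L <- stats::rnorm(n, params$low_mean, params$low_sd)
  # keep each cell's plateaus ordered; crossings are vanishingly rare at the
  # default separation but would invert the sigmoid
  L <- pmin(L, H - 1e-3)
  d <- stats::rnorm(n, params$duration_mean, params$duration_sd)
  clean <- sapply(seq_len(n), function(i)
    sigmoid_response(tgrid, H[i], L[i], d[i], params$rate_tau))
  clean <- t(clean)
  noise <- matrix(stats::rnorm(n * length(tgrid), 0, params$noise_sd),
                  nrow = n)
  if (params$noise_ar > 0 && params$noise_sd > 0) {
    a <- params$noise_ar
    for (j in 2:ncol(noise)) noise[, j] <- a * noise[, j - 1] +
        sqrt(1 - a^2) * noise[, j]
  }
  hist <- clean + noise
  ids <- sprintf("cell_%04d", seq_len(n))
  dimnames(hist) <- list(ids, signif(tgrid, 10))
  truth <- data.frame(
    cell_id = ids, H = H, L = L, d = d, tau = params$rate_tau,
    integral = sigmoid_integral(H, L, d, params$rate_tau,
                                params$t_start, params$t_end,
                                baseline = params$baseline),
    stringsAsFactors = FALSE
  )
  structure(list(histories = hist, time = tgrid, truth = truth,
                 params = params),
            class = "history_set")
}
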