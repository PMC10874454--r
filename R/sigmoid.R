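#' Descending sigmoid signaling response
#'
#' Canonical shape of a single-cell SMAD4 signaling history: a high initial
#' plateau `H` descending to a low final plateau `L`, with midpoint time `d`
#' (the signaling duration) and transition timescale `tau`:
#' `s(t) = L + (H - L) / (1 + exp((t - d) / tau))`.
#'
#' The same functional form is used by the generator ([gen_histories()]) and
#' by the feature fit ([fit_sigmoid()]), so noiseless round trips are exact.
#'
#' @param t numeric vector of times (hours).
#' @param H high (initial) plateau, N:C ratio units.
#' @param L low (final) plateau.
#' @param d duration: midpoint time of the transition (hours).
#' @param tau transition timescale (hours), > 0.
#' @return Numeric vector `s(t)`.
#' @export
sigmoid_response <- function(t, H, L, d, tau) {
  L + (H - L) / (1 + exp((t - d) / tau))
}

#' Closed-form time integral of the sigmoid response above a baseline
#'
#' Integrates `s(t) - baseline` from `t0` to `t1` analytically, using
#' `int 1/(1+e^{(t-d)/tau}) dt = t - tau * log(1 + e^{(t-d)/tau})`.
#'
#' @inheritParams sigmoid_response
#' @param t0,t1 integration window (hours).
#' @param baseline reference level subtracted before integrating.
#' @return Integral in ratio x hours.
#' @export
sigmoid_integral <- function(H, L, d, tau, t0, t1, baseline = 0) {
  prim <- function(t) t - tau * log1p(exp((t - d) / tau))
  (L - baseline) * (t1 - t0) + (H - L) * (prim(t1) - prim(t0))
}
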