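#' Idealized piecewise-constant SMAD4 input program
#'
#' @param segments data.frame with `start`, `end` (hours) and `level`
#'   (normalized signaling units); segments must be ordered and
#'   non-overlapping.
#' @param baseline level outside the segments (default 0).
#' @return list of class `smad4_input`.
#' @export
smad4_input <- function(segments, baseline = 0) {
  stopifnot(all(c("start", "end", "level") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end <= segments$start)) stop("segments must have end > start")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)]))
    stop("segments must be non-overlapping")
  structure(list(segments = segments, baseline = baseline),
            class = "smad4_input")
}

#' Evaluate a SMAD4 input program
#' @param input a [smad4_input()].
#' @param t times (hours).
#' @return Levels `B(t)`.
#' @export
smad4_level <- function(input, t) {
  out <- rep(input$baseline, length(t))
  for (i in seq_len(nrow(input$segments))) {
    s <- input$segments[i, ]
    out[t >= s$start & t < s$end] <- s$level
  }
  out
}

# constant-level pieces of [0, t_end] for exact piecewise integration
input_pieces <- function(input, t_end, t_start = 0) {
  br <- sort(unique(c(t_start, t_end,
                      input$segments$start, input$segments$end)))
  br <- br[br >= t_start & br <= t_end]
  if (br[1] > t_start) br <- c(t_start, br)
  if (br[length(br)] < t_end) br <- c(br, t_end)
  data.frame(start = br[-length(br)], end = br[-1],
             level = smad4_level(input, br[-length(br)]))
}

#' Plain time integral of a SMAD4 input
#' @inheritParams smad4_level
#' @param t_end,t_start integration window (hours).
#' @return Integral of `B` over the window.
#' @export
smad4_integral <- function(input, t_end, t_start = 0) {
  p <- input_pieces(input, t_end, t_start)
  sum(p$level * (p$end - p$start))
}

#' Exponentially weighted integral of a SMAD4 input
#'
#' `int_0^t B(t') e^{-gamma (t - t')} dt'`, the quantity a linear
#' production/degradation gene with decay rate `gamma` reads out; computed in
#' closed form per constant piece. As `gamma -> 0` this converges to the
#' plain integral, which is why a slowly decaying gene acts as a signaling
#' integrator.
#'
#' @inheritParams smad4_integral
#' @param gamma decay rate (1/h), >= 0.
#' @return Weighted integral at `t_end`.
#' @export
weighted_integral <- function(input, gamma, t_end) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (gamma == 0) return(smad4_integral(input, t_end))
  p <- input_pieces(input, t_end)
  sum(p$level / gamma *
        (exp(-gamma * (t_end - p$end)) - exp(-gamma * (t_end - p$start))))
}

#' Parameters of the SOX2/ISL1 integrator model
#'
#' Two coupled ODEs in units where the unstimulated SOX2 steady state is 1:
#' \deqn{dS/dt = \alpha \max(0, 1 - \beta B(t)) f_{auto}(S) f_{repI}(I) - \gamma_S S}
#' \deqn{dI/dt = \alpha_I f_{repS}(S) - \gamma_I I}
#' with Hill functions
#' `f_auto(S) = (basal + S^na/(Ka^na + S^na)) / (basal + 1/(Ka^na + 1))`
#' (normalized so `f_auto(1) = 1`),
#' `f_repI(I) = KI^nI / (KI^nI + I^nI)`, and
#' `f_repS(S) = KS^nS / (KS^nS + S^nS)`. SMAD4 linearly represses SOX2
#' production (clipped at zero), ISL1 represses SOX2, SOX2 autoregulates
#' positively and represses ISL1. Model tiers isolate these ingredients:
#' `"linear"` sets `f_auto = f_repI = 1` (pure production/degradation
#' integrator), `"isl1"` adds ISL1 repression, `"full"` (default) adds
#' autoregulation.
#'
#' The SOX2 decay rate defaults to `ln(2)/7` per hour, the directly measured
#' 7 h half-life (FRAP).
#'
#' @param alpha max SOX2 production (conc/h); default `gamma_S` so the
#'   unstimulated steady state is 1.
#' @param beta SMAD4 repression coefficient (per signaling unit).
#' @param gamma_S SOX2 decay rate (1/h).
#' @param Ka,na autoregulation Hill constant / coefficient.
#' @param basal basal (autoregulation-independent) production fraction.
#' @param KI,nI ISL1-repression-of-SOX2 Hill constant / coefficient.
#' @param alpha_I,gamma_I ISL1 production and decay.
#' @param KS,nS SOX2-repression-of-ISL1 Hill constant / coefficient.
#' @param tier `"linear"`, `"isl1"` or `"full"`.
#' @return list of class `integrator_params`.
#' @export
integrator_params <- function(alpha = NULL, beta = 0.8,
                              gamma_S = log(2) / 7,
                              Ka = 0.75, na = 2, basal = 0.1,
                              KI = 0.5, nI = 4,
                              alpha_I = 0.2, gamma_I = 0.2,
                              KS = 0.5, nS = 4,
                              tier = c("full", "isl1", "linear")) {
  tier <- match.arg(tier)
  alpha <- alpha %||% gamma_S
  vals <- c(alpha, beta, gamma_S, Ka, KI, alpha_I, gamma_I, KS, basal)
  if (any(vals < 0)) stop("rates and constants must be non-negative")
  if (na < 1 || nI < 1 || nS < 1) stop("Hill coefficients must be >= 1")
  p <- as.list(environment())
  class(p) <- "integrator_params"
  p
}

int_derivs <- function(p, B) {
  f_auto <- if (p$tier == "full") {
    norm <- p$basal + 1 / (p$Ka^p$na + 1)
    function(S) (p$basal + S^p$na / (p$Ka^p$na + S^p$na)) / norm
  } else function(S) 1
  f_repI <- if (p$tier != "linear") {
    function(I) p$KI^p$nI / (p$KI^p$nI + I^p$nI)
  } else function(I) 1
  f_repS <- function(S) p$KS^p$nS / (p$KS^p$nS + S^p$nS)
  function(t, y, parms) {
    S <- max(y[1], 0); I <- max(y[2], 0)
    dS <- p$alpha * max(0, 1 - p$beta * B) * f_auto(S) * f_repI(I) -
      p$gamma_S * y[1]
    dI <- p$alpha_I * f_repS(S) - p$gamma_I * y[2]
    list(c(dS, dI))
  }
}

#' Simulate the SOX2/ISL1 integrator model
#'
#' Integrates the two ODEs piecewise over the constant-level segments of the
#' input program (so input discontinuities are handled exactly), with tight
#' tolerances (`rtol = atol = 1e-10`).
#'
#' @param params an [integrator_params()].
#' @param input a [smad4_input()].
#' @param t_end end of simulation (hours).
#' @param S0 initial SOX2 (default 1, the unstimulated steady state).
#' @param I0 initial ISL1; default is the ISL1 quasi-steady state at `S0`.
#' @param dt_out output resolution (hours).
#' @return data.frame: `time`, `S`, `I`, `B`.
#' @export
simulate_integrator <- function(params, input, t_end = 48, S0 = 1,
                                I0 = NULL, dt_out = 0.1) {
  stopifnot(inherits(params, "integrator_params"),
            inherits(input, "smad4_input"))
  if (S0 < 0 || (!is.null(I0) && I0 < 0)) stop("initial conditions must be >= 0")
  I0 <- I0 %||% (params$alpha_I * params$KS^params$nS /
                   (params$KS^params$nS + S0^params$nS) / params$gamma_I)
  pieces <- input_pieces(input, t_end)
  y <- c(S = S0, I = I0)
  out <- list(data.frame(time = 0, S = S0, I = I0))
  for (i in seq_len(nrow(pieces))) {
    pc <- pieces[i, ]
    times <- unique(c(seq(pc$start, pc$end, by = dt_out), pc$end))
    sol <- deSolve::ode(y = y, times = times, func = int_derivs(params, pc$level),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0) stop("ODE integration failed in segment ", i)
    sol <- as.data.frame(sol)
    names(sol) <- c("time", "S", "I")
    y <- c(S = sol$S[nrow(sol)], I = sol$I[nrow(sol)])
    out[[i + 1L]] <- sol[-1, ]
  }
  traj <- do.call(rbind, out)
  traj$B <- smad4_level(input, traj$time)
  rownames(traj) <- NULL
  traj
}

#' Locate the unstimulated fixed point(s) of the model
#'
#' Solves `alpha f_auto(S) f_repI(I*(S)) = gamma_S S` with ISL1 at its
#' quasi-steady state, by sign changes on a grid.
#'
#' @param params an [integrator_params()].
#' @param S_range search interval.
#' @return Numeric vector of steady-state SOX2 values (ascending).
#' @export
find_steady_states <- function(params, S_range = c(1e-4, 3)) {
  d <- int_derivs(params, 0)
  g <- function(S) {
    I <- params$alpha_I * params$KS^params$nS /
      (params$KS^params$nS + S^params$nS) / params$gamma_I
    d(0, c(S, I), NULL)[[1]][1]
  }
  grid <- seq(S_range[1], S_range[2], length.out = 600)
  v <- vapply(grid, g, numeric(1))
  roots <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (sign(v[i]) != sign(v[i + 1])) {
      roots <- c(roots, stats::uniroot(g, c(grid[i], grid[i + 1]))$root)
    }
  }
  roots
}

#' Linear fit of the 16-hour SOX2 change against the signaling integral
#'
#' For each condition, the change in SOX2 over the first `window` hours is
#' regressed on the signaling integral over the same window. In the linear
#' model tier this slope is exactly `-alpha * beta`; in the full model it
#' stays near-linear at low integrals.
#'
#' @param traces list of trajectories from [simulate_integrator()] (one per
#'   condition).
#' @param inputs list of the matching [smad4_input()] programs.
#' @param window analysis window (hours), default 16.
#' @return list: `slope`, `intercept`, `r`, `r_squared`, `delta_S`, `sigma`.
#' @export
delta_sox2_vs_integral <- function(traces, inputs, window = 16) {
  if (length(traces) < 3) stop("need at least 3 conditions")
  dS <- vapply(traces, function(tr) {
    s_end <- stats::approx(tr$time, tr$S, window)$y
    s_end - tr$S[1]
  }, numeric(1))
  sig <- vapply(inputs, smad4_integral, numeric(1), t_end = window)
  if (stats::sd(sig) == 0) stop("conditions have identical integrals; fit refused")
  fit <- stats::lm(dS ~ sig)
  r <- stats::cor(dS, sig)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2, delta_S = dS, sigma = sig)
}

#' Fit the integrator model to observed SOX2 traces
#'
#' Least-squares over the free parameters with the SOX2 decay rate pinned to
#' its measured value (FRAP half-life), Levenberg-Marquardt with a small
#' deterministic multistart grid.
#'
#' @param traces list of data.frames with `time` and `S` per condition.
#' @param inputs matching list of [smad4_input()] programs.
#' @param gamma_S pinned decay rate (1/h), e.g. `log(2)/7`.
#' @param tier model tier to fit.
#' @param free names of free parameters (subset of alpha, beta).
#' @param template an [integrator_params()] supplying the fixed parameters.
#' @return list: `params` (fitted `integrator_params`), `residuals` (per
#'   condition), `converged`, `ssr`.
#' @export
fit_integrator <- function(traces, inputs, gamma_S = log(2) / 7,
                           tier = "linear", free = c("alpha", "beta"),
                           template = NULL) {
  if (length(traces) < 2) stop("need at least 2 conditions")
  template <- template %||% integrator_params(gamma_S = gamma_S, tier = tier)
  template$gamma_S <- gamma_S
  template$tier <- tier
  resid_fun <- function(theta) {
    p <- template
    p[free] <- as.list(exp(theta))  # log parameterization keeps rates positive
    unlist(lapply(seq_along(traces), function(i) {
      sim <- simulate_integrator(p, inputs[[i]],
                                 t_end = max(traces[[i]]$time),
                                 S0 = traces[[i]]$S[1])
      stats::approx(sim$time, sim$S, traces[[i]]$time)$y - traces[[i]]$S
    }))
  }
  starts <- expand.grid(alpha = gamma_S * c(0.5, 1, 2),
                        beta = c(0.4, 0.8, 1.5))[, free, drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(unlist(starts[i, , drop = FALSE])),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("model fitting failed from every start")
  p <- template
  p[free] <- as.list(exp(best$par))
  res <- resid_fun(best$par)
  list(params = p, residuals = res, converged = best$info %in% 1:4,
       ssr = best$deviance)
}

#' Fit an exponential FRAP recovery and report the protein half-life
#'
#' Least-squares fit of `A0 + A (1 - e^{-lambda t})` to post-bleach
#' fluorescence; the half-life is `ln(2) / lambda`. Because photobleaching
#' only removes fluorescence, recovery reflects turnover at equilibrium and is
#' a simple exponential even for autoregulated genes --- which is what makes
#' FRAP the direct half-life measurement.
#'
#' @param time recovery times (hours), >= 5 points.
#' @param intensity fluorescence values.
#' @return list of class `frap_fit`: `A0`, `A`, `lambda`, `half_life`, `fit`.
#' @export
frap_fit <- function(time, intensity) {
  if (length(time) < 5) stop("need at least 5 timepoints")
  if (length(time) != length(intensity)) stop("length mismatch")
  trend <- suppressWarnings(stats::cor(time, intensity))  # NA for constant data
  if (is.na(trend) || trend <= 0)
    stop("recovery must increase on average; lambda unidentifiable")
  amp <- max(intensity) - min(intensity)
  fit <- minpack.lm::nlsLM(
    intensity ~ A0 + A * (1 - exp(-lambda * time)),
    start = list(A0 = min(intensity), A = amp,
                 lambda = 1 / max(stats::median(time), 1e-6)),
    lower = c(A0 = -Inf, A = 0, lambda = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf["lambda"] <= 1e-9) stop("lambda fell to zero; recovery rate unidentifiable")
  structure(list(A0 = unname(cf["A0"]), A = unname(cf["A"]),
                 lambda = unname(cf["lambda"]),
                 half_life = log(2) / unname(cf["lambda"]), fit = fit),
            class = "frap_fit")
}

#' Simulate a grid of level x duration conditions and report final ISL1
#'
#' The simulated analogue of plotting ISL1 against the SMAD4 integral across
#' conditions: under integrator control the points from all levels and
#' durations fall on one curve with a single integral threshold.
#'
#' @param params an [integrator_params()].
#' @param levels signaling levels.
#' @param durations signaling durations (hours).
#' @param t_end readout time (hours).
#' @return data.frame: level, duration, sigma, S_final, I_final.
#' @export
simulate_dose_grid <- function(params, levels = c(1, 0.7),
                               durations = seq(10, 42, by = 4), t_end = 48) {
  grid <- expand.grid(level = levels, duration = durations)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    inp <- smad4_input(data.frame(start = 0, end = grid$duration[i],
                                  level = grid$level[i]))
    tr <- simulate_integrator(params, inp, t_end = t_end)
    data.frame(level = grid$level[i], duration = grid$duration[i],
               sigma = smad4_integral(inp, t_end),
               S_final = tr$S[nrow(tr)], I_final = tr$I[nrow(tr)])
  })
  do.call(rbind, res)
}
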