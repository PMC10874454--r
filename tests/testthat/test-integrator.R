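test_that("input programs: validation, evaluation, integrals", {
  expect_error(smad4_input(data.frame(start = 1, end = 0, level = 1)),
               "end > start")
  expect_error(smad4_input(data.frame(start = c(0, 5), end = c(6, 10),
                                      level = 1)), "non-overlapping")
  inp <- smad4_input(data.frame(start = c(0, 20), end = c(10, 30),
                                level = c(1, 0.5)))
  expect_equal(smad4_level(inp, c(5, 15, 25, 35)), c(1, 0, 0.5, 0))
  expect_equal(smad4_integral(inp, 42), 10 + 5)
  expect_equal(smad4_integral(inp, 5), 5)
})

test_that("weighted integral: closed forms and the slow-turnover limit", {
  step <- smad4_input(data.frame(start = 0, end = 10, level = 1))
  expect_equal(weighted_integral(step, 0, 10), 10)

  g <- log(2) / 7
  const <- smad4_input(data.frame(start = 0, end = 1000, level = 1))
  expect_equal(weighted_integral(const, g, 1000), 1 / g, tolerance = 1e-6)

  # relative gap to the plain integral < 5% when gamma * window < 0.1
  win <- 0.09 / g
  wi <- weighted_integral(step2 <- smad4_input(
    data.frame(start = 0, end = win, level = 1)), g, win)
  expect_lt(abs(wi - win) / win, 0.05)
  expect_error(weighted_integral(step, -1, 10), "non-negative")
})

test_that("ODE simulation: equilibrium, repressed limit, nonnegativity", {
  p <- integrator_params()
  ss <- find_steady_states(p)
  expect_gte(length(ss), 2)  # bistable at rest
  hi <- max(ss)
  none <- smad4_input(data.frame(start = 0, end = 0.1, level = 0))
  I_hi <- p$alpha_I * p$KS^p$nS / (p$KS^p$nS + hi^p$nS) / p$gamma_I
  tr <- simulate_integrator(p, none, t_end = 50, S0 = hi, I0 = I_hi)
  expect_lt(max(abs(tr$S - hi)), 1e-4)

  # saturating ISL1 fully represses SOX2 production: pure exponential decay
  p2 <- integrator_params(alpha_I = 1e5, gamma_I = 1e-6)
  tr2 <- simulate_integrator(p2, none, t_end = 21, S0 = 1, I0 = 1e6)
  expect_equal(tr2$S, exp(-p2$gamma_S * tr2$time), tolerance = 1e-4)
  expect_equal(tail(tr2$S, 1), 2^-3, tolerance = 1e-3)  # 3 half-lives

  expect_true(all(tr$S >= -1e-12) && all(tr$I >= -1e-12))
  expect_error(simulate_integrator(p, none, S0 = -1), ">= 0")
})

test_that("linear tier: SOX2 change equals -alpha*beta times the integral", {
  p <- integrator_params(alpha = 0.12, beta = 0.8, gamma_S = 0,
                         tier = "linear")
  levels <- c(0.2, 0.5, 0.8, 1)
  inputs <- lapply(levels, function(l)
    smad4_input(data.frame(start = 0, end = 42, level = l)))
  traces <- lapply(inputs, simulate_integrator, params = p, t_end = 20)
  fit <- delta_sox2_vs_integral(traces, inputs, window = 16)
  expect_lt(abs(fit$slope + 0.12 * 0.8) / (0.12 * 0.8), 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # identical conditions refuse the fit
  same <- rep(inputs[2], 3)
  tr_same <- rep(traces[2], 3)
  expect_error(delta_sox2_vs_integral(tr_same, same), "identical")
  expect_error(delta_sox2_vs_integral(traces[1:2], inputs[1:2]), "3 conditions")
})

test_that("full model stays near-linear at low integrals", {
  p <- integrator_params()
  levels <- seq(0.05, 0.4, length.out = 6)
  inputs <- lapply(levels, function(l)
    smad4_input(data.frame(start = 0, end = 16, level = l)))
  traces <- lapply(inputs, simulate_integrator, params = p, t_end = 16)
  fit <- delta_sox2_vs_integral(traces, inputs)
  expect_gt(abs(fit$r), 0.98)
  expect_lt(fit$slope, 0)
})

test_that("parameter recovery with the decay rate pinned by FRAP", {
  g <- log(2) / 7
  ptrue <- integrator_params(alpha = 0.15, beta = 0.9, gamma_S = g,
                             tier = "linear")
  inputs <- lapply(c(0.3, 0.6, 1), function(l)
    smad4_input(data.frame(start = 0, end = 42, level = l)))
  traces <- lapply(inputs, function(i)
    simulate_integrator(ptrue, i, t_end = 42, dt_out = 1)[, c("time", "S")])
  fit <- fit_integrator(traces, inputs, gamma_S = g, tier = "linear")
  expect_lt(abs(fit$params$alpha - 0.15) / 0.15, 0.1)
  expect_lt(abs(fit$params$beta - 0.9) / 0.9, 0.1)

  # 5% observation noise: median recovery within 20%
  set.seed(21)
  errs <- replicate(8, {
    noisy <- lapply(traces, function(tr) {
      tr$S <- tr$S + rnorm(nrow(tr), 0, 0.05)
      tr
    })
    f <- fit_integrator(noisy, inputs, gamma_S = g, tier = "linear")
    max(abs(f$params$alpha - 0.15) / 0.15, abs(f$params$beta - 0.9) / 0.9)
  })
  expect_lt(median(errs), 0.2)
})

test_that("commitment is permanent past the switch point", {
  p <- integrator_params()
  long <- simulate_integrator(p, smad4_input(
    data.frame(start = 0, end = 36, level = 1)), t_end = 150)
  short <- simulate_integrator(p, smad4_input(
    data.frame(start = 0, end = 6, level = 1)), t_end = 150)
  ss <- find_steady_states(p)
  expect_lt(tail(long$S, 1), min(ss) * 2)     # stays at the low state
  expect_gt(tail(long$I, 1), 0.9)             # ISL1 locked on
  expect_gt(tail(short$S, 1), max(ss) * 0.9)  # recovers to the high state
})

test_that("autoregulation slows the apparent SOX2 turnover", {
  p <- integrator_params()  # full tier, true half-life 7 h
  pulse <- smad4_input(data.frame(start = 0, end = 2, level = 1))
  tr <- simulate_integrator(p, pulse, t_end = 80)
  rec <- tr[tr$time >= 2, ]
  fit <- minpack.lm::nlsLM(S ~ Sinf - A * exp(-lam * (time - 2)), data = rec,
                           start = list(Sinf = 1, A = 0.3, lam = 0.1))
  apparent <- log(2) / coef(fit)[["lam"]]
  expect_gt(apparent, 2 * log(2) / p$gamma_S / log(2) * log(2))  # > 14 h
  expect_gt(apparent, 14)
})

test_that("simulated ISL1 collapses onto one integral threshold", {
  p <- integrator_params()
  grid <- simulate_dose_grid(p, levels = c(1, 0.7),
                             durations = seq(4, 36, by = 2), t_end = 48)
  thrs <- vapply(c(1, 0.7), function(l) {
    g <- grid[grid$level == l, ]
    threshold_from_dose_response(g$sigma,
                                 g$I_final / max(grid$I_final))$threshold
  }, numeric(1))
  expect_lt(abs(diff(thrs)) / min(thrs), 0.1)
})

test_that("FRAP fitting recovers the half-life", {
  tt <- seq(0, 30, by = 0.5)
  g <- log(2) / 7
  y <- 0.2 + 0.8 * (1 - exp(-g * tt))
  f <- frap_fit(tt, y)
  expect_equal(f$half_life, 7, tolerance = 1e-6)
  expect_equal(f$A0, 0.2, tolerance = 1e-6)

  expect_error(frap_fit(tt, rep(1, length(tt))), "increase")
  expect_error(frap_fit(1:4, 1:4), "5 timepoints")

  set.seed(22)
  errs <- replicate(100, {
    yn <- y + rnorm(length(y), 0, 0.05 * 0.8)
    abs(frap_fit(tt, yn)$half_life - 7) / 7
  })
  expect_lt(median(errs), 0.05)
})
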