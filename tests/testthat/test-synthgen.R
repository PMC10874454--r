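test_that("noiseless histories equal their generating sigmoids exactly", {
  hp <- history_gen_params(n_cells = 10, noise_sd = 0, high_mean = 2,
                           high_sd = 0, low_mean = 1, low_sd = 0,
                           duration_mean = 26, duration_sd = 0, seed = 1)
  hs <- gen_histories(hp)
  expect_equal(unname(hs$histories), unname(true_sigmoids(hs)),
               tolerance = 1e-12)
  expect_equal(stats::var(hs$truth$d), 0)
})

test_that("history generation is deterministic and validates parameters", {
  a <- gen_histories(history_gen_params(n_cells = 25, seed = 42))
  b <- gen_histories(history_gen_params(n_cells = 25, seed = 42))
  expect_identical(a$histories, b$histories)
  expect_identical(a$truth, b$truth)
  c <- gen_histories(history_gen_params(n_cells = 25, seed = 43))
  expect_false(identical(a$histories, c$histories))
  expect_error(history_gen_params(dt = 0), "dt")
  expect_error(history_gen_params(n_cells = 0), "n_cells")
  expect_error(history_gen_params(low_mean = 3, high_mean = 2), "low_mean")
})

test_that("initial-timepoint spread matches propagated variance", {
  # at t = 0 the sigmoid sits on its high plateau, so the across-cell SD is
  # sqrt(high_sd^2 + noise_sd^2)
  hp <- history_gen_params(n_cells = 500, high_sd = 0.1, noise_sd = 0.1,
                           seed = 7)
  hs <- gen_histories(hp)
  s <- stats::sd(hs$histories[, 1])
  expected <- sqrt(0.1^2 + 0.1^2)
  se <- expected / sqrt(2 * (500 - 1))
  expect_lt(abs(s - expected), 3 * se)
})

test_that("fate assignment follows the logistic integral threshold", {
  feats <- data.frame(integral = rep(30, 50))
  fp <- fate_gen_params(integral_threshold = 26, logistic_width = 0, seed = 1)
  ft <- gen_fates(feats, fp)
  expect_true(all(ft$true_fate == "amnion"))

  feats2 <- data.frame(integral = rep(26, 10000))
  ft2 <- gen_fates(feats2, fate_gen_params(logistic_width = 2, seed = 2))
  frac <- mean(ft2$true_fate == "amnion")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

  expect_error(gen_fates(data.frame(x = 1), fate_gen_params()), "integral")
})

test_that("marker bimodality: GMM recovers the mixing fraction", {
  hp <- history_gen_params(n_cells = 2000, seed = 3)
  hs <- gen_histories(hp)
  fp <- fate_gen_params(on_mean = 6, off_mean = 6 - 6 * 0.4, marker_sd = 0.4,
                        seed = 3)  # 6 SD separation
  ft <- gen_fates(hs$truth, fp)
  truth_frac <- mean(ft$true_fate == "amnion")
  gm <- mclust::Mclust(log(ft$ISL1), G = 2, verbose = FALSE)
  est_frac <- max(gm$parameters$pro)
  expect_lt(abs(est_frac - max(truth_frac, 1 - truth_frac)), 0.02)
  expect_true(all(gm$parameters$pro >= 0.05))
})

test_that("colony generator: geometry, binning counts and class recovery", {
  expect_error(colony_gen_params(class_boundaries = c(150, 60)), "increasing")
  expect_error(colony_gen_params(class_histories = list(history_gen_params())),
               "per radial class")

  col <- gen_colony(colony_gen_params(n_cells = 900, seed = 5))
  expect_true(all(col$positions$edge_dist >= 0 &
                    col$positions$edge_dist <= 350))
  bins <- radial_bin(col$positions, 350, n_bins = 30)
  expect_true(all(table(bins$bin) == 30))

  # one class only: kymograph rows statistically identical
  one <- colony_gen_params(
    class_boundaries = c(60, 150),
    class_histories = rep(list(history_gen_params(duration_mean = 26,
                                                  duration_sd = 1.5)), 3),
    n_cells = 600, seed = 6)
  col1 <- gen_colony(one)
  kym <- kymograph(col1$histories, radial_bin(col1$positions, 350, 20))
  spread <- apply(kym, 2, stats::sd)
  within <- apply(col1$histories, 2, stats::sd)
  expect_lt(mean(spread), mean(within))  # rows are bin medians of one class
  expect_lt(max(abs(sweep(kym, 2, colMeans(kym)))), 0.2)
})

test_that("tracking fixture: static case, no-division case, determinism", {
  fx <- gen_tracking_fixture(10, 5, step_sd = 0, division_prob = 0, seed = 1)
  pos <- split(fx$detections[, c("x", "y")], fx$detections$frame)
  for (f in 2:5) expect_equal(pos[[f]], pos[[1]], ignore_attr = TRUE)

  fx2 <- gen_tracking_fixture(8, 2, division_prob = 0, seed = 2)
  expect_equal(nrow(fx2$truth$tracks), 8)
  expect_true(all(is.na(fx2$truth$tracks$parent)))

  a <- gen_tracking_fixture(100, 50, seed = 11)
  b <- gen_tracking_fixture(100, 50, seed = 11)
  expect_identical(a$detections, b$detections)
  expect_identical(a$true_links, b$true_links)

  expect_error(gen_tracking_fixture(10, 5, label_fraction = 0), "label_fraction")
})

test_that("count generator: planted structure and degenerate cases", {
  # flat genes only: dynamic filter removes everything at any threshold
  cs <- gen_counts(n_genes = 50, class_fractions = c(decreasing = 0,
                                                     immediate = 0,
                                                     delayed = 0),
                   low_fraction = 0, seed = 1)
  dyn <- filter_dynamic(cpm_normalize(cs$time_counts), cs$timepoints,
                        threshold = max(
                          filter_dynamic(cpm_normalize(cs$time_counts),
                                         cs$timepoints)$statistic) * 1.01)
  expect_length(dyn$genes, 0)

  # zero-noise immediate gene correlates perfectly with SMAD4 level (up to
  # the library-composition rescaling shared by all genes in a sample)
  cs0 <- gen_counts(n_genes = 100, noise = FALSE, seed = 2)
  imm <- cs0$truth$gene[cs0$truth$class == "immediate"][1]
  expect_equal(stats::cor(cs0$dose_counts[imm, ], cs0$dose_levels), 1,
               tolerance = 1e-3)

  expect_error(gen_counts(timepoints = numeric(0)), "timepoints")
  a <- gen_counts(n_genes = 200, seed = 9)
  b <- gen_counts(n_genes = 200, seed = 9)
  expect_identical(a$time_counts, b$time_counts)
  expect_true(all(a$time_counts >= 0) && all(a$time_counts == round(a$time_counts)))
})

test_that("noiseless analysis round-trips recover generating parameters", {
  hp <- history_gen_params(n_cells = 8, noise_sd = 0, seed = 21)
  hs <- gen_histories(hp)
  fits <- fit_sigmoids(hs$histories, hs$time)
  expect_equal(fits$d, hs$truth$d, tolerance = 1e-6)
  expect_equal(fits$H, hs$truth$H, tolerance = 1e-6)
  expect_equal(fits$L, hs$truth$L, tolerance = 1e-6)
  expect_equal(fits$tau, rep(2, 8), tolerance = 1e-6)
})
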