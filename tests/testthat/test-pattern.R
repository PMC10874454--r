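disc_positions <- function(n, radius, seed = 1) {
  set.seed(seed)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(cell_id = seq_len(n), x = r * cos(th), y = r * sin(th))
}

test_that("radial binning: equal counts, degeneracy, analytic field", {
  pos <- disc_positions(90, 350)
  b <- radial_bin(pos, 350, n_bins = 30)
  expect_true(all(table(b$bin) == 3))
  expect_error(radial_bin(pos[1:10, ], 350, 30), "fewer cells")

  same <- data.frame(x = rep(100, 40), y = rep(0, 40))
  expect_warning(radial_bin(same, 350, 4), "degenerate")

  # medians of a radially linear field reproduce the field
  pos2 <- disc_positions(3000, 350, seed = 2)
  edge <- 350 - sqrt(pos2$x^2 + pos2$y^2)
  b2 <- radial_bin(pos2, 350, 30)
  field <- 1 + 0.01 * edge
  med <- tapply(field, b2$bin, stats::median)
  centers <- 1 + 0.01 * (b2$ranges$min_edge_dist + b2$ranges$max_edge_dist) / 2
  expect_lt(max(abs(med - centers)), 0.01 * diff(range(edge)) / 30 * 2)
})

test_that("kymograph rows: uniform, edge-high step, inner-late wave", {
  pos <- disc_positions(600, 350)
  b <- radial_bin(pos, 350, 30)
  tgrid <- seq(0, 10, by = 0.5)
  uniform <- matrix(2, 600, length(tgrid))
  k1 <- kymograph(uniform, b)
  expect_true(all(k1 == 2))

  edge <- 350 - sqrt(pos$x^2 + pos$y^2)
  step <- outer(ifelse(edge < 100, 2, 1), rep(1, length(tgrid)))
  k2 <- kymograph(step, b)
  expect_gt(mean(k2[1:5, ]), mean(k2[26:30, ]))

  # inner bins rise late: rising band visible in inner rows
  onset <- 2 + edge / 70          # hours; later toward the center
  wave <- t(vapply(seq_len(600), function(i)
    as.numeric(tgrid > onset[i]), numeric(length(tgrid))))
  k3 <- kymograph(wave, b)
  first_on <- apply(k3 > 0.5, 1, which.max)
  expect_true(all(diff(first_on) >= 0))  # monotone onset edge -> center
})

test_that("soft k-means on radial histories recovers planted classes", {
  col <- gen_colony(colony_gen_params(seed = 5))
  b <- radial_bin(col$positions, 350)
  kym <- kymograph(col$histories, b)
  cl <- cluster_radial_histories(kym, k = 3, seed = 1)
  expect_equal(rowSums(cl$membership), rep(1, 30), tolerance = 1e-9)
  true_map <- vapply(1:30, function(bb)
    names(which.max(table(col$positions$class[b$bin == bb]))), character(1))
  expect_gte(map_agreement(as.character(cl$cluster), true_map), 29 / 30)
  # class boundaries recovered within one bin
  expect_lt(max(abs(which(diff(cl$cluster) != 0) -
                      which(diff(as.integer(true_map)) != 0))), 2)
  # crisp memberships away from boundaries
  interior <- setdiff(1:30, c(which(diff(as.integer(true_map)) != 0),
                              which(diff(as.integer(true_map)) != 0) + 1))
  expect_gt(min(apply(cl$membership[interior, ], 1, max)), 0.95)

  k1 <- cluster_radial_histories(kym, k = 1, seed = 1)
  expect_true(all(k1$membership == 1))

  # two-class data with k = 3 duplicates a centroid
  set.seed(2)
  two <- rbind(matrix(0, 10, 5), matrix(5, 10, 5)) +
    matrix(rnorm(100, 0, 0.01), 20, 5)
  cl2 <- cluster_radial_histories(two, k = 3, seed = 1)
  expect_true(cl2$duplicated_clusters)
  expect_false(cl$duplicated_clusters)
})

test_that("manual elbow reassignment overrides one bin's cluster", {
  col <- gen_colony(colony_gen_params(seed = 5))
  b <- radial_bin(col$positions, 350)
  kym <- kymograph(col$histories, b)
  cl <- cluster_radial_histories(kym, k = 3, seed = 1,
                                 reassign = c(`15` = 3L))
  expect_equal(cl$cluster[15], 3L)
})

test_that("fate maps: uniform colony, boundary placement, agreement", {
  pos <- disc_positions(600, 350)
  b <- radial_bin(pos, 350, 30)
  fm <- fate_map(rep("amnion", 600), b)
  expect_true(all(fm == "amnion"))

  col <- gen_colony(colony_gen_params(seed = 5))
  b2 <- radial_bin(col$positions, 350)
  sc <- fate_score(col$fates)
  fm2 <- fate_map(sc$label, b2)
  # outer-ring amnion: boundary bin matches the generating fate boundary +-1
  true_fate <- ifelse(col$truth$integral >
                        col$params$fate_params$integral_threshold,
                      "amnion", "pluripotent")
  tm <- fate_map(true_fate, b2)
  expect_gte(mean(fm2 == tm), 29 / 30)
  expect_lt(abs(which(fm2 == "pluripotent")[1] -
                  which(tm == "pluripotent")[1]), 2)

  # noiseless (hard-threshold) generator: cluster map agrees with fate map
  cpq <- colony_gen_params(seed = 5,
                           fate_params = fate_gen_params(logistic_width = 0,
                                                         seed = 5))
  colq <- gen_colony(cpq)
  bq <- radial_bin(colq$positions, 350)
  kq <- kymograph(colq$histories, bq)
  clq <- cluster_radial_histories(kq, k = 3, seed = 1)
  fmq <- fate_map(fate_score(colq$fates)$label, bq)
  expect_equal(map_agreement(as.character(clq$cluster), fmq), 1)
})

test_that("dose-response threshold: round trip, step, binomial noise", {
  x <- seq(10, 40, by = 2)
  y <- 1 / (1 + exp(-(x - 26) / 2))
  expect_equal(threshold_from_dose_response(x, y)$threshold, 26,
               tolerance = 1e-6)

  # all-0/all-1 two-point step: midpoint between the two feature values
  st <- threshold_from_dose_response(c(20, 30), c(0, 1))
  expect_equal(st$threshold, 25, tolerance = 1)

  expect_error(threshold_from_dose_response(x, y / 10), "cross 50")

  set.seed(3)
  errs <- replicate(40, {
    frac <- rbinom(length(x), 200, 1 / (1 + exp(-(x - 26) / 2))) / 200
    abs(threshold_from_dose_response(x, frac)$threshold - 26) / 26
  })
  expect_lt(median(errs), 0.05)
})

test_that("integral collapse holds for the integral model and fails for the level model", {
  dr <- gen_dose_response(model = "integral", seed = 11)
  ct <- collapse_test(dr)
  expect_lt(ct$sigma_cv, 0.02)
  expect_gt(ct$feature_shift, 0.15)
  # model discrimination: integral CV strictly below the level model's
  dr2 <- gen_dose_response(model = "level_duration", seed = 11)
  ct2 <- collapse_test(dr2)
  expect_gt(ct2$sigma_cv, 0.15)
  expect_gt(ct2$sigma_cv, ct$sigma_cv)
  expect_error(collapse_test(dr[dr$level == 1, ]), "2 conditions")
})

test_that("pulsed inputs share the single-pulse integral threshold", {
  # one pulse of duration D vs two half-pulses: same integral, same fate
  set.seed(12)
  durs <- seq(18, 42, length.out = 6)
  one <- gen_dose_response(levels = 1, durations = durs, seed = 12)
  one$level <- "single"
  two <- one
  two$level <- "split"
  two$fraction <- rbinom(nrow(two), 200,
                         plogis((two$sigma - 26) / 2)) / 200
  ct <- collapse_test(rbind(one, two), group_col = "level")
  expect_lt(ct$sigma_cv, 0.02)
})

test_that("shutdown-style per-bin dose response feeds the collapse test", {
  col <- gen_colony(colony_gen_params(seed = 6))
  b <- radial_bin(col$positions, 350)
  kym <- kymograph(col$histories, b) - 1  # baseline-subtracted
  sdr <- shutdown_dose_response(kym, col$time, 30,
                                fate_score(col$fates)$score, b)
  expect_equal(nrow(sdr), 30)
  expect_true(all(sdr$fraction >= 0 & sdr$fraction <= 1))
  expect_true(all(diff(sdr$level) < 0.2))  # level decreases toward center
})
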