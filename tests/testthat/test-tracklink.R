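make_detections <- function(frames, xs, ys, cls = "interphase", ids = NULL) {
  n <- length(frames)
  data.frame(frame = frames,
             detection_id = ids %||% seq_len(n),
             x = xs, y = ys,
             division_class = rep_len(cls, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stationary well-separated points give clean tracks", {
  det <- make_detections(rep(1:10, each = 2),
                         rep(c(0, 100), 10), rep(c(0, 0), 10))
  ts <- link_frames(det, max_disp = 15)
  expect_equal(length(unique(ts$assignments$track_id)), 2)
  expect_equal(nrow(ts$links), 18)  # 9 links per track
  # each track keeps a constant x
  xs <- tapply(det$x[match(ts$assignments$detection_id, det$detection_id)],
               ts$assignments$track_id, function(v) length(unique(v)))
  expect_true(all(xs == 1))
})

test_that("frame-to-frame assignment equals the brute-force minimum cost", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    from <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    to <- from + matrix(rnorm(2 * n, 0, 2), n)  # small per-step motion
    oracle <- brute_force_pairing(from, to)
    det <- rbind(make_detections(rep(1, n), from[, 1], from[, 2],
                                 ids = 1:n),
                 make_detections(rep(2, n), to[, 1], to[, 2],
                                 ids = n + 1:n))
    ts <- link_frames(det, max_disp = 100)
    got <- ts$links[order(ts$links$from_detection), ]
    expect_equal(got$to_detection - n, oracle$assignment)
  }
})

test_that("points swapping positions are matched by global minimum cost", {
  # two points approach and pass each other with small per-step motion
  det <- rbind(make_detections(c(1, 1), c(0, 10), c(0, 0), ids = 1:2),
               make_detections(c(2, 2), c(4, 6), c(0, 0), ids = 3:4),
               make_detections(c(3, 3), c(10, 0), c(0, 0), ids = 5:6))
  ts <- link_frames(det, max_disp = 8)
  tid <- stats::setNames(ts$assignments$track_id, ts$assignments$detection_id)
  expect_equal(tid[["1"]], tid[["3"]])  # 0 -> 4 cheaper than 0 -> 6
  expect_equal(tid[["2"]], tid[["4"]])
})

test_that("a jump beyond max_disp terminates the track and births a new one", {
  det <- make_detections(1:3, c(0, 1, 50), c(0, 0, 0))
  ts <- link_frames(det, max_disp = 10, max_gap = 0)
  tid <- ts$assignments$track_id
  expect_equal(tid[1], tid[2])
  expect_false(tid[3] == tid[1])
})

test_that("junk detections are excluded before linking", {
  det <- make_detections(c(1, 1, 2), c(0, 0.5, 0), c(0, 0, 0),
                         cls = c("interphase", "junk", "interphase"))
  ts <- link_frames(det, max_disp = 10)
  expect_false(2 %in% ts$assignments$detection_id)
  expect_equal(length(unique(ts$assignments$track_id)), 1)
})

test_that("assignment is invariant to detection row order", {
  set.seed(9)
  fx <- gen_tracking_fixture(30, 10, seed = 9)
  ts1 <- link_frames(fx$detections, max_disp = 15)
  shuffled <- fx$detections[sample(nrow(fx$detections)), ]
  ts2 <- link_frames(shuffled, max_disp = 15)
  l1 <- ts1$links[order(ts1$links$from_detection), ]
  l2 <- ts2$links[order(ts2$links$from_detection), ]
  expect_equal(l1, l2, ignore_attr = TRUE)
})

test_that("raising max_disp never decreases the number of links", {
  fx <- gen_tracking_fixture(40, 15, step_sd = 4, seed = 13)
  n_links <- vapply(c(5, 10, 20, 40), function(md)
    nrow(link_frames(fx$detections, max_disp = md)$links), numeric(1))
  expect_true(all(diff(n_links) >= 0))
})

test_that("no track holds two detections in one frame; divisions keep counts", {
  fx <- gen_tracking_fixture(60, 40, division_prob = 0.004, seed = 2)
  ts <- resolve_divisions(link_frames(fx$detections, max_disp = 15),
                          fx$detections, division_radius = 15)
  dup <- tapply(ts$assignments$frame,
                ts$assignments$track_id, anyDuplicated)
  expect_true(all(dup == 0))
  expect_equal(nrow(ts$assignments), nrow(fx$detections))
})

test_that("division resolution builds the lineage tree", {
  # hand-built fixture: one cell divides at frame 2
  det <- rbind(
    make_detections(1, 0, 0, "interphase", ids = 1),
    make_detections(2, 0.5, 0, "metaphase", ids = 2),
    make_detections(c(3, 3), c(-4, 5), c(0, 0), "interphase", ids = 3:4),
    make_detections(4, -4.5, 0, "interphase", ids = 5),
    make_detections(4, 5.5, 0, "interphase", ids = 6))
  ts <- resolve_divisions(link_frames(det, max_disp = 10), det,
                          division_radius = 8)
  kids <- ts$tracks$track_id[!is.na(ts$tracks$parent)]
  expect_length(kids, 2)
  parent <- unique(ts$tracks$parent[!is.na(ts$tracks$parent)])
  tid <- stats::setNames(ts$assignments$track_id, ts$assignments$detection_id)
  expect_equal(unname(tid[["2"]]), parent)
  expect_setequal(unname(tid[c("3", "4")]), kids)
  expect_equal(unname(tid[["5"]]), unname(tid[["3"]]))

  # metaphase with a single nearby successor: plain continuation, no split
  det2 <- rbind(make_detections(1, 0, 0, "metaphase", ids = 1),
                make_detections(2, 1, 0, "interphase", ids = 2))
  ts2 <- resolve_divisions(link_frames(det2, max_disp = 10), det2,
                           division_radius = 8)
  expect_equal(length(unique(ts2$assignments$track_id)), 1)
  expect_true(all(is.na(ts2$tracks$parent)))
})

test_that("live-to-fixed matching handles shifts, dropouts and jitter", {
  set.seed(4)
  live <- data.frame(detection_id = 1:40,
                     x = runif(40, 0, 400), y = runif(40, 0, 400))
  fixed <- live
  fixed$x <- fixed$x + 2  # constant 2 um shift
  m <- match_live_fixed(live, fixed, max_disp = 10)
  expect_equal(nrow(m$matches), 40)
  expect_true(all(m$matches$live_id == m$matches$fixed_id))

  m2 <- match_live_fixed(live, fixed[-7, ], max_disp = 10)
  expect_equal(m2$unmatched_live, 7)

  # 10% deleted plus 3 um jitter at sparse-labeling density
  set.seed(8)
  live3 <- data.frame(detection_id = 1:100,
                      x = runif(100, 0, 600), y = runif(100, 0, 600))
  keep <- sort(sample(100, 90))
  fixed3 <- live3[keep, ]
  fixed3$x <- fixed3$x + rnorm(90, 0, 3)
  fixed3$y <- fixed3$y + rnorm(90, 0, 3)
  m3 <- match_live_fixed(live3, fixed3, max_disp = 15)
  acc <- mean(m3$matches$live_id == m3$matches$fixed_id)
  expect_gt(acc * nrow(m3$matches) / 90, 0.95)
})

test_that("track metrics count correct links, divisions and purity", {
  fx <- gen_tracking_fixture(50, 30, division_prob = 0.003, seed = 3)
  perfect <- perfect_trackset(fx)
  m <- track_metrics(perfect, fx)
  expect_equal(m$link_accuracy, 1)
  expect_equal(m$division_recall, 1)
  expect_equal(m$track_purity, 1)

  broken <- perfect
  broken$links <- broken$links[0, ]
  expect_equal(track_metrics(broken, fx)$link_accuracy, 0)

  # one wrong link among the true ones
  one_off <- perfect
  one_off$links$to_detection[1] <- -1
  m2 <- track_metrics(one_off, fx)
  n <- nrow(fx$true_links)
  expect_equal(m2$link_accuracy, (n - 1) / n)

  bad <- perfect
  bad$assignments <- bad$assignments[-1, ]
  expect_error(track_metrics(bad, fx), "different detections")
})
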