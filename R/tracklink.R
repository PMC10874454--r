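#' @importFrom clue solve_LSAP
NULL

BIG_COST <- 1e12

# Solve one frame-to-frame linking step with births and deaths.
#
# Augmented square cost matrix in the LAP-tracker convention (Jaqaman et al.
# 2008): top-left the gated squared-displacement costs, top-right a diagonal
# death block, bottom-left a
# diagonal birth block, bottom-right the transposed cost block as filler.
# Returns for each source row the matched target column index or NA (death);
# targets with no source are births.
lap_link <- function(cost, bd_cost) {
  n <- nrow(cost); m <- ncol(cost)
  finite <- cost[is.finite(cost) & cost < BIG_COST]
  if (!length(finite)) return(rep(NA_integer_, n))
  death <- matrix(BIG_COST, n, n); diag(death) <- bd_cost
  birth <- matrix(BIG_COST, m, m); diag(birth) <- bd_cost
  lower <- t(cost)
  lower[lower < BIG_COST] <- min(finite)
  aug <- rbind(cbind(cost, death), cbind(birth, lower))
  sol <- clue::solve_LSAP(aug)
  assign <- as.integer(sol)[seq_len(n)]
  assign[assign > m] <- NA_integer_
  assign
}

link_cost_matrix <- function(from_xy, to_xy, max_disp) {
  d2 <- outer(from_xy[, 1], to_xy[, 1], "-")^2 +
    outer(from_xy[, 2], to_xy[, 2], "-")^2
  d2[d2 > max_disp^2] <- BIG_COST
  d2
}

birth_death_cost <- function(cost) {
  valid <- cost[cost < BIG_COST]
  if (!length(valid)) return(1)
  # LAP-tracker convention (Jaqaman et al. 2008): 1.05 x the 90th percentile
  max(stats::quantile(valid, 0.9) * 1.05, 1e-9)
}

validate_detections <- function(detections) {
  need <- c("frame", "detection_id", "x", "y")
  if (!all(need %in% names(detections)))
    stop("detections must have columns frame, detection_id, x, y")
  if (anyDuplicated(detections[, c("frame", "detection_id")]))
    stop("(frame, detection_id) must be unique")
  if (!all(is.finite(detections$x)) || !all(is.finite(detections$y)))
    stop("coordinates must be finite")
  invisible(detections)
}

#' Link detections across frames into tracks
#'
#' Frame-to-frame linking by global assignment minimizing total squared
#' displacement, with birth and death costs (1.05 x the 90th percentile of
#' linking costs) permitting unmatched detections, followed by a gap-closing
#' pass joining track ends to track starts across up to `max_gap` skipped
#' frames. Junk-class detections are dropped before linking. Deterministic;
#' detections are processed in `detection_id` order so the result is invariant
#' to input row order.
#'
#' @param detections data.frame with `frame` (consecutive integers),
#'   `detection_id`, `x`, `y` (um) and optionally `division_class`.
#' @param max_disp maximum linking displacement per frame (um), > 0.
#' @param max_gap maximum number of skipped frames closed by gap closing
#'   (default 1; at a 10-minute imaging interval longer gaps are unreliable).
#' @return A list of class `track_set`: `assignments` (frame, detection_id,
#'   track_id), `tracks` (track_id, parent), `links` (from_detection,
#'   to_detection).
#' @export
link_frames <- function(detections, max_disp, max_gap = 1L) {
  validate_detections(detections)
  if (max_disp <= 0) stop("max_disp must be positive")
  det <- detections
  if ("division_class" %in% names(det)) det <- det[det$division_class != "junk", ]
  det <- det[order(det$frame, det$detection_id), ]
  frames <- sort(unique(det$frame))

  track_of <- integer(0)      # names: detection_id
  parent <- integer(0)        # per track
  next_track <- 1L
  links <- list()
  # active track fronts: detection id, x, y, frame, track
  front <- data.frame(detection_id = integer(0), x = numeric(0),
                      y = numeric(0), frame = integer(0), track = integer(0))

  for (f in frames) {
    cur <- det[det$frame == f, ]
    # candidate sources: fronts within the gap window
    src <- front[front$frame >= f - 1L - max_gap & front$frame <= f - 1L, ]
    assign <- rep(NA_integer_, nrow(src))
    if (nrow(src) && nrow(cur)) {
      cost <- link_cost_matrix(as.matrix(src[, c("x", "y")]),
                               as.matrix(cur[, c("x", "y")]), max_disp)
      # penalize gap links so same-frame links win ties
      gap <- f - src$frame - 1L
      cost <- cost + gap * 1e-9
      cost[cost > BIG_COST] <- BIG_COST
      assign <- lap_link(cost, birth_death_cost(cost))
    }
    matched_targets <- stats::na.omit(assign)
    new_front <- cur
    new_front$track <- NA_integer_
    if (nrow(src)) for (i in seq_len(nrow(src))) {
      j <- assign[i]
      if (is.na(j)) next
      tid <- src$track[i]
      did <- cur$detection_id[j]
      track_of[as.character(did)] <- tid
      links[[length(links) + 1L]] <- c(src$detection_id[i], did)
      new_front$track[j] <- tid
    }
    for (j in which(is.na(new_front$track))) {
      tid <- next_track; next_track <- next_track + 1L
      parent[tid] <- NA_integer_
      track_of[as.character(new_front$detection_id[j])] <- tid
      new_front$track[j] <- tid
    }
    # keep unmatched fronts alive within the gap window, replace matched ones
    stale <- front$track %in% new_front$track | front$frame < f - max_gap
    front <- rbind(front[!stale, ],
                   data.frame(detection_id = new_front$detection_id,
                              x = new_front$x, y = new_front$y,
                              frame = f, track = new_front$track))
  }

  assignments <- data.frame(
    frame = det$frame, detection_id = det$detection_id,
    track_id = unname(track_of[as.character(det$detection_id)]))
  links_df <- if (length(links)) {
    l <- do.call(rbind, links)
    data.frame(from_detection = l[, 1], to_detection = l[, 2])
  } else data.frame(from_detection = integer(0), to_detection = integer(0))
  structure(list(assignments = assignments,
                 tracks = data.frame(track_id = seq_len(next_track - 1L),
                                     parent = unname(parent[seq_len(next_track - 1L)])),
                 links = links_df),
            class = "track_set")
}

#' Resolve cell divisions in a linked track set
#'
#' A metaphase-class detection at frame `t` may link to two detections at
#' frame `t + 1` within `division_radius`: its own linked successor plus
#' track-start (birth) detections nearby. When two or more candidates exist,
#' the two lowest-cost ones become daughters: each daughter starts a new track
#' whose `parent` is the metaphase cell's track. A metaphase detection with a
#' single nearby successor keeps its one-to-one link (no spurious second
#' child). More than two candidates triggers a warning; the best two are kept.
#'
#' @param trackset a `track_set` from [link_frames()].
#' @param detections the detection table used for linking (must carry
#'   `division_class`).
#' @param division_radius maximum parent-to-daughter displacement (um).
#' @return The modified `track_set`, with daughter tracks parented.
#' @export
resolve_divisions <- function(trackset, detections, division_radius) {
  stopifnot(inherits(trackset, "track_set"))
  if (!"division_class" %in% names(detections))
    stop("detections must carry division_class labels")
  asn <- trackset$assignments
  tracks <- trackset$tracks
  links <- trackset$links
  det <- detections[match(asn$detection_id, detections$detection_id), ]
  next_track <- max(tracks$track_id) + 1L

  meta <- asn$detection_id[det$division_class == "metaphase"]
  for (mid in meta) {
    mrow <- which(asn$detection_id == mid)
    f <- asn$frame[mrow]
    mtrack <- asn$track_id[mrow]
    mx <- det$x[mrow]; my <- det$y[mrow]
    nxt <- which(asn$frame == f + 1L)
    if (!length(nxt)) next
    d2 <- (det$x[nxt] - mx)^2 + (det$y[nxt] - my)^2
    # candidates: own successor, or detections that start a track at f+1
    succ <- links$to_detection[links$from_detection == mid]
    starts <- vapply(nxt, function(i) {
      tid <- asn$track_id[i]
      min(asn$frame[asn$track_id == tid]) == f + 1L
    }, logical(1))
    cand <- nxt[(asn$detection_id[nxt] %in% succ | starts) &
                  d2 <= division_radius^2]
    if (length(cand) < 2L) next
    cd2 <- (det$x[cand] - mx)^2 + (det$y[cand] - my)^2
    if (length(cand) > 2L) {
      warning("metaphase detection ", mid, ": >2 daughter candidates, keeping best two")
    }
    cand <- cand[order(cd2, asn$detection_id[cand])][1:2]
    for (ci in cand) {
      old_track <- asn$track_id[ci]
      did <- asn$detection_id[ci]
      new_id <- next_track; next_track <- next_track + 1L
      tracks <- rbind(tracks, data.frame(track_id = new_id, parent = mtrack))
      # move this detection and all later detections of its old track
      move <- asn$track_id == old_track & asn$frame >= f + 1L
      asn$track_id[move] <- new_id
      # rewire links: the metaphase -> daughter link
      if (!did %in% succ)
        links <- rbind(links, data.frame(from_detection = mid,
                                         to_detection = did))
    }
  }
  structure(list(assignments = asn, tracks = tracks, links = links),
            class = "track_set")
}

#' Match the last live frame to fixed-cell detections
#'
#' One-to-one partial matching minimizing total squared displacement, with
#' birth/death costs so cells missing from either table stay unmatched --- the
#' same global-assignment machinery used for frame-to-frame linking, applied
#' between the final live frame and the fixed (stained) detections.
#'
#' @param live,fixed data.frames with `detection_id`, `x`, `y`; both nonempty.
#' @param max_disp maximum matching displacement (um).
#' @return list with `matches` (live_id, fixed_id), `unmatched_live`,
#'   `unmatched_fixed`.
#' @export
match_live_fixed <- function(live, fixed, max_disp) {
  if (!nrow(live) || !nrow(fixed)) stop("both tables must be nonempty")
  live <- live[order(live$detection_id), ]
  fixed <- fixed[order(fixed$detection_id), ]
  cost <- link_cost_matrix(as.matrix(live[, c("x", "y")]),
                           as.matrix(fixed[, c("x", "y")]), max_disp)
  assign <- lap_link(cost, birth_death_cost(cost))
  ok <- !is.na(assign)
  list(matches = data.frame(live_id = live$detection_id[ok],
                            fixed_id = fixed$detection_id[assign[ok]]),
       unmatched_live = live$detection_id[!ok],
       unmatched_fixed = setdiff(fixed$detection_id,
                                 fixed$detection_id[assign[ok]]))
}

#' Tracking performance against ground truth
#'
#' @param trackset a `track_set`.
#' @param fixture a `tracking_fixture` from [gen_tracking_fixture()] (or any
#'   list with `true_links` and `truth`).
#' @return list with `link_accuracy` (correct frame-to-frame links / true
#'   links, parent-daughter links included), `division_recall` (true divisions
#'   with both daughter links recovered), `track_purity` (detection-weighted
#'   max single-truth-track fraction per predicted track).
#' @export
track_metrics <- function(trackset, fixture) {
  stopifnot(inherits(trackset, "track_set"))
  truth_map <- fixture$truth$detection_track
  asn <- trackset$assignments
  if (!setequal(asn$detection_id, truth_map$detection_id))
    stop("trackset and truth cover different detections")
  true_links <- fixture$true_links
  key <- function(df) paste(df$from_detection, df$to_detection)
  correct <- sum(key(trackset$links) %in% key(true_links))
  link_accuracy <- if (nrow(true_links)) correct / nrow(true_links) else NA_real_

  # divisions: true parents with two daughter tracks
  tr <- fixture$truth$tracks
  parents <- unique(tr$parent[!is.na(tr$parent)])
  recalled <- 0L
  for (p in parents) {
    kids <- tr$track_id[!is.na(tr$parent) & tr$parent == p]
    dt <- fixture$truth$detection_track
    first_det <- vapply(kids, function(k) {
      ids <- dt$detection_id[dt$track_id == k]
      ids[which.min(fixture$detections$frame[match(ids, fixture$detections$detection_id)])]
    }, numeric(1))
    pl <- true_links[true_links$to_detection %in% first_det, ]
    if (all(key(pl) %in% key(trackset$links))) recalled <- recalled + 1L
  }
  division_recall <- if (length(parents)) recalled / length(parents) else NA_real_

  m <- merge(asn, truth_map, by = "detection_id",
             suffixes = c("_pred", "_true"))
  purity <- vapply(split(m$track_id_true, m$track_id_pred),
                   function(tt) max(table(tt)) / length(tt), numeric(1))
  sizes <- vapply(split(m$track_id_true, m$track_id_pred), length, numeric(1))
  list(link_accuracy = link_accuracy,
       division_recall = division_recall,
       track_purity = sum(purity * sizes) / sum(sizes))
}
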