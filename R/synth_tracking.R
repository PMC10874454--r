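#' Generate a tracking fixture: random-walk nuclei with divisions
#'
#' Emulates the sparse-labeling tracking regime (10-20% of nuclei carry the
#' label, imaged every 10 minutes): labeled nuclei perform independent 2D
#' Gaussian random walks in a square field; a dividing cell emits a
#' metaphase-class detection, then two daughters displaced symmetrically about
#' the parent position in the next frame.
#'
#' @param n_cells initial number of labeled cells.
#' @param n_frames number of frames.
#' @param step_sd random-walk step SD per frame (um); 3 um is a typical
#'   nuclear displacement over a 10-minute interval.
#' @param division_prob per-cell per-frame division probability.
#' @param label_fraction fraction of all nuclei that are labeled, in (0, 1];
#'   sets the field size so labeled-cell density matches sparse labeling at a
#'   total density of ~2000 cells/mm^2.
#' @param daughter_sep distance between the two daughters at birth (um).
#' @param seed integer seed.
#' @return A list of class `tracking_fixture`: `detections` (frame,
#'   detection_id, x, y, division_class), `truth` with `detection_track`
#'   (detection_id -> track_id) and `tracks` (track_id, parent), and
#'   `true_links` (from_detection, to_detection pairs in consecutive frames,
#'   including parent-to-daughter links).
#' @export
gen_tracking_fixture <- function(n_cells = 100L, n_frames = 50L, step_sd = 3,
                                 division_prob = 0.002,
                                 label_fraction = 0.15, daughter_sep = 10,
                                 seed = 1L) {
  if (label_fraction <= 0 || label_fraction > 1)
    stop("label_fraction must be in (0, 1]")
  if (n_cells < 1 || n_frames < 1) stop("n_cells and n_frames must be positive")
  if (step_sd < 0 || division_prob < 0 || division_prob > 1)
    stop("invalid step_sd or division_prob")
  set.seed(substream_seed(seed, "tracking"))

  # field sized so labeled density = label_fraction * 2000 cells/mm^2
  area_mm2 <- n_cells / (label_fraction * 2000)
  side <- sqrt(area_mm2) * 1000  # um

  next_track <- 1L
  next_det <- 1L
  active <- list()  # each: track_id, x, y
  for (i in seq_len(n_cells)) {
    active[[i]] <- list(track_id = next_track,
                        x = stats::runif(1, 0, side),
                        y = stats::runif(1, 0, side))
    next_track <- next_track + 1L
  }
  tracks <- data.frame(track_id = seq_len(n_cells), parent = NA_integer_)
  det <- list()
  dt_map <- list()
  links <- list()
  last_det <- rep(NA_integer_, n_cells + 64L)  # last detection id per track

  emit <- function(frame, tr, x, y, cls) {
    id <- next_det
    det[[id]] <<- data.frame(frame = frame, detection_id = id, x = x, y = y,
                             division_class = cls, stringsAsFactors = FALSE)
    dt_map[[id]] <<- c(detection = id, track = tr)
    if (tr > length(last_det)) last_det <<- c(last_det, rep(NA_integer_, tr))
    prev <- last_det[tr]
    if (!is.na(prev)) links[[length(links) + 1L]] <<- c(prev, id)
    last_det[tr] <<- id
    next_det <<- next_det + 1L
    id
  }

  dividing <- integer(0)  # track ids that divided this frame (split next frame)
  div_pos <- list()
  for (f in seq_len(n_frames)) {
    new_active <- list()
    # daughters from divisions in the previous frame
    for (tr in dividing) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- daughter_sep / 2 * c(cos(ang), sin(ang))
      px <- div_pos[[as.character(tr)]][1]
      py <- div_pos[[as.character(tr)]][2]
      parent_det <- last_det[tr]
      for (s in c(1, -1)) {
        dtr <- next_track; next_track <- next_track + 1L
        tracks <- rbind(tracks, data.frame(track_id = dtr, parent = tr))
        x <- px + s * off[1] + stats::rnorm(1, 0, step_sd)
        y <- py + s * off[2] + stats::rnorm(1, 0, step_sd)
        id <- emit(f, dtr, x, y, "interphase")
        links[[length(links) + 1L]] <- c(parent_det, id)
        new_active[[length(new_active) + 1L]] <- list(track_id = dtr, x = x, y = y)
      }
    }
    dividing <- integer(0)
    for (cell in active) {
      x <- cell$x + stats::rnorm(1, 0, step_sd)
      y <- cell$y + stats::rnorm(1, 0, step_sd)
      divide <- f < n_frames && stats::runif(1) < division_prob
      cls <- if (divide) "metaphase" else "interphase"
      emit(f, cell$track_id, x, y, cls)
      if (divide) {
        dividing <- c(dividing, cell$track_id)
        div_pos[[as.character(cell$track_id)]] <- c(x, y)
      } else {
        new_active[[length(new_active) + 1L]] <-
          list(track_id = cell$track_id, x = x, y = y)
      }
    }
    active <- new_active
  }

  detections <- do.call(rbind, det)
  dmap <- do.call(rbind, dt_map)
  detection_track <- data.frame(detection_id = dmap[, "detection"],
                                track_id = dmap[, "track"])
  true_links <- if (length(links)) {
    l <- do.call(rbind, links)
    data.frame(from_detection = l[, 1], to_detection = l[, 2])
  } else {
    data.frame(from_detection = integer(0), to_detection = integer(0))
  }
  structure(list(detections = detections,
                 truth = list(detection_track = detection_track,
                              tracks = tracks),
                 true_links = true_links, field_side = side),
            class = "tracking_fixture")
}
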