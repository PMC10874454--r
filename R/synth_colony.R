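#' Parameters for the micropattern colony generator
#'
#' Emulates a 700 um-diameter circular micropatterned colony in which BMP
#' signaling is organized radially: cells fall into concentric signaling
#' classes by distance from the colony edge, each class with its own
#' signaling-history distribution. Defaults give three classes -- sustained
#' signaling at the edge (duration 40 h), intermediate in the middle ring
#' (30 h) and transient in the center (12 h) -- so the outer rings exceed the
#' 26 ratio x hour integral threshold and differentiate.
#'
#' @param radius colony radius (um), default 350.
#' @param n_cells number of cells, default 900 (30 per radial bin at 30 bins).
#' @param class_boundaries strictly increasing edge distances (um) separating
#'   the classes; `length(class_boundaries) + 1` classes.
#' @param class_histories list of [history_gen_params()] objects, one per
#'   class, ordered edge to center (`n_cells` fields are ignored).
#' @param fate_params a [fate_gen_params()] for fate assignment.
#' @param seed integer seed.
#' @return A list of class `colony_gen_params`.
#' @export
colony_gen_params <- function(radius = 350, n_cells = 900L,
                              class_boundaries = c(60, 150),
                              class_histories = NULL,
                              fate_params = fate_gen_params(),
                              seed = 1L) {
  if (is.null(class_histories)) {
    class_histories <- lapply(c(40, 30, 12), function(d)
      history_gen_params(duration_mean = d, duration_sd = 1.5))
  }
  if (any(diff(class_boundaries) <= 0) ||
      any(class_boundaries <= 0) || any(class_boundaries >= radius))
    stop("class_boundaries must be strictly increasing within (0, radius)")
  if (length(class_histories) != length(class_boundaries) + 1L)
    stop("need one class_histories entry per radial class (boundaries + 1)")
  p <- as.list(environment())
  class(p) <- "colony_gen_params"
  p
}

#' Generate a synthetic micropatterned colony
#'
#' Places cells uniformly in the disc, draws each cell's signaling history
#' from the generator of its edge-distance class, and assigns fates from the
#' true signaling integrals via [gen_fates()].
#'
#' @param params a [colony_gen_params()] object.
#' @return A list of class `colony_set`: `positions` (cell_id, x, y,
#'   edge_dist, class), `histories`, `time`, `truth` (per-cell sigmoid
#'   features, integral and class), and `fates` (a FateTable).
#' @export
gen_colony <- function(params) {
  stopifnot(inherits(params, "colony_gen_params"))
  set.seed(substream_seed(params$seed, "colony"))
  n <- as.integer(params$n_cells)
  r <- params$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  edge <- params$radius - r
  cls <- findInterval(edge, c(params$class_boundaries, params$radius),
                      left.open = FALSE) + 1L
  cls <- pmin(cls, length(params$class_histories))
  ids <- sprintf("cell_%04d", seq_len(n))
  positions <- data.frame(cell_id = ids, x = r * cos(th), y = r * sin(th),
                          edge_dist = edge, class = cls,
                          stringsAsFactors = FALSE)

  # draw the whole-class history sets, then pick each cell's row
  hist <- NULL
  truth <- NULL
  for (k in seq_along(params$class_histories)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    hp <- params$class_histories[[k]]
    hp$n_cells <- length(idx)
    hp$seed <- substream_seed(params$seed, paste0("colony_class_", k))
    hs <- gen_histories(hp)
    if (is.null(hist)) {
      hist <- matrix(NA_real_, n, ncol(hs$histories),
                     dimnames = list(ids, colnames(hs$histories)))
      tgrid <- hs$time
      truth <- data.frame(cell_id = ids, H = NA_real_, L = NA_real_,
                          d = NA_real_, tau = NA_real_, integral = NA_real_,
                          class = cls, stringsAsFactors = FALSE)
    }
    hist[idx, ] <- hs$histories
    truth[idx, c("H", "L", "d", "tau", "integral")] <-
      hs$truth[, c("H", "L", "d", "tau", "integral")]
  }

  fp <- params$fate_params
  fp$seed <- substream_seed(params$seed, "colony_fates")
  fates <- gen_fates(truth, fp)
  structure(list(positions = positions, histories = hist, time = tgrid,
                 truth = truth, fates = fates, params = params),
            class = "colony_set")
}
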