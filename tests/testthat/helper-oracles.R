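# Independent oracles used across tests.

# Brute-force minimum-cost full pairing of two equal-size point sets
# (enumerates all permutations; total cost = sum of squared displacements).
brute_force_pairing <- function(from_xy, to_xy) {
  n <- nrow(from_xy)
  perms <- signalfate:::permutations_of(seq_len(n))
  best <- NULL
  best_cost <- Inf
  for (p in perms) {
    cost <- sum((from_xy[, 1] - to_xy[p, 1])^2 +
                  (from_xy[, 2] - to_xy[p, 2])^2)
    if (cost < best_cost) {
      best_cost <- cost
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

# Exhaustive threshold scan: every midpoint between sorted unique values plus
# sentinels; predicts amnion above the cut.
exhaustive_threshold_scan <- function(values, labels) {
  pos <- labels == "amnion" | labels == TRUE
  u <- sort(unique(values))
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  accs <- vapply(cuts, function(cut)
    mean((values > cut) == pos), numeric(1))
  list(accuracy = max(accs), cuts = cuts, accs = accs)
}

# Plug-in mutual information of a 2x2 table, direct entropy computation.
entropy_mi_oracle <- function(m) {
  p <- m / sum(m)
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  H(rowSums(p)) + H(colSums(p)) - H(as.vector(p))
}

# Build the perfect track_set implied by a tracking fixture's ground truth.
perfect_trackset <- function(fixture) {
  asn <- merge(fixture$detections[, c("frame", "detection_id")],
               fixture$truth$detection_track, by = "detection_id")
  structure(list(assignments = asn[, c("frame", "detection_id", "track_id")],
                 tracks = fixture$truth$tracks,
                 links = fixture$true_links),
            class = "track_set")
}

f1_score <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  if (!length(predicted) && !length(truth)) return(1)
  2 * tp / (length(predicted) + length(truth))
}

# Clean sigmoid matrix from a history_set's ground truth.
true_sigmoids <- function(hs) {
  t(vapply(seq_len(nrow(hs$truth)), function(i)
    sigmoid_response(hs$time, hs$truth$H[i], hs$truth$L[i], hs$truth$d[i],
                     hs$truth$tau[i]),
    numeric(length(hs$time))))
}
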