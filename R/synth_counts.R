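#' Generate synthetic RNA-seq count matrices with planted temporal classes
#'
#' Genes belong to one of four classes: `decreasing` (pluripotency-like,
#' continuously falling after BMP), `immediate` (immediately increasing),
#' `delayed` (late increasing) and `flat`. The time series follows per-class
#' templates; the dose series at the 5 h timepoint has immediate-responding
#' classes (immediate up, decreasing down) scaling proportionally with the
#' SMAD4 level, while delayed and flat genes do not respond at 5 h. Counts are
#' drawn with negative-binomial overdispersion.
#'
#' @param n_genes number of genes.
#' @param class_fractions named fractions for `decreasing`, `immediate`,
#'   `delayed` (remainder flat); must sum to <= 1. Defaults of 5% per class
#'   mirror the proportions of changing genes among expressed genes in a
#'   BMP-treatment time course.
#' @param low_fraction fraction of genes expressed near zero (below the usual
#'   2.5 CPM filter); drawn from the flat class.
#' @param timepoints time series sampling times (hours), must include 0.
#' @param dose_levels SMAD4 signaling levels of the dose series (normalized,
#'   0-1), sampled at 5 h.
#' @param library_size expected counts per sample.
#' @param dispersion negative-binomial size parameter (larger = less noise).
#' @param tf_fraction fraction of genes flagged as transcription factors.
#' @param noise if `FALSE`, return expected (possibly non-integer) counts --
#'   the zero-noise oracle mode.
#' @param seed integer seed.
#' @return A list of class `count_set`: `time_counts` (genes x timepoints),
#'   `dose_counts` (genes x doses), `timepoints`, `dose_levels`, and `truth`
#'   (gene, class, is_tf, base expression).
#' @export
gen_counts <- function(n_genes = 1000L,
                       class_fractions = c(decreasing = 0.05,
                                           immediate = 0.05, delayed = 0.05),
                       low_fraction = 0.15,
                       timepoints = c(0, 2, 5, 9, 14, 21, 30, 42),
                       dose_levels = seq(0.125, 1, by = 0.125),
                       library_size = 2e6, dispersion = 400,
                       tf_fraction = 0.3, noise = TRUE, seed = 1L) {
  if (!length(timepoints)) stop("timepoints must be non-empty")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  need <- c("decreasing", "immediate", "delayed")
  fr <- class_fractions[need]
  fr[is.na(fr)] <- 0
  if (sum(fr) > 1 + 1e-12) stop("class fractions must sum to <= 1")
  set.seed(substream_seed(seed, "counts"))

  n <- as.integer(n_genes)
  counts_per_class <- floor(fr * n)
  classes <- rep("flat", n)
  idx <- sample.int(n)
  pos <- 1L
  for (cl in need) {
    k <- counts_per_class[[cl]]
    if (k > 0) classes[idx[pos:(pos + k - 1L)]] <- cl
    pos <- pos + k
  }
  is_tf <- stats::runif(n) < tf_fraction
  base <- exp(stats::rnorm(n, log(50), 1.5))
  # a fraction of (flat) genes are near-silent, below the usual CPM filter
  low <- classes == "flat" & stats::runif(n) < low_fraction / max(1 - sum(fr), 1e-9)
  base[low] <- exp(stats::rnorm(sum(low), log(0.1), 0.8))

  template <- function(cl, t) {
    switch(cl,
      flat = rep(1, length(t)),
      decreasing = 0.15 + 0.85 * exp(-t / 8),
      immediate = 0.15 + 0.85 * (1 - exp(-t / 3)),
      delayed = 0.15 + 0.85 * stats::plogis((t - 18) / 4))
  }
  # dose response of expected expression at 5 h: immediate-responding classes
  # are linear in the SMAD4 level over their full dynamic range (integrator
  # behavior: transcription rate proportional to signaling), delayed and flat
  # genes do not respond at 5 h
  dose_template <- function(cl, level) {
    switch(cl,
      flat = rep(1, length(level)),
      decreasing = 1 - 0.85 * level,
      immediate = 0.15 + 0.85 * level,
      delayed = rep(template("delayed", 5), length(level)))
  }

  mu_time <- t(vapply(seq_len(n), function(i)
    base[i] * template(classes[i], timepoints), numeric(length(timepoints))))
  mu_dose <- t(vapply(seq_len(n), function(i)
    base[i] * dose_template(classes[i], dose_levels),
    numeric(length(dose_levels))))

  scale_to_lib <- function(mu) sweep(mu, 2, colSums(mu) / library_size, "/")
  mu_time <- scale_to_lib(mu_time)
  mu_dose <- scale_to_lib(mu_dose)

  draw <- function(mu) {
    if (!noise) return(mu)
    matrix(stats::rnbinom(length(mu), size = dispersion, mu = mu),
           nrow = nrow(mu))
  }
  genes <- sprintf("gene_%04d", seq_len(n))
  tc <- draw(mu_time); dimnames(tc) <- list(genes, paste0("t", timepoints))
  dc <- draw(mu_dose); dimnames(dc) <- list(genes, paste0("dose", seq_along(dose_levels)))
  structure(list(time_counts = tc, dose_counts = dc,
                 timepoints = timepoints, dose_levels = dose_levels,
                 truth = data.frame(gene = genes, class = classes,
                                    is_tf = is_tf, base = base,
                                    stringsAsFactors = FALSE)),
            class = "count_set")
}
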