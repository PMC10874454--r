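#' Default configuration for the end-to-end synthetic study
#'
#' Parameter blocks for every stage plus the master seed. Can be written to /
#' read from YAML. Unknown keys are rejected at validation.
#'
#' @param seed master seed.
#' @param n_cells cells in the disordered-culture arm.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_cells = 300L) {
  cfg <- list(
    seed = seed,
    histories = list(n_cells = n_cells, noise_sd = 0.1),
    fates = list(integral_threshold = 26, logistic_width = 2),
    tracking = list(n_cells = 100L, n_frames = 50L, step_sd = 3,
                    division_prob = 0.002, max_disp = 15,
                    division_radius = 15),
    denoise = list(knn = 3, t = 3),
    predict = list(folds = 5),
    colony = list(),
    model = list(gamma_S = log(2) / 7, tier = "full"),
    rnascreen = list(n_genes = 600L)
  )
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a seed")
  invisible(cfg)
}

#' Run the full synthetic study pipeline
#'
#' generate -> track -> features -> denoise -> fate -> predict -> pattern ->
#' model -> screen, writing every stage's artifacts to `out_dir` along with a
#' manifest (file list with md5 checksums, stage status and seeds). A rerun
#' with the same config is bit-identical for the deterministic stages.
#'
#' @param config a `run_config` (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return The manifest (invisibly), also written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) {
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
    class(config) <- "run_config"
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(seed = seed, stages = list(), files = list())
  note <- function(stage, status, ...) {
    manifest$stages[[stage]] <<- c(list(status = status), list(...))
  }
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, "error", message = conditionMessage(res))
      return(NULL)
    }
    note(stage, "ok")
    res
  }

  # 1. generate histories + fates
  hp <- do.call(history_gen_params,
                c(config$histories, list(seed = substream_seed(seed, "hist"))))
  hs <- gen_histories(hp)
  fp <- do.call(fate_gen_params,
                c(config$fates, list(seed = substream_seed(seed, "fate"))))
  fates <- gen_fates(hs$truth, fp)
  write_histories_csv(hs$histories, file.path(out_dir, "histories.csv"))
  utils::write.csv(fates, file.path(out_dir, "markers.csv"), row.names = FALSE)
  note("simulate", "ok")

  # 2. tracking
  tk <- config$tracking
  trk <- run_stage("track", function() {
    fx <- gen_tracking_fixture(tk$n_cells, tk$n_frames, tk$step_sd,
                               tk$division_prob,
                               seed = substream_seed(seed, "track"))
    ts <- link_frames(fx$detections, max_disp = tk$max_disp)
    ts <- resolve_divisions(ts, fx$detections, tk$division_radius)
    write_detections_tsv(fx$detections, file.path(out_dir, "detections.tsv"))
    write_lineage_json(ts, file.path(out_dir, "lineage.json"))
    track_metrics(ts, fx)
  })

  # 3. features
  feat <- run_stage("features", function() {
    f <- extract_features(hs$histories, hs$time, baseline = hp$baseline)
    utils::write.csv(f, file.path(out_dir, "features.csv"), row.names = FALSE)
    f
  })

  # 4. denoise + fate + predict
  dn <- config$denoise
  pred <- run_stage("predict", function() {
    score <- fate_score(fates)
    raw_cor <- stats::cor(feat$integral, score$score)
    den_cor <- fate_signal_correlation(hs$histories, fates, hs$time,
                                       baseline = hp$baseline,
                                       knn = dn$knn, t = dn$t)$correlation
    ctrl <- randomized_control(hs$histories, fates, hs$time,
                               baseline = hp$baseline, knn = dn$knn,
                               t = dn$t,
                               seed = substream_seed(seed, "control"))
    bt <- bayes_threshold(feat$integral, score$label)
    cls <- history_classifier(hs$histories, score$label,
                              model = "linear_sigmoid",
                              folds = config$predict$folds,
                              seed = substream_seed(seed, "cv"))
    out <- list(raw_correlation = raw_cor, denoised_correlation = den_cor,
                control_correlation = ctrl$correlation,
                integral_threshold = bt$threshold,
                integral_accuracy = bt$accuracy,
                history_cv_accuracy = cls$cv_accuracy,
                mutual_information_bits =
                  decoder_mutual_information(bt$confusion))
    jsonlite::write_json(out, file.path(out_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  # 5. pattern
  pat <- run_stage("pattern", function() {
    cp <- do.call(colony_gen_params,
                  c(config$colony, list(seed = substream_seed(seed, "colony"))))
    col <- gen_colony(cp)
    bins <- radial_bin(col$positions, cp$radius)
    kym <- kymograph(col$histories, bins)
    cl <- cluster_radial_histories(kym, k = 3,
                                   seed = substream_seed(seed, "fcm"))
    fm <- fate_map(fate_score(col$fates)$label, bins)
    utils::write.csv(kym, file.path(out_dir, "kymograph.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(cluster_map = cl$cluster, fate_map = fm),
                         file.path(out_dir, "maps.json"))
    true_map <- fate_map(col$positions$class, bins)
    list(cluster_fate_agreement = map_agreement(as.character(cl$cluster), fm),
         cluster_truth_agreement = map_agreement(as.character(cl$cluster),
                                                 true_map))
  })

  # 6. model
  mod <- run_stage("model", function() {
    p <- integrator_params(gamma_S = config$model$gamma_S,
                           tier = config$model$tier)
    grid <- simulate_dose_grid(p)
    utils::write.csv(grid, file.path(out_dir, "model_dose_grid.csv"),
                     row.names = FALSE)
    grid
  })

  # 7. screen
  scr <- run_stage("rnascreen", function() {
    cs <- gen_counts(n_genes = config$rnascreen$n_genes,
                     seed = substream_seed(seed, "counts"))
    cpm_t <- cpm_normalize(cs$time_counts)
    expressed <- filter_expressed(cpm_t)
    dyn <- filter_dynamic(cpm_t[expressed, ], cs$timepoints)
    cls <- cluster_timecourses(cpm_t[dyn$genes, ], cs$timepoints)
    ts_max <- apply(cpm_t, 1, max)
    scr <- dose_response_screen(cpm_normalize(cs$dose_counts)[dyn$genes, ],
                                cs$dose_levels, ts_max)
    tf <- stats::setNames(cs$truth$is_tf, cs$truth$gene)
    cand <- integrator_candidates(cls, scr, tf)
    utils::write.csv(cls, file.path(out_dir, "gene_classes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cand, file.path(out_dir, "candidates.json"))
    cand
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  manifest$metrics <- list(tracking = trk, prediction = pred, pattern = pat)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
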