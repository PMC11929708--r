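# End-to-end orchestration: keypoints -> point segmentation -> surface
# reconstruction -> evaluation, with per-stage persistence and a structured
# line-delimited JSON log.

#' Pipeline configuration
#'
#' @param keypoint_source `"foerstner"` or `"cnn"`.
#' @param arch segmentation architecture (`"pointnet"`, `"dgcnn"`,
#'   `"pointtransformer"`).
#' @param reconstructor `"psr"` or `"pcae"`.
#' @param K_max keypoint budget.
#' @param n_points points per forward pass.
#' @param rounds accumulated inference rounds.
#' @param depth Poisson grid depth.
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(keypoint_source = c("foerstner", "cnn"),
                            arch = c("dgcnn", "pointnet", "pointtransformer"),
                            reconstructor = c("psr", "pcae"),
                            K_max = 20000L, n_points = 2048L, rounds = 50L,
                            depth = 6L, seed = 1L) {
  structure(list(keypoint_source = match.arg(keypoint_source),
                 arch = match.arg(arch),
                 reconstructor = match.arg(reconstructor),
                 K_max = as.integer(K_max), n_points = as.integer(n_points),
                 rounds = as.integer(rounds), depth = as.integer(depth),
                 seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(
    pipeline_config)))])
}

log_entry <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  if (!is.null(con)) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  rec
}

#' Run the keypoint-based fissure segmentation pipeline on one case
#'
#' Extracts a sparse keypoint cloud (Foerstner operator or CNN
#' pre-segmentation), labels it with a trained point segmentation network
#' via accumulated inference, reconstructs the three fissure surfaces (grid
#' Poisson reconstruction with lung-mask clipping, or the point-cloud
#' autoencoder), and, if ground truth is available, evaluates surface
#' distances. Stage outputs are persisted under `out_dir`: keypoints
#' (CSV + RDS), per-point labels (CSV), meshes (PLY + sidecar), metrics
#' (CSV), and a line-delimited JSON log. Deterministic given the config
#' seed.
#'
#' @param vol a [new_volume()] (raw HU or normalized).
#' @param mask 3D binary lung mask.
#' @param seg_model trained [build_seg_model()].
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip persistence.
#' @param preseg_model [build_preseg_cnn()] (required for CNN keypoints).
#' @param pcae_model [build_pcae()] (required for `reconstructor="pcae"`).
#' @param gt_meshes optional list of 3 reference meshes (normalized frame).
#' @param patch sliding-window patch size for CNN keypoints.
#' @return list with `cloud`, `scores`, `meshes`, `na`, `n_na`,
#'   `evaluation` (or NULL), `status` (`"ok"` or `"partial"`), `log`.
#' @export
run_pipeline <- function(vol, mask, seg_model, cfg = pipeline_config(),
                         out_dir = NULL, preseg_model = NULL,
                         pcae_model = NULL, gt_meshes = NULL,
                         patch = 128L) {
  stopifnot(inherits(cfg, "pipeline_config"))
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(out_dir, "pipeline_log.jsonl"), "w")
    on.exit(close(con))
  }
  logs <- list()
  # --- keypoints
  if (cfg$keypoint_source == "foerstner") {
    cloud <- foerstner_keypoints(vol, mask, K_max = cfg$K_max)
  } else {
    if (is.null(preseg_model)) stop_fmt("cnn keypoints need a preseg model")
    rng <- range(vol$voxels)
    nvol <- if (rng[1] < 0 || rng[2] > 1) normalize_intensity(vol) else vol
    pm <- sliding_window_predict(preseg_model, nvol, patch = patch)
    cloud <- cnn_keypoints(pm, mask, nvol, K_max = cfg$K_max,
                           seed = child_seed(cfg$seed, 11))
  }
  logs <- c(logs, list(log_entry(con, "keypoints",
                                 source = cfg$keypoint_source,
                                 n = nrow(cloud$coords))))
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(x = cloud$coords[, 1], y = cloud$coords[, 2],
                                z = cloud$coords[, 3]),
                     file.path(out_dir, "keypoints.csv"), row.names = FALSE)
    saveRDS(cloud, file.path(out_dir, "keypoints.rds"))
  }
  if (nrow(cloud$coords) == 0L) {
    # n.a.-only outcome: no candidates at all
    na <- rep(TRUE, 3)
    logs <- c(logs, list(log_entry(con, "done", status = "partial",
                                   n_na = 3L)))
    return(list(cloud = cloud, scores = NULL,
                meshes = vector("list", 3), na = na, n_na = 3L,
                evaluation = NULL, status = "partial", log = logs))
  }
  # --- point segmentation
  scores <- infer_full_cloud(seg_model, cloud, rounds = cfg$rounds,
                             n_points = cfg$n_points,
                             seed = child_seed(cfg$seed, 12))
  sets <- split_by_label(cloud, scores)
  logs <- c(logs, list(log_entry(con, "segmentation",
                                 arch = seg_model$arch,
                                 n_per_class = vapply(sets$points, nrow,
                                                      integer(1)))))
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(label = scores$labels),
                     file.path(out_dir, "point_labels.csv"),
                     row.names = FALSE)
  }
  # --- reconstruction
  rec <- if (cfg$reconstructor == "psr") {
    reconstruct_from_segmentation(sets$points, mask, depth = cfg$depth)
  } else {
    if (is.null(pcae_model)) stop_fmt("pcae reconstruction needs a model")
    reconstruct_with_pcae(sets$points, pcae_model,
                          seed = child_seed(cfg$seed, 13))
  }
  logs <- c(logs, list(log_entry(con, "reconstruction",
                                 method = cfg$reconstructor,
                                 n_na = sum(rec$na))))
  if (!is.null(out_dir)) save_fissure_meshes(rec, file.path(out_dir,
                                                            "meshes"))
  # --- evaluation
  evaluation <- NULL
  if (!is.null(gt_meshes)) {
    evaluation <- evaluate_case(rec, gt_meshes,
                                seed = child_seed(cfg$seed, 14))
    logs <- c(logs, list(log_entry(con, "evaluation",
                                   assd = evaluation$summary$assd,
                                   n_na = evaluation$n_na)))
    if (!is.null(out_dir)) {
      write_metrics_csv(list(case = evaluation),
                        file.path(out_dir, "metrics.csv"))
    }
  }
  status <- if (any(rec$na)) "partial" else "ok"
  logs <- c(logs, list(log_entry(con, "done", status = status,
                                 n_na = sum(rec$na))))
  list(cloud = cloud, scores = scores, meshes = rec$meshes, na = rec$na,
       n_na = sum(rec$na), evaluation = evaluation, status = status,
       log = logs)
}
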