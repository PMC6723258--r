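#' Run the full weakly supervised workflow end-to-end on synthetic data
#'
#' Simulates paired fluorescence/phase patches, manufactures instance-mask
#' labels from the fluorescence channel by blob detection (with an erosion
#' sweep against a small golden subset to pick the erosion degree), trains the
#' compact detector on the phase patches with those weak labels, predicts on
#' held-out patches and evaluates box and mask AP over an IoU threshold grid
#' against the exact simulation truth. All outputs (AP table, PR points,
#' sweep table, effective configuration) are written under `out_dir`.
#'
#' @param out_dir output directory (created; contents overwritten).
#' @param seed root seed; the whole run is a deterministic function of it.
#' @param n_train,n_test number of training and held-out patches.
#' @param n_golden number of training frames whose exact truth plays the role
#'   of a small golden annotation set for the erosion sweep.
#' @param scene_cfg template [scene_config()] for the patches.
#' @param params a [blob_params()] for label generation (erosion degree is
#'   overridden by the sweep winner).
#' @param train_cfg a [train_config()].
#' @param e_values erosion degrees swept.
#' @param t_iou_grid IoU thresholds evaluated.
#' @return invisibly, a list with the sweep table, selected erosion degree,
#'   model, AP table and evaluation report paths.
#' @export
run_all <- function(out_dir, seed = 1L, n_train = 40, n_test = 15,
                    n_golden = 8,
                    scene_cfg = patch_scene_config(),
                    params = blob_params(diameter_range =
                                           scene_cfg$diameter_range),
                    train_cfg = train_config(),
                    e_values = c(0, 2, 4, 6),
                    t_iou_grid = seq(0.3, 0.7, by = 0.05)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  train_scenes <- simulate_scenes(n_train, scene_cfg, seed = child_seed(seed, 1))
  test_scenes <- simulate_scenes(n_test, scene_cfg, seed = child_seed(seed, 2))

  golden_idx <- seq_len(min(n_golden, n_train))
  sweep <- erosion_sweep(lapply(train_scenes[golden_idx], `[[`, "fluor"),
                         lapply(train_scenes[golden_idx], `[[`, "truth"),
                         e_values = e_values, params = params)
  best_e <- attr(sweep, "best_e")
  params$erosion_degree <- best_e
  utils::write.csv(sweep, file.path(out_dir, "erosion_sweep.csv"),
                   row.names = FALSE)

  patches <- lapply(train_scenes, function(sc)
    list(image = sc$phase, labels = generate_labels(sc$fluor, params)))
  tc <- train_cfg
  tc$seed <- child_seed(seed, 3)
  model <- train_detector(patches, tc)
  utils::write.csv(model$trace, file.path(out_dir, "loss_trace.csv"),
                   row.names = FALSE)

  images <- lapply(test_scenes, function(sc) {
    dets <- predict_detections(model, sc$phase)
    list(labels = sc$truth,
         preds = detections_to_mask_set(dets, dim(sc$phase)))
  })
  report <- evaluate_suite(images, t_iou_grid = t_iou_grid)
  utils::write.csv(report$ap, file.path(out_dir, "ap.csv"), row.names = FALSE)
  pr_rows <- do.call(rbind, lapply(names(report$pr), function(k) {
    if (is.null(report$pr[[k]])) return(NULL)
    cbind(key = k, as.data.frame(report$pr[[k]]))
  }))
  utils::write.csv(pr_rows, file.path(out_dir, "pr_points.csv"),
                   row.names = FALSE)

  effective <- list(seed = seed, n_train = n_train, n_test = n_test,
                    n_golden = n_golden, best_erosion = best_e,
                    scene_config = unclass(scene_cfg),
                    blob_params = unclass(params),
                    train_config = unclass(tc),
                    t_iou_grid = t_iou_grid,
                    version = as.character(utils::packageVersion("nucseg")))
  jsonlite::write_json(effective, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sweep = sweep, best_e = best_e, model = model,
                 ap = report$ap, report = report, out_dir = out_dir))
}
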