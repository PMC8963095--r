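#' Run the full phantom-to-metrics demonstration pipeline
#'
#' Generates a cohort of phantoms, enhances and label-constructs each one,
#' trains a reduced model on the train/validation partition, segments the
#' held-out phantoms, postprocesses (largest connected component, except
#' for the fissure target) and evaluates. Artifacts (masks, weights,
#' history, metrics CSV) are written under `out_dir`. Deterministic for a
#' fixed `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param n_train,n_val,n_test cohort sizes.
#' @param grid phantom grid side (divisible by 16).
#' @param target label map to learn; see [training_config()].
#' @param epochs training epochs.
#' @param spec an [arch_spec()]; defaults to [arch_spec_tiny()].
#' @param noise_sigma phantom noise level.
#' @param augment_per_image augmented copies per image.
#' @param seed master seed.
#' @param verbose log stage progress to stderr?
#' @return Invisibly, a list with `metrics` (data frame), `history`, and
#'   the output paths.
#' @export
run_pipeline <- function(out_dir, n_train = 8, n_val = 2, n_test = 2,
                         grid = 32, target = "whole", epochs = 20,
                         spec = arch_spec_tiny(), noise_sigma = 0,
                         augment_per_image = 0, seed = 1L,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  n <- n_train + n_val + n_test
  log_stage("[phantom] generating %d phantoms on a %d^3 grid", n, grid)
  samples <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_params(
      grid_shape = rep(grid, 3),
      ellipsoid_semi_axes = round(grid * c(0.38, 0.31, 0.25)),
      noise_sigma = noise_sigma, seed = seed * 1000L + i))
    log_stage("[preprocess+maskgen] phantom %d", i)
    enhanced <- enhance_contrast(ph$volume)
    labels <- build_label_triplet(enhanced, ph$truth$whole,
                                  use_snakes = FALSE)
    list(volume = enhanced, labels = labels, truth = ph$truth)
  })
  dataset <- list(train = samples[seq_len(n_train)],
                  val = samples[n_train + seq_len(n_val)])
  test <- samples[n_train + n_val + seq_len(n_test)]
  cfg <- training_config(epochs = epochs, target = target,
                         augment_per_image = augment_per_image,
                         seed = seed)
  log_stage("[train] target=%s, %d epochs, %d train / %d val volumes",
            target, epochs, length(dataset$train), length(dataset$val))
  fit <- train_model(spec, dataset, cfg)
  write.csv(fit$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  save_weights(fit$best_model, file.path(out_dir, "weights.json"))
  log_stage("[segment] %d test phantoms", length(test))
  rows <- list()
  for (i in seq_along(test)) {
    pred <- segment(fit$best_model, test[[i]]$volume)
    mask <- if (target == "fissures") pred$mask else
      largest_component(pred$mask)
    write_volume(mask, file.path(out_dir, sprintf("test%02d_%s.nii.gz",
                                                  i, target)),
                 force = TRUE)
    rep <- evaluate_masks(mask, test[[i]]$labels[[target]])
    rows[[i]] <- report_row(rep, id = sprintf("test%02d", i))
  }
  metrics <- do.call(rbind, rows)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  log_stage("[done] %.1f s elapsed; mean DSC %.3f",
            as.numeric(difftime(Sys.time(), t0, units = "secs")),
            mean(metrics$DSC))
  invisible(list(metrics = metrics, history = fit$history,
                 out_dir = out_dir))
}
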