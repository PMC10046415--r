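# End-to-end replication experiment: configuration presets, orchestration,
# artifacts, reporting.

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end experiment. Two scale presets:
#' * `"full"` — 128 x 128 grid, 10 frequencies in [0.9, 1.8] GHz,
#'   N1 = 3000 tumor / N2 = 2000 cord samples (hours of CPU);
#' * `"reduced"` — 32 x 32 grid, 3 frequencies, 400/300 samples (desk scale,
#'   minutes), same physics and protocol otherwise.
#'
#' Defaults shared by both: 12 point antennas, 30 dB SNR, sd 0.1 tissue
#' randomization, Pcut = 1, 10-fold cross-validation, Adam with learning
#' rate 1e-4 and batch 16, at most 300 epochs, patience 10.
#'
#' @param preset "full" or "reduced".
#' @param seed master seed for the whole experiment.
#' @param ... overrides for any field of the returned list (e.g. `snr_db`,
#'   `n_tumor`, `train`).
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = c("reduced", "full"), seed = 1L, ...) {
  preset <- match.arg(preset)
  # the reduced preset shrinks the imaging domain with the grid: the cell
  # size (which sets the tumor-to-ROI-window pixel fraction and thereby the
  # structure of the Pcut=1 inverse problem) stays as close to the
  # full-scale setup as a 32-cell grid that still contains the neck allows
  cfg <- if (preset == "full") {
    list(grid_n = 128L, domain = 0.24, n_freq = 10L,
         n_tumor = 3000L, n_cord = 2000L)
  } else {
    list(grid_n = 32L, domain = 0.12, n_freq = 3L,
         n_tumor = 400L, n_cord = 300L)
  }
  base <- list(
    preset = preset, seed = as.integer(seed),
    grid_n = cfg$grid_n, domain_size = cfg$domain, n_freq = cfg$n_freq,
    band = c(0.9e9, 1.8e9),
    n_tumor = cfg$n_tumor, n_cord = cfg$n_cord,
    snr_db = 30, pcut = 1L, randomize_sd = 0.1,
    tumor_temps = 37:46, cord_temps = 37:40,
    operator_phantom = "sample",
    phantom = NULL,   # filled from phantom_config(grid_n) unless overridden
    train = train_config(seed = seed)
  )
  over <- list(...)
  base[names(over)] <- over
  if (is.null(base$phantom)) {
    base$phantom <- phantom_config(n = base$grid_n,
                                   domain_size = base$domain_size)
  }
  base$train$seed <- as.integer(seed)
  structure(base, class = "run_config")
}

#' Run the end-to-end monitoring experiment
#'
#' Generates the two labelled datasets, trains both CNNs under K-fold
#' cross-validation, and computes the fold-averaged metric reports. With
#' `out_dir` set, writes the metric tables, aggregated confusion matrices
#' and per-fold loss histories as CSV files.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV artifacts.
#' @param progress print progress dots during dataset generation.
#' @return list of class `experiment_result` with `tumor`/`cord` (each:
#'   `dataset`, `kfold`, `report`), the `config`, and elapsed seconds.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  phantom <- build_neck_phantom(config$phantom)
  layout <- antenna_layout()
  freqs <- frequency_set(config$n_freq, config$band)
  ds <- generate_dataset(phantom, layout, freqs,
                         n_tumor = config$n_tumor, n_cord = config$n_cord,
                         seed = config$seed, snr_db = config$snr_db,
                         pcut = config$pcut,
                         randomize_sd = config$randomize_sd,
                         tumor_temps = config$tumor_temps,
                         cord_temps = config$cord_temps,
                         operator_phantom = config$operator_phantom,
                         progress = progress)
  out <- list(config = config)
  for (roi in c("tumor", "cord")) {
    kf <- kfold_train(ds[[roi]], config$train)
    pf <- fold_metrics(kf, ds[[roi]]$n_classes,
                       class_names = if (roi == "tumor") {
                         c("unheated", "therapeutic", "hot")
                       } else c("unheated", "hot"))
    out[[roi]] <- list(dataset = ds[[roi]], kfold = kf,
                       report = fold_average(pf))
  }
  out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out <- structure(out, class = "experiment_result")
  if (!is.null(out_dir)) write_experiment_artifacts(out, out_dir)
  out
}

#' @noRd
write_experiment_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (roi in c("tumor", "cord")) {
    rep <- result[[roi]]$report
    utils::write.csv(rep$metrics,
                     file.path(out_dir, paste0("metrics_", roi, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(rep$confusion),
                     file.path(out_dir, paste0("confusion_", roi, ".csv")),
                     row.names = FALSE)
    hist <- do.call(rbind, lapply(seq_along(result[[roi]]$kfold),
      function(i) {
        fr <- result[[roi]]$kfold[[i]]
        data.frame(fold = i, epoch = seq_along(fr$train_loss),
                   train_loss = fr$train_loss, val_loss = fr$val_loss)
      }))
    utils::write.csv(hist,
                     file.path(out_dir, paste0("loss_history_", roi, ".csv")),
                     row.names = FALSE)
  }
  writeLines(sprintf("seed: %d\npreset: %s\nelapsed_s: %.1f",
                     result$config$seed, result$config$preset,
                     result$elapsed_s),
             file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}

#' Human-readable experiment summary
#'
#' Prints the per-class metric tables, the aggregated confusion matrices and
#' a misclassification breakdown for both CNNs, plus provenance (seed,
#' preset).
#'
#' @param result an [run_experiment()] result.
#' @return the result, invisibly.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  cat(sprintf("Experiment preset '%s', seed %d (%.0f s)\n\n",
              result$config$preset, result$config$seed, result$elapsed_s))
  for (roi in c("tumor", "cord")) {
    cat(sprintf("== %s CNN ==\n", roi))
    print(result[[roi]]$report)
    cat("\n")
  }
  invisible(result)
}

#' @export
print.experiment_result <- function(x, ...) report(x)
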