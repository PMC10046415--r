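# Labelled-dataset generation and the K-fold CNN training protocol.

#' Temperature-class label for the tumor ROI
#'
#' Three classes from the temperature rise over the 37 C baseline:
#' 0 (unheated) for dT < 3 C, 1 (therapeutic) for 3 <= dT < 7 C,
#' 2 (hot) for dT >= 7 C. The therapeutic band corresponds to the usual
#' hyperthermia target of 40-43 C.
#'
#' @param delta_T temperature rise in C, >= 0 (vectorised).
#' @return integer class in {0, 1, 2}.
#' @export
assign_tumor_label <- function(delta_T) {
  if (any(delta_T < 0)) stop("delta_T must be non-negative")
  ifelse(delta_T < 3, 0L, ifelse(delta_T < 7, 1L, 2L))
}

#' Temperature-class label for the spinal-cord ROI
#'
#' Binary: 0 (unheated) for dT < 2 C, 1 (hot) otherwise — a rise of 1 C is
#' still counted as unheated.
#'
#' @param delta_T temperature rise in C, >= 0 (vectorised).
#' @return integer class in {0, 1}.
#' @export
assign_cord_label <- function(delta_T) {
  if (any(delta_T < 0)) stop("delta_T must be non-negative")
  ifelse(delta_T < 2, 0L, 1L)
}

#' Generate the labelled ROI-image datasets
#'
#' Runs `n_sim = max(N_tumor, N_cord)` independent simulated measurement
#' pairs. Each simulation: randomize all tissue permittivities (Gaussian,
#' `randomize_sd`), draw the two ROI temperatures uniformly from their
#' discrete 1 C grids, solve the forward problem for the baseline (37 C) and
#' heated states at every frequency, corrupt both scattered-field sets with
#' AWGN, form the differential data, build the two ROI operators from the
#' (noiseless) baseline total fields, invert with TSVD at `pcut`, split the
#' complex images into Re/Im channels, and attach the ground-truth labels.
#' The first `N_tumor` simulations feed the tumor dataset and the first
#' `N_cord` the cord dataset.
#'
#' @param phantom nominal phantom from [build_neck_phantom()].
#' @param layout an [antenna_layout()].
#' @param freqs frequency vector (Hz).
#' @param n_tumor,n_cord dataset sizes.
#' @param seed master seed; every random stage derives its own child seed.
#' @param snr_db measurement SNR in dB (default 30; `Inf` disables noise).
#' @param pcut TSVD truncation (default 1).
#' @param randomize_sd per-tissue permittivity randomization sd (default 0.1).
#' @param tumor_temps,cord_temps discrete temperature grids to draw from.
#' @param operator_phantom "sample" (default) builds the DWBA operators from
#'   each sample's own randomized baseline (perfect treatment-planning
#'   knowledge); "nominal" uses the unrandomized phantom (model mismatch).
#' @param progress print a dot every 50 simulations.
#' @return list with elements `tumor` and `cord`, each a `roi_dataset`:
#'   `images` (N, crop, crop, 2 array), `labels` (0-based integer),
#'   `delta_T`, `n`, `roi`.
#' @export
generate_dataset <- function(phantom, layout, freqs, n_tumor, n_cord,
                             seed, snr_db = 30, pcut = 1L,
                             randomize_sd = 0.1,
                             tumor_temps = 37:46, cord_temps = 37:40,
                             operator_phantom = c("sample", "nominal"),
                             progress = FALSE) {
  operator_phantom <- match.arg(operator_phantom)
  stopifnot(inherits(phantom, "phantom"))
  n_sim <- max(n_tumor, n_cord)
  ws <- make_forward_workspace(phantom, layout, freqs)
  crop_t <- phantom$rois$tumor$crop
  crop_c <- phantom$rois$cord$crop
  img_t <- array(0, c(n_tumor, crop_t, crop_t, 2L))
  img_c <- array(0, c(n_cord, crop_c, crop_c, 2L))
  dT_t <- numeric(n_tumor); dT_c <- numeric(n_cord)
  skipped <- 0L
  for (i in seq_len(n_sim)) {
    res <- tryCatch(
      simulate_sample(phantom, ws, freqs, seed, i, snr_db, pcut,
                      randomize_sd, tumor_temps, cord_temps,
                      operator_phantom),
      error = function(e) {
        message("sample ", i, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      skipped <- skipped + 1L
      if (skipped > max(1, 0.01 * n_sim)) {
        stop("more than 1% of the simulations failed; aborting run")
      }
      next
    }
    if (i <= n_tumor) {
      img_t[i, , , ] <- split_channels(res$img_tumor)
      dT_t[i] <- res$dT_tumor
    }
    if (i <= n_cord) {
      img_c[i, , , ] <- split_channels(res$img_cord)
      dT_c[i] <- res$dT_cord
    }
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(
    tumor = structure(list(images = img_t,
                           labels = assign_tumor_label(dT_t),
                           delta_T = dT_t, n = n_tumor, roi = "tumor",
                           n_classes = 3L), class = "roi_dataset"),
    cord = structure(list(images = img_c,
                          labels = assign_cord_label(dT_c),
                          delta_T = dT_c, n = n_cord, roi = "cord",
                          n_classes = 2L), class = "roi_dataset")
  )
}

# one simulated measurement pair -> two labelled ROI images
#' @noRd
simulate_sample <- function(phantom, ws, freqs, seed, i, snr_db, pcut,
                            randomize_sd, tumor_temps, cord_temps,
                            operator_phantom) {
  ph_i <- randomize_tissues(phantom, child_seed(seed, i, 1L),
                            sd = randomize_sd)
  temps <- with_local_seed(child_seed(seed, i, 2L), {
    c(tumor_temps[sample.int(length(tumor_temps), 1L)],
      cord_temps[sample.int(length(cord_temps), 1L)])
  })
  ph_heat <- set_roi_temperatures(ph_i, temps[1], temps[2])
  ph_op <- if (operator_phantom == "sample") ph_i else phantom
  nf <- length(freqs)
  nm <- nrow(ws$layout$rx); nv <- nrow(ws$layout$tx)
  es0 <- array(0 + 0i, c(nm, nv, nf))
  ess <- array(0 + 0i, c(nm, nv, nf))
  base_records <- vector("list", nf)
  for (k in seq_len(nf)) {
    f <- freqs[k]
    chi0 <- contrast_map(ph_op, f)[ws$mask]
    sol0 <- solve_masked(ws$per_freq[[k]], chi0)
    chis <- contrast_map(ph_heat, f)[ws$mask]
    sols <- solve_masked(ws$per_freq[[k]], chis)
    es0[, , k] <- sol0$es
    ess[, , k] <- sols$es
    base_records[[k]] <- structure(
      list(f = f, kb = ws$per_freq[[k]]$kb, es = sol0$es, etot = sol0$etot,
           einc = ws$per_freq[[k]]$einc, mask = ws$mask,
           layout = ws$layout, n = ws$n, h = ws$h),
      class = "field_record")
  }
  es0n <- add_awgn(es0, snr_db, child_seed(seed, i, 3L))
  essn <- add_awgn(ess, snr_db, child_seed(seed, i, 4L))
  dd <- differential_data(essn, es0n)
  op_t <- build_roi_operator(base_records, phantom$rois$tumor)
  op_c <- build_roi_operator(base_records, phantom$rois$cord)
  list(img_tumor = tsvd_invert(op_t, dd, pcut),
       img_cord = tsvd_invert(op_c, dd, pcut),
       dT_tumor = temps[1] - 37, dT_cord = temps[2] - 37)
}

#' Training configuration
#'
#' Defaults follow the training protocol of the simulated study: Adam with
#' learning rate 1e-4, batch size 16, at most 300 epochs with early stopping
#' after 10 epochs without validation-loss improvement, 10-fold
#' cross-validation.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience consecutive non-improving epochs before stopping.
#' @param folds number of cross-validation folds.
#' @param seed master training seed (fold assignment, init, shuffling).
#' @param per_class_loss use the Nc-normalised cross-entropy (default TRUE).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         max_epochs = 300L, patience = 10L, folds = 10L,
                         seed = 1L, per_class_loss = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, folds >= 2)
  structure(as.list(environment()), class = "train_config")
}

#' K-fold cross-validated CNN training
#'
#' Splits the dataset into `folds` equal parts by a seeded permutation; for
#' each fold, trains a freshly initialised CNN (fold-indexed seed) on the
#' remaining samples with Adam and early stopping, restores the
#' best-validation-loss weights, and records the loss histories and the
#' validation predictions.
#'
#' @param dataset a `roi_dataset` from [generate_dataset()].
#' @param cfg a [train_config()].
#' @return list of class `kfold_result`: one element per fold with `model`,
#'   `train_loss`, `val_loss`, `best_epoch`, `val_idx`, `val_truth`,
#'   `val_pred`.
#' @export
kfold_train <- function(dataset, cfg = train_config()) {
  stopifnot(inherits(dataset, "roi_dataset"), inherits(cfg, "train_config"))
  N <- dataset$n
  k <- cfg$folds
  if (N %% k != 0) {
    divs <- Filter(function(d) d >= 2 && d <= N / 2, seq_len(N))
    divs <- divs[N %% divs == 0]
    stop("dataset size ", N, " is not divisible into ", k,
         " equal folds; valid fold counts: ", paste(divs, collapse = ", "))
  }
  nval <- N %/% k
  perm <- with_local_seed(child_seed(cfg$seed, 0L, 7L), sample(N))
  folds <- lapply(seq_len(k), function(i) {
    sort(perm[((i - 1L) * nval + 1L):(i * nval)])
  })
  shape <- dim(dataset$images)[2:4]
  results <- lapply(seq_len(k), function(i) {
    val_idx <- folds[[i]]
    train_idx <- setdiff(seq_len(N), val_idx)
    fit <- train_fold(dataset, train_idx, val_idx, shape, cfg,
                      fold_seed = child_seed(cfg$seed, i, 13L))
    fit$val_idx <- val_idx
    fit
  })
  structure(results, class = "kfold_result")
}

#' @noRd
train_fold <- function(dataset, train_idx, val_idx, shape, cfg, fold_seed) {
  n_classes <- dataset$n_classes
  Xtr <- dataset$images[train_idx, , , , drop = FALSE]
  ytr <- dataset$labels[train_idx]
  Xva <- dataset$images[val_idx, , , , drop = FALSE]
  yva <- dataset$labels[val_idx]
  Yva <- one_hot(yva, n_classes)
  model <- build_cnn(shape, n_classes, seed = fold_seed)
  with_local_seed(child_seed(fold_seed, 1L, 17L), {
    st <- adam_init(model$weights)
    ntr <- length(train_idx)
    nb <- ceiling(ntr / cfg$batch_size)
    nc_norm <- if (cfg$per_class_loss) n_classes else 1
    best <- list(loss = Inf, weights = model$weights, epoch = 0L)
    train_hist <- val_hist <- numeric(0)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(ntr)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * cfg$batch_size + 1L):
                   min(b * cfg$batch_size, ntr)]
        Xb <- Xtr[idx, , , , drop = FALSE]
        Yb <- one_hot(ytr[idx], n_classes)
        fw <- cnn_forward(model, Xb, keep_cache = TRUE)
        ep_loss <- ep_loss +
          cross_entropy(fw$probs, Yb, cfg$per_class_loss) * length(idx)
        gr <- cnn_backward(model, fw, Yb, nc_norm)
        upd <- adam_step(model$weights, gr, st, cfg$learning_rate)
        model$weights <- upd$w
        st <- upd$st
      }
      train_hist[epoch] <- ep_loss / ntr
      pv <- cnn_forward(model, Xva)$probs
      val_hist[epoch] <- cross_entropy(pv, Yva, cfg$per_class_loss)
      if (val_hist[epoch] < best$loss) {
        best <- list(loss = val_hist[epoch], weights = model$weights,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    model$weights <- best$weights
    pred <- cnn_predict(model, Xva)
    list(model = model, train_loss = train_hist, val_loss = val_hist,
         best_epoch = best$epoch, val_truth = yva, val_pred = pred)
  })
}
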