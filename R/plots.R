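# Plot helpers (ggplot2, optional).

#' Plot the phantom tissue segmentation
#'
#' @param phantom a [build_neck_phantom()] result.
#' @return a ggplot object.
#' @export
plot_phantom <- function(phantom) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- expand.grid(x = phantom$xc * 100, y = phantom$yc * 100)
  df$tissue <- factor(as.vector(phantom$labels), levels = TISSUE_CODES,
                      labels = names(TISSUE_CODES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "tissue") +
    ggplot2::theme_minimal()
}

#' Plot training/validation loss curves of a cross-validated run
#'
#' @param kfold a [kfold_train()] result.
#' @param fold which fold to show (default: the one whose final validation
#'   loss is closest to the across-fold average).
#' @return a ggplot object.
#' @export
plot_loss_curves <- function(kfold, fold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  finals <- vapply(kfold, function(fr) fr$val_loss[fr$best_epoch],
                   numeric(1))
  if (is.null(fold)) fold <- which.min(abs(finals - mean(finals)))
  fr <- kfold[[fold]]
  df <- rbind(
    data.frame(epoch = seq_along(fr$train_loss), loss = fr$train_loss,
               split = "training"),
    data.frame(epoch = seq_along(fr$val_loss), loss = fr$val_loss,
               split = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("Cross-entropy, fold %d", fold),
                  x = "epoch", y = "categorical cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed ROI image (Re/Im channels)
#'
#' @param img a `roi_image` from [tsvd_invert()].
#' @return a ggplot object.
#' @export
plot_roi_image <- function(img) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  m <- img$delta_chi
  df <- rbind(
    cbind(expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m))),
          value = as.vector(Re(m)), channel = "Re"),
    cbind(expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m))),
          value = as.vector(Im(m)), channel = "Im"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = sprintf("Reconstructed differential contrast (%s, Pcut=%d)",
                                  img$roi$name, img$pcut),
                  x = NULL, y = NULL, fill = "delta-chi") +
    ggplot2::theme_minimal()
}
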