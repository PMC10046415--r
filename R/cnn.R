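# Compact convolutional network for tiny two-channel ROI images:
# conv(3x3, 16) -> ReLU -> conv(3x3, 32) -> ReLU -> dense(64) -> ReLU ->
# dense(n_classes) -> softmax, trained with Adam on categorical
# cross-entropy. Convolutions use same padding and are evaluated as matrix
# products on gathered 3x3 patches (im2col), which is fast at these sizes.

# neighbor table for 3x3 same-padding convolution on an H x W grid:
# (H*W) x 9 matrix of linear pixel indices (column-major, i fastest),
# 0 where the neighbor falls outside the grid
#' @noRd
conv_neighbors <- function(H, W) {
  nb <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    for (j in seq_len(W)) for (i in seq_len(H)) {
      ii <- i + di; jj <- j + dj
      p <- i + (j - 1L) * H
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        nb[p, k] <- ii + (jj - 1L) * H
      }
    }
  }
  nb
}

#' Build a compact CNN classifier for ROI images
#'
#' @param input_shape integer vector (H, W, channels); the two ROI designs
#'   use (5, 5, 2) and (6, 6, 2).
#' @param n_classes number of output classes (2 or 3 here).
#' @param kernels numbers of 3x3 kernels in the two conv layers.
#' @param dense_units width of the fully connected layer.
#' @param seed seed for the weight initialization (He-scaled Gaussians).
#' @return object of class `cnn_model`; `$param_count` reports the number of
#'   trainable parameters.
#' @export
build_cnn <- function(input_shape, n_classes, kernels = c(16L, 32L),
                      dense_units = 64L, seed = 1L) {
  stopifnot(length(input_shape) == 3, n_classes >= 2)
  H <- input_shape[1]; W <- input_shape[2]; Cin <- input_shape[3]
  K1 <- kernels[1]; K2 <- kernels[2]; D <- dense_units
  init <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  w <- with_local_seed(seed, list(
    W1 = init(9 * Cin, K1, 9 * Cin), b1 = numeric(K1),
    W2 = init(9 * K1, K2, 9 * K1), b2 = numeric(K2),
    W3 = init(H * W * K2, D, H * W * K2), b3 = numeric(D),
    W4 = init(D, n_classes, D), b4 = numeric(n_classes)
  ))
  pc <- sum(vapply(w, length, integer(1)))
  structure(list(weights = w, H = H, W = W, Cin = Cin, K1 = K1, K2 = K2,
                 D = D, n_classes = n_classes, nb = conv_neighbors(H, W),
                 param_count = pc, seed = seed),
            class = "cnn_model")
}

# gather 3x3 patches: A is (B*HW) x C activations, returns (B*HW) x (9C)
#' @noRd
im2col <- function(A, nb, B, HW) {
  off <- rep((seq_len(B) - 1L) * HW, each = HW)
  idxB <- nb[rep(seq_len(HW), B), , drop = FALSE]
  pad <- idxB == 0L
  idxB <- idxB + off
  idxB[pad] <- 0L
  C <- ncol(A)
  P <- matrix(0, nrow(A), 9L * C)
  for (c in seq_len(C)) {
    Ac <- c(0, A[, c])
    P[, (c - 1L) * 9L + 1:9] <- Ac[idxB + 1L]
  }
  list(P = P, idxB = idxB)
}

# scatter patch gradients back: dP is (B*HW) x (9C); returns (B*HW) x C
#' @noRd
col2im <- function(dP, idxB, nrows, C) {
  dA <- matrix(0, nrows, C)
  for (c in seq_len(C)) {
    for (k in 1:9) {
      col <- dP[, (c - 1L) * 9L + k]
      tgt <- idxB[, k]
      keep <- tgt > 0L
      dA[tgt[keep], c] <- dA[tgt[keep], c] + col[keep]
    }
  }
  dA
}

# batch images (B, H, W, C) -> activation matrix (B*HW) x C
#' @noRd
images_to_act <- function(X) {
  B <- dim(X)[1]; H <- dim(X)[2]; W <- dim(X)[3]; C <- dim(X)[4]
  A <- matrix(0, B * H * W, C)
  for (c in seq_len(C)) {
    A[, c] <- as.vector(aperm(array(X[, , , c], c(B, H, W)), c(2, 3, 1)))
  }
  A
}

#' Forward pass of the CNN
#'
#' @param model a [build_cnn()] model.
#' @param X image batch, array (B, H, W, channels).
#' @param keep_cache retain intermediate activations for backprop.
#' @return list with `probs` (B x n_classes softmax outputs) and, if
#'   requested, the backprop cache.
#' @export
cnn_forward <- function(model, X, keep_cache = FALSE) {
  w <- model$weights
  B <- dim(X)[1]; HW <- model$H * model$W
  A0 <- images_to_act(X)
  g1 <- im2col(A0, model$nb, B, HW)
  Z1 <- sweep(g1$P %*% w$W1, 2, w$b1, "+")
  A1 <- pmax(Z1, 0)
  g2 <- im2col(A1, model$nb, B, HW)
  Z2 <- sweep(g2$P %*% w$W2, 2, w$b2, "+")
  A2 <- pmax(Z2, 0)
  Fm <- t(matrix(aperm(array(A2, c(HW, B, model$K2)), c(1, 3, 2)),
                 HW * model$K2, B))
  Z3 <- sweep(Fm %*% w$W3, 2, w$b3, "+")
  A3 <- pmax(Z3, 0)
  Z4 <- sweep(A3 %*% w$W4, 2, w$b4, "+")
  Z4 <- Z4 - apply(Z4, 1, max)
  E <- exp(Z4)
  probs <- E / rowSums(E)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(g1 = g1, g2 = g2, Z1 = Z1, A1 = A1, Z2 = Z2,
                      Fm = Fm, Z3 = Z3, A3 = A3, B = B)
  }
  out
}

# gradients of the categorical cross-entropy w.r.t. all weights
#' @noRd
cnn_backward <- function(model, fw, Y, nc_norm) {
  w <- model$weights
  ca <- fw$cache
  B <- ca$B; HW <- model$H * model$W
  dZ4 <- (fw$probs - Y) / (B * nc_norm)
  gW4 <- t(ca$A3) %*% dZ4
  gb4 <- colSums(dZ4)
  dA3 <- dZ4 %*% t(w$W4)
  dZ3 <- dA3 * (ca$Z3 > 0)
  gW3 <- t(ca$Fm) %*% dZ3
  gb3 <- colSums(dZ3)
  dF <- dZ3 %*% t(w$W3)
  dA2 <- matrix(aperm(array(t(dF), c(HW, model$K2, B)), c(1, 3, 2)),
                HW * B, model$K2)
  dZ2 <- dA2 * (ca$Z2 > 0)
  gW2 <- t(ca$g2$P) %*% dZ2
  gb2 <- colSums(dZ2)
  dP2 <- dZ2 %*% t(w$W2)
  dA1 <- col2im(dP2, ca$g2$idxB, B * HW, model$K1)
  dZ1 <- dA1 * (ca$Z1 > 0)
  gW1 <- t(ca$g1$P) %*% dZ1
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Categorical cross-entropy
#'
#' Le = -(1/(N*Nc)) * sum_n sum_c C log C-hat: the per-class-normalised form
#' (dividing by both the batch size and the class count). `per_class = FALSE`
#' gives the conventional 1/N normalisation; the two differ by the constant
#' factor Nc only.
#'
#' @param predictions N x Nc matrix of predicted probabilities.
#' @param truths one-hot N x Nc matrix, or an integer vector of 0-based
#'   class labels.
#' @param per_class divide by Nc as well as N (default TRUE).
#' @return scalar loss.
#' @export
cross_entropy <- function(predictions, truths, per_class = TRUE) {
  nc <- ncol(predictions)
  if (!is.matrix(truths)) truths <- one_hot(truths, nc)
  stopifnot(identical(dim(predictions), dim(truths)))
  p <- predictions[truths > 0]
  if (any(p < 1e-12)) {
    warning("predicted probability below 1e-12 at a true class; clipping")
    p <- pmax(p, 1e-12)
  }
  norm <- nrow(predictions) * (if (per_class) nc else 1)
  -sum(truths[truths > 0] * log(p)) / norm
}

#' One-hot encoding of 0-based class labels
#' @param labels integer vector in 0..(n_classes-1).
#' @param n_classes number of classes.
#' @return length(labels) x n_classes 0/1 matrix.
#' @export
one_hot <- function(labels, n_classes) {
  if (any(labels < 0 | labels >= n_classes)) stop("label out of range")
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Class predictions of a CNN
#'
#' @param model a trained [build_cnn()] model.
#' @param X image batch, array (B, H, W, channels).
#' @return integer vector of 0-based predicted classes.
#' @export
cnn_predict <- function(model, X) {
  max.col(cnn_forward(model, X)$probs, ties.method = "first") - 1L
}

# Adam state and update
#' @noRd
adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

#' @noRd
adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(w)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}
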