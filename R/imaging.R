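# DWBA differential imaging: ROI-restricted linear operators and TSVD
# inversion of multi-frequency differential data.

#' Differential scattered-field data
#'
#' Element-wise difference between the heated-state and baseline scattered
#' fields, stacked across frequencies. Rows of the stacked vector are ordered
#' receiver-fastest, then transmitter, then frequency — the same ordering the
#' ROI operators use.
#'
#' @param es_heated,es_baseline complex Nm x Nv x Nf arrays (or Nm x Nv
#'   matrices for a single frequency).
#' @return object of class `differential_data`: `delta` (array) and `stacked`
#'   (vector of length Nm*Nv*Nf).
#' @export
differential_data <- function(es_heated, es_baseline) {
  if (!identical(dim(es_heated), dim(es_baseline)) ||
      length(es_heated) != length(es_baseline)) {
    stop("heated and baseline data shapes do not match")
  }
  d <- es_heated - es_baseline
  if (is.matrix(d)) d <- array(d, c(dim(d), 1L))
  structure(list(delta = d, stacked = as.vector(d)),
            class = "differential_data")
}

#' Build the DWBA linear operator restricted to one ROI
#'
#' Row (m, v, f), column p of the operator is
#' `kb(f)^2 * Etot0(rp; rm, f) * Etot0(rp; rv, f) * cell_area`:
#' the unheated-state total field plays the role of the Green's function, and
#' the field "received at rm" is obtained from the source solve at antenna m
#' by reciprocity (co-located arrays). The per-frequency blocks are stacked
#' row-wise into a single system (frequency-diversity reading of the
#' multi-frequency inversion) and the SVD is computed once and cached.
#'
#' @param baseline_fields list of `field_record`s (one per frequency) for the
#'   unheated phantom state.
#' @param roi a [roi_spec()].
#' @return object of class `roi_operator` with the stacked matrix `L`, its
#'   SVD (`u`, `d`, `v`, with `L = u diag(d) v^H`), the ROI, and bookkeeping.
#' @export
build_roi_operator <- function(baseline_fields, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (inherits(baseline_fields, "field_record")) {
    baseline_fields <- list(baseline_fields)
  }
  fr1 <- baseline_fields[[1]]
  npix <- roi$crop^2
  # ROI pixel (i, j) enumeration: i (row) fastest, matching matrix() refill
  pix <- as.matrix(expand.grid(i = roi$rows, j = roi$cols))
  mask_key <- fr1$mask[, 1] * 1e6 + fr1$mask[, 2]
  rows_l <- lapply(baseline_fields, function(fr) {
    idx <- match(pix[, 1] * 1e6 + pix[, 2], mask_key)
    if (any(is.na(idx))) {
      stop("ROI '", roi$name, "' contains pixels outside the scatterer ",
           "support; baseline fields are unavailable there")
    }
    E <- fr$etot[idx, , drop = FALSE]        # npix x Nant
    scale <- fr$kb^2 * fr$h^2
    lf <- vapply(seq_len(npix), function(p) {
      as.vector(outer(E[p, ], E[p, ])) * scale
    }, complex(ncol(E)^2))
    lf
  })
  L <- do.call(rbind, rows_l)
  sv <- svd(L)
  structure(list(L = L, u = sv$u, d = sv$d, v = sv$v, roi = roi,
                 freqs = vapply(baseline_fields, `[[`, numeric(1), "f")),
            class = "roi_operator")
}

#' Rank of a ROI operator
#'
#' Number of singular values above `tol` times the largest.
#' @param op a [build_roi_operator()] result.
#' @param tol relative threshold (default 1e-12).
#' @export
operator_rank <- function(op, tol = 1e-12) {
  sum(op$d > tol * op$d[1])
}

#' TSVD inversion of differential data on one ROI
#'
#' delta_chi = sum_{p <= Pcut} (1/lambda_p) v_p (u_p^H Delta), reshaped to
#' the ROI window. The expensive SVD lives in the cached operator, so each
#' inversion is a Pcut-term matrix-vector product (real-time online step).
#'
#' @param op a [build_roi_operator()] result.
#' @param data a [differential_data()] object (or a stacked complex vector).
#' @param pcut truncation index, `1 <= pcut <= rank(op)`.
#' @return object of class `roi_image`: `delta_chi` (crop x crop complex
#'   matrix), `pcut`, `roi`.
#' @export
tsvd_invert <- function(op, data, pcut = 1L) {
  stopifnot(inherits(op, "roi_operator"))
  d <- if (inherits(data, "differential_data")) data$stacked else data
  if (length(d) != nrow(op$L)) stop("data length does not match operator rows")
  rk <- operator_rank(op)
  if (pcut < 1 || pcut > rk) {
    stop("pcut must be between 1 and the operator rank (", rk, ")")
  }
  keep <- seq_len(pcut)
  small <- op$d[keep] < 1e-12 * op$d[1]
  if (any(small)) {
    warning("excluding ", sum(small), " singular value(s) below 1e-12 of ",
            "the largest")
    keep <- keep[!small]
  }
  coef <- as.vector(Conj(t(op$u[, keep, drop = FALSE])) %*% d) / op$d[keep]
  x <- as.vector(op$v[, keep, drop = FALSE] %*% coef)
  structure(list(delta_chi = matrix(x, op$roi$crop, op$roi$crop),
                 pcut = pcut, roi = op$roi),
            class = "roi_image")
}

#' Solution-norm curve over the truncation index
#'
#' Norms of the TSVD solution for Pcut = 1..rank; non-decreasing by
#' construction (each additional triplet adds an orthogonal component).
#'
#' @inheritParams tsvd_invert
#' @return numeric vector of length `rank(op)`.
#' @export
solution_norm_curve <- function(op, data) {
  d <- if (inherits(data, "differential_data")) data$stacked else data
  rk <- operator_rank(op)
  coef <- as.vector(Conj(t(op$u[, seq_len(rk), drop = FALSE])) %*% d) /
    op$d[seq_len(rk)]
  sqrt(cumsum(Mod(coef)^2))
}

#' Split a complex ROI image into a two-channel real array
#'
#' @param img a `roi_image` (or complex matrix).
#' @return real array of shape (crop, crop, 2): Re and Im channels.
#' @export
split_channels <- function(img) {
  m <- if (inherits(img, "roi_image")) img$delta_chi else img
  out <- array(0, c(nrow(m), ncol(m), 2L))
  out[, , 1] <- Re(m)
  out[, , 2] <- Im(m)
  out
}
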