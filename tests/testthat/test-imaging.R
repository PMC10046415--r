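test_that("differential data is an element-wise subtraction with strict shape checks", {
  a <- array(complex(real = rnorm(36), imaginary = rnorm(36)), c(3, 4, 3))
  b <- array(complex(real = rnorm(36), imaginary = rnorm(36)), c(3, 4, 3))
  expect_true(all(differential_data(a, a)$delta == 0))
  expect_equal(differential_data(a + b, a)$delta, b, tolerance = 1e-14)
  expect_error(differential_data(a, b[, 1:3, ]), "shapes")
})

test_that("DWBA linearization error shrinks with the imposed contrast step", {
  ph <- small_phantom()
  ws <- small_workspace()
  base <- baseline_state()
  op <- tumor_operator()
  errs <- vapply(c(1e-1, 1e-2, 1e-3), function(step) {
    # impose a uniform complex permittivity offset on the tumor tissue so
    # that delta-chi = offset / eps_b on the tumor pixels, zero elsewhere
    ph2 <- ph
    eps_b0 <- background_permittivity(ph$config$background_eps,
                                      ph$config$background_sigma,
                                      ws$freqs[1])
    ph2$offsets[["tumor"]] <- step * (1 - 0.5i) * Re(eps_b0)
    pert <- solve_state(ph2)
    des <- as.vector(pert$es - base$es)
    # predicted by the linear ROI operator: delta-chi on tumor pixels
    dchi <- vapply(ws$freqs, function(f) {
      eb <- background_permittivity(ph$config$background_eps,
                                    ph$config$background_sigma, f)
      step * (1 - 0.5i) * Re(eps_b0) / eb
    }, complex(1))
    pix <- expand.grid(i = ph$rois$tumor$rows, j = ph$rois$tumor$cols)
    on_tumor <- ph$labels[cbind(pix$i, pix$j)] == 7L
    nmv <- nrow(ws$layout$rx) * nrow(ws$layout$tx)
    pred <- complex(length(des))
    for (k in seq_along(ws$freqs)) {
      x <- rep(0 + 0i, nrow(pix))
      x[on_tumor] <- dchi[k]
      rows <- ((k - 1) * nmv + 1):(k * nmv)
      pred[rows] <- op$L[rows, ] %*% x
    }
    sqrt(sum(Mod(des - pred)^2) / sum(Mod(des)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("TSVD at full rank recovers consistent data (pseudo-inverse oracle)", {
  op <- tumor_operator()
  rk <- operator_rank(op)
  expect_lte(rk, 25)
  set.seed(11)
  x_true <- complex(real = rnorm(25, sd = 0.01), imaginary = rnorm(25, sd = 0.01))
  d <- as.vector(op$L %*% x_true)
  img <- tsvd_invert(op, d, pcut = rk)
  expect_lt(sqrt(sum(Mod(as.vector(img$delta_chi) - x_true)^2) /
                 sum(Mod(x_true)^2)), 1e-8)
  # independent oracle: QR least squares
  x_qr <- qr.solve(op$L, d)
  expect_equal(as.vector(img$delta_chi), as.vector(x_qr), tolerance = 1e-8)
})

test_that("TSVD truncation behaves as the filtered expansion", {
  op <- tumor_operator()
  set.seed(3)
  d <- complex(real = rnorm(nrow(op$L)), imaginary = rnorm(nrow(op$L)))
  # zero data -> zero image
  expect_true(all(tsvd_invert(op, 0 * d, 1)$delta_chi == 0))
  # Pcut = 1 is exactly the single-triplet formula
  img1 <- tsvd_invert(op, d, 1)
  manual <- op$v[, 1] * sum(Conj(op$u[, 1]) * d) / op$d[1]
  expect_equal(as.vector(img1$delta_chi), manual, tolerance = 1e-12)
  expect_identical(dim(img1$delta_chi), c(5L, 5L))
  # out-of-range truncation rejected
  expect_error(tsvd_invert(op, d, 0), "pcut")
  expect_error(tsvd_invert(op, d, operator_rank(op) + 1), "pcut")
  # solution norms never decrease in Pcut, and the fitted-data norm
  # (monotone filter property) does not either
  curve <- solution_norm_curve(op, d)
  expect_true(all(diff(curve) >= 0))
  fitted <- vapply(seq_len(operator_rank(op)), function(p) {
    sqrt(sum(Mod(op$L %*% as.vector(tsvd_invert(op, d, p)$delta_chi))^2))
  }, numeric(1))
  expect_true(all(diff(fitted) >= -1e-10))
  # consistent data: final norm equals the pseudo-inverse solution norm
  dcons <- as.vector(op$L %*% (0.01 * (1 + 1i) * seq_len(25)))
  expect_equal(max(solution_norm_curve(op, dcons)),
               sqrt(sum(Mod(qr.solve(op$L, dcons))^2)), tolerance = 1e-8)
})

test_that("operator entries are bilinear in the baseline fields and ROI-restricted", {
  base <- baseline_state()
  ph <- small_phantom()
  scaled <- lapply(base$records, function(fr) { fr$etot <- 2 * fr$etot; fr })
  op1 <- build_roi_operator(base$records, ph$rois$tumor)
  op2 <- build_roi_operator(scaled, ph$rois$tumor)
  expect_equal(op2$L, 4 * op1$L, tolerance = 1e-12)
  # single-pixel ROI: TSVD with Pcut=1 equals scalar least squares
  roi1 <- ph$rois$tumor
  roi1$rows <- roi1$rows[3]; roi1$cols <- roi1$cols[3]; roi1$crop <- 1L
  op_1px <- build_roi_operator(base$records, roi1)
  expect_identical(dim(op_1px$L), c(432L, 1L))
  set.seed(5)
  d <- complex(real = rnorm(432), imaginary = rnorm(432))
  x_ls <- sum(Conj(op_1px$L) * d) / sum(Mod(op_1px$L)^2)
  expect_equal(as.vector(tsvd_invert(op_1px, d, 1)$delta_chi), x_ls,
               tolerance = 1e-10)
})

test_that("heating one ROI leaks little into the other ROI's image", {
  ph <- small_phantom()
  base <- baseline_state()
  op_t <- tumor_operator()
  op_c <- cord_operator()
  hot_t <- solve_state(set_roi_temperatures(ph, 46, 37))
  hot_c <- solve_state(set_roi_temperatures(ph, 37, 40))
  img_own <- tsvd_invert(op_t, as.vector(hot_t$es - base$es), 1)
  img_leak <- tsvd_invert(op_t, as.vector(hot_c$es - base$es), 1)
  leak <- sqrt(sum(Mod(img_leak$delta_chi)^2) /
               sum(Mod(img_own$delta_chi)^2))
  expect_lt(leak, 0.10)
})
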