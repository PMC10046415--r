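# 2D TM scattering: method-of-moments solution of the state equation,
# multistatic scattered-field simulation, analytic cylinder oracle,
# measurement noise.

C0 <- 299792458  # vacuum speed of light, m/s

#' Multistatic antenna layout
#'
#' Point-source transmitters/receivers (co-located by default) on a circle
#' around the neck. The default angles leave a gap at 0 deg (anterior, where
#' the hyperthermia applicator sits): two groups of three flanking it at
#' around +/-45 deg, and six antennas evenly spaced over the posterior arc
#' [120, 240] deg.
#'
#' @param radius circle radius in m (default 0.09).
#' @param angles_deg antenna angles in degrees.
#' @return object of class `antenna_layout` with `tx` and `rx` position
#'   matrices (rows = antennas, columns = x, y in m).
#' @export
antenna_layout <- function(radius = 0.09,
                           angles_deg = c(-55, -45, -35, 35, 45, 55,
                                          120, 144, 168, 192, 216, 240)) {
  stopifnot(radius > 0, length(angles_deg) >= 1)
  a <- angles_deg * pi / 180
  pos <- cbind(radius * cos(a), radius * sin(a))
  structure(list(tx = pos, rx = pos, radius = radius,
                 angles_deg = angles_deg),
            class = "antenna_layout")
}

#' Acquisition frequency set
#'
#' @param n_freq number of frequencies (default 10).
#' @param band frequency band in Hz, default c(0.9e9, 1.8e9).
#' @return strictly increasing numeric vector of length `n_freq`.
#' @export
frequency_set <- function(n_freq = 10L, band = c(0.9e9, 1.8e9)) {
  stopifnot(n_freq >= 1, band[1] > 0, band[2] > band[1] || n_freq == 1)
  if (n_freq == 1) return(mean(band))
  seq(band[1], band[2], length.out = n_freq)
}

#' Background wavenumber
#'
#' kb = (2 pi f / c0) * sqrt(eps_rb), principal square root; for a lossy
#' background (Im eps_rb < 0 under exp(jwt)) this gives Im kb < 0, i.e. decay
#' of the outgoing wave exp(-j kb r).
#'
#' @param f frequency in Hz.
#' @param eps_rb complex background relative permittivity.
#' @return complex wavenumber in rad/m.
#' @export
background_wavenumber <- function(f, eps_rb) {
  (2 * pi * f / C0) * sqrt(as.complex(eps_rb))
}

#' Scalar 2D Green's function of the homogeneous background
#'
#' g(r, r') = -(j/4) H0^(2)(kb |r - r'|) under the exp(jwt) convention
#' (outgoing, decaying in a lossy background).
#'
#' @param kb complex background wavenumber.
#' @param dist distances |r - r'| in m (vectorised), > 0.
#' @return complex vector.
#' @export
background_green <- function(kb, dist) {
  if (any(dist <= 0)) {
    stop("background_green is singular at coincident points; the self-cell ",
         "term is integrated analytically inside the MoM solver")
  }
  -0.25i * besselh2(0, kb * dist)
}

#' Incident field of one point (line) source
#'
#' Einc(r; rv) = amplitude * g(r, rv): the field of a 2D line source in the
#' homogeneous background.
#'
#' @param layout an [antenna_layout()].
#' @param kb complex background wavenumber.
#' @param v source index (1-based).
#' @param points matrix of observation points (rows = points, cols = x, y).
#' @param amplitude complex source amplitude (default 1).
#' @return complex vector, one value per observation point.
#' @export
incident_field <- function(layout, kb, v, points, amplitude = 1) {
  stopifnot(inherits(layout, "antenna_layout"), v >= 1, v <= nrow(layout$tx))
  rv <- layout$tx[v, ]
  d <- sqrt((points[, 1] - rv[1])^2 + (points[, 2] - rv[2])^2)
  amplitude * background_green(kb, d)
}

# MoM self-term: kb^2 * integral of g over the square cell, via the
# equal-area circular cell (radius a = h/sqrt(pi)):
#   kb^2 int_cell g dA = -(j pi kb a / 2) H1^(2)(kb a) - 1
#' @noRd
mom_self_term <- function(kb, h) {
  a <- h / sqrt(pi)
  -0.5i * pi * kb * a * besselh2(1, kb * a) - 1
}

# Convolution kernel K(di, dj) on pixel offsets: K(0,0) = self-term,
# otherwise kb^2 g(d) h^2 (midpoint rule). (2n-1)x(2n-1), center (n, n).
#' @noRd
mom_kernel <- function(kb, h, n) {
  off <- seq(-(n - 1), n - 1) * h
  # distances between cell centers at integer offsets
  d <- sqrt(outer(off^2, off^2, "+"))
  k <- matrix(0 + 0i, 2 * n - 1, 2 * n - 1)
  ctr <- d == 0
  k[!ctr] <- kb^2 * background_green(kb, d[!ctr]) * h^2
  k[ctr] <- mom_self_term(kb, h)
  k
}

#' Precompute geometry-dependent forward-solver workspace
#'
#' Everything in the state/data equations that depends only on the grid, the
#' tissue-label mask, the antenna layout and the frequencies (Green's
#' matrices, incident fields, receiver matrices) is computed once here and
#' reused across samples, whose randomized permittivities only change the
#' diagonal contrast scaling.
#'
#' @param phantom a phantom (labels define the scatterer support).
#' @param layout an [antenna_layout()].
#' @param freqs frequency vector in Hz.
#' @return object of class `forward_workspace`.
#' @export
make_forward_workspace <- function(phantom, layout, freqs) {
  stopifnot(inherits(phantom, "phantom"), inherits(layout, "antenna_layout"))
  n <- nrow(phantom$labels)
  h <- phantom$cell_size
  cfg <- phantom$config
  # solve on every tissue cell plus the ROI windows: window pixels can fall
  # just outside the neck on coarse grids, and the imaging operators need the
  # total field there (the state equation at a zero-contrast cell still
  # returns the correct total field)
  sup <- phantom$labels > 0L
  for (roi in phantom$rois) sup[roi$rows, roi$cols] <- TRUE
  mask <- which(sup, arr.ind = TRUE)
  pts <- cbind(phantom$xc[mask[, 1]], phantom$yc[mask[, 2]])
  # sources must sit outside the scatterer support
  for (v in seq_len(if (nrow(mask) > 0) nrow(layout$tx) else 0L)) {
    dmin <- min(sqrt((pts[, 1] - layout$tx[v, 1])^2 +
                     (pts[, 2] - layout$tx[v, 2])^2))
    if (dmin < h / 2) {
      stop("antenna ", v, " lies inside the scatterer support")
    }
  }
  per_freq <- lapply(freqs, function(f) {
    eps_b <- background_permittivity(cfg$background_eps, cfg$background_sigma,
                                     f)
    kb <- background_wavenumber(f, eps_b)
    lam <- 2 * pi / Re(kb)
    if (h > lam / 10) {
      warning(sprintf(
        "%.0f cells per background wavelength at %.3g GHz (fewer than 10)",
        lam / h, f / 1e9), call. = FALSE)
    }
    kern <- mom_kernel(kb, h, n)
    di <- outer(mask[, 1], mask[, 1], "-") + n
    dj <- outer(mask[, 2], mask[, 2], "-") + n
    G <- matrix(kern[cbind(as.vector(di), as.vector(dj))],
                nrow(mask), nrow(mask))
    einc <- vapply(seq_len(nrow(layout$tx)), function(v) {
      incident_field(layout, kb, v, pts)
    }, complex(nrow(mask)))
    grec <- t(vapply(seq_len(nrow(layout$rx)), function(m) {
      d <- sqrt((pts[, 1] - layout$rx[m, 1])^2 +
                (pts[, 2] - layout$rx[m, 2])^2)
      kb^2 * background_green(kb, d) * h^2
    }, complex(nrow(mask))))
    list(f = f, kb = kb, eps_b = eps_b, kernel = kern, G = G,
         einc = einc, grec = grec)
  })
  structure(list(mask = mask, points = pts, n = n, h = h,
                 xc = phantom$xc, yc = phantom$yc,
                 layout = layout, freqs = freqs, per_freq = per_freq),
            class = "forward_workspace")
}

# solve the state equation on the masked cells for one frequency, given the
# per-pixel contrast on the mask; returns Etot on the mask (n_mask x Nv) and
# the receiver fields ES (Nm x Nv)
#' @noRd
solve_masked <- function(ws_f, chi_mask) {
  nm <- length(chi_mask)
  if (nm == 0 || all(chi_mask == 0)) {
    es <- matrix(0 + 0i, nrow(ws_f$grec), ncol(ws_f$einc))
    return(list(etot = ws_f$einc, es = es))
  }
  A <- -ws_f$G * matrix(chi_mask, nm, nm, byrow = TRUE)
  diag(A) <- diag(A) + 1
  etot <- solve(A, ws_f$einc)
  es <- ws_f$grec %*% (chi_mask * etot)
  list(etot = etot, es = es)
}

#' Solve the 2D TM total-field (state) equation for a phantom
#'
#' Pulse-basis, point-matching method of moments on the raster: the self cell
#' is integrated analytically over the equal-area circle, off-diagonal
#' interactions use the midpoint rule. Small systems are solved by dense LU;
#' above `dense_limit` unknowns a conjugate-gradient solver on the normal
#' equations with FFT-accelerated operator application is used.
#'
#' @param phantom a phantom.
#' @param layout an [antenna_layout()].
#' @param f frequency in Hz.
#' @param solver "auto" (default), "dense" or "cgfft".
#' @param tol relative-residual tolerance for the iterative solver.
#' @param dense_limit unknown count above which "auto" switches to cgfft.
#' @param workspace optionally, a [make_forward_workspace()] for this
#'   geometry (dense path only); avoids recomputing Green's matrices.
#' @return object of class `field_record`: `f`, `kb`, `es` (Nm x Nv complex
#'   receiver matrix), `etot` (n_mask x Nv total field on the scatterer
#'   cells), `mask` (their pixel indices), `einc`, and the layout.
#' @export
solve_total_field <- function(phantom, layout, f, solver = "auto",
                              tol = 1e-6, dense_limit = 4096L,
                              workspace = NULL) {
  if (is.null(workspace)) {
    workspace <- make_forward_workspace(phantom, layout, f)
    fi <- 1L
  } else {
    fi <- match(f, workspace$freqs)
    if (is.na(fi)) stop("frequency not present in the supplied workspace")
  }
  ws_f <- workspace$per_freq[[fi]]
  chi_full <- contrast_map(phantom, f)
  chi_mask <- chi_full[workspace$mask]
  nm <- length(chi_mask)
  use_cgfft <- solver == "cgfft" || (solver == "auto" && nm > dense_limit)
  if (!use_cgfft) {
    sol <- solve_masked(ws_f, chi_mask)
  } else {
    sol <- solve_cgfft(ws_f, workspace, chi_full, tol = tol)
  }
  structure(list(f = f, kb = ws_f$kb, es = sol$es, etot = sol$etot,
                 einc = ws_f$einc, mask = workspace$mask,
                 layout = layout, n = workspace$n, h = workspace$h),
            class = "field_record")
}

# CGNR with FFT-accelerated application of (I - K * chi .) on the full grid.
#' @noRd
solve_cgfft <- function(ws_f, ws, chi_full, tol = 1e-6, maxit = 2000L) {
  n <- ws$n
  np <- 2L * n
  kern_pad <- matrix(0 + 0i, np, np)
  kern_pad[1:(2 * n - 1), 1:(2 * n - 1)] <- ws_f$kernel
  # kernel center (n, n) must land on index (1, 1) of the circulant
  kern_pad <- kern_pad[c(n:np, 1:(n - 1)), c(n:np, 1:(n - 1))]
  Kf <- stats::fft(kern_pad)
  conv_k <- function(x, kf) {
    xp <- matrix(0 + 0i, np, np)
    xp[1:n, 1:n] <- x
    y <- stats::fft(stats::fft(xp) * kf, inverse = TRUE) / (np * np)
    y[1:n, 1:n]
  }
  A_apply <- function(x) x - conv_k(chi_full * x, Kf)
  Ah_apply <- function(x) x - Conj(chi_full) * conv_k(x, Conj(Kf))
  nv <- ncol(ws_f$einc)
  etot_full <- matrix(0 + 0i, n * n, nv)
  # incident field on the full grid for each source
  for (v in seq_len(nv)) {
    kb <- ws_f$kb
    rv <- ws$layout$tx[v, ]
    dx <- outer(ws$xc - rv[1], rep(1, n))
    dy <- outer(rep(1, n), ws$yc - rv[2])
    b <- matrix(background_green(kb, sqrt(dx^2 + dy^2)), n, n)
    x <- b
    r <- b - A_apply(x)
    s <- Ah_apply(r)
    p <- s
    gamma <- sum(Mod(s)^2)
    bnorm <- sqrt(sum(Mod(b)^2))
    for (it in seq_len(maxit)) {
      q <- A_apply(p)
      alpha <- gamma / sum(Mod(q)^2)
      x <- x + alpha * p
      r <- r - alpha * q
      if (sqrt(sum(Mod(r)^2)) / bnorm < tol) break
      s <- Ah_apply(r)
      gamma_new <- sum(Mod(s)^2)
      p <- s + (gamma_new / gamma) * p
      gamma <- gamma_new
    }
    if (sqrt(sum(Mod(r)^2)) / bnorm >= tol) {
      stop(sprintf("CG-FFT did not converge: relative residual %.3e",
                   sqrt(sum(Mod(r)^2)) / bnorm))
    }
    etot_full[, v] <- as.vector(x)
  }
  idx <- (ws$mask[, 2] - 1L) * n + ws$mask[, 1]
  etot <- etot_full[idx, , drop = FALSE]
  chi_mask <- chi_full[ws$mask]
  es <- ws_f$grec %*% (chi_mask * etot)
  list(etot = etot, es = es)
}

#' Analytic series solution for TM scattering by a homogeneous cylinder
#'
#' Independent reference (Bessel/Hankel partial-wave series with the
#' line-source addition theorem) for a homogeneous circular cylinder centered
#' at the origin, used as an oracle for the MoM solver. The series is summed
#' until the added term falls below 1e-12 of the running sum.
#'
#' @param radius cylinder radius in m.
#' @param eps_cyl,eps_bg complex relative permittivities.
#' @param layout an [antenna_layout()]; antennas must be outside the
#'   cylinder.
#' @param f frequency in Hz.
#' @return Nm x Nv complex matrix of scattered fields.
#' @export
analytic_cylinder_reference <- function(radius, eps_cyl, eps_bg, layout, f) {
  stopifnot(radius >= 0)
  nv <- nrow(layout$tx); nmr <- nrow(layout$rx)
  if (radius == 0 || eps_cyl == eps_bg) {
    return(matrix(0 + 0i, nmr, nv))
  }
  kb <- background_wavenumber(f, eps_bg)
  kc <- background_wavenumber(f, eps_cyl)
  rho_v <- sqrt(rowSums(layout$tx^2)); phi_v <- atan2(layout$tx[, 2],
                                                      layout$tx[, 1])
  rho_m <- sqrt(rowSums(layout$rx^2)); phi_m <- atan2(layout$rx[, 2],
                                                      layout$rx[, 1])
  if (any(rho_v <= radius) || any(rho_m <= radius)) {
    stop("antennas must lie outside the cylinder")
  }
  nmax <- ceiling(Mod(kb) * radius) + 40L
  jb <- bessel_j_seq(kb * radius, nmax + 1L)
  jc <- bessel_j_seq(kc * radius, nmax + 1L)
  hb <- bessel_h2_seq(kb * radius, nmax + 1L)
  dfun <- function(seq0, z, ord) {
    # derivative of cylinder function of order ord: C_{ord-1} - (ord/z) C_ord
    if (ord == 0) -seq0[2] else seq0[ord] - (ord / z) * seq0[ord + 1]
  }
  hv <- lapply(seq_len(nv), function(v) bessel_h2_seq(kb * rho_v[v], nmax))
  hm <- lapply(seq_len(nmr), function(m) bessel_h2_seq(kb * rho_m[m], nmax))
  es <- matrix(0 + 0i, nmr, nv)
  run <- 0
  for (nn in 0:nmax) {
    jbd <- dfun(jb, kb * radius, nn)
    jcd <- dfun(jc, kc * radius, nn)
    hbd <- dfun(hb, kb * radius, nn)
    bn <- (kb * jc[nn + 1] * jbd - kc * jcd * jb[nn + 1]) /
          (kc * jcd * hb[nn + 1] - kb * jc[nn + 1] * hbd)
    hvv <- vapply(hv, function(x) x[nn + 1], complex(1))
    hmm <- vapply(hm, function(x) x[nn + 1], complex(1))
    ang <- outer(phi_m, phi_v, "-")
    term <- -0.25i * bn * outer(hmm, hvv) *
      (if (nn == 0) exp(1i * nn * ang) else 2 * cos(nn * ang))
    es <- es + term
    run <- max(run, max(Mod(es)))
    if (nn > Mod(kb) * radius + 5 && max(Mod(term)) < 1e-12 * run) {
      return(es)
    }
  }
  stop("cylinder series did not converge; increase truncation")
}

#' Add white Gaussian measurement noise to scattered-field data
#'
#' Complex circular Gaussian noise, with power chosen per frequency so the
#' ratio of total signal power to noise power over the whole Nm x Nv block
#' equals `10^(snr_db/10)`. Reproducible under `seed`.
#'
#' @param es complex array (Nm x Nv, or Nm x Nv x Nf).
#' @param snr_db signal-to-noise ratio in dB; `Inf` returns `es` unchanged.
#' @param seed integer seed.
#' @return noisy array of the same shape.
#' @export
add_awgn <- function(es, snr_db, seed) {
  if (!is.finite(snr_db)) return(es)
  dm <- dim(es)
  if (length(dm) == 2) {
    es <- array(es, c(dm, 1L))
    dm <- dim(es)
  }
  out <- with_local_seed(seed, {
    noisy <- es
    for (k in seq_len(dm[3])) {
      slab <- es[, , k]
      p_sig <- mean(Mod(slab)^2)
      sdc <- sqrt(p_sig / 10^(snr_db / 10) / 2)
      nre <- stats::rnorm(length(slab), 0, sdc)
      nim <- stats::rnorm(length(slab), 0, sdc)
      noisy[, , k] <- slab + complex(real = nre, imaginary = nim)
    }
    noisy
  })
  if (dm[3] == 1) out[, , 1] else out
}
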