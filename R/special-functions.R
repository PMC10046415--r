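# Complex-argument Bessel/Hankel functions.
#
# The lossy background medium makes the wavenumber complex, so the 2D Green's
# function needs H0^(2), H1^(2) at complex argument; the analytic cylinder
# series additionally needs J_n, Y_n up to moderate order. Base R's
# besselJ/besselY accept only real arguments, hence these kernels: power
# series for |z| <= 11, Hankel asymptotic expansions beyond, with the
# standard recurrences for higher orders. Valid for |arg z| < pi (our
# arguments always sit in the lower right half-plane, arg in (-pi/2, 0]).

EULER_GAMMA <- 0.5772156649015328606

#' Order-0 and order-1 Bessel/Hankel values at complex argument
#'
#' Computes J0, J1, Y0, Y1 for a vector of complex arguments, from which the
#' Hankel functions of either kind follow. Internal workhorse.
#'
#' @param z complex vector, `Mod(z) > 0`, `|Arg(z)| < pi`.
#' @return list with complex vectors `j0`, `j1`, `y0`, `y1`.
#' @keywords internal
#' @noRd
bessel01_complex <- function(z) {
  z <- as.complex(z)
  stopifnot(all(is.finite(z)), all(Mod(z) > 0))
  n <- length(z)
  j0 <- j1 <- y0 <- y1 <- complex(n)
  small <- Mod(z) <= 11

  if (any(small)) {
    zs <- z[small]
    q <- zs * zs / 4                       # (z/2)^2
    # J0, J1 and the log-free parts of Y0, Y1 share the term recursion.
    tj0 <- rep(1 + 0i, length(zs))         # (-1)^k q^k / (k!)^2
    sj0 <- tj0
    sy0 <- 0 + 0i                          # sum (-1)^k H_k q^k/(k!)^2
    tj1 <- rep(1 + 0i, length(zs))         # (-1)^k q^k / (k!(k+1)!)
    sj1 <- tj1
    sy1 <- (0 - EULER_GAMMA) + (1 - EULER_GAMMA)  # psi(1)+psi(2) at k=0
    sy1 <- rep(as.complex(sy1), length(zs))
    ty1 <- rep(1 + 0i, length(zs))
    hk <- 0
    for (k in seq_len(48)) {
      tj0 <- -tj0 * q / (k * k)
      sj0 <- sj0 + tj0
      hk <- hk + 1 / k
      sy0 <- sy0 + tj0 * hk
      tj1 <- -tj1 * q / (k * (k + 1))
      sj1 <- sj1 + tj1
      ty1 <- -ty1 * q / (k * (k + 1))
      psis <- (-EULER_GAMMA + hk) + (-EULER_GAMMA + hk + 1 / (k + 1))
      sy1 <- sy1 + ty1 * psis
    }
    lg <- log(zs / 2)
    j0s <- sj0
    j1s <- (zs / 2) * sj1
    y0s <- (2 / pi) * ((lg + EULER_GAMMA) * j0s - sy0)
    y1s <- (2 / pi) * lg * j1s - 2 / (pi * zs) - (zs / (2 * pi)) * sy1
    j0[small] <- j0s; j1[small] <- j1s; y0[small] <- y0s; y1[small] <- y1s
  }

  if (any(!small)) {
    zl <- z[!small]
    h <- function(nu, kind) hankel_asymptotic(zl, nu, kind)
    h10 <- h(0, 1); h20 <- h(0, 2); h11 <- h(1, 1); h21 <- h(1, 2)
    j0[!small] <- (h10 + h20) / 2
    y0[!small] <- (h10 - h20) / (2i)
    j1[!small] <- (h11 + h21) / 2
    y1[!small] <- (h11 - h21) / (2i)
  }
  list(j0 = j0, j1 = j1, y0 = y0, y1 = y1)
}

# Hankel asymptotic expansion for order nu in {0,1}; terms added while they
# keep shrinking elementwise (optimal truncation of the divergent series).
#' @noRd
hankel_asymptotic <- function(z, nu, kind) {
  sgn <- if (kind == 1) 1i else -1i
  mu <- 4 * nu * nu
  s <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  last <- rep(Inf, length(z))
  active <- rep(TRUE, length(z))
  for (k in seq_len(24)) {
    term <- term * sgn * (mu - (2 * k - 1)^2) / (8 * k * z)
    mag <- Mod(term)
    active <- active & (mag < last)
    if (!any(active)) break
    s[active] <- s[active] + term[active]
    last <- mag
  }
  phase <- z - nu * pi / 2 - pi / 4
  sqrt(2 / (pi * z)) * exp(sgn * phase) * s
}

#' Hankel function of the second kind, orders 0 and 1, complex argument
#'
#' Under the `exp(jwt)` time convention, outgoing cylindrical waves are
#' described by the Hankel function of the second kind. These two orders are
#' the building blocks of the 2D background Green's function and of the MoM
#' self-term.
#'
#' @param nu order, 0 or 1.
#' @param z complex (or real) vector with `Mod(z) > 0`.
#' @return complex vector of the same length.
#' @examples
#' besselh2(0, 1.5)                      # J0(1.5) - i Y0(1.5)
#' besselh2(1, 2 - 0.5i)
#' @export
besselh2 <- function(nu, z) {
  stopifnot(nu %in% c(0, 1))
  b <- bessel01_complex(z)
  if (nu == 0) b$j0 - 1i * b$y0 else b$j1 - 1i * b$y1
}

#' Sequences of Bessel functions at complex argument
#'
#' `bessel_j_seq()` returns J_0(z)..J_nmax(z) by Miller's downward recurrence
#' normalised against the order-0 kernel; `bessel_h2_seq()` returns
#' H^(2)_0(z)..H^(2)_nmax(z) by (stable) upward recurrence. Both are used by
#' the analytic cylinder-series reference solution.
#'
#' @param z a single complex value, `Mod(z) > 0`.
#' @param nmax highest order (>= 1).
#' @return complex vector of length `nmax + 1`, orders 0..nmax.
#' @keywords internal
bessel_j_seq <- function(z, nmax) {
  z <- as.complex(z)
  stopifnot(length(z) == 1, Mod(z) > 0, nmax >= 1)
  m <- nmax + max(20L, ceiling(Mod(z)))
  jp <- 0 + 0i                     # J_{k+1}, seeded at order m+1
  jc <- 1e-30 + 0i                 # J_k, seeded at order m
  out <- complex(nmax + 1)
  for (k in m:1) {
    jm <- (2 * k / z) * jc - jp    # J_{k-1}
    jp <- jc
    jc <- jm
    if (k - 1 <= nmax) out[k] <- jc
  }
  ref <- bessel01_complex(z)$j0
  out * (ref / out[1])
}

#' @rdname bessel_j_seq
#' @keywords internal
bessel_h2_seq <- function(z, nmax) {
  z <- as.complex(z)
  stopifnot(length(z) == 1, Mod(z) > 0, nmax >= 1)
  b <- bessel01_complex(z)
  out <- complex(nmax + 1)
  out[1] <- b$j0 - 1i * b$y0
  out[2] <- b$j1 - 1i * b$y1
  if (nmax >= 2) {
    for (k in 2:nmax) out[k + 1] <- (2 * (k - 1) / z) * out[k] - out[k - 1]
  }
  out
}
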