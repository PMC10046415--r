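# Temperature-dependent Cole-Cole tissue dielectrics.

EPS0_DEFAULT <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Cole-Cole dispersion parameters for one tissue
#'
#' A two-pole Cole-Cole parameter set at the reference temperature of 37 C.
#' `eps_inf` is the optical (high-frequency) permittivity, `delta_eps1/2` the
#' dispersion amplitudes with relaxation times `tau1/2` (seconds) and
#' broadening exponents `alpha1/2` in [0,1), and `sigma` the static ionic
#' conductivity in S/m.
#'
#' @param eps_inf,delta_eps1,delta_eps2,tau1,tau2,alpha1,alpha2,sigma numeric
#'   scalars, see Details.
#' @return an object of class `cole_cole_params`.
#' @examples
#' p <- cole_cole_params(4, 50, 7000, 7.2e-12, 3.5e-7, 0.1, 0.1, 0.2)
#' cole_cole(p, 1e9)
#' @export
cole_cole_params <- function(eps_inf, delta_eps1, delta_eps2,
                             tau1, tau2, alpha1, alpha2, sigma) {
  p <- list(eps_inf = eps_inf, delta_eps1 = delta_eps1,
            delta_eps2 = delta_eps2, tau1 = tau1, tau2 = tau2,
            alpha1 = alpha1, alpha2 = alpha2, sigma = sigma)
  stopifnot(eps_inf >= 1, delta_eps1 >= 0, delta_eps2 >= 0,
            tau1 > 0, tau2 > 0,
            alpha1 >= 0, alpha1 < 1, alpha2 >= 0, alpha2 < 1,
            sigma >= 0)
  structure(p, class = "cole_cole_params")
}

#' Complex relative permittivity from the Cole-Cole model
#'
#' Evaluates the two-pole Cole-Cole dispersion
#' eps_r(w) = eps_inf + d_eps1/(1+(jw tau1)^(1-alpha1))
#'          + d_eps2/(1+(jw tau2)^(1-alpha2)) + sigma/(jw eps0),
#' with w = 2 pi f, under the exp(jwt) convention so eps_r = eps' - j eps''
#' with eps'' >= 0. The (1-alpha) power of the complex quantity uses the
#' principal branch.
#'
#' @param params a [cole_cole_params()] object.
#' @param f frequency in Hz (vectorised), must be > 0.
#' @param eps0 vacuum permittivity; default the CODATA value. (Some printed
#'   tables round this constant differently; it is exposed for bit-matching.)
#' @return complex vector `eps' - 1i*eps''`.
#' @export
cole_cole <- function(params, f, eps0 = EPS0_DEFAULT) {
  stopifnot(inherits(params, "cole_cole_params"))
  if (any(f <= 0)) stop("frequency must be positive")
  w <- 2 * pi * f
  p <- params
  e <- p$eps_inf +
    p$delta_eps1 / (1 + (1i * w * p$tau1)^(1 - p$alpha1)) +
    p$delta_eps2 / (1 + (1i * w * p$tau2)^(1 - p$alpha2)) +
    p$sigma / (1i * w * eps0)
  # numerical dust can leave a tiny positive imaginary part; clamp to passivity
  complex(real = Re(e), imaginary = pmin(Im(e), 0))
}

#' Linear temperature coefficients for Cole-Cole parameters
#'
#' One relative rate of change per degree Celsius for each Cole-Cole
#' parameter, about the 37 C reference. The coefficients act multiplicatively:
#' parameter p becomes `p * (1 + c_p * (T - 37))`.
#'
#' The bundled defaults (conductivity +2 %/C, first dispersion amplitude
#' -0.5 %/C, all other parameters temperature-insensitive) reflect the
#' commonly reported dominant temperature sensitivities of tissue
#' conductivity and permittivity in the low-GHz band; the exact per-tissue
#' rates are configuration, not physics baked into the code.
#'
#' @param eps_inf,delta_eps1,delta_eps2,tau1,tau2,alpha1,alpha2,sigma relative
#'   rates in 1/C (default 0 except as noted above).
#' @return an object of class `temperature_coefficients`.
#' @export
temperature_coefficients <- function(eps_inf = 0, delta_eps1 = -0.005,
                                     delta_eps2 = 0, tau1 = 0, tau2 = 0,
                                     alpha1 = 0, alpha2 = 0, sigma = 0.02) {
  structure(list(eps_inf = eps_inf, delta_eps1 = delta_eps1,
                 delta_eps2 = delta_eps2, tau1 = tau1, tau2 = tau2,
                 alpha1 = alpha1, alpha2 = alpha2, sigma = sigma),
            class = "temperature_coefficients")
}

#' Cole-Cole parameters at a treatment temperature
#'
#' Applies the linear relative-rate model: each parameter p of `base` becomes
#' `p * (1 + c_p * (T - 37))`. At T = 37 C the base set is returned unchanged.
#'
#' @param base a [cole_cole_params()] object at 37 C.
#' @param coeffs a [temperature_coefficients()] object.
#' @param T_celsius temperature in C, inside `window`.
#' @param window validity window in C, default c(37, 46).
#' @return a [cole_cole_params()] object.
#' @export
params_at_temperature <- function(base, coeffs, T_celsius,
                                  window = c(37, 46)) {
  stopifnot(inherits(base, "cole_cole_params"),
            inherits(coeffs, "temperature_coefficients"))
  if (T_celsius < window[1] || T_celsius > window[2]) {
    stop(sprintf("temperature %.2f C outside validity window [%g, %g]",
                 T_celsius, window[1], window[2]))
  }
  dT <- T_celsius - 37
  vals <- lapply(names(unclass(base)), function(nm) {
    base[[nm]] * (1 + coeffs[[nm]] * dT)
  })
  names(vals) <- names(unclass(base))
  do.call(cole_cole_params, vals)
}

#' Contrast function with respect to the background medium
#'
#' chi = eps_r / eps_rb - 1, the normalized complex permittivity contrast
#' that drives the scattering equations.
#'
#' @param eps complex relative permittivity (vectorised).
#' @param eps_background complex relative permittivity of the background,
#'   non-zero.
#' @return complex contrast values.
#' @export
contrast <- function(eps, eps_background) {
  if (any(eps_background == 0)) stop("background permittivity must be non-zero")
  # algebraically eps/eps_b - 1, but this form keeps the contrast exactly
  # zero where eps equals the background (complex x/x leaves a rounding
  # residue in the imaginary part)
  (eps - eps_background) / eps_background
}

#' Complex permittivity of a conductive background medium
#'
#' Non-dispersive background (water-mixture matching medium):
#' eps_rb = eps_prime - j sigma/(w eps0).
#'
#' @param eps_prime real relative permittivity.
#' @param sigma conductivity in S/m.
#' @param f frequency in Hz.
#' @param eps0 vacuum permittivity.
#' @return complex scalar (or vector over `f`).
#' @export
background_permittivity <- function(eps_prime, sigma, f,
                                    eps0 = EPS0_DEFAULT) {
  stopifnot(all(f > 0))
  complex(real = eps_prime, imaginary = -sigma / (2 * pi * f * eps0))
}

#' @export
print.cole_cole_params <- function(x, ...) {
  cat("Cole-Cole parameters:\n")
  cat(sprintf(
    "  eps_inf=%g  d_eps1=%g  d_eps2=%g\n  tau1=%.3e s  tau2=%.3e s  alpha1=%g  alpha2=%g\n  sigma=%g S/m\n",
    x$eps_inf, x$delta_eps1, x$delta_eps2, x$tau1, x$tau2,
    x$alpha1, x$alpha2, x$sigma))
  invisible(x)
}
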