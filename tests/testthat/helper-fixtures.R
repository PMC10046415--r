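# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small desk-scale phantom at full-scale cell size (3.75 mm)
small_phantom <- function() {
  fixture("small_phantom", function() {
    build_neck_phantom(phantom_config(n = 32L, domain_size = 0.12))
  })
}

small_workspace <- function() {
  fixture("small_workspace", function() {
    suppressWarnings(
      make_forward_workspace(small_phantom(), antenna_layout(),
                             frequency_set(3L)))
  })
}

# solve baseline + return field records and ES stack for a phantom state
solve_state <- function(phantom, ws = small_workspace()) {
  nf <- length(ws$freqs)
  nm <- nrow(ws$layout$rx); nv <- nrow(ws$layout$tx)
  es <- array(0 + 0i, c(nm, nv, nf))
  rec <- vector("list", nf)
  for (k in seq_len(nf)) {
    fr <- suppressWarnings(
      solve_total_field(phantom, ws$layout, ws$freqs[k], workspace = ws))
    es[, , k] <- fr$es
    rec[[k]] <- fr
  }
  list(es = es, records = rec)
}

baseline_state <- function() {
  fixture("baseline_state", function() solve_state(small_phantom()))
}

tumor_operator <- function() {
  fixture("tumor_operator", function() {
    build_roi_operator(baseline_state()$records, small_phantom()$rois$tumor)
  })
}

cord_operator <- function() {
  fixture("cord_operator", function() {
    build_roi_operator(baseline_state()$records, small_phantom()$rois$cord)
  })
}

# literal term-by-term transcription of the two-pole Cole-Cole dispersion,
# kept independent of the package implementation (test oracle)
cole_cole_oracle <- function(p, f, eps0 = 8.8541878128e-12) {
  w <- 2 * pi * f
  term1 <- p$delta_eps1 / (1 + (1i * w * p$tau1)^(1 - p$alpha1))
  term2 <- p$delta_eps2 / (1 + (1i * w * p$tau2)^(1 - p$alpha2))
  p$eps_inf + term1 + term2 + p$sigma / (1i * w * eps0)
}
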