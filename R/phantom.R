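# Synthetic 2D neck phantom: tissue-label raster, ROI geometry, imposed
# ROI temperatures and per-sample permittivity randomization.

TISSUE_CODES <- c(background = 0L, skin = 1L, fat = 2L, muscle = 3L,
                  bone = 4L, spinal_cord = 5L, thyroid = 6L, tumor = 7L)

#' Configuration for the synthetic neck phantom
#'
#' The imaging domain is a square of side `domain_size` discretized into
#' `n x n` square cells. Pixel (i, j) has its center at
#' `((i - 0.5) * h - domain_size/2, (j - 0.5) * h - domain_size/2)` with
#' `h = domain_size / n`; i runs along x (anterior direction, toward the
#' thyroid/tumor), j along y (lateral). All lengths in meters.
#'
#' The anatomy is a stylized neck cross-section: an elliptical outline with a
#' skin and a subcutaneous-fat shell around a muscle bulk, a vertebral-bone
#' disc enclosing the spinal cord posteriorly, two anterior thyroid lobes,
#' and a circular tumor (default radius 4.5 mm) inside one lobe. The default
#' 24 cm domain keeps the 5x5-pixel tumor crop (at n = 128) just large enough
#' to enclose the 9 mm tumor disc.
#'
#' @param n grid size per side (default 128).
#' @param domain_size side of the square imaging domain in m (default 0.24).
#' @param neck_semiaxes ellipse semi-axes (x, y) in m.
#' @param skin_thickness,fat_thickness shell thicknesses in m.
#' @param vertebra_center,vertebra_radius bone disc, m.
#' @param cord_radius spinal cord disc radius, m (concentric with vertebra).
#' @param thyroid_centers 2x2 matrix of lobe centers (rows), m.
#' @param thyroid_radius lobe radius, m.
#' @param tumor_center tumor disc center, m (defaults inside the second lobe).
#' @param tumor_radius tumor disc radius, m (default 0.0045).
#' @param tumor_crop,cord_crop ROI window sizes in pixels (5 and 6).
#' @param background_eps,background_sigma matching-medium properties
#'   (relative permittivity and S/m).
#' @param tissue_table a [load_tissue_table()] result (default: bundled).
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(n = 128L,
                           domain_size = 0.24,
                           neck_semiaxes = c(0.055, 0.050),
                           skin_thickness = 0.004,
                           fat_thickness = 0.004,
                           vertebra_center = c(-0.020, 0),
                           vertebra_radius = 0.018,
                           cord_radius = 0.0045,
                           thyroid_centers = rbind(c(0.033, 0.016),
                                                   c(0.033, -0.016)),
                           thyroid_radius = 0.010,
                           tumor_center = c(0.033, -0.016),
                           tumor_radius = 0.0045,
                           tumor_crop = 5L,
                           cord_crop = 6L,
                           background_eps = 23,
                           background_sigma = 1.0,
                           tissue_table = load_tissue_table()) {
  cfg <- as.list(environment())
  structure(cfg, class = "phantom_config")
}

# pixel-center coordinate vectors for a config
#' @noRd
grid_centers <- function(n, domain_size) {
  h <- domain_size / n
  (seq_len(n) - 0.5) * h - domain_size / 2
}

# label all pixels whose center lies in a disc; guarantee at least the pixel
# containing the disc center carries the label (sub-cell structures on
# coarse grids must not vanish from the raster)
#' @noRd
label_disc <- function(labels, xc, yc, center, radius, code) {
  dx <- outer(xc - center[1], rep(1, length(yc)))
  dy <- outer(rep(1, length(xc)), yc - center[2])
  inside <- dx^2 + dy^2 <= radius^2
  if (!any(inside)) {
    i <- which.min(abs(xc - center[1]))
    j <- which.min(abs(yc - center[2]))
    inside[i, j] <- TRUE
  }
  labels[inside] <- code
  labels
}

#' Build the synthetic neck phantom
#'
#' Rasterizes the stylized neck anatomy onto the configured grid and returns
#' a phantom at a uniform physiological temperature of 37 C with no
#' per-sample randomization. The raster is a pure function of the
#' configuration.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom` with fields `labels` (n x n integer
#'   matrix of tissue codes), `cell_size`, `xc`/`yc` pixel-center
#'   coordinates, `rois` (tumor and cord [roi_spec()]s), `offsets`
#'   (per-tissue complex permittivity perturbations, zero), and
#'   `T_tumor`/`T_cord` (37).
#' @export
build_neck_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  if (cfg$tumor_radius <= 0) stop("tumor radius must be positive")
  ax <- cfg$neck_semiaxes[1]; ay <- cfg$neck_semiaxes[2]
  if (ax + cfg$tumor_radius > cfg$domain_size / 2 ||
      ay > cfg$domain_size / 2) {
    stop("neck outline does not fit inside the imaging domain")
  }
  d_tum <- sqrt(sum((cfg$tumor_center)^2))
  if (d_tum + cfg$tumor_radius > max(ax, ay)) {
    stop("tumor does not fit inside the neck outline")
  }
  n <- cfg$n
  xc <- grid_centers(n, cfg$domain_size)
  yc <- xc
  h <- cfg$domain_size / n

  labels <- matrix(TISSUE_CODES[["background"]], n, n)
  ell <- function(axx, ayy) {
    outer(xc^2 / axx^2, rep(1, n)) + outer(rep(1, n), yc^2 / ayy^2) <= 1
  }
  labels[ell(ax, ay)] <- TISSUE_CODES[["skin"]]
  labels[ell(ax - cfg$skin_thickness, ay - cfg$skin_thickness)] <-
    TISSUE_CODES[["fat"]]
  inner <- cfg$skin_thickness + cfg$fat_thickness
  labels[ell(ax - inner, ay - inner)] <- TISSUE_CODES[["muscle"]]
  labels <- label_disc(labels, xc, yc, cfg$vertebra_center,
                       cfg$vertebra_radius, TISSUE_CODES[["bone"]])
  labels <- label_disc(labels, xc, yc, cfg$vertebra_center,
                       cfg$cord_radius, TISSUE_CODES[["spinal_cord"]])
  for (k in seq_len(nrow(cfg$thyroid_centers))) {
    labels <- label_disc(labels, xc, yc, cfg$thyroid_centers[k, ],
                         cfg$thyroid_radius, TISSUE_CODES[["thyroid"]])
  }
  labels <- label_disc(labels, xc, yc, cfg$tumor_center, cfg$tumor_radius,
                       TISSUE_CODES[["tumor"]])

  rois <- list(
    tumor = roi_spec("tumor", labels, xc, yc, cfg$tumor_center,
                     cfg$tumor_crop, TISSUE_CODES[["tumor"]]),
    cord = roi_spec("cord", labels, xc, yc, cfg$vertebra_center,
                    cfg$cord_crop, TISSUE_CODES[["spinal_cord"]])
  )
  offs <- rep(0 + 0i, length(TISSUE_CODES) - 1L)
  names(offs) <- setdiff(names(TISSUE_CODES), "background")
  structure(list(labels = labels, cell_size = h,
                 domain_size = cfg$domain_size, xc = xc, yc = yc,
                 config = cfg, tissue_table = cfg$tissue_table,
                 offsets = offs, T_tumor = 37, T_cord = 37,
                 rois = rois),
            class = "phantom")
}

#' ROI window specification
#'
#' A square pixel window of side `crop` centered on the pixel nearest the
#' structure center; errors if the window does not enclose every pixel
#' carrying the structure's label or does not fit inside the grid.
#'
#' @param name ROI name.
#' @param labels tissue raster.
#' @param xc,yc pixel-center coordinates.
#' @param center structure center in m.
#' @param crop window side in pixels.
#' @param code tissue code the window must enclose.
#' @return list of class `roi_spec` with `rows`, `cols` (pixel index
#'   ranges), `crop` and `name`.
#' @export
roi_spec <- function(name, labels, xc, yc, center, crop, code) {
  n <- nrow(labels)
  i0 <- which.min(abs(xc - center[1]))
  j0 <- which.min(abs(yc - center[2]))
  half_lo <- floor((crop - 1) / 2)
  rows <- (i0 - half_lo):(i0 - half_lo + crop - 1)
  cols <- (j0 - half_lo):(j0 - half_lo + crop - 1)
  if (min(rows) < 1 || max(rows) > n || min(cols) < 1 || max(cols) > n) {
    stop("ROI window for '", name, "' does not fit inside the grid")
  }
  idx <- which(labels == code, arr.ind = TRUE)
  if (nrow(idx) > 0 &&
      (min(idx[, 1]) < min(rows) || max(idx[, 1]) > max(rows) ||
       min(idx[, 2]) < min(cols) || max(idx[, 2]) > max(cols))) {
    stop("ROI window for '", name, "' does not enclose its structure")
  }
  structure(list(name = name, rows = rows, cols = cols, crop = crop),
            class = "roi_spec")
}

#' Randomize tissue electromagnetic properties
#'
#' Draws, independently for each tissue, Gaussian offsets for the real and
#' imaginary parts of the frequency-evaluated complex permittivity
#' (`sd` 0.1 by default), held constant across the frequency band and across
#' the baseline/heated measurement pair of one sample. Optionally truncates
#' the offsets to +/- `truncate_at` (rejection sampling).
#'
#' @param phantom a [build_neck_phantom()] result.
#' @param seed integer seed; draws are reproducible under it.
#' @param sd standard deviation of the offsets (default 0.1).
#' @param truncate_at optional bound; NULL (default) leaves the Gaussians
#'   untruncated.
#' @return the phantom with new per-tissue `offsets`.
#' @export
randomize_tissues <- function(phantom, seed, sd = 0.1, truncate_at = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  tissues <- names(phantom$offsets)
  draws <- with_local_seed(seed, {
    dre <- stats::rnorm(length(tissues), 0, sd)
    dim_ <- stats::rnorm(length(tissues), 0, sd)
    if (!is.null(truncate_at) && sd > 0) {
      for (v in c("dre", "dim_")) {
        x <- get(v)
        while (any(bad <- abs(x) > truncate_at)) {
          x[bad] <- stats::rnorm(sum(bad), 0, sd)
        }
        assign(v, x)
      }
    }
    list(dre = dre, dim_ = dim_)
  })
  # eps = eps' - j eps''; an increase of eps'' lowers the imaginary part
  offs <- complex(real = draws$dre, imaginary = -draws$dim_)
  names(offs) <- tissues
  phantom$offsets <- offs
  phantom
}

#' Impose treatment temperatures on the two ROIs
#'
#' Sets the tumor and spinal-cord temperatures; all other tissues stay at
#' 37 C. Permittivity maps computed afterwards reflect the
#' temperature-dependent Cole-Cole parameters of the two ROI tissues.
#'
#' @param phantom a phantom.
#' @param T_tumor tumor temperature in C, within [37, 46].
#' @param T_cord spinal-cord temperature in C, within [37, 40].
#' @return the phantom with temperatures set.
#' @export
set_roi_temperatures <- function(phantom, T_tumor, T_cord) {
  stopifnot(inherits(phantom, "phantom"))
  if (T_tumor < 37 || T_tumor > 46) stop("T_tumor outside [37, 46] C")
  if (T_cord < 37 || T_cord > 40) stop("T_cord outside [37, 40] C")
  phantom$T_tumor <- T_tumor
  phantom$T_cord <- T_cord
  phantom
}

#' Per-tissue complex permittivities of a phantom at one frequency
#'
#' @param phantom a phantom.
#' @param f frequency in Hz.
#' @return named complex vector over the phantom's tissues (randomization
#'   offsets and ROI temperatures applied).
#' @export
tissue_permittivities <- function(phantom, f) {
  tab <- phantom$tissue_table
  tissues <- names(phantom$offsets)
  miss <- setdiff(tissues, names(tab))
  if (length(miss) > 0) {
    stop("tissue(s) missing from the tissue table: ",
         paste(miss, collapse = ", "))
  }
  vals <- vapply(tissues, function(tn) {
    entry <- tab[[tn]]
    p <- entry$params
    if (tn == "tumor" && phantom$T_tumor != 37) {
      p <- params_at_temperature(p, entry$coeffs, phantom$T_tumor,
                                 window = c(37, 46))
    } else if (tn == "spinal_cord" && phantom$T_cord != 37) {
      p <- params_at_temperature(p, entry$coeffs, phantom$T_cord,
                                 window = c(37, 40))
    }
    cole_cole(p, f) + phantom$offsets[[tn]]
  }, complex(1))
  names(vals) <- tissues
  vals
}

#' Complex permittivity raster at one frequency
#'
#' Maps every pixel's tissue label to its complex permittivity (with the
#' imposed ROI temperatures and the per-sample randomization offsets);
#' background pixels get the matching-medium permittivity. Pure function of
#' the phantom state.
#'
#' @param phantom a phantom.
#' @param f frequency in Hz.
#' @return n x n complex matrix.
#' @export
permittivity_map <- function(phantom, f) {
  cfg <- phantom$config
  eps_b <- background_permittivity(cfg$background_eps, cfg$background_sigma, f)
  vals <- tissue_permittivities(phantom, f)
  lut <- c(eps_b, vals[names(TISSUE_CODES)[-1]])  # index = code + 1
  m <- matrix(lut[phantom$labels + 1L], nrow(phantom$labels),
              ncol(phantom$labels))
  m
}

#' Contrast raster at one frequency
#'
#' @inheritParams permittivity_map
#' @return n x n complex matrix, `eps/eps_b - 1`; exactly zero outside the
#'   neck cross-section.
#' @export
contrast_map <- function(phantom, f) {
  cfg <- phantom$config
  eps_b <- background_permittivity(cfg$background_eps, cfg$background_sigma, f)
  contrast(permittivity_map(phantom, f), eps_b)
}

#' Export a phantom raster with sidecar metadata
#'
#' Writes the tissue-label raster as CSV plus a JSON sidecar holding the
#' cell size, domain size, imposed temperatures and tissue codes.
#'
#' @param phantom a phantom.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
export_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab_path <- file.path(dir, "labels.csv")
  meta_path <- file.path(dir, "phantom.json")
  utils::write.table(phantom$labels, lab_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- sprintf(paste0(
    '{"cell_size": %.10g, "domain_size": %.10g, "n": %d, ',
    '"T_tumor": %g, "T_cord": %g, "tissue_codes": {%s}}'),
    phantom$cell_size, phantom$domain_size, nrow(phantom$labels),
    phantom$T_tumor, phantom$T_cord,
    paste(sprintf('"%s": %d', names(TISSUE_CODES), TISSUE_CODES),
          collapse = ", "))
  writeLines(meta, meta_path)
  invisible(c(lab_path, meta_path))
}

#' @export
print.phantom <- function(x, ...) {
  n <- nrow(x$labels)
  counts <- table(factor(x$labels, levels = TISSUE_CODES,
                         labels = names(TISSUE_CODES)))
  cat(sprintf("Neck phantom: %dx%d grid, %.3g mm cells, T_tumor=%g C, T_cord=%g C\n",
              n, n, x$cell_size * 1e3, x$T_tumor, x$T_cord))
  print(counts)
  invisible(x)
}
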