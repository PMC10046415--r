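test_that("phantom rasterization matches the configured geometry", {
  cfg <- phantom_config()       # 128 x 128, 24 cm
  ph <- build_neck_phantom(cfg)
  # tumor disc area close to pi r^2; center-sampling rasterization of a
  # ~5-cell-diameter disc deviates by up to a few perimeter cells
  area <- sum(ph$labels == 7L) * ph$cell_size^2
  expect_lt(abs(area / (pi * 0.0045^2) - 1), 0.2)
  # deterministic
  expect_identical(ph$labels, build_neck_phantom(cfg)$labels)
  # ROI crops: 5x5 tumor, 6x6 cord, windows enclose their structures
  expect_identical(dim(ph$labels), c(128L, 128L))
  expect_equal(length(ph$rois$tumor$rows), 5L)
  expect_equal(length(ph$rois$cord$cols), 6L)
  tum <- which(ph$labels == 7L, arr.ind = TRUE)
  expect_true(all(tum[, 1] %in% ph$rois$tumor$rows))
  expect_true(all(tum[, 2] %in% ph$rois$tumor$cols))
  # tumor and cord ROIs disjoint
  expect_length(intersect(
    paste(rep(ph$rois$tumor$rows, 5), rep(ph$rois$tumor$cols, each = 5)),
    paste(rep(ph$rois$cord$rows, 6), rep(ph$rois$cord$cols, each = 6))), 0)
  # degenerate tumor rejected
  expect_error(build_neck_phantom(phantom_config(tumor_radius = 0)),
               "tumor radius")
  # every labelled tissue exists in the table
  tab <- load_tissue_table()
  present <- setdiff(unique(as.vector(ph$labels)), 0L)
  codes <- c(skin = 1L, fat = 2L, muscle = 3L, bone = 4L,
             spinal_cord = 5L, thyroid = 6L, tumor = 7L)
  expect_true(all(names(codes)[codes %in% present] %in% names(tab)))
})

test_that("contrast vanishes identically outside the neck cross-section", {
  ph <- small_phantom()
  chi <- contrast_map(ph, 1.35e9)
  expect_true(all(chi[ph$labels == 0L] == 0))
  expect_true(all(chi[ph$labels != 0L] != 0))
})

test_that("tissue randomization has the configured spread and is reproducible", {
  ph <- small_phantom()
  # zero sd leaves the phantom unchanged
  expect_equal(randomize_tissues(ph, 1, sd = 0)$offsets, ph$offsets)
  # sd of 1e4 draws of one tissue's real offset within [0.09, 0.11]
  draws <- vapply(seq_len(1e4), function(i) {
    Re(randomize_tissues(ph, i, sd = 0.1)$offsets[["muscle"]])
  }, numeric(1))
  expect_gt(sd(draws), 0.09)
  expect_lt(sd(draws), 0.11)
  expect_lt(abs(mean(draws)), 0.005)
  # seed contract
  expect_identical(randomize_tissues(ph, 5)$offsets,
                   randomize_tissues(ph, 5)$offsets)
  expect_false(identical(randomize_tissues(ph, 5)$offsets,
                         randomize_tissues(ph, 6)$offsets))
  # labels never change
  expect_identical(randomize_tissues(ph, 5)$labels, ph$labels)
  # truncation bounds the offsets
  tr <- randomize_tissues(ph, 7, sd = 0.1, truncate_at = 0.2)$offsets
  expect_true(all(abs(Re(tr)) <= 0.2 & abs(Im(tr)) <= 0.2))
})

test_that("ROI temperatures only perturb their own tissues", {
  ph <- small_phantom()
  f <- 1.35e9
  base_map <- permittivity_map(ph, f)
  # reference temperature: identical maps
  expect_equal(permittivity_map(set_roi_temperatures(ph, 37, 37), f),
               base_map)
  # heating the tumor only changes tumor-labelled pixels
  hot <- permittivity_map(set_roi_temperatures(ph, 42, 37), f)
  changed <- which(hot != base_map)
  expect_true(length(changed) > 0)
  expect_true(all(ph$labels[changed] == 7L))
  # both ROIs heated: change magnitude agrees with the dielectric model
  both <- set_roi_temperatures(ph, 46, 40)
  hot2 <- permittivity_map(both, f)
  tab <- ph$tissue_table
  expected_tumor <- cole_cole(
    params_at_temperature(tab$tumor$params, tab$tumor$coeffs, 46), f)
  ix <- which(ph$labels == 7L)[1]
  expect_equal(hot2[ix], expected_tumor, tolerance = 1e-12)
  expected_cord <- cole_cole(
    params_at_temperature(tab$spinal_cord$params, tab$spinal_cord$coeffs, 40,
                          window = c(37, 40)), f)
  ic <- which(ph$labels == 5L)[1]
  expect_equal(hot2[ic], expected_cord, tolerance = 1e-12)
  # out-of-range temperatures rejected
  expect_error(set_roi_temperatures(ph, 47, 37), "T_tumor")
  expect_error(set_roi_temperatures(ph, 42, 41), "T_cord")
})

test_that("permittivity maps are pure functions and dispersive across frequency", {
  ph <- small_phantom()
  m1 <- permittivity_map(ph, 0.9e9)
  m2 <- permittivity_map(ph, 1.8e9)
  expect_identical(m1, permittivity_map(ph, 0.9e9))
  # dispersive tissues differ between frequencies
  expect_false(any(m1[ph$labels == 3L] == m2[ph$labels == 3L]))
  # background pixels carry the background permittivity exactly
  eb <- background_permittivity(ph$config$background_eps,
                                ph$config$background_sigma, 0.9e9)
  expect_true(all(m1[ph$labels == 0L] == eb))
})
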