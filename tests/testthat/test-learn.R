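test_that("temperature-class boundaries are exact", {
  # tumor: three classes split at 3 and 7 C
  expect_identical(assign_tumor_label(c(0, 2.999, 3, 4, 6.999, 7, 9)),
                   c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
  # cord: binary split at 2 C; 1 C is still unheated
  expect_identical(assign_cord_label(c(0, 1, 1.999, 2, 3)),
                   c(0L, 0L, 0L, 1L, 1L))
  expect_error(assign_tumor_label(-0.1), "non-negative")
  expect_error(assign_cord_label(-1), "non-negative")
})

test_that("an unheated noiseless run yields null images and labels", {
  ph <- small_phantom()
  ds <- suppressWarnings(
    generate_dataset(ph, antenna_layout(), frequency_set(3L),
                     n_tumor = 4, n_cord = 4, seed = 3, snr_db = Inf,
                     tumor_temps = 37, cord_temps = 37))
  expect_true(all(abs(ds$tumor$images) < 1e-10))
  expect_true(all(abs(ds$cord$images) < 1e-10))
  expect_true(all(ds$tumor$labels == 0L))
  expect_true(all(ds$cord$labels == 0L))
})

test_that("dataset generation is reproducible and draws from the configured grids", {
  ph <- small_phantom()
  lay <- antenna_layout()
  fr <- frequency_set(3L)
  d1 <- suppressWarnings(
    generate_dataset(ph, lay, fr, n_tumor = 6, n_cord = 5, seed = 12))
  d2 <- suppressWarnings(
    generate_dataset(ph, lay, fr, n_tumor = 6, n_cord = 5, seed = 12))
  expect_identical(d1$tumor$images, d2$tumor$images)
  expect_identical(d1$cord$labels, d2$cord$labels)
  d3 <- suppressWarnings(
    generate_dataset(ph, lay, fr, n_tumor = 6, n_cord = 5, seed = 13))
  expect_false(identical(d1$tumor$images, d3$tumor$images))
  # shapes and label consistency with the temperature draws
  expect_identical(dim(d1$tumor$images), c(6L, 5L, 5L, 2L))
  expect_identical(dim(d1$cord$images), c(5L, 6L, 6L, 2L))
  expect_true(all(d1$tumor$delta_T %in% 0:9))
  expect_true(all(d1$cord$delta_T %in% 0:3))
  expect_identical(d1$tumor$labels, assign_tumor_label(d1$tumor$delta_T))
  expect_identical(d1$cord$labels, assign_cord_label(d1$cord$delta_T))
})

test_that("uniform temperature draws hit the 3:4:3 tumor class proportions", {
  # label proportions implied by uniform draws over the 1-degree grid
  dt <- rep(0:9, times = 200)
  tab <- tabulate(assign_tumor_label(dt) + 1L, 3)
  expect_equal(tab / length(dt), c(0.3, 0.4, 0.3))
})

test_that("K-fold assignment partitions the dataset", {
  ds <- structure(list(images = array(rnorm(40 * 5 * 5 * 2),
                                      c(40, 5, 5, 2)),
                       labels = rep(0:1, 20), delta_T = rep(c(0, 9), 20),
                       n = 40L, roi = "toy", n_classes = 2L),
                  class = "roi_dataset")
  cfg <- train_config(folds = 5L, max_epochs = 2L, seed = 4)
  kf <- kfold_train(ds, cfg)
  idx <- sort(unlist(lapply(kf, `[[`, "val_idx")))
  expect_identical(idx, 1:40)
  expect_true(all(vapply(kf, function(f) length(f$val_idx), integer(1)) == 8L))
  # non-divisible fold counts are rejected with the valid alternatives
  expect_error(kfold_train(ds, train_config(folds = 3L)), "valid fold")
  # deterministic under the seed
  kf2 <- kfold_train(ds, cfg)
  expect_identical(lapply(kf, `[[`, "val_idx"), lapply(kf2, `[[`, "val_idx"))
  expect_identical(kf[[1]]$model$weights, kf2[[1]]$model$weights)
})

test_that("training separates a trivially separable dataset", {
  set.seed(21)
  n <- 60L
  lab <- rep(0:1, each = n / 2)
  imgs <- array(rnorm(n * 5 * 5 * 2, sd = 0.05), c(n, 5, 5, 2))
  imgs[lab == 1L, , , 1] <- imgs[lab == 1L, , , 1] + 1
  ds <- structure(list(images = imgs, labels = lab,
                       delta_T = 9 * lab, n = n, roi = "toy",
                       n_classes = 2L), class = "roi_dataset")
  cfg <- train_config(folds = 10L, max_epochs = 150L,
                      learning_rate = 1e-3, seed = 5)
  kf <- suppressWarnings(kfold_train(ds, cfg))
  acc <- mean(unlist(lapply(kf, function(f) f$val_pred == f$val_truth)))
  expect_gt(acc, 0.99)
  # optimization sanity: best-epoch training loss never above the initial one
  for (f in kf) expect_lte(f$train_loss[f$best_epoch], f$train_loss[1])
})
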