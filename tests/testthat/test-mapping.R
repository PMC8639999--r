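small_grid_cfg <- function() {
  generator_config(grid = list(nrow = 12L, ncol = 12L, lon_min = 0,
                               lon_max = 6, lat_min = 0, lat_max = 6,
                               correlation_length_deg = 2))
}

fit_small_forest <- function(seed = 2) {
  set.seed(seed)
  n <- 200
  rng <- globeseed:::predictor_ranges()
  X <- data.frame(pH = runif(n, rng$pH[1], rng$pH[2]),
                  AP = runif(n, rng$AP[1], rng$AP[2]),
                  npp = runif(n, rng$npp[1], rng$npp[2]))
  y <- 2 * X$pH + 0.001 * X$AP + rnorm(n, 0, 0.5)
  list(fit = fit_forest(X, y, seed = seed), X = X)
}

test_that("grid prediction equals flatten-predict-reshape bit for bit", {
  g <- generate_grid(small_grid_cfg(), seed = 6)
  f <- fit_small_forest()
  ras <- predict_grid(f$fit, g)
  tab <- data.frame(pH = as.vector(g$layers$pH),
                    AP = as.vector(g$layers$AP),
                    npp = as.vector(g$layers$npp))
  want <- matrix(predict(f$fit$forest, tab), nrow = length(g$lat))
  expect_identical(ras$values, want)
})

test_that("a grid of identical predictor vectors yields a constant raster
           equal to the tabular prediction", {
  f <- fit_small_forest()
  v <- data.frame(pH = 6.5, AP = 800, npp = 900)
  layers <- lapply(v, function(x) matrix(x, 4, 5))
  g <- predictor_grid(layers, lon = 1:5, lat = 4:1, res_arcmin = 60)
  ras <- predict_grid(f$fit, g)
  expect_equal(unique(as.vector(ras$values)),
               unname(predict(f$fit$forest, v)))
})

test_that("nodata propagates and missing layers are refused by name", {
  f <- fit_small_forest()
  g <- generate_grid(small_grid_cfg(), seed = 6)
  g$layers$pH[3, 4] <- NA
  ras <- predict_grid(f$fit, g)
  expect_true(is.na(ras$values[3, 4]))
  expect_equal(sum(is.na(ras$values)), 1)

  g$layers$AP <- NULL
  expect_error(predict_grid(f$fit, g), "AP")
})

test_that("log10 display transform follows the domain rules and inverts", {
  ras <- list(values = matrix(c(1000, 0, -2, 10), 2, 2), lon = 1:2,
              lat = 2:1, res_arcmin = c(60, 60), log10 = FALSE,
              model_seed = 1)
  class(ras) <- "prediction_raster"
  lt <- log10_display(ras)
  expect_equal(lt$values[1, 1], 3)       # 1000 -> 3
  expect_true(is.na(lt$values[2, 1]))    # 0 -> nodata
  expect_true(is.na(lt$values[1, 2]))    # negative -> nodata
  expect_true(lt$log10)
  # round trip for positive cells
  pos <- ras$values > 0
  expect_equal(10^lt$values[pos], ras$values[pos], tolerance = 1e-12)
})

test_that("ASCII raster round trip preserves values, mask and
           georeferencing", {
  set.seed(9)
  vals <- matrix(rnorm(30), 5, 6)
  vals[2, 3] <- NA
  ras <- list(values = vals, lon = seq(0.25, 2.75, by = 0.5),
              lat = seq(2.25, 0.25, by = -0.5), res_arcmin = c(30, 30),
              log10 = TRUE, model_seed = 77)
  class(ras) <- "prediction_raster"
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(ras, path)
  back <- read_raster(path)
  expect_equal(back$values, ras$values, tolerance = 1e-12)
  expect_equal(sum(is.na(back$values)), 1)    # nodata count preserved
  expect_equal(back$lon, ras$lon)
  expect_equal(back$lat, ras$lat)
  expect_true(back$log10)
  expect_equal(back$model_seed, 77)
})

test_that("predictor grid round trip and misalignment refusal", {
  cfg <- small_grid_cfg()
  g <- generate_grid(cfg, seed = 10)
  dir <- withr::local_tempdir()
  paths <- write_grid(g, dir)
  sub <- paths[c("pH", "AP", "abs.latit")]
  back <- read_grid(sub)
  for (nm in names(sub)) {
    expect_equal(back$layers[[nm]], g$layers[[nm]], tolerance = 1e-12)
  }
  expect_equal(back$lon, g$lon, tolerance = 1e-12)

  # a layer with a different geometry is refused with a per-layer report
  other <- generate_grid(generator_config(
    grid = list(nrow = 6L, ncol = 6L, lon_min = 0, lon_max = 3,
                lat_min = 0, lat_max = 3, correlation_length_deg = 1)),
    seed = 1)
  p2 <- write_grid(other, file.path(dir, "other"))
  expect_error(read_grid(c(pH = unname(sub["pH"]),
                           AP = unname(p2["AP"]))), "misaligned")
})

test_that("zonal mean density tracks a generative latitudinal gradient", {
  # a world where density increases with absolute latitude
  cfg <- generator_config(
    n_diversity = 0L, n_density = 600L, sigma = 0.1,
    effects = list(diversity = list(),
                   density = list(`abs.latit` = list(type = "linear",
                                                     coef = 0.02))),
    grid = list(nrow = 30L, ncol = 20L, lon_min = 0, lon_max = 10,
                lat_min = -55, lat_max = 55, correlation_length_deg = 3))
  ds <- generate_dataset(cfg, seed = 14)
  std <- run_standardization(ds$records,
                             options = list(models = truth_models(ds$truth)))
  tab <- merge(std$records[, c("record_id", "value")], ds$predictors,
               by = "record_id")
  f <- fit_forest(tab[, predictor_names()], tab$value, seed = 4)
  g <- generate_grid(cfg, seed = 15)
  ras <- predict_grid(f, g)
  zm <- zonal_means(ras)
  rho <- cor(abs(zm$latitude), zm$mean_value, method = "spearman")
  expect_gte(rho, 0.9)
})
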