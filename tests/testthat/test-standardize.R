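test_that("season assignment is hemisphere-aware and month-driven", {
  df <- make_records(4)
  df$sampling_month <- c(1, 1, NA, NA)
  df$latitude <- c(40, -40, 40, 40)
  df$season <- c(NA, NA, "autumn", NA)
  out <- assign_season(df)
  expect_equal(out$season, c("winter", "summer", "autumn", NA))
})

test_that("season ratios are winter-mean over season-mean, with the
           (sub)tropical exemption", {
  # winter mean 20, summer mean 10 -> r_summer = 2; a summer 8 becomes 16
  df <- rbind(make_records(4, value = 20, season = "winter", month = NA),
              make_records(4, value = 10, season = "summer", month = NA))
  df$record_id <- sprintf("r%03d", 1:8)
  ratios <- fit_season_ratios(df)
  expect_equal(ratios$diversity$ratio[ratios$diversity$season == "summer"], 2)
  expect_equal(ratios$diversity$ratio[ratios$diversity$season == "winter"], 1)

  one <- make_records(1, value = 8, season = "summer", month = NA)
  std <- apply_season_standardization(one, ratios)
  expect_equal(std$value, 16)
  expect_true(std$flag_season)

  # winter record unchanged
  w <- make_records(1, value = 12, season = "winter", month = NA)
  expect_equal(apply_season_standardization(w, ratios)$value, 12)

  # tropical-biome record exempt
  tr <- make_records(1, value = 7, season = "summer", month = NA,
                     biome = "TSMF", lat = 5)
  std_tr <- apply_season_standardization(tr, ratios)
  expect_equal(std_tr$value, 7)
  expect_true(std_tr$flag_season)

  # all four season means equal -> every ratio 1
  eq <- do.call(rbind, lapply(c("spring", "summer", "autumn", "winter"),
                              function(s) make_records(3, value = 20,
                                                       season = s,
                                                       month = NA)))
  eq$record_id <- sprintf("e%03d", seq_len(nrow(eq)))
  r_eq <- fit_season_ratios(eq)
  expect_equal(r_eq$diversity$ratio, rep(1, 4))

  # a purely tropical dataset has no eligible records
  trop <- make_records(5, biome = "MAN", season = "winter", month = NA,
                       lat = 3)
  expect_error(fit_season_ratios(trop), "eligible")
})

test_that("species-area fit recovers an exact power law and matches the
           normal-equations oracle under noise", {
  # noise-free S = 5 * A^0.3
  areas <- rep(c(0.005, 0.01, 0.02, 0.04), each = 5)
  df <- make_records(20, value = 5 * areas^0.3, area = areas)
  m <- suppressWarnings(fit_species_area(df, cap = FALSE))  # exact fit
  expect_equal(m$C, 5, tolerance = 1e-10)
  expect_equal(m$Z, 0.3, tolerance = 1e-10)
  expect_false(m$insufficient_data)

  # seeded lognormal noise: coefficients equal the closed-form OLS oracle
  set.seed(33)
  areas <- sample(c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.1), 200,
                  replace = TRUE)
  vals <- 5 * areas^0.3 * exp(rnorm(200, 0, 0.2))
  dfn <- make_records(200, value = vals, area = areas)
  mn <- fit_species_area(dfn, cap = FALSE)
  beta <- oracle_ols(matrix(log(areas), ncol = 1), log(vals))
  expect_equal(mn$C, exp(beta[1]), tolerance = 1e-10)
  expect_equal(mn$Z, beta[2], tolerance = 1e-10)

  # zero values are excluded from the log fit and counted
  dfz <- dfn
  dfz$value[1] <- 0
  mz <- fit_species_area(dfz, cap = FALSE)
  expect_equal(mz$n_excluded_zero, 1)
  expect_equal(mz$n, 199)

  # a single distinct area cannot identify Z
  df1 <- make_records(20, value = 5, area = 0.01)
  expect_true(fit_species_area(df1)$insufficient_data)
})

test_that("area standardization follows value * (0.01/A)^Z", {
  models <- suppressWarnings(fit_area_models(make_records(
    20, value = 5 * rep(c(0.005, 0.01, 0.02, 0.04), 5)^0.3,
    area = rep(c(0.005, 0.01, 0.02, 0.04), 5)), cap = FALSE))
  # identity at the target area
  at_target <- make_records(1, value = 9, area = 0.01)
  expect_equal(standardize_area(at_target, models)$value, 9)

  # value 12 at A = 0.04 with Z = 0.3 -> 12 * 0.25^0.3
  m03 <- models
  m03$TBMF$Z <- 0.3
  rec <- make_records(1, value = 12, area = 0.04)
  expect_equal(standardize_area(rec, m03)$value, 12 * 0.25^0.3,
               tolerance = 1e-12)

  # Z = 0: unchanged for any area
  m0 <- models
  m0$TBMF$Z <- 0
  rec_any <- make_records(1, value = 12, area = 0.1)
  expect_equal(standardize_area(rec_any, m0)$value, 12)

  # monotonicity for Z > 0: shrink from above 0.01, grow from below
  big <- standardize_area(make_records(1, value = 10, area = 0.04), m03)
  small <- standardize_area(make_records(1, value = 10, area = 0.005), m03)
  expect_lt(big$value, 10)
  expect_gt(small$value, 10)
})

test_that("depth model fitting is exact on noise-free data, matches the OLS
           oracle under noise, and degrades gracefully", {
  slices <- list(c(0, 5), c(0, 10), c(5, 10), c(2, 5))
  n <- 40
  idx <- rep(1:4, each = 10)
  u <- vapply(slices[idx], `[`, numeric(1), 1)
  l <- vapply(slices[idx], `[`, numeric(1), 2)
  vals <- 10^(1 + 0.02 * u + 0.03 * l)
  df <- make_records(n, value = vals, upper = u, lower = l)
  m <- suppressWarnings(fit_depth_model(df, measure = "diversity"))
  expect_equal(c(m$b0, m$b1, m$b2), c(1, 0.02, 0.03), tolerance = 1e-10)

  set.seed(44)
  valsn <- vals * exp(rnorm(n, 0, 0.2))
  dfn <- make_records(n, value = valsn, upper = u, lower = l)
  mn <- fit_depth_model(dfn, measure = "diversity")
  beta <- oracle_ols(cbind(u, l), log10(valsn))
  expect_equal(c(mn$b0, mn$b1, mn$b2), beta, tolerance = 1e-10)

  # collinear boundaries (always 5 cm thick) -> reduced-rank lower-only fit
  dfc <- make_records(20, value = 10^(1 + 0.03 * c(rep(5, 10), rep(10, 10))),
                      upper = c(rep(0, 10), rep(5, 10)),
                      lower = c(rep(5, 10), rep(10, 10)))
  mc <- suppressWarnings(fit_depth_model(dfc, measure = "diversity"))
  expect_true(mc$reduced_rank)
  expect_equal(mc$b1, 0)
  expect_equal(mc$b2, 0.03, tolerance = 1e-10)

  # a single distinct slice is insufficient
  m1 <- fit_depth_model(make_records(20), measure = "diversity")
  expect_true(m1$insufficient_data)
})

test_that("depth standardization follows value * 10^(b1(0-u) + b2(5-l))", {
  mods <- list(`TBMF.diversity` = structure(
    list(biome = "TBMF", measure = "diversity", b0 = 1, b1 = 0, b2 = 0.03,
         n = 10L, r_squared = 1, reduced_rank = FALSE,
         insufficient_data = FALSE), class = "biome_depth_model"))
  class(mods) <- "depth_models"

  # slice (0,10) with b1 = 0, b2 = 0.03: 100 * 10^(0.03 * -5)
  rec <- make_records(1, value = 100, upper = 0, lower = 10)
  expect_equal(standardize_depth(rec, mods)$value, 100 * 10^(-0.15),
               tolerance = 1e-12)

  # identity at the target slice
  at <- make_records(1, value = 42, upper = 0, lower = 5)
  expect_equal(standardize_depth(at, mods)$value, 42)

  # b1 = b2 = 0: unchanged
  mods0 <- mods
  mods0$TBMF.diversity$b2 <- 0
  any_slice <- make_records(1, value = 42, upper = 2, lower = 20)
  expect_equal(standardize_depth(any_slice, mods0)$value, 42)
})

test_that("density unit conversion divides counts by area and is idempotent", {
  rec <- make_records(1, measure = "density", value = 250, area = 0.25)
  out <- density_to_per_m2(rec)
  expect_equal(out$value, 1000)
  expect_true(out$flag_density_unit)
  # applying again changes nothing
  expect_equal(density_to_per_m2(out)$value, 1000)
  # per-m2 sources are encoded with area 1: conversion is the identity
  per_m2 <- make_records(1, measure = "density", value = 800, area = 1)
  expect_equal(density_to_per_m2(per_m2)$value, 800)
})

test_that("the full pipeline is the identity on already-standard records
           and conserves record counts", {
  # winter, 0.01 m2, 0-5 cm, density encoded per m2 (area 1)
  std_div <- make_records(30, value = 10 + seq_len(30) / 10,
                          season = "winter", month = NA)
  std_den <- make_records(30, measure = "density", value = 1000, area = 1,
                          season = "winter", month = NA)
  std_den$record_id <- sprintf("d%03d", 1:30)
  recs <- rbind(std_div, std_den)
  res <- run_standardization(recs)
  expect_equal(res$records$value, recs$value, tolerance = 1e-12)
  expect_equal(nrow(res$records), nrow(recs))
  expect_equal(res$report$n_records, 60)
  # no record dropped; step bookkeeping covers everything
  expect_true(all(vapply(res$report$steps,
                         function(s) s$n_applied + s$n_unflagged <= 60,
                         logical(1))))
})

test_that("standardization with the generator's true parameters inverts
           the noise-free distortions elementwise", {
  cfg <- generator_config(n_diversity = 120L, n_density = 120L, sigma = 0)
  ds <- generate_dataset(cfg, seed = 5)
  res <- run_standardization(ds$records,
                             options = list(models = truth_models(ds$truth)))
  m <- merge(data.frame(record_id = res$records$record_id,
                        std = res$records$value, stringsAsFactors = FALSE),
             ds$truth$records[, c("record_id", "latent")], by = "record_id")
  expect_lt(max(abs(m$std - m$latent) / m$latent), 1e-6)
})
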