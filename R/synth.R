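#' Configuration for the synthetic seed bank data generator
#'
#' Builds the full generator configuration with defaults chosen to emulate
#' the statistical structure of a global seed bank survey compilation: two
#' response types, per-biome stratification, mixed sampling seasons, quadrat
#' areas and depth slices, hemispheric imbalance, and known environmental
#' effect shapes (e.g. a humped pH response of diversity, a latitudinal
#' trend). The generated world is multiplicative: an environment-driven
#' latent value at the standard conventions (winter season, 0.01 m2 quadrat,
#' 0-5 cm slice, seeds per m2) is distorted by season, area and depth
#' factors and lognormal noise, so the ratio-based standardization steps
#' invert the distortions exactly when the noise is switched off.
#'
#' @param ... Named overrides of any default (see the returned list for the
#'   full set of fields). Effect shapes are lists like
#'   `list(type = "humped", center = 6.5, width = 1.2, amp = 0.6)`,
#'   `list(type = "linear", coef = 2.5e-4)` (slope per raw predictor unit) or
#'   `list(type = "threshold", cut = 800, amp = -0.4)`.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(...) {
  bt <- biome_table()
  trop <- bt$code[bt$is_subtropical_or_tropical]
  cfg <- list(
    n_diversity = 400L,
    n_density = 400L,
    fraction_tropical = 0.3,
    fraction_northern = 0.8,
    biome_weights = NULL,  # NULL: uniform within the tropical/other groups
    season_weights = c(spring = 0.3, summer = 0.3, autumn = 0.2,
                       winter = 0.2),
    fraction_month_missing = 0.3,
    fraction_season_missing = 0,
    area_levels = c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.1),
    area_weights = c(0.10, 0.15, 0.40, 0.15, 0.10, 0.10),
    depth_slices = list(c(0, 5), c(0, 10), c(5, 10), c(0, 2), c(2, 5)),
    depth_weights = c(0.40, 0.20, 0.10, 0.15, 0.15),
    fraction_density_as_count = 0.7,
    # true standardization parameters
    season_mult = c(spring = 0.8, summer = 0.5, autumn = 0.7, winter = 1),
    Z = stats::setNames(rep(0.25, nrow(bt)), bt$code),
    depth_b1 = -0.04,  # log10 change per cm of upper boundary
    depth_b2 = 0.03,   # log10 change per cm of lower boundary
    # true response model (latent at standard conventions)
    diversity_baseline = 12,    # species per 0.01 m2
    density_baseline = 2000,    # seeds per m2
    biome_mult = stats::setNames(rep(1, nrow(bt)), bt$code),
    effects = list(
      diversity = list(
        `abs.latit` = list(type = "humped", center = 27, width = 25,
                           amp = 0.5),
        pH = list(type = "humped", center = 6.5, width = 1.2, amp = 0.6),
        AP = list(type = "linear", coef = 2.5e-4),
        CEC = list(type = "linear", coef = 0.01)
      ),
      density = list(
        npp = list(type = "humped", center = 1000, width = 500, amp = 0.7),
        PDQ = list(type = "humped", center = 300, width = 150, amp = 0.5),
        BULK = list(type = "linear", coef = -4e-4),
        TWM = list(type = "humped", center = 34, width = 8, amp = 0.4)
      )
    ),
    sigma = 0.3,  # lognormal noise sd on the log scale
    # grid generation
    grid = list(nrow = 40L, ncol = 80L, lon_min = -20, lon_max = 20,
                lat_min = -10, lat_max = 10, correlation_length_deg = 3)
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) stop("unknown config field(s): ",
                              paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
    # effect lists are replaced wholly, never merged with the defaults
    if ("effects" %in% names(over)) cfg$effects <- over$effects
  }
  stopifnot(abs(sum(cfg$season_weights) - 1) < 1e-8,
            abs(sum(cfg$area_weights) - 1) < 1e-8,
            abs(sum(cfg$depth_weights) - 1) < 1e-8,
            cfg$sigma >= 0)
  for (m in names(cfg$effects)) {
    for (p in names(cfg$effects[[m]])) {
      ef <- cfg$effects[[m]][[p]]
      if (ef$type == "humped") {
        rng <- predictor_ranges()[[p]]
        stopifnot(ef$center >= rng[1], ef$center <= rng[2])
      }
    }
  }
  class(cfg) <- "generator_config"
  cfg
}

eval_effect <- function(ef, x) {
  switch(ef$type,
         linear = ef$coef * x,
         humped = ef$amp * exp(-((x - ef$center)^2) / (2 * ef$width^2)),
         threshold = ef$amp * as.numeric(x > ef$cut),
         stop("unknown effect type: ", ef$type))
}

#' Evaluate the true (latent) response model
#'
#' Deterministically evaluates the configured effect shapes for each row of
#' a complete predictor table, returning the latent diversity (species per
#' 0.01 m2) and density (seeds per m2) at the standard conventions, before
#' any biome multiplier, sampling distortion or noise.
#'
#' @param predictors Data frame with the 31 predictor columns (a
#'   `record_id` column is permitted and ignored).
#' @param config A `generator_config`.
#' @return Data frame with columns `diversity` and `density`.
#' @export
true_response <- function(predictors, config) {
  out <- data.frame(diversity = numeric(nrow(predictors)),
                    density = numeric(nrow(predictors)))
  for (m in c("diversity", "density")) {
    base <- if (m == "diversity") config$diversity_baseline else
      config$density_baseline
    logsum <- rep(0, nrow(predictors))
    for (p in names(config$effects[[m]])) {
      if (is.null(predictors[[p]]))
        stop("predictor '", p, "' missing from table")
      if (any(is.na(predictors[[p]])))
        stop("predictor '", p, "' contains missing values")
      logsum <- logsum + eval_effect(config$effects[[m]][[p]],
                                     predictors[[p]])
    }
    out[[m]] <- base * exp(logsum)
  }
  out
}

resolve_biome_weights <- function(cfg) {
  bt <- biome_table()
  if (!is.null(cfg$biome_weights)) {
    w <- cfg$biome_weights[bt$code]
    w[is.na(w)] <- 0
    names(w) <- bt$code
    return(w / sum(w))
  }
  w <- numeric(nrow(bt))
  trop <- bt$is_subtropical_or_tropical
  w[trop] <- cfg$fraction_tropical / sum(trop)
  w[!trop] <- (1 - cfg$fraction_tropical) / sum(!trop)
  stats::setNames(w, bt$code)
}

season_months <- function(season, northern) {
  north <- list(winter = c(12, 1, 2), spring = 3:5, summer = 6:8,
                autumn = 9:11)
  m <- north[[season]]
  if (!northern) m <- ((m + 5) %% 12) + 1
  m
}

#' Generate a synthetic seed bank dataset with ground truth
#'
#' Draws records and their 31-predictor vectors from the configured
#' mixtures, computes latent responses from the true effect shapes, applies
#' the configured season / area / depth / unit distortions and lognormal
#' noise, and returns everything together with a ground-truth ledger
#' recording every latent value and true parameter so downstream recovery
#' can be verified.
#'
#' @param config A `generator_config`.
#' @param seed Integer random seed; the output is fully reproducible given
#'   `(config, seed)`.
#' @return A list of class `"synthetic_dataset"`:
#'   `records` (a `seedbank_records` data frame), `predictors` (data frame
#'   keyed by `record_id` with the 31 predictor columns), and `truth` — a
#'   list with `params` (all true parameters), `records` (per-record data
#'   frame of latent value and each distortion factor applied), `tallies`
#'   (per-biome per-measure counts), `informative` (names of predictors
#'   with configured effects, per measure), and `warnings`.
#' @export
generate_dataset <- function(config, seed) {
  set.seed(seed)
  cfg <- config
  bt <- biome_table()
  trop_codes <- tropical_biome_codes()
  bw <- resolve_biome_weights(cfg)
  warnings <- character(0)
  if (length(unique(cfg$area_levels)) < 2)
    warnings <- c(warnings,
                  "single sampling area configured: species-area fit downstream will be degenerate")

  n <- cfg$n_diversity + cfg$n_density
  measure <- c(rep("diversity", cfg$n_diversity),
               rep("density", cfg$n_density))
  biome <- sample(names(bw), n, replace = TRUE, prob = bw)
  is_trop <- biome %in% trop_codes
  northern <- stats::runif(n) < cfg$fraction_northern
  abslat <- ifelse(is_trop, stats::runif(n, 0, 23.5),
                   stats::runif(n, 23.5, 70))
  latitude <- ifelse(northern, abslat, -abslat)
  longitude <- stats::runif(n, -180, 180)

  # predictor table: abs.latit from the coordinate, the rest iid uniform
  rng <- predictor_ranges()
  predictors <- data.frame(record_id = sprintf("rec%05d", seq_len(n)))
  for (p in predictor_names()) {
    predictors[[p]] <- if (p == "abs.latit") abslat else
      stats::runif(n, rng[[p]][1], rng[[p]][2])
  }

  latent <- true_response(predictors, cfg)
  lat_div <- latent$diversity * cfg$biome_mult[biome]
  lat_den <- latent$density * cfg$biome_mult[biome]
  latent_value <- ifelse(measure == "diversity", lat_div, lat_den)

  season <- sample(names(cfg$season_weights), n, replace = TRUE,
                   prob = cfg$season_weights)
  month <- vapply(seq_len(n), function(i) {
    sample(season_months(season[i], northern[i]), 1)
  }, numeric(1))
  month[stats::runif(n) < cfg$fraction_month_missing] <- NA
  drop_season <- stats::runif(n) < cfg$fraction_season_missing
  season_out <- season
  season_out[drop_season] <- NA
  month[drop_season] <- NA

  slice_idx <- sample(seq_along(cfg$depth_slices), n, replace = TRUE,
                      prob = cfg$depth_weights)
  depth_upper <- vapply(cfg$depth_slices[slice_idx], `[`, numeric(1), 1)
  depth_lower <- vapply(cfg$depth_slices[slice_idx], `[`, numeric(1), 2)

  area <- sample(cfg$area_levels, n, replace = TRUE, prob = cfg$area_weights)
  as_count <- measure == "density" &
    stats::runif(n) < cfg$fraction_density_as_count
  area[measure == "density" & !as_count] <- 1  # reported per m2 directly

  # multiplicative distortions (season exemption for (sub)tropical biomes)
  season_factor <- ifelse(is_trop, 1, cfg$season_mult[season])
  area_factor <- ifelse(measure == "diversity",
                        (area / 0.01)^cfg$Z[biome], 1)
  depth_factor <- 10^(cfg$depth_b1 * (depth_upper - 0) +
                        cfg$depth_b2 * (depth_lower - 5))
  count_factor <- ifelse(measure == "density" & as_count, area, 1)
  noise_factor <- if (cfg$sigma > 0)
    exp(stats::rnorm(n, 0, cfg$sigma)) else rep(1, n)

  value <- latent_value * season_factor * area_factor * depth_factor *
    count_factor * noise_factor

  records <- data.frame(
    record_id = predictors$record_id,
    latitude = latitude, longitude = longitude, biome = biome,
    measure = measure, value = value, sample_area_m2 = area,
    depth_upper_cm = depth_upper, depth_lower_cm = depth_lower,
    sampling_month = month, season = season_out,
    stringsAsFactors = FALSE
  )
  records <- as_seedbank_records(records)

  tallies <- as.data.frame(table(biome = biome, measure = measure),
                           stringsAsFactors = FALSE)
  names(tallies)[3] <- "count"

  truth <- list(
    params = list(season_mult = cfg$season_mult, Z = cfg$Z,
                  depth_b1 = cfg$depth_b1, depth_b2 = cfg$depth_b2,
                  diversity_baseline = cfg$diversity_baseline,
                  density_baseline = cfg$density_baseline,
                  biome_mult = cfg$biome_mult, effects = cfg$effects,
                  sigma = cfg$sigma, seed = seed),
    records = data.frame(
      record_id = records$record_id, measure = measure, biome = biome,
      latent = latent_value, true_season = season,
      season_factor = unname(season_factor),
      area_factor = unname(area_factor),
      depth_factor = unname(depth_factor),
      count_factor = unname(count_factor),
      noise_factor = unname(noise_factor),
      observed = value, stringsAsFactors = FALSE),
    tallies = tallies,
    informative = lapply(cfg$effects, names),
    warnings = warnings
  )
  out <- list(records = records, predictors = predictors, truth = truth)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic seed bank dataset:", nrow(x$records), "records,",
      length(predictor_names()), "predictors\n")
  cat("  informative predictors (diversity):",
      paste(x$truth$informative$diversity, collapse = ", "), "\n")
  cat("  informative predictors (density):  ",
      paste(x$truth$informative$density, collapse = ", "), "\n")
  invisible(x)
}

#' Build the true standardization model bundle from a truth ledger
#'
#' Converts the generator's true parameters into the fitted-model structures
#' used by [run_standardization()] (season ratios as the reciprocal of the
#' generative season multipliers; per-biome species-area exponents; depth
#' boundary slopes), e.g. to standardize with known rather than estimated
#' parameters.
#'
#' @param truth The `truth` element of a `synthetic_dataset`.
#' @return A list with `season_ratios`, `area_models`, `depth_models`.
#' @export
truth_models <- function(truth) {
  p <- truth$params
  sr <- list()
  for (m in c("diversity", "density")) {
    sr[[m]] <- data.frame(season = season_levels(),
                          ratio = 1 / unname(p$season_mult[season_levels()]),
                          n = NA_integer_, stringsAsFactors = FALSE)
  }
  class(sr) <- "season_ratios"

  am <- list()
  for (b in names(p$Z)) {
    mod <- list(biome = b, C = NA_real_, Z = unname(p$Z[b]), n = NA_integer_,
                r_squared = NA_real_, n_excluded_zero = 0L,
                insufficient_data = FALSE)
    class(mod) <- "biome_area_model"
    am[[b]] <- mod
  }
  am$pooled <- am[[1]]
  class(am) <- "area_models"

  dm <- list()
  for (m in c("diversity", "density")) {
    for (b in c(names(p$Z), "pooled")) {
      mod <- list(biome = b, measure = m, b0 = NA_real_, b1 = p$depth_b1,
                  b2 = p$depth_b2, n = NA_integer_, r_squared = NA_real_,
                  reduced_rank = FALSE, insufficient_data = FALSE)
      class(mod) <- "biome_depth_model"
      dm[[paste(b, m, sep = ".")]] <- mod
    }
  }
  class(dm) <- "depth_models"
  list(season_ratios = sr, area_models = am, depth_models = dm)
}

# Separable Gaussian smoothing with edge renormalization.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  smooth_vec <- function(v) {
    num <- stats::convolve(v, rev(k), type = "open")
    den <- stats::convolve(rep(1, length(v)), rev(k), type = "open")
    (num / den)[(r + 1):(r + length(v))]
  }
  tmp <- apply(mat, 2, smooth_vec)
  t(apply(tmp, 1, smooth_vec))
}

#' Generate a synthetic gridded predictor stack
#'
#' One layer per predictor: spatially smooth random fields built by Gaussian
#' smoothing of white noise (correlation length configurable as the
#' practical range, the distance at which spatial correlation effectively
#' vanishes), rescaled into each predictor's plausible range. The
#' `abs.latit` layer is computed from the cell-center latitude, not
#' simulated.
#'
#' @param config A `generator_config`; its `grid` element sets extent,
#'   dimensions and `correlation_length_deg`.
#' @param seed Integer random seed.
#' @return A `predictor_grid` (see [predictor_grid()]).
#' @export
generate_grid <- function(config, seed) {
  set.seed(seed)
  g <- config$grid
  if (g$nrow <= 0 || g$ncol <= 0) stop("grid dimensions must be positive")
  cell_lon <- (g$lon_max - g$lon_min) / g$ncol
  cell_lat <- (g$lat_max - g$lat_min) / g$nrow
  if (cell_lon <= 0 || cell_lat <= 0) stop("grid resolution must be positive")
  lon <- g$lon_min + (seq_len(g$ncol) - 0.5) * cell_lon
  lat <- g$lat_max - (seq_len(g$nrow) - 0.5) * cell_lat  # north to south
  # practical range L ~ 2*sigma*sqrt(log(20)) for Gaussian-kernel smoothing
  sigma_cells <- g$correlation_length_deg / cell_lat / (2 * sqrt(log(20)))

  rng <- predictor_ranges()
  layers <- list()
  for (p in predictor_names()) {
    if (p == "abs.latit") {
      layers[[p]] <- matrix(rep(abs(lat), g$ncol), nrow = g$nrow)
    } else {
      z <- gaussian_smooth(matrix(stats::rnorm(g$nrow * g$ncol),
                                  nrow = g$nrow), sigma_cells)
      z <- (z - mean(z)) / stats::sd(z)
      u <- stats::pnorm(z)
      layers[[p]] <- rng[[p]][1] + u * (rng[[p]][2] - rng[[p]][1])
    }
  }
  predictor_grid(layers, lon = lon, lat = lat,
                 res_arcmin = c(cell_lon, cell_lat) * 60)
}
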