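#' Assign meteorological seasons to records
#'
#' Fills the `season` field from `sampling_month`, hemisphere-aware:
#' in the Northern Hemisphere December-February is winter, in the Southern
#' Hemisphere June-August is winter (and so on, shifted by six months). An
#' explicitly recorded season always wins over the month. Records with both
#' month and season missing keep `season = NA` and are reported as
#' unstandardizable for the seasonal step.
#'
#' @param records A `seedbank_records` data frame.
#' @return The records with `season` filled where derivable.
#' @export
assign_season <- function(records) {
  month_season_north <- c("winter", "winter", "spring", "spring", "spring",
                          "summer", "summer", "summer", "autumn", "autumn",
                          "autumn", "winter")
  shift <- c(spring = "autumn", summer = "winter",
             autumn = "spring", winter = "summer")
  needs <- is.na(records$season) & !is.na(records$sampling_month)
  if (any(needs)) {
    s <- month_season_north[records$sampling_month[needs]]
    south <- records$latitude[needs] < 0
    s[south] <- shift[s[south]]
    records$season[needs] <- s
  }
  records
}

#' Fit season-to-winter standardization ratios
#'
#' Winter is the season with the highest seed bank values; all other seasons
#' are standardized to it by an average ratio. The default definition is the
#' ratio of means, \eqn{r_s = \bar{y}_{winter} / \bar{y}_s}, computed per
#' measure over all eligible records pooled; multiplying season-\eqn{s}
#' values by \eqn{r_s} maps them to the winter level and makes winter the
#' fixed point (\eqn{r_{winter} = 1}). Records from (sub)tropical biomes are
#' excluded from the computation (they are exempt from the seasonal step
#' because tropical regions have low seasonality).
#'
#' @param records A `seedbank_records` data frame with seasons assigned.
#' @param method `"ratio_of_means"` (default) or `"per_biome_mean"`, which
#'   computes the winter/season ratio within each eligible biome and averages
#'   the per-biome ratios (a mean-of-ratios variant; pairing of individual
#'   records across seasons is undefined across studies).
#' @return A list of class `"season_ratios"` with one data frame per measure
#'   (`season`, `ratio`, `n`), `NA` ratio for seasons without data.
#' @export
fit_season_ratios <- function(records, method = c("ratio_of_means",
                                                  "per_biome_mean")) {
  method <- match.arg(method)
  eligible <- records[!(records$biome %in% tropical_biome_codes()) &
                        !is.na(records$season), , drop = FALSE]
  if (nrow(eligible) == 0)
    stop("no eligible records: all records are (sub)tropical or lack a season")
  out <- list()
  for (m in c("diversity", "density")) {
    sub <- eligible[eligible$measure == m, , drop = FALSE]
    df <- data.frame(season = season_levels(), ratio = NA_real_,
                     n = 0L, stringsAsFactors = FALSE)
    if (nrow(sub) > 0) {
      winter_vals <- sub$value[sub$season == "winter"]
      if (length(winter_vals) == 0)
        stop("no winter records for measure '", m,
             "': season ratios undefined")
      for (i in seq_len(nrow(df))) {
        s <- df$season[i]
        vals <- sub$value[sub$season == s]
        df$n[i] <- length(vals)
        if (s == "winter") {
          df$ratio[i] <- 1
        } else if (length(vals) > 0) {
          if (method == "ratio_of_means") {
            sm <- mean(vals)
            df$ratio[i] <- if (sm > 0) mean(winter_vals) / sm else NA_real_
          } else {
            ratios <- c()
            for (b in unique(sub$biome)) {
              wv <- sub$value[sub$biome == b & sub$season == "winter"]
              sv <- sub$value[sub$biome == b & sub$season == s]
              if (length(wv) > 0 && length(sv) > 0 && mean(sv) > 0)
                ratios <- c(ratios, mean(wv) / mean(sv))
            }
            df$ratio[i] <- if (length(ratios) > 0) mean(ratios) else NA_real_
          }
        }
      }
    }
    out[[m]] <- df
  }
  class(out) <- "season_ratios"
  out
}

#' Apply seasonal standardization
#'
#' Multiplies each eligible record's value by its season's ratio. Winter
#' records (ratio 1) and (sub)tropical records (exempt) pass through
#' unchanged; both count as seasonally comparable and get the `season` flag.
#' Records whose season is missing, or whose season has no fitted ratio,
#' are left unflagged.
#'
#' @param records A `seedbank_records` data frame with seasons assigned.
#' @param ratios A `season_ratios` object from [fit_season_ratios()].
#' @return The records with values standardized and `flag_season` set.
#' @export
apply_season_standardization <- function(records, ratios) {
  records <- ensure_flags(records)
  tropical <- records$biome %in% tropical_biome_codes()
  records$flag_season[tropical & !records$flag_season] <- TRUE
  for (m in c("diversity", "density")) {
    rt <- stats::setNames(ratios[[m]]$ratio, ratios[[m]]$season)
    idx <- which(!tropical & records$measure == m &
                   !is.na(records$season) & !records$flag_season)
    for (i in idx) {
      r <- rt[[records$season[i]]]
      if (!is.na(r)) {
        records$value[i] <- records$value[i] * r
        records$flag_season[i] <- TRUE
      }
    }
  }
  records
}

#' Fit a species-area curve for one biome (or pooled)
#'
#' Fits the power law \eqn{S = C A^Z} by ordinary least squares of
#' \eqn{\log S} on \eqn{\log A} over diversity records; \eqn{C} is the
#' exponentiated intercept and \eqn{Z} the slope. Values are first capped
#' with [rosner_cap()] (high-side outliers to the 95th percentile) unless
#' `cap = FALSE`. Zero values cannot enter the log fit and are excluded and
#' counted.
#'
#' @param records A `seedbank_records` data frame (diversity rows are used).
#' @param biome A biome code, or `NULL` for the pooled fit over all biomes.
#' @param cap Apply generalized ESD capping to values before fitting.
#' @param min_n Minimum records for a fit (default 10).
#' @param alpha,max_k Passed to [rosner_cap()] (`max_k = NULL` for its
#'   default).
#' @return A list of class `"biome_area_model"` with `biome`, `C`, `Z`, `n`,
#'   `r_squared`, `n_excluded_zero`, `insufficient_data`.
#' @export
fit_species_area <- function(records, biome = NULL, cap = TRUE,
                             min_n = 10L, alpha = 0.05, max_k = NULL) {
  sub <- records[records$measure == "diversity", , drop = FALSE]
  if (!is.null(biome)) sub <- sub[sub$biome == biome, , drop = FALSE]
  label <- if (is.null(biome)) "pooled" else biome
  model <- list(biome = label, C = NA_real_, Z = NA_real_, n = 0L,
                r_squared = NA_real_, n_excluded_zero = 0L,
                insufficient_data = TRUE)
  class(model) <- "biome_area_model"

  vals <- sub$value
  if (cap && length(vals) > 0) {
    mk <- if (is.null(max_k)) max(1L, ceiling(0.05 * length(vals))) else max_k
    vals <- suppressWarnings(rosner_cap(vals, alpha = alpha, max_k = mk))$values
  }
  pos <- which(vals > 0)
  model$n_excluded_zero <- sum(vals == 0)
  if (length(pos) < min_n ||
      length(unique(sub$sample_area_m2[pos])) < 2) {
    return(model)
  }
  fit <- stats::lm(log(vals[pos]) ~ log(sub$sample_area_m2[pos]))
  model$C <- exp(unname(stats::coef(fit)[1]))
  model$Z <- unname(stats::coef(fit)[2])
  model$n <- length(pos)
  model$r_squared <- summary(fit)$r.squared
  model$insufficient_data <- FALSE
  model
}

#' Fit species-area curves for every biome plus a pooled fallback
#'
#' @inheritParams fit_species_area
#' @return A list of class `"area_models"`: per-biome `biome_area_model`s
#'   keyed by code plus element `pooled`.
#' @export
fit_area_models <- function(records, cap = TRUE, min_n = 10L,
                            alpha = 0.05, max_k = NULL) {
  out <- list()
  for (b in unique(records$biome[records$measure == "diversity"])) {
    out[[b]] <- fit_species_area(records, biome = b, cap = cap,
                                 min_n = min_n, alpha = alpha, max_k = max_k)
  }
  out$pooled <- fit_species_area(records, biome = NULL, cap = cap,
                                 min_n = min_n, alpha = alpha, max_k = max_k)
  class(out) <- "area_models"
  out
}

#' Standardize diversity records to the reference sampling area
#'
#' Rescales each diversity value to the most commonly reported area
#' (0.01 m2) with the ratio form \eqn{S_{0.01} = S (0.01/A)^Z} using the
#' record's biome-specific exponent (pooled fallback when the biome fit has
#' insufficient data). The ratio form preserves record-level variation
#' instead of replacing values by curve predictions. Density records are not
#' touched (density is already per unit area after unit conversion).
#'
#' @param records A `seedbank_records` data frame.
#' @param models An `area_models` list from [fit_area_models()].
#' @param target_area_m2 Reference area (default 0.01).
#' @return Records with diversity values rescaled and `flag_area` set;
#'   attribute `"n_fallback"` counts records standardized with the pooled
#'   fit.
#' @export
standardize_area <- function(records, models, target_area_m2 = 0.01) {
  records <- ensure_flags(records)
  n_fallback <- 0L
  idx <- which(records$measure == "diversity" & !records$flag_area)
  for (i in idx) {
    m <- models[[records$biome[i]]]
    if (is.null(m) || m$insufficient_data) {
      m <- models$pooled
      if (is.null(m) || m$insufficient_data) next
      n_fallback <- n_fallback + 1L
    }
    records$value[i] <- records$value[i] *
      (target_area_m2 / records$sample_area_m2[i])^m$Z
    records$flag_area[i] <- TRUE
  }
  attr(records, "n_fallback") <- n_fallback
  records
}

#' Fit a depth-boundary model for one biome and measure
#'
#' Regresses \eqn{\log_{10}} of the value on the untransformed upper and
#' lower boundaries of the sampled depth slice (boundaries include 0 cm, so
#' they cannot themselves be log-transformed). When the boundaries are
#' perfectly collinear across records (e.g. every slice is exactly 5 cm
#' thick) the model is rank deficient; a lower-boundary-only model is fitted
#' instead and flagged `reduced_rank`.
#'
#' @param records A `seedbank_records` data frame.
#' @param biome A biome code, or `NULL` for pooled.
#' @param measure `"diversity"` or `"density"`.
#' @param min_n Minimum positive-valued records (default 10).
#' @return A list of class `"biome_depth_model"`: `biome`, `measure`, `b0`,
#'   `b1` (upper-boundary slope), `b2` (lower-boundary slope), `n`,
#'   `r_squared`, `reduced_rank`, `insufficient_data`.
#' @export
fit_depth_model <- function(records, biome = NULL, measure, min_n = 10L) {
  sub <- records[records$measure == measure & records$value > 0, , drop = FALSE]
  if (!is.null(biome)) sub <- sub[sub$biome == biome, , drop = FALSE]
  label <- if (is.null(biome)) "pooled" else biome
  model <- list(biome = label, measure = measure, b0 = NA_real_,
                b1 = NA_real_, b2 = NA_real_, n = 0L, r_squared = NA_real_,
                reduced_rank = FALSE, insufficient_data = TRUE)
  class(model) <- "biome_depth_model"
  slices <- unique(paste(sub$depth_upper_cm, sub$depth_lower_cm))
  if (nrow(sub) < min_n || length(slices) < 2) return(model)

  u <- sub$depth_upper_cm
  l <- sub$depth_lower_cm
  y <- log10(sub$value)
  X <- cbind(1, u, l)
  if (qr(X)$rank < 3) {
    fit <- stats::lm(y ~ l)
    model$b0 <- unname(stats::coef(fit)[1])
    model$b1 <- 0
    model$b2 <- unname(stats::coef(fit)[2])
    model$reduced_rank <- TRUE
  } else {
    fit <- stats::lm(y ~ u + l)
    cf <- stats::coef(fit)
    model$b0 <- unname(cf[1]); model$b1 <- unname(cf[2])
    model$b2 <- unname(cf[3])
  }
  model$n <- nrow(sub)
  model$r_squared <- summary(fit)$r.squared
  model$insufficient_data <- FALSE
  model
}

#' Fit depth models for every biome and measure, plus pooled fallbacks
#'
#' @inheritParams fit_depth_model
#' @param records A `seedbank_records` data frame.
#' @return A list of class `"depth_models"` keyed `"<biome>.<measure>"` plus
#'   `"pooled.<measure>"`.
#' @export
fit_depth_models <- function(records, min_n = 10L) {
  out <- list()
  for (m in c("diversity", "density")) {
    for (b in unique(records$biome[records$measure == m])) {
      out[[paste(b, m, sep = ".")]] <-
        fit_depth_model(records, biome = b, measure = m, min_n = min_n)
    }
    out[[paste("pooled", m, sep = ".")]] <-
      fit_depth_model(records, biome = NULL, measure = m, min_n = min_n)
  }
  class(out) <- "depth_models"
  out
}

#' Standardize records to the reference depth slice (0-5 cm)
#'
#' Rescales each value to the most frequently reported slice with
#' \eqn{y_{0-5} = y \cdot 10^{b_1 (0 - u) + b_2 (5 - l)}} where \eqn{(u, l)}
#' are the record's depth boundaries and \eqn{(b_1, b_2)} the biome- and
#' measure-specific boundary slopes (pooled fallback when needed).
#'
#' @param records A `seedbank_records` data frame.
#' @param models A `depth_models` list from [fit_depth_models()].
#' @param target_upper_cm,target_lower_cm Reference slice (default 0-5 cm).
#' @return Records rescaled with `flag_depth` set; attribute `"n_fallback"`
#'   counts pooled-fallback uses.
#' @export
standardize_depth <- function(records, models, target_upper_cm = 0,
                              target_lower_cm = 5) {
  records <- ensure_flags(records)
  n_fallback <- 0L
  idx <- which(!records$flag_depth)
  for (i in idx) {
    key <- paste(records$biome[i], records$measure[i], sep = ".")
    m <- models[[key]]
    if (is.null(m) || m$insufficient_data) {
      m <- models[[paste("pooled", records$measure[i], sep = ".")]]
      if (is.null(m) || m$insufficient_data) next
      n_fallback <- n_fallback + 1L
    }
    adj <- 10^(m$b1 * (target_upper_cm - records$depth_upper_cm[i]) +
                 m$b2 * (target_lower_cm - records$depth_lower_cm[i]))
    records$value[i] <- records$value[i] * adj
    records$flag_depth[i] <- TRUE
  }
  attr(records, "n_fallback") <- n_fallback
  records
}

#' Convert density records to seeds per square metre
#'
#' Density values in the schema are raw seed counts for the stated sample
#' area; dividing by `sample_area_m2` yields seeds per m2. Sources reporting
#' per-m2 values directly are encoded with `sample_area_m2 = 1`, for which
#' the conversion is the identity. Idempotent: records already carrying the
#' `density_unit` flag are untouched.
#'
#' @param records A `seedbank_records` data frame.
#' @return Records with density values in seeds per m2 and
#'   `flag_density_unit` set.
#' @export
density_to_per_m2 <- function(records) {
  records <- ensure_flags(records)
  if (any(records$sample_area_m2 <= 0, na.rm = TRUE))
    stop("non-positive sample_area_m2: record(s) must be rejected upstream")
  idx <- records$measure == "density" & !records$flag_density_unit
  records$value[idx] <- records$value[idx] / records$sample_area_m2[idx]
  records$flag_density_unit[idx] <- TRUE
  records
}

#' Run the full standardization pipeline
#'
#' Applies the harmonization steps in a fixed (configurable) order:
#' density unit conversion, then seasonal standardization to winter, then
#' area standardization to 0.01 m2 (diversity only), then depth
#' standardization to the 0-5 cm slice. Each step is the identity on records
#' already at its target convention. No record is ever dropped; records a
#' step cannot standardize simply do not receive that step's flag, and the
#' report tallies everything.
#'
#' @param records A `seedbank_records` data frame.
#' @param options List of options: `alpha`, `max_k`, `cap` (Rosner
#'   parameters for the species-area fit input), `min_n` (minimum fit size),
#'   `season_method` (see [fit_season_ratios()]), `steps` (character vector
#'   ordering a subset of `c("units", "season", "area", "depth")`), and
#'   optionally `models` — a pre-fitted bundle
#'   `list(season_ratios=, area_models=, depth_models=)` used instead of
#'   fitting from the data (e.g. parameters from an external calibration).
#' @return A list of class `"standardization_result"`: `records`
#'   (standardized), `models` (the bundle used), `report` (per-step counts
#'   and fit summaries).
#' @export
run_standardization <- function(records, options = list()) {
  opt <- utils::modifyList(
    list(alpha = 0.05, max_k = NULL, cap = TRUE, min_n = 10L,
         season_method = "ratio_of_means",
         steps = c("units", "season", "area", "depth"), models = NULL),
    options)
  records <- ensure_flags(assign_season(records))
  n_total <- nrow(records)
  report <- list(n_records = n_total, steps = list(), n_fallback_area = 0L,
                 n_fallback_depth = 0L)
  models <- if (is.null(opt$models)) list() else opt$models

  for (step in opt$steps) {
    before <- records
    if (step == "units") {
      records <- density_to_per_m2(records)
      n_applied <- sum(records$flag_density_unit) -
        sum(before$flag_density_unit)
    } else if (step == "season") {
      if (is.null(models$season_ratios))
        models$season_ratios <- fit_season_ratios(records,
                                                  method = opt$season_method)
      records <- apply_season_standardization(records, models$season_ratios)
      n_applied <- sum(records$flag_season) - sum(before$flag_season)
    } else if (step == "area") {
      if (is.null(models$area_models))
        models$area_models <- fit_area_models(records, cap = opt$cap,
                                              min_n = opt$min_n,
                                              alpha = opt$alpha,
                                              max_k = opt$max_k)
      records <- standardize_area(records, models$area_models)
      report$n_fallback_area <- attr(records, "n_fallback")
      n_applied <- sum(records$flag_area) - sum(before$flag_area)
    } else if (step == "depth") {
      if (is.null(models$depth_models))
        models$depth_models <- fit_depth_models(records, min_n = opt$min_n)
      records <- standardize_depth(records, models$depth_models)
      report$n_fallback_depth <- attr(records, "n_fallback")
      n_applied <- sum(records$flag_depth) - sum(before$flag_depth)
    } else {
      stop("unknown standardization step: ", step)
    }
    report$steps[[step]] <- list(n_applied = n_applied,
                                 n_unflagged = n_total - switch(step,
        units = sum(records$flag_density_unit |
                      records$measure == "diversity"),
        season = sum(records$flag_season),
        area = sum(records$flag_area | records$measure == "density"),
        depth = sum(records$flag_depth)))
  }
  out <- list(records = records, models = models, report = report)
  class(out) <- "standardization_result"
  out
}

#' @export
print.standardization_result <- function(x, ...) {
  cat("Seed bank standardization:", x$report$n_records, "records\n")
  for (s in names(x$report$steps)) {
    cat(sprintf("  %-8s applied to %d record(s), %d not standardizable\n",
                s, x$report$steps[[s]]$n_applied,
                x$report$steps[[s]]$n_unflagged))
  }
  invisible(x)
}
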