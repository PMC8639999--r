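#' Empirical semivariogram with great-circle distances
#'
#' Classical (Matheron) semivariance per lag bin,
#' \eqn{\gamma(h) = \frac{1}{2 N(h)} \sum_{(i,j) \in h} (z_i - z_j)^2},
#' with pair distances measured along great circles (haversine) in km.
#' A flat semivariogram near the sample variance indicates no spatial
#' autocorrelation.
#'
#' @param coordinates Data frame or matrix with columns `longitude`,
#'   `latitude` (decimal degrees).
#' @param values Numeric vector, finite, one per point.
#' @param n_bins Number of equal-width lag bins (default 15).
#' @param max_lag_km Maximum lag; default half the maximum pairwise
#'   distance.
#' @param bin_edges_km Optional explicit bin edges (overrides `n_bins` /
#'   `max_lag_km`).
#' @return A data frame of class `"semivariogram"` with columns `lag_lower`,
#'   `lag_upper`, `lag_mid` (km), `n_pairs`, `gamma` (`NA` for empty bins),
#'   plus attributes `sample_variance` and `total_pairs`.
#' @export
empirical_semivariogram <- function(coordinates, values, n_bins = 15L,
                                    max_lag_km = NULL, bin_edges_km = NULL) {
  coordinates <- as.data.frame(coordinates)
  n <- nrow(coordinates)
  if (n < 2) stop("need at least 2 points")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(values) != n) stop("values and coordinates differ in length")
  pts <- cbind(coordinates$longitude, coordinates$latitude)
  d_km <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  iu <- which(upper.tri(d_km), arr.ind = TRUE)
  pd <- d_km[iu]
  sqdiff <- (values[iu[, 1]] - values[iu[, 2]])^2

  if (is.null(bin_edges_km)) {
    if (is.null(max_lag_km)) max_lag_km <- max(pd) / 2
    bin_edges_km <- seq(0, max_lag_km, length.out = n_bins + 1)
  }
  nb <- length(bin_edges_km) - 1
  bin <- findInterval(pd, bin_edges_km, rightmost.closed = TRUE)
  use <- bin >= 1 & bin <= nb
  out <- data.frame(lag_lower = bin_edges_km[seq_len(nb)],
                    lag_upper = bin_edges_km[-1])
  out$lag_mid <- (out$lag_lower + out$lag_upper) / 2
  out$n_pairs <- vapply(seq_len(nb), function(b) sum(use & bin == b),
                        integer(1))
  out$gamma <- vapply(seq_len(nb), function(b) {
    s <- use & bin == b
    if (!any(s)) return(NA_real_)
    sum(sqdiff[s]) / (2 * sum(s))
  }, numeric(1))
  attr(out, "sample_variance") <- stats::var(values)
  attr(out, "total_pairs") <- sum(use)
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' Estimate the semivariogram range
#'
#' The smallest lag at which the (monotonized) semivariance first reaches
#' `level` times the sill, taking the sample variance as the sill (the
#' theoretical plateau). A crude but serviceable practical-range estimate
#' for checking generated correlation lengths.
#'
#' @param sv A `semivariogram`.
#' @param level Fraction of the sill defining the range (default 0.9).
#' @return Range in km (`NA` when the semivariogram never reaches the
#'   level).
#' @export
semivariogram_range <- function(sv, level = 0.9) {
  ok <- !is.na(sv$gamma)
  if (sum(ok) < 3) return(NA_real_)
  # the theoretical plateau of the semivariance is the field variance;
  # using it (rather than long-lag bin means) avoids bias from
  # finite-domain drift at large lags
  sill <- attr(sv, "sample_variance")
  g <- cummax(ifelse(ok, sv$gamma, -Inf))  # enforce a monotone rise
  hit <- which(g >= level * sill)
  if (length(hit) == 0) return(NA_real_)
  sv$lag_mid[min(hit)]
}

#' Kruskal-Wallis comparison of seed bank values among biomes
#'
#' Rank-based H statistic with tie correction (chi-square reference,
#' df = number of biomes - 1), comparing one measure's values across biome
#' types.
#'
#' @param records A `seedbank_records` data frame.
#' @param measure `"diversity"` or `"density"`.
#' @return A list of class `"kruskal_biomes"`: `H`, `df`, `p_value`,
#'   `medians` (named per-biome medians), `n` (per-biome counts).
#' @export
kruskal_wallis_by_biome <- function(records, measure) {
  sub <- records[records$measure == measure, , drop = FALSE]
  groups <- unique(sub$biome)
  if (length(groups) < 2)
    stop("need at least 2 biomes with records for measure '", measure, "'")
  kt <- stats::kruskal.test(sub$value, factor(sub$biome))
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value,
              medians = tapply(sub$value, sub$biome, stats::median),
              n = tapply(sub$value, sub$biome, length))
  class(out) <- "kruskal_biomes"
  out
}

#' @export
print.kruskal_biomes <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis among biomes: H = %.4g, df = %d, p = %.3g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Compare seed bank values between hemispheres, per biome
#'
#' For every biome present in both hemispheres, a two-sample Wilcoxon rank
#' sum test of the measure's values north versus south of the equator (a
#' sampling-bias diagnostic: systematic hemispheric differences within
#' biomes would indicate artifacts). Biomes found in only one hemisphere
#' are listed as skipped.
#'
#' @param records A `seedbank_records` data frame.
#' @param measure `"diversity"` or `"density"`.
#' @return A list of class `"hemisphere_comparison"`: `table` (one row per
#'   both-hemisphere biome: `biome`, `n_north`, `n_south`, `mean_north`,
#'   `mean_south`, `p_value`) and `skipped` (biome codes in one hemisphere
#'   only).
#' @export
hemisphere_comparison <- function(records, measure) {
  sub <- records[records$measure == measure, , drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (b in sort(unique(sub$biome))) {
    bn <- sub$value[sub$biome == b & sub$latitude >= 0]
    bs <- sub$value[sub$biome == b & sub$latitude < 0]
    if (length(bn) == 0 || length(bs) == 0) {
      skipped <- c(skipped, b)
      next
    }
    p <- suppressWarnings(stats::wilcox.test(bn, bs)$p.value)
    rows[[b]] <- data.frame(biome = b, n_north = length(bn),
                            n_south = length(bs), mean_north = mean(bn),
                            mean_south = mean(bs), p_value = p,
                            stringsAsFactors = FALSE)
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(biome = character(0), n_north = integer(0),
               n_south = integer(0), mean_north = numeric(0),
               mean_south = numeric(0), p_value = numeric(0))
  rownames(tab) <- NULL
  out <- list(table = tab, skipped = skipped)
  class(out) <- "hemisphere_comparison"
  out
}

#' @export
print.hemisphere_comparison <- function(x, ...) {
  cat("Hemisphere comparison:", nrow(x$table), "biome(s) compared,",
      length(x$skipped), "skipped (single hemisphere)\n")
  if (nrow(x$table) > 0) print.data.frame(x$table, digits = 3)
  invisible(x)
}
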