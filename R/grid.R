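#' Gridded predictor stack
#'
#' A lightweight geographic raster stack: one matrix layer per predictor on
#' a shared cell-center registered longitude/latitude grid (rows run north
#' to south, columns west to east). Cells with a missing value in any layer
#' are treated as nodata for prediction.
#'
#' @param layers Named list of numeric matrices, all of identical dimension.
#' @param lon,lat Numeric vectors of cell-center longitudes (length =
#'   `ncol`) and latitudes (length = `nrow`, decreasing).
#' @param res_arcmin Numeric length-2 resolution (lon, lat) in arcminutes.
#' @return A list of class `"predictor_grid"`.
#' @export
predictor_grid <- function(layers, lon, lat, res_arcmin) {
  stopifnot(length(layers) > 0, !is.null(names(layers)))
  d <- dim(layers[[1]])
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !identical(dim(layers[[nm]]), d))
      stop("layer '", nm, "' is misaligned with the stack")
  }
  stopifnot(length(lat) == d[1], length(lon) == d[2])
  out <- list(layers = layers, lon = lon, lat = lat,
              res_arcmin = rep(res_arcmin, length.out = 2))
  class(out) <- "predictor_grid"
  out
}

#' @export
print.predictor_grid <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("Predictor grid: %d layers, %d x %d cells, %.2f' x %.2f'\n",
              length(x$layers), d[1], d[2], x$res_arcmin[1],
              x$res_arcmin[2]))
  cat("  extent: lon", format(range(x$lon)), " lat", format(range(x$lat)),
      "\n")
  invisible(x)
}

# Flatten a grid to a cellwise predictor table (column-major cell order).
grid_to_table <- function(grid, predictors) {
  as.data.frame(lapply(stats::setNames(predictors, predictors),
                       function(p) as.vector(grid$layers[[p]])))
}

#' Predict a fitted forest onto a predictor grid
#'
#' Cellwise prediction, identical by construction to flattening the grid to
#' a table, predicting, and reshaping. Cells with a missing value in any
#' required layer are nodata in the output (no imputation).
#'
#' @param fit A `forest_fit`.
#' @param grid A `predictor_grid` whose layers cover every model predictor.
#' @return A list of class `"prediction_raster"`: `values` (matrix, `NA` =
#'   nodata), `lon`, `lat`, `res_arcmin`, `log10` (display-transform flag,
#'   `FALSE`), `model_seed`.
#' @export
predict_grid <- function(fit, grid) {
  missing_layers <- setdiff(fit$predictors, names(grid$layers))
  if (length(missing_layers) > 0)
    stop("grid lacks predictor layer(s): ",
         paste(missing_layers, collapse = ", "))
  tab <- grid_to_table(grid, fit$predictors)
  cc <- stats::complete.cases(tab)
  vals <- rep(NA_real_, nrow(tab))
  if (any(cc))
    vals[cc] <- stats::predict(fit$forest, tab[cc, , drop = FALSE])
  out <- list(values = matrix(vals, nrow = dim(grid$layers[[1]])[1]),
              lon = grid$lon, lat = grid$lat, res_arcmin = grid$res_arcmin,
              log10 = FALSE, model_seed = fit$seed)
  class(out) <- "prediction_raster"
  out
}

#' @export
print.prediction_raster <- function(x, ...) {
  cat(sprintf("Prediction raster: %d x %d cells, %d nodata%s\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              if (x$log10) ", log10 display scale" else ""))
  cat("  value range:", format(range(x$values, na.rm = TRUE), digits = 4),
      "\n")
  invisible(x)
}

#' Log10 display transform of a prediction raster
#'
#' Cells with positive values become their base-10 logarithm; zero or
#' negative cells become nodata. The transform is flagged in the raster's
#' metadata.
#'
#' @param raster A `prediction_raster`.
#' @return The transformed raster with `log10 = TRUE`.
#' @export
log10_display <- function(raster) {
  v <- raster$values
  v[!is.na(v) & v <= 0] <- NA
  raster$values <- log10(v)
  raster$log10 <- TRUE
  raster
}

#' Zonal (latitude-band) means of a prediction raster
#'
#' @param raster A `prediction_raster`.
#' @return Data frame `latitude`, `mean_value` (rows with all-nodata bands
#'   dropped).
#' @export
zonal_means <- function(raster) {
  mv <- rowMeans(raster$values, na.rm = TRUE)
  out <- data.frame(latitude = raster$lat, mean_value = mv)
  out[is.finite(out$mean_value), , drop = FALSE]
}

# ---- headered ASCII grid I/O (plain-text raster format) ----

#' Write a raster layer as a headered ASCII grid
#'
#' The standard six-line ASCII grid header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of cell values
#' north to south. A small JSON sidecar (`<path>.meta.json`) carries the
#' metadata that the format itself cannot (display-transform flag, model
#' seed). Requires square cells.
#'
#' @param raster A `prediction_raster`, or a bare matrix together with
#'   `lon`, `lat`.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  r <- raster
  dx <- r$res_arcmin[1] / 60
  dy <- r$res_arcmin[2] / 60
  if (abs(dx - dy) > 1e-9 * max(dx, dy))
    stop("ASCII grid format requires square cells (got ",
         signif(dx, 6), " x ", signif(dy, 6), " degrees)")
  nodata <- -9999
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(min(r$lon) - dx / 2, digits = 15)),
    paste("yllcorner", format(min(r$lat) - dy / 2, digits = 15)),
    paste("cellsize", format(dx, digits = 15)),
    paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(log10 = r$log10, model_seed = r$model_seed),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

# Parse one ASCII grid file into values + georeferencing.
read_ascii_raster <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  hdr_lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in hdr_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- utils::read.table(path, skip = 6)
  v <- as.matrix(vals)
  dimnames(v) <- NULL
  v[v == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  lon <- hdr$xllcorner + (seq_len(hdr$ncols) - 0.5) * cs
  lat <- hdr$yllcorner + (rev(seq_len(hdr$nrows)) - 0.5) * cs
  list(values = v, lon = lon, lat = lat, cellsize = cs)
}

#' Read a prediction raster written by [write_raster()]
#'
#' @param path Path to the ASCII grid; the `<path>.meta.json` sidecar is
#'   read when present.
#' @return A `prediction_raster`.
#' @export
read_raster <- function(path) {
  a <- read_ascii_raster(path)
  meta <- list(log10 = FALSE, model_seed = NA)
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) meta <- utils::modifyList(meta, jsonlite::read_json(mp))
  out <- list(values = a$values, lon = a$lon, lat = a$lat,
              res_arcmin = rep(a$cellsize * 60, 2),
              log10 = isTRUE(meta$log10), model_seed = meta$model_seed)
  class(out) <- "prediction_raster"
  out
}

#' Read a predictor grid from per-layer ASCII grid files
#'
#' @param paths Named character vector: layer name -> file path. All layers
#'   must share extent and resolution; misalignment raises an error naming
#'   each layer's geometry.
#' @return A `predictor_grid`.
#' @export
read_grid <- function(paths) {
  stopifnot(length(paths) > 0, !is.null(names(paths)))
  parsed <- lapply(paths, read_ascii_raster)
  geo <- vapply(parsed, function(a)
    sprintf("%dx%d cellsize %.8g origin (%.8g, %.8g)", nrow(a$values),
            ncol(a$values), a$cellsize, min(a$lon), min(a$lat)),
    character(1))
  if (length(unique(geo)) > 1) {
    stop("grid layers are misaligned:\n",
         paste(sprintf("  %s: %s", names(paths), geo), collapse = "\n"))
  }
  first <- parsed[[1]]
  predictor_grid(lapply(parsed, `[[`, "values"), lon = first$lon,
                 lat = first$lat, res_arcmin = rep(first$cellsize * 60, 2))
}

#' Write every layer of a predictor grid as ASCII grids
#'
#' @param grid A `predictor_grid`.
#' @param dir Output directory (created if needed); files are named
#'   `<layer>.asc`.
#' @return Named vector of paths, invisibly.
#' @export
write_grid <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(grid$layers)) {
    r <- list(values = grid$layers[[nm]], lon = grid$lon, lat = grid$lat,
              res_arcmin = grid$res_arcmin, log10 = FALSE, model_seed = NA)
    class(r) <- "prediction_raster"
    p <- file.path(dir, paste0(nm, ".asc"))
    write_raster(r, p)
    paths[nm] <- p
  }
  invisible(paths)
}
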