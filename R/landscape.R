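#' @title Gridded environmental layers
#' @description Container for the four gridded covariate surfaces used by the
#'   morph-cline analysis: urban heat island effect (UHI, degrees C above the
#'   rural surroundings), mean annual temperature (degrees C), mean annual
#'   number of dry days (days/year) and a categorical land-use class. All
#'   grids share one extent and resolution; values are stored as matrices
#'   with row 1 the northernmost row (the Esri ASCII grid convention).
#' @param uhi,temperature,dry_days numeric matrices (same dimensions).
#' @param landuse integer matrix with codes 1-4, see `habitat_levels()`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees
#'   (x = longitude, y = latitude).
#' @param cell_size cell edge in decimal degrees, > 0.
#' @return an object of class `env_layers`.
#' @export
env_layers <- function(uhi, temperature, dry_days, landuse, extent, cell_size) {
  if (cell_size <= 0) stop("cell_size must be positive")
  dims <- lapply(list(uhi, temperature, dry_days, landuse), dim)
  if (length(unique(dims)) != 1L) stop("all layers must share the same grid shape")
  if (any(uhi < 0)) stop("uhi must be non-negative everywhere")
  structure(list(uhi = uhi, temperature = temperature, dry_days = dry_days,
                 landuse = landuse, extent = as.numeric(extent),
                 cell_size = cell_size),
            class = "env_layers")
}

#' Land-use classes
#' @return character vector of the four habitat classes, in code order.
#' @export
habitat_levels <- function() c("agricultural", "nature", "urban_green", "urban_grey")

#' @export
print.env_layers <- function(x, ...) {
  d <- dim(x$uhi)
  cat(sprintf("<env_layers> %d x %d cells of %g deg, extent lon [%g, %g] lat [%g, %g]\n",
              d[1], d[2], x$cell_size, x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  cat(sprintf("  uhi %0.2f-%0.2f degC | temperature %0.2f-%0.2f degC | dry days %0.0f-%0.0f\n",
              min(x$uhi), max(x$uhi), min(x$temperature), max(x$temperature),
              min(x$dry_days), max(x$dry_days)))
  invisible(x)
}

# row/col indices of the grid cell containing each point (nearest-cell lookup,
# no interpolation); points exactly on the max edge fall in the last cell.
.grid_index <- function(layers, latitude, longitude) {
  e <- layers$extent; cs <- layers$cell_size
  d <- dim(layers$uhi)
  out <- longitude < e[1] | longitude > e[2] | latitude < e[3] | latitude > e[4]
  if (any(out))
    stop(sprintf("%d point(s) outside the layer extent", sum(out)))
  col <- pmin(d[2], floor((longitude - e[1]) / cs) + 1L)
  row <- pmin(d[1], floor((e[4] - latitude) / cs) + 1L)
  cbind(row, col)
}

#' Sample all layers at point locations
#'
#' Nearest-cell extraction of every gridded covariate at a set of coordinates.
#'
#' @param layers an [env_layers()] object.
#' @param latitude,longitude numeric vectors of equal length, decimal degrees.
#' @return data.frame with columns `uhi`, `temperature`, `dry_days`, `habitat`.
#' @export
sample_layers <- function(layers, latitude, longitude) {
  idx <- .grid_index(layers, latitude, longitude)
  data.frame(uhi = layers$uhi[idx],
             temperature = layers$temperature[idx],
             dry_days = layers$dry_days[idx],
             habitat = habitat_levels()[layers$landuse[idx]],
             stringsAsFactors = FALSE)
}

#' Assign each record to a habitat class
#'
#' Nearest-cell lookup of the categorical land-use grid: agricultural land,
#' nature (incl. forests), urban green (parks, sport and recreational areas)
#' or urban grey (residential, commercial, industrial).
#'
#' @param records a `shell_records` data.frame, or anything with `latitude`
#'   and `longitude` columns.
#' @param layers an [env_layers()] object.
#' @return character vector of habitat classes, one per record.
#' @export
assign_habitat <- function(records, layers) {
  idx <- .grid_index(layers, records$latitude, records$longitude)
  habitat_levels()[layers$landuse[idx]]
}

# ---- plain-text grid I/O (6-line Esri ASCII header) -------------------------

#' Write a grid as an Esri-convention ASCII raster
#'
#' Plain-text format with a 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows north to south.
#'
#' @param mat numeric matrix, row 1 = northernmost row.
#' @param path output file.
#' @param xll,yll coordinates of the lower-left corner.
#' @param cell_size cell edge in degrees.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(mat, path, xll, yll, cell_size, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(mat)),
               sprintf("nrows %d", nrow(mat)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an Esri-convention ASCII raster
#' @param path file written by [write_ascii_grid()] (or any Esri ASCII grid).
#' @return list with `mat` (matrix, row 1 = north), `xll`, `yll`, `cell_size`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  mat <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(mat) <- NULL
  stopifnot(nrow(mat) == h[["nrows"]], ncol(mat) == h[["ncols"]])
  mat[mat == h[["nodata_value"]]] <- NA
  list(mat = mat, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
       cell_size = h[["cellsize"]])
}

#' Write / read a full layer set as ASCII grids
#'
#' One file per layer (`uhi.asc`, `temperature.asc`, `dry_days.asc`,
#' `landuse.asc`) in `dir`; land use is stored as its integer code.
#'
#' @param layers an [env_layers()] object.
#' @param dir directory (created if needed).
#' @rdname layer_io
#' @export
write_layers <- function(layers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- layers$extent
  for (nm in c("uhi", "temperature", "dry_days", "landuse"))
    write_ascii_grid(layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     xll = e[1], yll = e[3], cell_size = layers$cell_size)
  invisible(dir)
}

#' @param dir directory holding the four `.asc` files.
#' @rdname layer_io
#' @export
read_layers <- function(dir) {
  g <- lapply(c("uhi", "temperature", "dry_days", "landuse"),
              function(nm) read_ascii_grid(file.path(dir, paste0(nm, ".asc"))))
  x <- g[[1]]
  extent <- c(x$xll, x$xll + ncol(x$mat) * x$cell_size,
              x$yll, x$yll + nrow(x$mat) * x$cell_size)
  env_layers(g[[1]]$mat, g[[2]]$mat, g[[3]]$mat,
             matrix(as.integer(g[[4]]$mat), nrow(g[[4]]$mat)),
             extent = extent, cell_size = x$cell_size)
}
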