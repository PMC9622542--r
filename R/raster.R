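# Grids are plain numeric/integer matrices, row 1 = northernmost row,
# column 1 = westernmost column. Areas are cell counts times cell_size^2.

#' Land-use and soil class codes
#'
#' Integer codes used in land-use and soils grids throughout the package.
#' Land use: 1 = agriculture, 2 = developed, 3 = natural, 4 = open water.
#' Soils: 0 = other, 1 = A/D, 2 = B/D, 3 = C/D (the dual-class hydrologic
#' soil groups treated as high water-storage potential).
#'
#' @format Named integer vectors.
#' @name class-codes
NULL

#' @rdname class-codes
#' @export
landuse_codes <- function() {
  c(agriculture = 1L, developed = 2L, natural = 3L, water = 4L)
}

#' @rdname class-codes
#' @export
soil_codes <- function() {
  c(other = 0L, `A/D` = 1L, `B/D` = 2L, `C/D` = 3L)
}

#' Bundle co-registered grids into a raster stack
#'
#' A raster stack holds the five landscape grids consumed by the screening
#' pipeline: elevation (m), land-use classes, soil classes, a binary
#' 100-year-floodplain mask and a binary above-average climate-flow mask.
#' All grids must share dimensions.
#'
#' @param dem Numeric elevation matrix (meters).
#' @param landuse Integer matrix of land-use codes (see [landuse_codes()]).
#' @param soils Integer matrix of soil codes (see [soil_codes()]).
#' @param floodplain Binary (0/1) matrix.
#' @param climateflow Binary (0/1) matrix.
#' @param cell_size Cell side length in meters (> 0).
#' @param nodata Value marking missing cells in `dem` (stored as `NA`
#'   internally).
#' @return An object of class `raster_stack`: a list with the five grids plus
#'   `cell_size` and `nodata`.
#' @export
raster_stack <- function(dem, landuse, soils, floodplain, climateflow,
                         cell_size, nodata = -9999) {
  grids <- list(dem = dem, landuse = landuse, soils = soils,
                floodplain = floodplain, climateflow = climateflow)
  dims <- vapply(grids, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all grids in a raster_stack must share dimensions")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  dem[dem == nodata] <- NA_real_
  structure(list(dem = dem, landuse = landuse, soils = soils,
                 floodplain = floodplain, climateflow = climateflow,
                 cell_size = cell_size, nodata = nodata),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d x %d cells, cell size %g m\n",
              nrow(x$dem), ncol(x$dem), x$cell_size))
  cat(sprintf("  dem range: [%g, %g] m; %d nodata cells\n",
              min(x$dem, na.rm = TRUE), max(x$dem, na.rm = TRUE),
              sum(is.na(x$dem))))
  invisible(x)
}

#' Read and write Esri ASCII grids
#'
#' Single-band grid exchange in the plain-text Esri ASCII raster format
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header
#' followed by rows north to south).
#'
#' @param path File path.
#' @param grid Numeric matrix, row 1 = north.
#' @param cell_size Cell side length written to the header.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata Value written for `NA` cells.
#' @return `read_esri_ascii` returns a numeric matrix with attributes
#'   `cell_size`, `xll`, `yll` (`NA` where the file holds the nodata value);
#'   `write_esri_ascii` returns `path` invisibly.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("missing '", key, "' in Esri ASCII header")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("Esri ASCII body has ", length(vals), " values, expected ", nr * nc)
  g <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) g[g == hdr$nodata_value] <- NA_real_
  attr(g, "cell_size") <- hdr$cellsize
  attr(g, "xll") <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  attr(g, "yll") <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  g
}

#' @rdname read_esri_ascii
#' @export
write_esri_ascii <- function(grid, path, cell_size = attr(grid, "cell_size"),
                             xll = 0, yll = 0, nodata = -9999) {
  if (is.null(cell_size)) cell_size <- 1
  g <- grid
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(g)),
           sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.6g", xll),
           sprintf("yllcorner %.6g", yll),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(g, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a raster stack as Esri ASCII grids
#'
#' Writes one `.asc` file per layer (`dem.asc`, `landuse.asc`, `soils.asc`,
#' `floodplain.asc`, `climateflow.asc`) into `dir`.
#'
#' @param stack A [raster_stack()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_raster_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (layer in c("dem", "landuse", "soils", "floodplain", "climateflow"))
    write_esri_ascii(stack[[layer]], file.path(dir, paste0(layer, ".asc")),
                     cell_size = stack$cell_size, nodata = stack$nodata)
  invisible(dir)
}
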