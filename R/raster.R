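#' Raster grids
#'
#' A minimal georeferenced raster: a numeric matrix of cell values plus cell
#' size (km), the x/y of the lower-left corner, and an `NA` nodata convention.
#' Row 1 of the matrix is the TOP row of the map (the ESRI ASCII reading
#' order); cell centres are at `x = xll + (col - 0.5) * cell_size`,
#' `y = yll + (nrow - row + 0.5) * cell_size`.
#'
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param cell_size Cell edge length in km.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1, xll = 0, yll = 0) {
  stopifnot(is.matrix(values), cell_size > 0)
  structure(list(values = values, cell_size = cell_size, xll = xll, yll = yll),
            class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("# raster_grid %dx%d, cell %g km, origin (%g, %g), range [%g, %g], %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of every cell
#'
#' @param x A `raster_grid`.
#' @return Tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
raster_coords <- function(x) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  cx <- x$xll + (g$col - 0.5) * x$cell_size
  cy <- x$yll + (nr - g$row + 0.5) * x$cell_size
  val <- x$values[cbind(g$row, g$col)]
  tibble::tibble(row = g$row, col = g$col, x = cx, y = cy, value = val)
}

#' Read and write ESRI ASCII grids
#'
#' The six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) is followed by rows of cell values, first row
#' northernmost. Nodata cells are `NA` in the `raster_grid` and written back
#' as the nodata marker.
#'
#' @param path File path.
#' @return `read_ascii_grid()` returns a [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII header incomplete in ", path, " (line ", i, ")")
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("expected ", hdr$ncols * hdr$nrows, " cells, found ", length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, cell_size = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @param grid A [raster_grid()].
#' @param nodata Numeric marker written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", format(grid$xll, trim = TRUE)),
           paste("yllcorner", format(grid$yll, trim = TRUE)),
           paste("cellsize", format(grid$cell_size, trim = TRUE)),
           paste("NODATA_value", nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Plot a raster grid
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_coords(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)")
}
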