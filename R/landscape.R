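#' Rescale a raster linearly to the 1-100 resistance range
#'
#' `v -> 1 + 99 * (v - min) / (max - min)` over valid cells; with
#' `invert = TRUE` the map is applied to `max - v` so that low input values
#' get high resistance. A constant raster maps to all 1.
#'
#' @param grid A [raster_grid()].
#' @param invert Reverse the direction of the mapping.
#' @return A [raster_grid()] with values in `[1, 100]` (NA preserved).
#' @export
rescale_1_100 <- function(grid, invert = FALSE) {
  v <- grid$values
  ok <- !is.na(v)
  if (!any(ok)) stop("all-nodata raster cannot be rescaled")
  lo <- min(v[ok]); hi <- max(v[ok])
  out <- v
  if (hi == lo) {
    out[ok] <- 1
  } else {
    x <- if (invert) hi - v[ok] else v[ok] - lo
    out[ok] <- pmin(100, pmax(1, 1 + 99 * x / (hi - lo)))
  }
  raster_grid(out, grid$cell_size, grid$xll, grid$yll)
}

# distance (km) of every cell to the nearest TRUE cell of `mask`
distance_to <- function(mask, cell_size) {
  stopifnot(any(mask))
  d <- as.matrix(EBImage::distmap(1 - mask))
  d * cell_size
}

#' Habitat patches and habitat-proximity resistance
#'
#' Cells of the listed land-cover classes form the habitat mask; its
#' 8-connected components with area strictly greater than `min_patch_km2`
#' are the retained patches. Resistance is the rescaled Euclidean distance
#' to the nearest retained patch, with habitat cells themselves at the
#' minimum resistance of 1.
#'
#' @param landcover A [raster_grid()] of class codes.
#' @param habitat_classes Codes counting as habitat.
#' @param min_patch_km2 Patch-area filter (area must exceed this).
#' @return List with `resistance` (a [raster_grid()] in `[1, 100]`),
#'   `patches` (a [raster_grid()] of patch labels, NA off-patch) and
#'   `patch_areas` (tibble `patch`, `area_km2`).
#' @export
habitat_resistance <- function(landcover, habitat_classes = 1,
                               min_patch_km2 = 10) {
  mask <- !is.na(landcover$values) & landcover$values %in% habitat_classes
  lab <- label_components(mask)
  cell_area <- landcover$cell_size^2
  areas <- table(lab[lab > 0]) * cell_area
  keep <- as.integer(names(areas)[areas > min_patch_km2])
  if (length(keep) == 0) stop("no habitat patch larger than ", min_patch_km2, " km2")
  retained <- matrix(match(lab, keep), nrow(lab), ncol(lab))
  dist <- distance_to(!is.na(retained), landcover$cell_size)
  res <- rescale_1_100(raster_grid(dist, landcover$cell_size,
                                   landcover$xll, landcover$yll))
  res$values[!is.na(retained)] <- 1
  list(resistance = res,
       patches = raster_grid(retained, landcover$cell_size,
                             landcover$xll, landcover$yll),
       patch_areas = tibble::tibble(patch = seq_along(keep),
                                    area_km2 = as.numeric(areas[as.character(keep)])))
}

# 8-connected component labels of a logical matrix (0 = background)
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  rc <- cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
  key <- function(r, c) (c - 1) * nr + r
  pos <- stats::setNames(seq_along(idx), idx)
  edges <- list()
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in seq_len(nrow(shifts))) {
    r2 <- rc[, 1] + shifts[s, 1]
    c2 <- rc[, 2] + shifts[s, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges[[s]] <- cbind(pos[as.character(key(rc[ok, 1], rc[ok, 2]))],
                          pos[as.character(key(r2[ok], c2[ok]))])
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges) %||%
                                     matrix(integer(0), 0, 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Settlement-proximity resistance and urban mask
#'
#' Illuminated cells (light value > 0) are settlements; resistance is the
#' inverted rescale of the distance to the nearest settlement, so cells at
#' or near settlements get 100 and the farthest cell gets 1. Cells with
#' light above `urban_threshold` form the urban mask that is later removed
#' from the landscape graph entirely.
#'
#' @param lights A [raster_grid()] of night-light radiance.
#' @param urban_threshold Radiance above which a cell is an urban centre.
#' @return List with `resistance` ([raster_grid()]), `urban` (logical
#'   matrix) and `settlement` (logical matrix of illuminated cells).
#' @export
settlement_resistance <- function(lights, urban_threshold = 20) {
  v <- lights$values
  settlement <- !is.na(v) & v > 0
  urban <- !is.na(v) & v > urban_threshold
  if (!any(settlement)) {
    res <- raster_grid(matrix(1, nrow(v), ncol(v)), lights$cell_size,
                       lights$xll, lights$yll)
    return(list(resistance = res, urban = urban, settlement = settlement))
  }
  dist <- distance_to(settlement, lights$cell_size)
  res <- rescale_1_100(raster_grid(dist, lights$cell_size,
                                   lights$xll, lights$yll), invert = TRUE)
  list(resistance = res, urban = urban, settlement = settlement)
}

#' Road-density resistance
#'
#' Per-cell road density is the total polyline length falling inside the
#' cell (exact segment clipping) divided by the cell area (km per km2);
#' the resistance layer is its 1-100 rescale, with road-free cells at 1.
#'
#' @param roads Tibble of polyline vertices (`road`, `x`, `y`), in the
#'   grid's coordinate system (km).
#' @param grid A [raster_grid()] defining the cell geometry.
#' @return List with `resistance` and `density` (both [raster_grid()]).
#' @export
road_resistance <- function(roads, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  dens <- matrix(0, nr, nc)
  for (rd in split(roads, roads$road)) {
    for (s in seq_len(nrow(rd) - 1)) {
      seg <- clip_segment_to_cells(rd$x[s] - grid$xll, rd$y[s] - grid$yll,
                                   rd$x[s + 1] - grid$xll, rd$y[s + 1] - grid$yll,
                                   nr, nc, cs)
      if (is.null(seg)) next
      for (q in seq_len(nrow(seg))) {
        dens[seg[q, 1], seg[q, 2]] <- dens[seg[q, 1], seg[q, 2]] + seg[q, 3]
      }
    }
  }
  dens <- dens / cs^2
  density <- raster_grid(dens, cs, grid$xll, grid$yll)
  res <- rescale_1_100(density)
  if (all(dens == 0)) res$values[] <- 1
  list(resistance = res, density = density)
}

# exact lengths of one segment inside each crossed cell; returns matrix
# (row, col, length) or NULL if fully outside. Coordinates relative to the
# grid's lower-left corner; row 1 = top row.
clip_segment_to_cells <- function(x1, y1, x2, y2, nr, nc, cs) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len == 0) return(NULL)
  # breakpoints where the segment crosses cell boundaries
  ts <- c(0, 1)
  for (k in 0:nc) {
    xb <- k * cs
    if ((x1 < xb && x2 > xb) || (x1 > xb && x2 < xb)) {
      ts <- c(ts, (xb - x1) / (x2 - x1))
    }
  }
  for (k in 0:nr) {
    yb <- k * cs
    if ((y1 < yb && y2 > yb) || (y1 > yb && y2 < yb)) {
      ts <- c(ts, (yb - y1) / (y2 - y1))
    }
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  out <- NULL
  for (q in seq_len(length(ts) - 1)) {
    tm <- (ts[q] + ts[q + 1]) / 2
    xm <- x1 + tm * (x2 - x1)
    ym <- y1 + tm * (y2 - y1)
    col <- floor(xm / cs) + 1
    row <- nr - floor(ym / cs)
    if (col < 1 || col > nc || row < 1 || row > nr) next
    out <- rbind(out, c(row, col, (ts[q + 1] - ts[q]) * len))
  }
  out
}

#' Study-area mask from habitat patches and the urban mask
#'
#' Valid cells lie within `buffer_km` of a retained habitat patch and are
#' not urban; everything else becomes nodata in every layer it is applied
#' to.
#'
#' @param patches Patch-label [raster_grid()] (from [habitat_resistance()]).
#' @param urban Logical urban matrix (from [settlement_resistance()]).
#' @param buffer_km Buffer distance around patches.
#' @return Logical matrix of valid cells.
#' @export
study_area <- function(patches, urban = NULL, buffer_km = 30) {
  dist <- distance_to(!is.na(patches$values), patches$cell_size)
  valid <- dist <= buffer_km
  if (!is.null(urban)) valid <- valid & !urban
  if (!any(valid)) stop("empty study area")
  valid
}

#' Apply a validity mask to a layer
#'
#' @param grid A [raster_grid()].
#' @param valid Logical matrix from [study_area()].
#' @export
mask_layer <- function(grid, valid) {
  v <- grid$values
  v[!valid] <- NA
  raster_grid(v, grid$cell_size, grid$xll, grid$yll)
}

#' Combine resistance layers
#'
#' Cell-wise weighted arithmetic mean of co-registered 1-100 layers,
#' rescaled back to 1-100; nodata propagates.
#'
#' @param layers List of [raster_grid()] layers.
#' @param weights Numeric weights (default equal).
#' @return A [raster_grid()] in `[1, 100]`.
#' @export
combine_layers <- function(layers, weights = NULL) {
  stopifnot(length(layers) >= 1)
  dims <- vapply(layers, function(l) dim(l$values), numeric(2))
  if (any(dims != dims[, 1])) stop("layer shape mismatch")
  if (is.null(weights)) weights <- rep(1, length(layers))
  weights <- weights / sum(weights)
  acc <- matrix(0, nrow(layers[[1]]$values), ncol(layers[[1]]$values))
  for (i in seq_along(layers)) acc <- acc + weights[i] * layers[[i]]$values
  rescale_1_100(raster_grid(acc, layers[[1]]$cell_size,
                            layers[[1]]$xll, layers[[1]]$yll))
}
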