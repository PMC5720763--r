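# Gridded-surface geometry and map rendering. Coordinates are WGS84 decimal
# degrees throughout, rasters are north-up, and cells are registered on
# their centroids.

#' Infer the cell geometry of a centroid lattice
#'
#' Cell sizes are inferred per axis as the mode of the positive gaps between
#' sorted unique coordinates (ties resolved to the smallest gap), so the
#' inference tolerates missing cells in an otherwise regular lattice. The
#' extent is the centroid bounding box padded by half a cell.
#'
#' @param lons,lats Cell centroid coordinate vectors (>= 2 distinct values
#'   each).
#' @return A `cell_geometry` list: `dx`, `dy`, `extent`
#'   (`xmin`, `xmax`, `ymin`, `ymax`).
#' @export
auto_cell_size <- function(lons, lats) {
  dx <- gap_mode(lons, "longitude")
  dy <- gap_mode(lats, "latitude")
  structure(
    list(
      dx = dx, dy = dy,
      extent = c(
        xmin = min(lons) - dx / 2, xmax = max(lons) + dx / 2,
        ymin = min(lats) - dy / 2, ymax = max(lats) + dy / 2
      )
    ),
    class = "cell_geometry"
  )
}

gap_mode <- function(coords, axis) {
  u <- sort(unique(coords))
  if (length(u) < 2) {
    abort(paste0("cannot infer cell size: a single distinct ", axis,
                 " value"))
  }
  gaps <- round(diff(u), 10)  # collapse FP jitter before tabulating
  tab <- table(gaps)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}

#' Rasterize per-cell values onto the inferred lattice
#'
#' Places `(lon, lat, value)` triples into a north-up matrix addressed by the
#' cell geometry. Values are placed, never resampled; absent cells become
#' `NA`. Centroids must sit on the lattice within 1e-6 degrees.
#'
#' @param cells A data frame with columns `longitude`, `latitude`, `value`
#'   (or the three first columns in that order).
#' @param geom A [auto_cell_size()] geometry; inferred from the cells when
#'   omitted.
#' @return A `geo_raster`: list with `values` (matrix, row 1 = northernmost
#'   row), `geom`.
#' @export
rasterize_surface <- function(cells, geom = NULL) {
  cells <- as_tibble(cells)
  if (!all(c("longitude", "latitude", "value") %in% names(cells))) {
    names(cells)[1:3] <- c("longitude", "latitude", "value")
  }
  if (is.null(geom)) geom <- auto_cell_size(cells$longitude, cells$latitude)
  x0 <- geom$extent[["xmin"]] + geom$dx / 2
  y0 <- geom$extent[["ymin"]] + geom$dy / 2
  ci <- (cells$longitude - x0) / geom$dx
  ri <- (cells$latitude - y0) / geom$dy
  off <- abs(ci - round(ci)) * geom$dx > 1e-6 |
    abs(ri - round(ri)) * geom$dy > 1e-6
  if (any(off)) {
    k <- which(off)[1]
    abort(paste0("cell centroid off-lattice at lon=", cells$longitude[k],
                 ", lat=", cells$latitude[k]))
  }
  ncol_r <- round((geom$extent[["xmax"]] - geom$extent[["xmin"]]) / geom$dx)
  nrow_r <- round((geom$extent[["ymax"]] - geom$extent[["ymin"]]) / geom$dy)
  m <- matrix(NA_real_, nrow = nrow_r, ncol = ncol_r)
  # row 1 is the northernmost row
  m[cbind(nrow_r - round(ri), round(ci) + 1)] <- cells$value
  structure(list(values = m, geom = geom), class = "geo_raster")
}

#' Recover cell triples from a raster
#'
#' The inverse of [rasterize_surface()] on aligned inputs: returns the
#' non-missing cells as centroid/value triples.
#'
#' @param raster A `geo_raster`.
#' @return A tibble with `longitude`, `latitude`, `value`.
#' @export
raster_cells <- function(raster) {
  stopifnot(inherits(raster, "geo_raster"))
  g <- raster$geom
  m <- raster$values
  idx <- which(!is.na(m), arr.ind = TRUE)
  tibble(
    longitude = g$extent[["xmin"]] + (idx[, 2] - 0.5) * g$dx,
    latitude = g$extent[["ymax"]] - (idx[, 1] - 0.5) * g$dy,
    value = m[idx]
  ) |> arrange(.data$longitude, .data$latitude)
}

#' Export a raster as an ESRI ASCII grid
#'
#' Writes the plain-text `.asc` format (NCOLS/NROWS header, centroid-derived
#' lower-left corner, row-major values north to south) readable by any GIS.
#' The format carries a single cell size, so `dx` and `dy` must agree.
#'
#' @param raster A `geo_raster`.
#' @param path Output path.
#' @param nodata Missing-data code (default -9999).
#' @return The path, invisibly.
#' @export
write_ascii_raster <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "geo_raster"))
  g <- raster$geom
  if (abs(g$dx - g$dy) > 1e-9) {
    abort("ESRI ASCII grids require square cells (dx == dy)")
  }
  m <- raster$values
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("NCOLS", ncol(m)), paste("NROWS", nrow(m)),
    paste("XLLCORNER", format(g$extent[["xmin"]], digits = 15)),
    paste("YLLCORNER", format(g$extent[["ymin"]], digits = 15)),
    paste("CELLSIZE", format(g$dx, digits = 15)),
    paste("NODATA_VALUE", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, digits = 15,
                                               trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Crop coastline polygons to a study extent
#'
#' Reads polygons from a GeoJSON file (`Polygon` / `MultiPolygon` geometries,
#' bare or in a `FeatureCollection`) and clips every ring to the extent
#' rectangle with the Sutherland–Hodgman algorithm. An empty result (open
#' ocean) is allowed.
#'
#' @param polygon_file Path to a GeoJSON file.
#' @param extent Named vector `c(xmin, xmax, ymin, ymax)` (a
#'   `cell_geometry$extent` works directly).
#' @return A tibble of ring vertices: `poly`, `ring`, `x`, `y`; zero rows
#'   when nothing intersects the extent.
#' @export
crop_basemap <- function(polygon_file, extent) {
  rings <- read_geojson_rings(polygon_file)
  out <- list()
  for (i in seq_along(rings)) {
    cl <- clip_ring(rings[[i]], extent)
    if (!is.null(cl) && nrow(cl) >= 3) {
      out[[length(out) + 1]] <- tibble(
        poly = attr(rings[[i]], "poly"), ring = attr(rings[[i]], "ring"),
        x = cl[, 1], y = cl[, 2]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(poly = integer(0), ring = integer(0),
                  x = numeric(0), y = numeric(0)))
  }
  list_rbind(out)
}

read_geojson_rings <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("invalid GeoJSON in '", path, "': ",
                                     conditionMessage(e)))
  )
  geoms <- if (identical(gj$type, "FeatureCollection")) {
    lapply(gj$features, function(f) f$geometry)
  } else if (identical(gj$type, "Feature")) {
    list(gj$geometry)
  } else {
    list(gj)
  }
  rings <- list()
  pid <- 0L
  for (g in geoms) {
    pid <- pid + 1L
    polys <- switch(g$type %||% "",
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      abort(paste0("unsupported geometry type: ", g$type %||% "<none>"))
    )
    for (p in polys) {
      for (ri in seq_along(p)) {
        coords <- p[[ri]]
        m <- matrix(unlist(coords), ncol = 2, byrow = TRUE)
        # drop the GeoJSON closing vertex; rings here are implicitly closed
        if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
          m <- m[-nrow(m), , drop = FALSE]
        }
        attr(m, "poly") <- pid
        attr(m, "ring") <- ri
        rings[[length(rings) + 1]] <- m
      }
    }
  }
  rings
}

# Sutherland–Hodgman clip of one ring (n x 2 matrix, open) against the
# axis-aligned rectangle; returns NULL when nothing remains.
clip_ring <- function(ring, extent) {
  inside <- list(
    function(p) p[1] >= extent[["xmin"]],
    function(p) p[1] <= extent[["xmax"]],
    function(p) p[2] >= extent[["ymin"]],
    function(p) p[2] <= extent[["ymax"]]
  )
  intersect_edge <- list(
    function(a, b) {
      t <- (extent[["xmin"]] - a[1]) / (b[1] - a[1])
      c(extent[["xmin"]], a[2] + t * (b[2] - a[2]))
    },
    function(a, b) {
      t <- (extent[["xmax"]] - a[1]) / (b[1] - a[1])
      c(extent[["xmax"]], a[2] + t * (b[2] - a[2]))
    },
    function(a, b) {
      t <- (extent[["ymin"]] - a[2]) / (b[2] - a[2])
      c(a[1] + t * (b[1] - a[1]), extent[["ymin"]])
    },
    function(a, b) {
      t <- (extent[["ymax"]] - a[2]) / (b[2] - a[2])
      c(a[1] + t * (b[1] - a[1]), extent[["ymax"]])
    }
  )
  pts <- ring
  for (e in seq_along(inside)) {
    if (nrow(pts) == 0) return(NULL)
    keep <- inside[[e]]
    cross <- intersect_edge[[e]]
    out <- list()
    n <- nrow(pts)
    for (i in seq_len(n)) {
      a <- pts[i, ]
      b <- pts[if (i == n) 1 else i + 1, ]
      a_in <- keep(a)
      b_in <- keep(b)
      if (a_in) out[[length(out) + 1]] <- a
      if (xor(a_in, b_in)) out[[length(out) + 1]] <- cross(a, b)
    }
    if (length(out) == 0) return(NULL)
    pts <- do.call(rbind, out)
  }
  pts
}

# Shoelace area of a ring tibble/matrix (absolute value).
ring_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Render a surface as a PNG map
#'
#' Draws a per-cell surface (a `geo_raster`, a `prediction_surface`, or any
#' tibble with `longitude`, `latitude` and a value column) as a north-up
#' ggplot2 raster map and writes it to `out`. Missing cells are drawn in a
#' neutral grey distinguishable from low values; a coastline overlay (from
#' [crop_basemap()]) is clipped to the map extent.
#'
#' @param surface The surface to draw.
#' @param value Name of the value column (ignored for `geo_raster`).
#' @param palette `"viridis"` (colour) or `"greys"` (monotone-luminance
#'   greyscale).
#' @param legend Legend title; extra lines (e.g. an effort-overlap note)
#'   are kept verbatim.
#' @param coastline Optional ring tibble from [crop_basemap()].
#' @param out Output PNG path; `NULL` returns the plot unwritten.
#' @param width_px,height_px Image size in pixels.
#' @return The ggplot object, invisibly (written to `out` when given).
#' @export
render_map <- function(surface, value = "combined_index",
                       palette = c("viridis", "greys"), legend = value,
                       coastline = NULL, out = NULL,
                       width_px = 1920, height_px = 1440) {
  palette <- match.arg(palette)
  cells <- if (inherits(surface, "geo_raster")) {
    rename(raster_cells(surface), value = "value")
  } else {
    tibble(longitude = surface$longitude, latitude = surface$latitude,
           value = surface[[value]])
  }
  g <- auto_cell_size(cells$longitude, cells$latitude)
  p <- ggplot(cells, aes(.data$longitude, .data$latitude)) +
    geom_raster(aes(fill = .data$value)) +
    coord_cartesian(
      xlim = g$extent[c("xmin", "xmax")], ylim = g$extent[c("ymin", "ymax")],
      expand = FALSE
    ) +
    labs(x = "Longitude", y = "Latitude", fill = legend) +
    theme_minimal()
  p <- if (palette == "viridis") {
    p + scale_fill_viridis_c(na.value = "grey80")
  } else {
    p + scale_fill_gradient(low = "grey95", high = "grey5",
                            na.value = "white")
  }
  if (!is.null(coastline) && nrow(coastline) > 0) {
    p <- p + geom_polygon(
      data = coastline,
      aes(.data$x, .data$y, group = interaction(.data$poly, .data$ring)),
      fill = "grey60", colour = "grey30", linewidth = 0.2,
      inherit.aes = FALSE
    )
  }
  if (!is.null(out)) {
    ggsave(out, p, width = width_px, height = height_px, units = "px",
           dpi = 300)
  }
  invisible(p)
}
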