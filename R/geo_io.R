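#' Read a demand or supply point table
#'
#' Reads point tables from delimited text (UTF-8, header row, `.`
#' decimal; delimiter inferred from the extension, comma by default) or
#' from a GeoJSON FeatureCollection of Point features. Coordinates are
#' planar metres (easting `x`, northing `y`); input that looks like
#' unprojected longitude/latitude is rejected with guidance to project
#' first, unless `allow_geographic = TRUE`.
#'
#' @param path File path (`.csv`, `.tsv`/`.txt`, `.geojson`/`.json`).
#' @param role `"demand"` (needs `population`) or `"supply"` (optional
#'   `capacity`, default 1).
#' @param allow_geographic Skip the longitude/latitude magnitude check.
#' @return A validated tibble (see [as_demand_points()] /
#'   [as_supply_points()]).
#' @export
read_points <- function(path, role = c("demand", "supply"),
                        allow_geographic = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path),
          class = "e2sfca_error_missing_file")
  }
  raw <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    geojson_to_table(jsonlite::read_json(path))
  } else {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
             else ","
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE)
  }
  pts <- if (role == "demand") as_demand_points(raw) else
    as_supply_points(raw)
  check_planar(pts, allow_geographic, what = role)
  pts
}

#' Write a point table
#'
#' Writes any point table (demand, supply, accessibility surface,
#' hot-spot table) as delimited text or GeoJSON, chosen from the file
#' extension. GeoJSON output is an RFC 7946-shaped FeatureCollection of
#' Point features whose coordinates are planar metres, flagged by a
#' top-level `"coordinate_system": "planar_metres"` member; all columns
#' other than `x`/`y` become feature properties.
#'
#' @param data A data frame with numeric `x` and `y` columns.
#' @param path Output path (`.csv`, `.tsv`, `.geojson`/`.json`).
#' @return `path`, invisibly.
#' @export
write_points <- function(data, path) {
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    write_points_geojson(data, path)
  } else if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

write_points_geojson <- function(data, path) {
  props <- setdiff(names(data), c("x", "y"))
  features <- purrr::pmap(data, function(...) {
    row <- list(...)
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(row$x, row$y)),
      properties = row[props]
    )
  })
  fc <- list(type = "FeatureCollection",
             coordinate_system = "planar_metres",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

geojson_to_table <- function(gj) {
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort("GeoJSON input must be a FeatureCollection",
          class = "e2sfca_error_bad_geojson")
  }
  purrr::map_dfr(gj$features, function(f) {
    if (is.null(f$geometry) || f$geometry$type != "Point") {
      abort("GeoJSON features must be Points",
            class = "e2sfca_error_bad_geojson")
    }
    co <- unlist(f$geometry$coordinates)
    props <- purrr::map(f$properties, function(p) if (is.null(p)) NA else p)
    tibble::as_tibble(c(list(x = co[1], y = co[2]), props))
  })
}

#' Planning-area polygons
#'
#' Bundles named simple polygons (same planar CRS as the points) for
#' area labelling. Each area is one or more rings given as two-column
#' matrices or data frames of vertices; rings may repeat the first
#' vertex at the end or leave closure implicit.
#'
#' @param names Character vector of unique area names.
#' @param polygons A list, one element per area, each a ring or list of
#'   rings (two-column `x`,`y` matrices).
#' @return An `area_polygons` tibble with columns `name` and `rings`.
#' @examples
#' sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
#' areas <- area_polygons("A", list(sq))
#' @export
area_polygons <- function(names, polygons) {
  if (anyDuplicated(names)) {
    abort("area names must be unique", class = "e2sfca_error_duplicate_id")
  }
  if (length(names) != length(polygons)) {
    abort("`names` and `polygons` must align",
          class = "e2sfca_error_length_mismatch")
  }
  rings <- purrr::map(polygons, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(p)
    purrr::map(p, function(ring) {
      ring <- as.matrix(ring)
      storage.mode(ring) <- "double"
      if (ncol(ring) != 2 || nrow(ring) < 3) {
        abort("each ring needs >= 3 vertices with 2 coordinates",
              class = "e2sfca_error_bad_polygon")
      }
      # drop an explicit closing vertex; closure is implicit
      if (all(ring[1, ] == ring[nrow(ring), ])) {
        ring <- ring[-nrow(ring), , drop = FALSE]
      }
      if (nrow(ring) < 3) {
        abort("each ring needs >= 3 distinct vertices",
              class = "e2sfca_error_bad_polygon")
      }
      ring
    })
  })
  structure(tibble::tibble(name = as.character(names), rings = rings),
            class = c("area_polygons", class(tibble::tibble())))
}

#' Read planning areas from GeoJSON
#'
#' Reads a FeatureCollection of Polygon / MultiPolygon features; the
#' area name is taken from the `name` property (falling back to
#' `area_label`, then a running number). Coordinates are interpreted as
#' planar metres.
#'
#' @param path GeoJSON file path.
#' @return An [area_polygons()] set.
#' @export
read_areas <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort("GeoJSON input must be a FeatureCollection",
          class = "e2sfca_error_bad_geojson")
  }
  ring_to_matrix <- function(ring) {
    do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
  }
  nms <- character(0)
  polys <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    nm <- f$properties$name %||% f$properties$area_label %||%
      paste0("area_", i)
    rings <- switch(
      f$geometry$type,
      Polygon = purrr::map(f$geometry$coordinates, ring_to_matrix),
      MultiPolygon = purrr::flatten(purrr::map(
        f$geometry$coordinates,
        function(poly) purrr::map(poly, ring_to_matrix))),
      abort(paste0("unsupported geometry type: ", f$geometry$type),
            class = "e2sfca_error_bad_geojson")
    )
    nms <- c(nms, nm)
    polys <- c(polys, list(rings))
  }
  area_polygons(nms, polys)
}

#' Write planning areas to GeoJSON
#'
#' @param areas An [area_polygons()] set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_areas <- function(areas, path) {
  stopifnot(inherits(areas, "area_polygons"))
  features <- purrr::map2(areas$name, areas$rings, function(nm, rings) {
    coords <- purrr::map(rings, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      purrr::map(seq_len(nrow(closed)),
                 function(i) c(closed[i, 1], closed[i, 2]))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(name = nm))
  })
  fc <- list(type = "FeatureCollection",
             coordinate_system = "planar_metres",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# Even-odd (ray casting) containment of points in a set of rings, with
# points exactly on a ring edge counted as inside. Vectorized over
# points, looping over edges.
points_in_rings <- function(px, py, rings, eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in rings) {
    nv <- nrow(ring)
    j <- nv
    for (i in seq_len(nv)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      # boundary test: collinear with the edge and within its bbox
      cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
      seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
      on_seg <- abs(cross) <= eps * max(seg_len, 1) &
        px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
        py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
      on_edge <- on_edge | on_seg
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside | on_edge
}

#' Label points with their containing planning area
#'
#' Assigns each point the name of the first area (in file order) that
#' contains it under the even-odd rule; points exactly on a boundary
#' belong to the first containing area, and points inside no area get
#' `NA`. Points and areas are assumed to share the same planar CRS.
#' The result does not depend on the order of the points.
#'
#' @param points A data frame with numeric `x` and `y` columns.
#' @param areas An [area_polygons()] set.
#' @return `points` with an `area_label` column (existing labels are
#'   overwritten).
#' @export
label_points <- function(points, areas) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)),
            inherits(areas, "area_polygons"))
  lab <- rep(NA_character_, nrow(points))
  for (i in seq_len(nrow(areas))) {
    todo <- is.na(lab)
    if (!any(todo)) break
    hit <- points_in_rings(points$x[todo], points$y[todo],
                           areas$rings[[i]])
    lab[todo][hit] <- areas$name[i]
  }
  points$area_label <- lab
  tibble::as_tibble(points)
}
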