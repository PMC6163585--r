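#' Validate a demand-point table
#'
#' Demand points are residential blocks: an `id`, planar coordinates `x`/`y`
#' in metres (easting/northing, already projected -- the package never
#' reprojects), and `population`, the elderly head count used as the
#' demand weight. An optional `area_label` column carries a planning-area
#' name for summaries.
#'
#' @param data A data frame with columns `id`, `x`, `y`, `population` and
#'   optionally `area_label`.
#' @return A tibble with the validated columns, `id` as character,
#'   coordinates as double and `population` as a non-negative double.
#' @examples
#' as_demand_points(data.frame(id = "b1", x = 0, y = 0, population = 120))
#' @export
as_demand_points <- function(data) {
  pts <- validate_points(data, required = c("id", "x", "y", "population"),
                         what = "demand")
  bad <- which(pts$population < 0)
  if (length(bad) > 0) {
    abort(
      paste0("`population` must be non-negative; offending row(s): ",
             paste(bad, collapse = ", ")),
      class = "e2sfca_error_negative_population"
    )
  }
  pts
}

#' Validate a supply-point table
#'
#' Supply points are clinics: an `id`, planar coordinates in metres and a
#' positive `capacity`. Capacity defaults to 1 when the column is absent,
#' reflecting the one-provider-per-clinic convention that avoids
#' overstating provider-to-population ratios.
#'
#' @param data A data frame with columns `id`, `x`, `y` and optionally
#'   `capacity`.
#' @return A tibble with validated columns; `capacity` is filled with 1
#'   when missing from the input.
#' @examples
#' as_supply_points(data.frame(id = "c1", x = 100, y = 50))
#' @export
as_supply_points <- function(data) {
  if (!"capacity" %in% names(data)) data$capacity <- 1
  pts <- validate_points(data, required = c("id", "x", "y", "capacity"),
                         what = "supply")
  bad <- which(!(pts$capacity > 0))
  if (length(bad) > 0) {
    abort(
      paste0("`capacity` must be positive; offending row(s): ",
             paste(bad, collapse = ", ")),
      class = "e2sfca_error_nonpositive_capacity"
    )
  }
  pts
}

# Shared column/type/id checks for both point roles. Distinct error classes
# so callers (and tests) can tell a missing column from a bad value.
validate_points <- function(data, required, what) {
  if (!is.data.frame(data)) {
    abort(paste0(what, " points must be a data frame"),
          class = "e2sfca_error_not_a_table")
  }
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing required column(s) in ", what, " table: ",
             paste0("`", missing_cols, "`", collapse = ", ")),
      class = "e2sfca_error_missing_column"
    )
  }
  keep <- intersect(c(required, "area_label"), names(data))
  pts <- tibble::as_tibble(data[keep])
  pts$id <- as.character(pts$id)
  for (col in setdiff(required, "id")) {
    v <- pts[[col]]
    if (is.character(v) || is.factor(v)) {
      v_num <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(v_num) & !is.na(v))
      if (length(bad) > 0) {
        abort(
          paste0("column `", col, "` is not numeric; offending row(s): ",
                 paste(bad, collapse = ", ")),
          class = "e2sfca_error_non_numeric"
        )
      }
      v <- v_num
    }
    if (!is.numeric(v)) {
      abort(paste0("column `", col, "` is not numeric"),
            class = "e2sfca_error_non_numeric")
    }
    pts[[col]] <- as.double(v)
  }
  bad <- which(!is.finite(pts$x) | !is.finite(pts$y))
  if (length(bad) > 0) {
    abort(
      paste0("coordinates must be finite; offending row(s): ",
             paste(bad, collapse = ", ")),
      class = "e2sfca_error_non_numeric"
    )
  }
  dup <- which(duplicated(pts$id))
  if (length(dup) > 0) {
    abort(
      paste0("duplicate id(s) in ", what, " table: ",
             paste0("`", unique(pts$id[dup]), "`", collapse = ", "),
             " (row(s) ", paste(dup, collapse = ", "), ")"),
      class = "e2sfca_error_duplicate_id"
    )
  }
  pts
}

# Heuristic guard against unprojected longitude/latitude input: planar
# metre coordinates for any real study area do not all fit in the
# [-180, 180] x [-90, 90] box. Applied at the IO boundary, overridable.
check_planar <- function(pts, allow_geographic = FALSE, what = "point") {
  if (allow_geographic || nrow(pts) == 0) return(invisible(pts))
  if (all(abs(pts$x) <= 180) && all(abs(pts$y) <= 90)) {
    abort(
      paste0(what, " coordinates all lie within [-180, 180] x [-90, 90] ",
             "and look like unprojected longitude/latitude. Project them ",
             "to a planar metric CRS first, or pass ",
             "`allow_geographic = TRUE` if they really are planar metres."),
      class = "e2sfca_error_geographic_coords"
    )
  }
  invisible(pts)
}
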