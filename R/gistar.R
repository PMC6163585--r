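#' Distance-band neighbor sets
#'
#' Builds the binary spatial weights used by the Gi* statistic: every
#' point within `band` metres (inclusive) is a neighbor with weight 1,
#' and each point neighbors itself when `include_self = TRUE` (the `*` in
#' Gi*). When `band` is `NULL` it defaults to the smallest distance at
#' which every point has at least one neighbor besides itself -- the
#' largest nearest-neighbor distance in the data -- so no point is
#' isolated, mirroring common GIS practice.
#'
#' @param points A data frame with numeric `x` and `y` columns (planar
#'   metres).
#' @param band Band distance in metres, or `NULL` to resolve from the
#'   data.
#' @param include_self Include each point in its own neighbor set
#'   (default `TRUE`, as Gi* requires).
#' @return A list of integer neighbor-index vectors, one per point, with
#'   the resolved band in attribute `"band"`.
#' @export
distance_band_neighbors <- function(points, band = NULL,
                                    include_self = TRUE) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  n <- nrow(points)
  if (n < 2) {
    abort("at least 2 points are needed to define a neighborhood",
          class = "e2sfca_error_too_few_points")
  }
  if (is.null(band)) band <- critical_band(points$x, points$y)
  if (!is.numeric(band) || length(band) != 1 || !is.finite(band) ||
      band <= 0) {
    abort("`band` must be a single positive number",
          class = "e2sfca_error_bad_spec")
  }
  pairs <- radius_pairs(points$x, points$y, points$x, points$y, band)
  if (!include_self) pairs <- pairs[pairs$a != pairs$b, ]
  nbr <- unname(split(pairs$b, factor(pairs$a, levels = seq_len(n))))
  nbr <- lapply(nbr, as.integer)
  attr(nbr, "band") <- as.double(band)
  nbr
}

# Largest nearest-neighbor distance, computed in row chunks to bound
# memory on larger point sets.
critical_band <- function(x, y, chunk = 512L) {
  n <- length(x)
  worst <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    worst <- max(worst, sqrt(min_by_row(d2)))
  }
  worst
}

min_by_row <- function(m) apply(m, 1, min)

#' Getis-Ord Gi* z-scores
#'
#' The local Gi* statistic compares the sum of attribute values in each
#' point's neighborhood (including the point itself) with the global
#' mean, standardized to a z-score:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{(n \sum_j w_{ij}^2 - W_i^2)/(n-1)}}}
#' with binary weights, \eqn{W_i = \sum_j w_{ij}}, \eqn{\bar{X}} the mean
#' and \eqn{S} the population standard deviation of all values. Large
#' positive z marks a cluster of high values (hot spot), large negative z
#' a cluster of low values (cold spot). When the denominator degenerates
#' (all values identical, or a point neighbors every other point) the
#' z-score is defined as 0. Two-sided p-values use the normal
#' approximation, `p = 2 * (1 - pnorm(|z|))`.
#'
#' @param values Numeric vector of attribute values, aligned with the
#'   points used to build `neighbors`.
#' @param neighbors Neighbor sets from [distance_band_neighbors()].
#' @return A tibble with columns `gi_z` and `gi_p`.
#' @export
gi_star <- function(values, neighbors) {
  n <- length(neighbors)
  if (length(values) != n) {
    abort(sprintf("`values` has length %d but there are %d points",
                  length(values), n),
          class = "e2sfca_error_length_mismatch")
  }
  if (any(!is.finite(values))) {
    abort("`values` must be finite", class = "e2sfca_error_bad_values")
  }
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2)
  wi <- vapply(neighbors, length, integer(1))
  sumx <- vapply(neighbors, function(j) sum(values[j]), double(1))
  num <- sumx - xbar * wi
  radicand <- (n * wi - wi^2) / (n - 1)
  denom <- s * sqrt(pmax(radicand, 0))
  z <- ifelse(denom > 0, num / denom, 0)
  tibble::tibble(gi_z = z, gi_p = 2 * pnorm(-abs(z)))
}

# Two-tailed normal z thresholds for 90/95/99% confidence.
GI_Z_THRESHOLDS <- c(`90` = 1.645, `95` = 1.960, `99` = 2.576)
GI_P_THRESHOLDS <- c(`90` = 0.10, `95` = 0.05, `99` = 0.01)

#' Confidence bins for Gi* z-scores
#'
#' Classifies each z-score into one of seven bins: sign gives the cluster
#' direction (positive = hot, negative = cold) and magnitude the
#' two-tailed confidence level -- 1 for 90% (|z| >= 1.645), 2 for 95%
#' (|z| >= 1.960), 3 for 99% (|z| >= 2.576), and 0 for not significant.
#' With `fdr = TRUE`, p-values are Benjamini-Hochberg adjusted across all
#' points and each point is binned at the highest confidence whose
#' adjusted p-value survives the corresponding threshold.
#'
#' @param z Numeric vector of finite Gi* z-scores.
#' @param fdr Apply a Benjamini-Hochberg false-discovery-rate correction
#'   before binning (default `FALSE`).
#' @return A tibble with `gi_z`, `gi_p`, `gi_bin` and, when `fdr` is on,
#'   the adjusted p-values `gi_q`.
#' @examples
#' classify_bins(c(-2.58, -1, 0, 1.7, 2.0))$gi_bin  # -3 0 0 1 2
#' @export
classify_bins <- function(z, fdr = FALSE) {
  if (any(!is.finite(z))) {
    abort("`z` must be finite", class = "e2sfca_error_bad_values")
  }
  p <- 2 * pnorm(-abs(z))
  if (fdr) {
    q <- p.adjust(p, method = "BH")
    mag <- (q <= GI_P_THRESHOLDS["90"]) + (q <= GI_P_THRESHOLDS["95"]) +
      (q <= GI_P_THRESHOLDS["99"])
  } else {
    az <- abs(z)
    mag <- (az >= GI_Z_THRESHOLDS["90"]) + (az >= GI_Z_THRESHOLDS["95"]) +
      (az >= GI_Z_THRESHOLDS["99"])
  }
  out <- tibble::tibble(gi_z = z, gi_p = p,
                        gi_bin = as.integer(sign(z) * mag))
  if (fdr) out$gi_q <- q
  out
}

#' Hot- and cold-spot detection on an accessibility surface
#'
#' Runs the Getis-Ord Gi* statistic on per-block accessibility values
#' with binary distance-band weights and bins the z-scores at 90/95/99%
#' confidence. For an [e2sfca()] fit the default band is
#' `max(2 * d0, largest nearest-neighbor distance)`, a reproducible
#' neighborhood that spans adjacent catchments and never leaves a block
#' isolated; pass `band` to override.
#'
#' @param x An `e2sfca_fit` object, or a data frame with `id`, `x`, `y`
#'   and a value column.
#' @param band Neighborhood distance band in metres (`NULL` = default,
#'   see Details).
#' @param fdr Apply Benjamini-Hochberg correction before binning.
#' @param value Name of the value column (data-frame method only;
#'   default `"a_index"`).
#' @param ... Passed between methods.
#' @return A `gi_star_result`: a list with `table` (tibble `id`, `x`,
#'   `y`, the value column, `gi_z`, `gi_p`, `gi_bin`, optionally `gi_q`),
#'   the resolved `band` and the `fdr` flag. `tidy()` returns the table,
#'   `glance()` a one-row summary, `autoplot()` a hot/cold map.
#' @export
hotspot <- function(x, ...) UseMethod("hotspot")

#' @rdname hotspot
#' @export
hotspot.e2sfca_fit <- function(x, band = NULL, fdr = FALSE, ...) {
  if (is.null(band)) {
    band <- max(2 * x$spec$d0,
                critical_band(x$surface$x, x$surface$y))
  }
  hotspot(x$surface, band = band, fdr = fdr, ...)
}

#' @rdname hotspot
#' @export
hotspot.data.frame <- function(x, band = NULL, fdr = FALSE,
                               value = "a_index", ...) {
  stopifnot(all(c("id", "x", "y", value) %in% names(x)))
  nbr <- distance_band_neighbors(x, band = band)
  zs <- gi_star(x[[value]], nbr)
  bins <- classify_bins(zs$gi_z, fdr = fdr)
  tab <- tibble::as_tibble(x) |>
    dplyr::bind_cols(bins)
  structure(
    list(table = tab, band = attr(nbr, "band"), fdr = fdr, value = value),
    class = "gi_star_result"
  )
}

#' @export
print.gi_star_result <- function(x, ...) {
  b <- x$table$gi_bin
  cat(sprintf(
    "<gi_star_result> %d points, band = %g m%s\n", nrow(x$table), x$band,
    if (x$fdr) ", BH-adjusted" else ""))
  cat(sprintf("  hot: %d (>=90%%), cold: %d, not significant: %d\n",
              sum(b > 0), sum(b < 0), sum(b == 0)))
  invisible(x)
}

#' @rdname hotspot
#' @method tidy gi_star_result
#' @export
tidy.gi_star_result <- function(x, ...) {
  x$table
}

#' @rdname hotspot
#' @method glance gi_star_result
#' @export
glance.gi_star_result <- function(x, ...) {
  b <- x$table$gi_bin
  tibble::tibble(
    n = nrow(x$table),
    band = x$band,
    fdr = x$fdr,
    n_hot_90 = sum(b >= 1), n_hot_95 = sum(b >= 2), n_hot_99 = sum(b >= 3),
    n_cold_90 = sum(b <= -1), n_cold_95 = sum(b <= -2),
    n_cold_99 = sum(b <= -3),
    z_min = min(x$table$gi_z), z_max = max(x$table$gi_z)
  )
}

#' @rdname hotspot
#' @param object A `gi_star_result`.
#' @method autoplot gi_star_result
#' @export
autoplot.gi_star_result <- function(object, ...) {
  tab <- object$table
  tab$bin <- factor(tab$gi_bin, levels = -3:3)
  ggplot2::ggplot(tab, ggplot2::aes(.data$x, .data$y, colour = .data$bin)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_manual(
      name = "Gi* bin",
      values = c(`-3` = "#08306b", `-2` = "#2171b5", `-1` = "#6baed6",
                 `0` = "#ffffb2", `1` = "#fdae6b", `2` = "#e6550d",
                 `3` = "#a63603"),
      drop = FALSE,
      labels = c("cold 99%", "cold 95%", "cold 90%", "not significant",
                 "hot 90%", "hot 95%", "hot 99%")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  title = "Gi* hot/cold spots") +
    ggplot2::theme_minimal()
}

#' Per-area tally of hot, cold and non-significant points
#'
#' Counts classified points per planning area and confidence bin; points
#' without an area label are grouped under `NA`.
#'
#' @param result A `gi_star_result` (or its tidied table) containing an
#'   `area_label` column, or one supplied via `area_labels`.
#' @param area_labels Optional character vector of labels aligned with
#'   the points, overriding any `area_label` column.
#' @return A tibble with one row per (area, bin) combination present:
#'   `area_label`, `gi_bin`, `class` (`"hot"`, `"cold"`,
#'   `"not_significant"`) and `n`; counts sum to the number of points.
#' @export
hotspot_summary <- function(result, area_labels = NULL) {
  tab <- if (inherits(result, "gi_star_result")) result$table else
    tibble::as_tibble(result)
  stopifnot("gi_bin" %in% names(tab))
  if (!is.null(area_labels)) {
    if (length(area_labels) != nrow(tab)) {
      abort("`area_labels` must align with the points",
            class = "e2sfca_error_length_mismatch")
    }
    tab$area_label <- as.character(area_labels)
  }
  if (!"area_label" %in% names(tab)) tab$area_label <- NA_character_
  tab |>
    dplyr::count(.data$area_label, .data$gi_bin) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$gi_bin > 0 ~ "hot",
      .data$gi_bin < 0 ~ "cold",
      TRUE ~ "not_significant"
    )) |>
    dplyr::select("area_label", "gi_bin", "class", "n")
}
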