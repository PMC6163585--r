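#' Step 1: provider-to-population ratios
#'
#' For each supply point j, computes the ratio of its capacity to the
#' decay-weighted demand inside its catchment:
#' `R_j = S_j / sum_k P_k W(d_kj)` over demand points k with
#' `d_kj <= d0`. A clinic whose catchment holds no population (or only
#' zero-population blocks) has no defined ratio; it is recorded with
#' `ratio = NA` and contributes nothing downstream -- an empty catchment
#' is a reported condition, not an error.
#'
#' @param demand Demand-point table (see [as_demand_points()]).
#' @param supply Supply-point table (see [as_supply_points()]).
#' @param spec A [decay_spec()] giving the decay family and threshold.
#' @return A tibble with one row per supply point: `supply_id`,
#'   `capacity`, `weighted_demand` and `ratio` (`NA` for empty
#'   catchments), carrying the spec in attribute `"decay"`.
#' @examples
#' d <- as_demand_points(data.frame(id = "b", x = 0, y = 0, population = 100))
#' s <- as_supply_points(data.frame(id = "c", x = 0, y = 0))
#' supply_ratios(d, s)  # ratio = 1 / 100
#' @export
supply_ratios <- function(demand, supply, spec = decay_spec()) {
  demand <- as_demand_points(demand)
  supply <- as_supply_points(supply)
  stopifnot(inherits(spec, "decay_spec"))
  pairs <- catchment_pairs(demand, supply, spec$d0)
  pairs$w <- decay_weight(pairs$distance, spec)
  pairs$pop <- demand$population[match(pairs$demand_id, demand$id)]
  wd <- pairs |>
    dplyr::group_by(.data$supply_id) |>
    dplyr::summarise(weighted_demand = sum(.data$pop * .data$w))
  out <- supply |>
    dplyr::select("id", "capacity") |>
    dplyr::rename(supply_id = "id") |>
    dplyr::left_join(wd, by = "supply_id") |>
    dplyr::mutate(
      weighted_demand = tidyr::replace_na(.data$weighted_demand, 0),
      ratio = dplyr::if_else(.data$weighted_demand > 0,
                             .data$capacity / .data$weighted_demand,
                             NA_real_)
    )
  attr(out, "decay") <- spec
  out
}

#' Step 2: accessibility index per demand point
#'
#' Sums, for each demand point i, the ratios of all supply points within
#' its catchment. Two weighting modes are offered because the lineage of
#' the enhanced method is ambiguous about where the decay weight enters:
#'
#' * `"demand_only"` (default): the decay weight appears only inside the
#'   step-1 denominators, and step 2 sums the raw ratios,
#'   `A_i = sum_j R_j` over `d_ij <= d0`.
#' * `"symmetric"`: the conventional E2SFCA, which also decay-weights the
#'   step-2 sum, `A_i = sum_j W(d_ij) R_j`. This mode satisfies the
#'   conservation identity `sum_i P_i A_i = sum_j S_j` (over clinics with
#'   non-empty catchments).
#'
#' Blocks with zero population still receive an index (the index does not
#' depend on the block's own count); blocks with no clinic within `d0`
#' get `A_i = 0`.
#'
#' @param demand,supply Point tables as in [supply_ratios()].
#' @param ratios Ratio table from [supply_ratios()], computed with the
#'   same `demand`, `supply` and `spec`.
#' @param spec The same [decay_spec()] used for `ratios`.
#' @param mode `"demand_only"` or `"symmetric"`.
#' @return A tibble `id`, `x`, `y`, `population` (plus `area_label` when
#'   present) and `a_index`.
#' @export
accessibility <- function(demand, supply, ratios, spec = decay_spec(),
                          mode = c("demand_only", "symmetric")) {
  mode <- match.arg(mode)
  demand <- as_demand_points(demand)
  supply <- as_supply_points(supply)
  stopifnot(inherits(spec, "decay_spec"))
  rspec <- attr(ratios, "decay")
  if (!is.data.frame(ratios) ||
      !all(c("supply_id", "ratio") %in% names(ratios)) ||
      !setequal(ratios$supply_id, supply$id) ||
      (!is.null(rspec) && !identical(unclass(rspec), unclass(spec)))) {
    abort("`ratios` was not computed from this supply table and spec",
          class = "e2sfca_error_ratio_mismatch")
  }
  pairs <- catchment_pairs(demand, supply, spec$d0)
  pairs$ratio <- ratios$ratio[match(pairs$supply_id, ratios$supply_id)]
  pairs$w <- if (mode == "symmetric") decay_weight(pairs$distance, spec) else 1
  a <- pairs |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$demand_id) |>
    dplyr::summarise(a_index = sum(.data$w * .data$ratio))
  demand |>
    dplyr::left_join(a, by = c(id = "demand_id")) |>
    dplyr::mutate(a_index = tidyr::replace_na(.data$a_index, 0))
}

#' Enhanced two-step floating catchment area accessibility
#'
#' Runs both steps of the E2SFCA method: provider-to-population ratios
#' per clinic ([supply_ratios()]), then the per-block accessibility index
#' ([accessibility()]). Higher `a_index` means better geographical access
#' to primary care; `a_index = 0` means no clinic within walking range.
#'
#' @inheritParams accessibility
#' @param spec A [decay_spec()]; the default is a Gaussian decay with a
#'   400 m catchment and 200 m bandwidth.
#' @return An object of class `e2sfca_fit`: a list with `surface` (the
#'   per-block tibble with `a_index`), `ratios`, `spec` and `mode`.
#'   Use [tidy()] for the per-block table, [glance()] for a one-row
#'   summary and [autoplot()] for a map.
#' @examples
#' d <- as_demand_points(data.frame(
#'   id = c("b1", "b2"), x = c(0, 200), y = 0, population = 50))
#' s <- as_supply_points(data.frame(id = c("c1", "c2"), x = c(0, 300), y = 0))
#' fit <- e2sfca(d, s)
#' tidy(fit)
#' glance(fit)
#' @export
e2sfca <- function(demand, supply, spec = decay_spec(),
                   mode = c("demand_only", "symmetric")) {
  mode <- match.arg(mode)
  demand <- as_demand_points(demand)
  supply <- as_supply_points(supply)
  ratios <- supply_ratios(demand, supply, spec)
  surface <- accessibility(demand, supply, ratios, spec, mode)
  structure(
    list(surface = surface, ratios = ratios, spec = spec, mode = mode,
         n_demand = nrow(demand), n_supply = nrow(supply)),
    class = "e2sfca_fit"
  )
}

#' @export
print.e2sfca_fit <- function(x, ...) {
  cat(sprintf(
    "<e2sfca_fit> %d demand x %d supply, %s decay, d0 = %g m, mode = %s\n",
    x$n_demand, x$n_supply, x$spec$family, x$spec$d0, x$mode))
  cat(sprintf("  a_index: min %.6g, median %.6g, max %.6g (%d zero)\n",
              min(x$surface$a_index), stats::median(x$surface$a_index),
              max(x$surface$a_index), sum(x$surface$a_index == 0)))
  invisible(x)
}

#' @rdname e2sfca
#' @param x An `e2sfca_fit` object.
#' @param ... Unused.
#' @method tidy e2sfca_fit
#' @export
tidy.e2sfca_fit <- function(x, ...) {
  x$surface
}

#' @rdname e2sfca
#' @method glance e2sfca_fit
#' @export
glance.e2sfca_fit <- function(x, ...) {
  tibble::tibble(
    n_demand = x$n_demand,
    n_supply = x$n_supply,
    n_empty_catchment = sum(is.na(x$ratios$ratio)),
    d0 = x$spec$d0,
    beta = x$spec$beta,
    family = x$spec$family,
    mode = x$mode,
    a_min = min(x$surface$a_index),
    a_max = max(x$surface$a_index),
    a_mean = mean(x$surface$a_index),
    n_zero_access = sum(x$surface$a_index == 0)
  )
}

#' @rdname e2sfca
#' @param object An `e2sfca_fit` object.
#' @method autoplot e2sfca_fit
#' @export
autoplot.e2sfca_fit <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$x, .data$y, colour = .data$a_index)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_viridis_c(name = "A index") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  title = "E2SFCA accessibility surface") +
    ggplot2::theme_minimal()
}
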