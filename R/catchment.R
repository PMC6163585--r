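# Fixed-radius neighbor search on planar points via square grid buckets.
# Cells have side r, so all neighbors of a point lie in its 3x3 cell
# block; results are identical to the exhaustive O(n*m) scan.
radius_pairs <- function(ax, ay, bx, by, r) {
  n <- length(ax)
  m <- length(bx)
  if (n == 0 || m == 0) {
    return(tibble::tibble(a = integer(), b = integer(), distance = double()))
  }
  cell_a <- cbind(floor(ax / r), floor(ay / r))
  key_b <- paste(floor(bx / r), floor(by / r))
  bucket <- split(seq_len(m), key_b)
  out_a <- vector("list", n)
  out_b <- vector("list", n)
  out_d <- vector("list", n)
  for (i in seq_len(n)) {
    keys <- paste(rep(cell_a[i, 1] + (-1:1), each = 3),
                  rep(cell_a[i, 2] + (-1:1), times = 3))
    cand <- unlist(bucket[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    cand <- sort(cand)
    d <- sqrt((bx[cand] - ax[i])^2 + (by[cand] - ay[i])^2)
    keep <- d <= r
    if (any(keep)) {
      out_a[[i]] <- rep.int(i, sum(keep))
      out_b[[i]] <- cand[keep]
      out_d[[i]] <- d[keep]
    }
  }
  tibble::tibble(
    a = unlist(out_a, use.names = FALSE) %||% integer(),
    b = unlist(out_b, use.names = FALSE) %||% integer(),
    distance = unlist(out_d, use.names = FALSE) %||% double()
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Demand-supply pairs within a catchment
#'
#' Enumerates every (demand, supply) pair whose straight-line distance on
#' the planar coordinates is at most `d0`, the inclusive catchment
#' threshold. These pairs are exactly the index sets over which the
#' two-step floating catchment sums run. Distances are Euclidean:
#' the method is designed for pre-projected metric coordinates and does
#' not use a street network.
#'
#' @param demand Demand-point table (see [as_demand_points()]).
#' @param supply Supply-point table (see [as_supply_points()]).
#' @param d0 Catchment threshold in metres (inclusive).
#' @return A tibble with columns `demand_id`, `supply_id`, `distance`,
#'   one row per pair within the catchment, ordered by demand then supply
#'   input position.
#' @examples
#' d <- as_demand_points(data.frame(id = "b", x = 0, y = 0, population = 10))
#' s <- as_supply_points(data.frame(id = "c", x = 400, y = 0))
#' catchment_pairs(d, s, d0 = 400)  # boundary pair is included
#' @export
catchment_pairs <- function(demand, supply, d0 = 400) {
  demand <- as_demand_points(demand)
  supply <- as_supply_points(supply)
  if (nrow(demand) == 0 || nrow(supply) == 0) {
    abort("`demand` and `supply` must be non-empty",
          class = "e2sfca_error_empty_input")
  }
  if (!is.numeric(d0) || length(d0) != 1 || !is.finite(d0) || d0 <= 0) {
    abort("`d0` must be a single positive number",
          class = "e2sfca_error_bad_spec")
  }
  pairs <- radius_pairs(demand$x, demand$y, supply$x, supply$y, d0)
  tibble::tibble(
    demand_id = demand$id[pairs$a],
    supply_id = supply$id[pairs$b],
    distance = pairs$distance
  )
}
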