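#' Describe a synthetic city
#'
#' Builds the parameter set for a seeded synthetic city with the
#' statistical structure the accessibility analysis assumes: residential
#' blocks clustered into towns, overdispersed elderly counts per block,
#' clinics scattered around town centres, and planted disk-shaped regions
#' where the clinic intensity is multiplied up (intended hot spots) or
#' down (intended cold spots).
#'
#' Defaults emulate a dense public-housing city at town scale: a
#' 12 x 8 km extent, 6 towns of 60 blocks scattered with a 500 m
#' standard deviation, a mean of 40 elderly residents per block with
#' strong overdispersion (negative binomial, dispersion 5, so block
#' variance far exceeds the mean, as real block sizes do), and 8 clinics
#' of capacity 1 per town. The default planted regions are disks of
#' radius 1000 m centred on the first two towns, with supply multipliers
#' 4 (hot) and 0.1 (cold).
#'
#' @param bbox Numeric `c(width, height)` of the city extent in metres.
#' @param n_towns Number of towns; centres are drawn uniformly in the
#'   bounding box.
#' @param blocks_per_town Blocks per town: a single count or a
#'   `c(min, max)` range sampled per town.
#' @param town_spread Within-town scatter SD in metres.
#' @param clinic_spread Clinic scatter SD around town centres in metres.
#' @param elderly_mean Mean elderly count per block.
#' @param elderly_dispersion Negative-binomial `size`; smaller means more
#'   overdispersion (variance = mean + mean^2 / size).
#' @param supply_intensity Expected clinics per town (Poisson mean).
#' @param planted A list of planted regions. Each region is a list with
#'   `radius` (metres), `multiplier` (> 0; > 1 plants a hot region, < 1 a
#'   cold one) and either `center = c(x, y)` or `town = k` (resolved to
#'   town k's sampled centre at generation time). `NULL` plants nothing.
#' @param seed Integer seed; the same spec and seed reproduce the city
#'   exactly.
#' @return An object of class `synthetic_scenario`.
#' @examples
#' sc <- synthetic_scenario(seed = 1)
#' city <- generate_scenario(sc)
#' dplyr::count(city$truth, label)
#' @export
synthetic_scenario <- function(bbox = c(12000, 8000),
                               n_towns = 6,
                               blocks_per_town = 60,
                               town_spread = 500,
                               clinic_spread = 500,
                               elderly_mean = 40,
                               elderly_dispersion = 5,
                               supply_intensity = 8,
                               planted = list(
                                 list(town = 1, radius = 1000,
                                      multiplier = 4),
                                 list(town = 2, radius = 1000,
                                      multiplier = 0.1)),
                               seed = 1L) {
  if (length(bbox) != 2 || any(!is.finite(bbox)) || any(bbox <= 0)) {
    abort("`bbox` must be two positive lengths (metres)",
          class = "e2sfca_error_bad_spec")
  }
  if (n_towns < 1) {
    abort("`n_towns` must be at least 1", class = "e2sfca_error_bad_spec")
  }
  if (any(blocks_per_town < 1) || length(blocks_per_town) > 2) {
    abort("`blocks_per_town` must be a positive count or range",
          class = "e2sfca_error_bad_spec")
  }
  if (elderly_mean < 0 || supply_intensity < 0) {
    abort("rates must be non-negative", class = "e2sfca_error_bad_spec")
  }
  for (pr in planted) {
    ok <- is.list(pr) && !is.null(pr$radius) && pr$radius > 0 &&
      !is.null(pr$multiplier) && pr$multiplier > 0 &&
      (!is.null(pr$center) || !is.null(pr$town))
    if (!ok) {
      abort(paste0("each planted region needs a positive `radius`, a ",
                   "positive `multiplier` and a `center` or `town`"),
            class = "e2sfca_error_bad_spec")
    }
    if (!is.null(pr$town) && (pr$town < 1 || pr$town > n_towns)) {
      abort("planted `town` index out of range",
            class = "e2sfca_error_bad_spec")
    }
  }
  structure(
    list(bbox = as.double(bbox), n_towns = as.integer(n_towns),
         blocks_per_town = as.integer(blocks_per_town),
         town_spread = as.double(town_spread),
         clinic_spread = as.double(clinic_spread),
         elderly_mean = as.double(elderly_mean),
         elderly_dispersion = as.double(elderly_dispersion),
         supply_intensity = as.double(supply_intensity),
         planted = planted, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

in_disk <- function(x, y, center, radius) {
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

# First planted region containing the point, or 0.
first_region <- function(x, y, regions) {
  hit <- rep(0L, length(x))
  for (r in seq_along(regions)) {
    inside <- hit == 0L & in_disk(x, y, regions[[r]]$center,
                                  regions[[r]]$radius)
    hit[inside] <- r
  }
  hit
}

#' Generate a synthetic city
#'
#' Draws a city from a [synthetic_scenario()] using a single seeded
#' random stream. Town centres are uniform in the bounding box; block
#' coordinates are Gaussian around their town centre; elderly counts are
#' negative binomial; clinics are an inhomogeneous Poisson process whose
#' town-centred intensity is multiplied inside planted regions, realized
#' by simulating at the maximum multiplier and thinning, so clinic
#' counts are Poisson with the multiplied mean everywhere. All clinic
#' capacities are fixed at 1.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `demand` (block table with `area_label =
#'   "town_<k>"`), `supply` (clinic table), `truth` (tibble `id`,
#'   `label` in hot/cold/neutral from the planted regions), and
#'   `regions` (resolved planted-region tibble).
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  withr::local_seed(sc$seed)

  centers <- cbind(runif(sc$n_towns, 0, sc$bbox[1]),
                   runif(sc$n_towns, 0, sc$bbox[2]))

  regions <- lapply(sc$planted, function(pr) {
    if (is.null(pr$center)) pr$center <- centers[pr$town, ]
    pr
  })

  n_blocks <- if (length(sc$blocks_per_town) == 2) {
    sample(sc$blocks_per_town[1]:sc$blocks_per_town[2], sc$n_towns,
           replace = TRUE)
  } else {
    rep(sc$blocks_per_town, sc$n_towns)
  }
  town_of <- rep(seq_len(sc$n_towns), n_blocks)
  bx <- rnorm(sum(n_blocks), centers[town_of, 1], sc$town_spread)
  by <- rnorm(sum(n_blocks), centers[town_of, 2], sc$town_spread)
  pop <- rnbinom(sum(n_blocks), size = sc$elderly_dispersion,
                 mu = sc$elderly_mean)
  demand <- tibble::tibble(
    id = sprintf("B%04d", seq_along(bx)),
    x = bx, y = by, population = as.double(pop),
    area_label = sprintf("town_%d", town_of)
  )

  # Clinics form an inhomogeneous Poisson process: town-centred Gaussian
  # intensity integrating to supply_intensity per town, rescaled by the
  # planted multiplier m(x). Simulated exactly by drawing at the maximum
  # multiplier and thinning each point with probability m(x)/m_max, so
  # local counts are Poisson with the multiplied mean everywhere.
  mult <- vapply(regions, `[[`, double(1), "multiplier")
  m_max <- max(1, mult)
  n_clin <- rpois(sc$n_towns, sc$supply_intensity * m_max)
  clin_town <- rep(seq_len(sc$n_towns), n_clin)
  cx <- rnorm(sum(n_clin), centers[clin_town, 1], sc$clinic_spread)
  cy <- rnorm(sum(n_clin), centers[clin_town, 2], sc$clinic_spread)
  if (length(cx) > 0 && m_max > 1) {
    reg <- first_region(cx, cy, regions)
    m <- ifelse(reg == 0L, 1, mult[pmax(reg, 1L)])
    keep <- runif(length(cx)) <= m / m_max
    cx <- cx[keep]
    cy <- cy[keep]
  }
  supply <- tibble::tibble(
    id = sprintf("C%04d", seq_along(cx)),
    x = cx, y = cy, capacity = 1
  )

  truth_lab <- rep("neutral", nrow(demand))
  if (length(regions) > 0) {
    reg_b <- first_region(demand$x, demand$y, regions)
    mult <- vapply(regions, `[[`, double(1), "multiplier")
    truth_lab[reg_b > 0 & mult[pmax(reg_b, 1L)] > 1] <- "hot"
    truth_lab[reg_b > 0 & mult[pmax(reg_b, 1L)] < 1] <- "cold"
  }
  truth <- tibble::tibble(id = demand$id, label = truth_lab)

  region_tab <- if (length(regions) > 0) {
    tibble::tibble(
      region = seq_along(regions),
      center_x = vapply(regions, function(r) r$center[1], double(1)),
      center_y = vapply(regions, function(r) r$center[2], double(1)),
      radius = vapply(regions, `[[`, double(1), "radius"),
      multiplier = vapply(regions, `[[`, double(1), "multiplier")
    )
  } else {
    tibble::tibble(region = integer(), center_x = double(),
                   center_y = double(), radius = double(),
                   multiplier = double())
  }

  list(demand = demand, supply = supply, truth = truth,
       regions = region_tab)
}

#' Planted-structure recovery metrics
#'
#' Compares hot/cold detections against the planted ground truth:
#' a block counts as detected hot (cold) when its Gi* bin magnitude
#' reaches the stated confidence with positive (negative) sign. Recall is
#' detections among truth blocks; precision is truth blocks among
#' detections; both are `NA` when their denominator is empty.
#'
#' @param result A `gi_star_result` (or its tidied table with `id` and
#'   `gi_bin`).
#' @param truth Ground-truth tibble (`id`, `label`) from
#'   [generate_scenario()].
#' @param confidence Detection confidence: 90, 95 or 99.
#' @return A tibble with one row per class (`hot`, `cold`): `n_truth`,
#'   `n_detected`, `n_correct`, `precision`, `recall`, plus
#'   `false_hot_rate` / `false_cold_rate` among truth-neutral blocks.
#' @export
evaluate_recovery <- function(result, truth, confidence = 95) {
  tab <- if (inherits(result, "gi_star_result")) result$table else
    tibble::as_tibble(result)
  stopifnot(all(c("id", "gi_bin") %in% names(tab)),
            all(c("id", "label") %in% names(truth)))
  if (!any(tab$id %in% truth$id)) {
    abort("`result` and `truth` share no ids",
          class = "e2sfca_error_id_mismatch")
  }
  conf <- as.character(confidence)
  if (!conf %in% c("90", "95", "99")) {
    abort("`confidence` must be 90, 95 or 99",
          class = "e2sfca_error_bad_spec")
  }
  need <- c(`90` = 1L, `95` = 2L, `99` = 3L)[[conf]]
  joined <- dplyr::inner_join(tab[, c("id", "gi_bin")], truth, by = "id")
  det <- list(hot = joined$gi_bin >= need, cold = joined$gi_bin <= -need)
  neutral <- joined$label == "neutral"
  purrr::map_dfr(c("hot", "cold"), function(cls) {
    is_truth <- joined$label == cls
    is_det <- det[[cls]]
    n_correct <- sum(is_truth & is_det)
    tibble::tibble(
      class = cls,
      n_truth = sum(is_truth),
      n_detected = sum(is_det),
      n_correct = n_correct,
      precision = if (sum(is_det) > 0) n_correct / sum(is_det) else
        NA_real_,
      recall = if (sum(is_truth) > 0) n_correct / sum(is_truth) else
        NA_real_,
      false_rate_neutral = if (sum(neutral) > 0)
        sum(neutral & is_det) / sum(neutral) else NA_real_
    )
  })
}
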