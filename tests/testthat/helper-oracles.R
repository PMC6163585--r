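# Independent brute-force oracles and instance generators. These use
# plain double loops and the closed-form definitions only, never the
# package's production path.

rand_instance <- function(seed, n_demand = 200, n_supply = 30,
                          extent = 3000) {
  withr::local_seed(seed)
  list(
    demand = tibble::tibble(
      id = sprintf("d%03d", seq_len(n_demand)),
      x = runif(n_demand, 0, extent),
      y = runif(n_demand, 0, extent),
      population = rpois(n_demand, 50)
    ),
    supply = tibble::tibble(
      id = sprintf("s%03d", seq_len(n_supply)),
      x = runif(n_supply, 0, extent),
      y = runif(n_supply, 0, extent),
      capacity = 1
    )
  )
}

# Exhaustive O(n*m) scan for pairs within the inclusive threshold.
oracle_pairs <- function(demand, supply, d0) {
  out <- list()
  for (k in seq_len(nrow(demand))) {
    for (j in seq_len(nrow(supply))) {
      d <- sqrt((demand$x[k] - supply$x[j])^2 +
                  (demand$y[k] - supply$y[j])^2)
      if (d <= d0) {
        out[[length(out) + 1]] <-
          data.frame(demand_id = demand$id[k], supply_id = supply$id[j],
                     distance = d)
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(demand_id = character(),
                                        supply_id = character(),
                                        distance = double()))))
}

# Naive double-loop evaluation of both steps of the floating-catchment
# accessibility index.
oracle_access <- function(demand, supply, d0, beta = d0 / 2,
                          family = "gaussian", mode = "demand_only") {
  wfun <- function(d) {
    if (family == "gaussian") {
      ifelse(d <= d0, exp(-d^2 / beta^2), 0)
    } else {
      as.numeric(d <= d0)
    }
  }
  n <- nrow(demand)
  m <- nrow(supply)
  r <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    wd <- 0
    for (k in seq_len(n)) {
      d <- sqrt((demand$x[k] - supply$x[j])^2 +
                  (demand$y[k] - supply$y[j])^2)
      if (d <= d0) wd <- wd + demand$population[k] * wfun(d)
    }
    if (wd > 0) r[j] <- supply$capacity[j] / wd
  }
  a <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- sqrt((demand$x[i] - supply$x[j])^2 +
                  (demand$y[i] - supply$y[j])^2)
      if (d <= d0 && !is.na(r[j])) {
        w <- if (mode == "symmetric") wfun(d) else 1
        a[i] <- a[i] + w * r[j]
      }
    }
  }
  list(ratio = r, a_index = a)
}

# Direct per-point evaluation of the Gi* closed form with binary
# distance-band weights (self included).
oracle_gi <- function(values, xs, ys, band) {
  n <- length(values)
  xbar <- mean(values)
  s <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wi <- 0
    sumx <- 0
    for (j in seq_len(n)) {
      d <- sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2)
      if (d <= band) {
        wi <- wi + 1
        sumx <- sumx + values[j]
      }
    }
    num <- sumx - xbar * wi
    rad <- (n * wi - wi^2) / (n - 1)
    den <- s * sqrt(rad)
    z[i] <- if (is.finite(den) && den > 0) num / den else 0
  }
  z
}

rigid_transform <- function(df, theta, dx, dy) {
  out <- df
  out$x <- cos(theta) * df$x - sin(theta) * df$y + dx
  out$y <- sin(theta) * df$x + cos(theta) * df$y + dy
  out
}

max_rel_err <- function(got, want) {
  denom <- pmax(abs(want), 1e-300)
  max(abs(got - want) / denom)
}
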