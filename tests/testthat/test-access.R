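two_block_instance <- function() {
  list(
    demand = data.frame(id = c("b1", "b2"), x = c(0, 200), y = 0,
                        population = 50),
    supply = data.frame(id = c("c1", "c2"), x = c(0, 300), y = 0,
                        capacity = 1)
  )
}

test_that("step-1 ratios match hand-computed weighted demand", {
  # single clinic, single block at distance 0: W = 1, R = S/P
  d1 <- data.frame(id = "b", x = 0, y = 0, population = 100)
  s1 <- data.frame(id = "c", x = 0, y = 0)
  r1 <- supply_ratios(d1, s1)
  expect_equal(r1$ratio, 0.01)
  expect_equal(r1$weighted_demand, 100)

  # blocks P=50 at d=0 and d=200 (beta=200): 50 + 50 exp(-1)
  inst <- two_block_instance()
  r <- supply_ratios(inst$demand, inst$supply)
  expect_equal(r$weighted_demand[r$supply_id == "c1"], 68.393972,
               tolerance = 1e-7)
  expect_equal(r$ratio[r$supply_id == "c1"], 0.0146212, tolerance = 1e-5)
  # ratio * weighted demand recovers capacity
  expect_equal(r$ratio * r$weighted_demand, r$capacity, tolerance = 1e-12)
})

test_that("a clinic with an empty catchment gets a null ratio, not infinity", {
  d <- data.frame(id = "b", x = 0, y = 0, population = 100)
  s <- data.frame(id = c("near", "far"), x = c(0, 5000), y = 0)
  r <- supply_ratios(d, s)
  expect_true(is.na(r$ratio[r$supply_id == "far"]))
  expect_equal(r$weighted_demand[r$supply_id == "far"], 0)
  # and it contributes nothing to step 2
  fit <- e2sfca(d, s)
  expect_equal(tidy(fit)$a_index, 0.01)
})

test_that("step-2 index matches the hand-computed two-clinic example", {
  inst <- two_block_instance()
  fit <- e2sfca(inst$demand, inst$supply)
  a <- tidy(fit)
  expect_equal(a$a_index[a$id == "b1"], 0.0372405, tolerance = 1e-5)
  expect_equal(a$a_index[a$id == "b1"], 0.0146212 + 0.0226193,
               tolerance = 1e-5)
})

test_that("blocks with no reachable clinic and zero-population blocks behave", {
  d <- data.frame(id = c("b1", "b2", "b3"), x = c(0, 10000, 100), y = 0,
                  population = c(100, 50, 0))
  s <- data.frame(id = "c", x = 0, y = 0)
  fit <- e2sfca(d, s)
  a <- tidy(fit)
  expect_equal(a$a_index[a$id == "b2"], 0)            # nothing in range
  expect_gt(a$a_index[a$id == "b3"], 0)               # zero pop still scored
  # zero-population block contributes nothing to the denominator
  expect_equal(fit$ratios$weighted_demand, 100)
  # A_i = 0 iff no supply within d0
  expect_true(all((a$a_index == 0) == (a$id == "b2")))
})

test_that("a ratio table from other inputs is rejected", {
  inst <- two_block_instance()
  r <- supply_ratios(inst$demand, inst$supply)
  other_supply <- data.frame(id = "elsewhere", x = 9, y = 9)
  expect_error(accessibility(inst$demand, other_supply, r),
               class = "e2sfca_error_ratio_mismatch")
  r2 <- supply_ratios(inst$demand, inst$supply, decay_spec(d0 = 800))
  expect_error(accessibility(inst$demand, inst$supply, r2),
               class = "e2sfca_error_ratio_mismatch")
})

test_that("production path equals the naive double-loop on random instances", {
  for (seed in 1:5) {
    inst <- rand_instance(seed, 200, 30)
    for (mode in c("demand_only", "symmetric")) {
      fit <- e2sfca(inst$demand, inst$supply, decay_spec(400), mode)
      want <- oracle_access(inst$demand, inst$supply, 400, mode = mode)
      expect_lt(max_rel_err(tidy(fit)$a_index, want$a_index), 1e-9)
      expect_equal(fit$ratios$ratio, want$ratio, tolerance = 1e-9)
    }
  }
})

test_that("gaussian decay dominates plain 2SFCA in demand_only mode", {
  for (seed in 1:10) {
    inst <- rand_instance(seed, 150, 20)
    a_gauss <- tidy(e2sfca(inst$demand, inst$supply,
                           decay_spec(400, "gaussian")))$a_index
    a_unif <- tidy(e2sfca(inst$demand, inst$supply,
                          decay_spec(400, "uniform")))$a_index
    expect_true(all(a_gauss >= a_unif - 1e-12))
  }
})

test_that("symmetric mode conserves total capacity over served clinics", {
  for (seed in 1:5) {
    inst <- rand_instance(seed, 150, 20)
    for (family in c("gaussian", "uniform")) {
      fit <- e2sfca(inst$demand, inst$supply, decay_spec(400, family),
                    mode = "symmetric")
      served <- sum(fit$ratios$capacity[!is.na(fit$ratios$ratio)])
      total <- sum(tidy(fit)$population * tidy(fit)$a_index)
      expect_equal(total, served, tolerance = 1e-6)
    }
  }
})

test_that("adding supply never lowers and adding demand never raises A_i", {
  for (seed in 1:5) {
    inst <- rand_instance(seed, 100, 10)
    base <- tidy(e2sfca(inst$demand, inst$supply))$a_index

    extra <- rbind(inst$supply,
                   data.frame(id = "new", x = 1500, y = 1500, capacity = 1))
    more_supply <- tidy(e2sfca(inst$demand, extra))$a_index
    expect_true(all(more_supply >= base - 1e-12))

    bigger <- inst$demand
    bigger$population[1] <- bigger$population[1] + 500
    more_demand <- tidy(e2sfca(bigger, inst$supply))$a_index
    expect_true(all(more_demand <= base + 1e-12))
  }
})

test_that("ratios and indices are invariant under rigid motions", {
  inst <- rand_instance(42, 120, 15)
  fit <- e2sfca(inst$demand, inst$supply)
  moved <- e2sfca(rigid_transform(inst$demand, 0.7, 12345, -678),
                  rigid_transform(inst$supply, 0.7, 12345, -678))
  expect_lt(max(abs(tidy(fit)$a_index - tidy(moved)$a_index) /
                  pmax(tidy(fit)$a_index, 1e-300)), 1e-9)
  expect_equal(fit$ratios$ratio, moved$ratios$ratio, tolerance = 1e-9)
})

test_that("glance summarises the fit", {
  inst <- two_block_instance()
  g <- glance(e2sfca(inst$demand, inst$supply))
  expect_equal(g$n_demand, 2)
  expect_equal(g$n_supply, 2)
  expect_equal(g$d0, 400)
  expect_equal(g$beta, 200)
  expect_equal(g$mode, "demand_only")
})
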