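test_that("length ratios are elementwise quotients with missing propagation", {
  buds <- data.frame(bud_id = c("b1", "b2", "b3"),
                     outer_length = c(120, 80, 100),
                     inner_length = c(60, 80, NA),
                     bud_length = c(200, 160, 180))
  r <- length_ratios(buds)
  expect_equal(r$outer_inner, c(2.0, 1.0, NA))
  expect_equal(r$outer_bud, c(0.6, 0.5, 100 / 180))
  expect_equal(r$inner_bud, c(0.3, 0.5, NA))
  expect_error(length_ratios(transform(buds, outer_length = c(-1, 80, 100))),
               "positive")
})

test_that("absolute growth matches the exponential closed form", {
  g <- 0.06; t1 <- 12
  series <- data.frame(bud_id = "b1", sepal_id = "b1_outer", position = "outer",
                       time_h = c(0, 12), area_um2 = 100 * exp(g * c(0, 12)))
  ag <- absolute_growth(series)
  expect_equal(ag$delta_area, 100 * (exp(0.72) - 1), tolerance = 1e-9)
  # constant area -> zero deltas; shrinkage clamped and flagged
  flat <- data.frame(bud_id = "b", sepal_id = "s", position = "outer",
                     time_h = c(0, 12, 24), area_um2 = rep(50, 3))
  expect_equal(absolute_growth(flat)$delta_area, c(0, 0))
  shrink <- data.frame(bud_id = "b", sepal_id = "s", position = "outer",
                       time_h = c(0, 12), area_um2 = c(100, 90))
  expect_warning(ag2 <- absolute_growth(shrink), "clamped")
  expect_equal(ag2$delta_area, 0)
  expect_true(ag2$clamped)
})

test_that("growth contributions are increment shares summing to 1", {
  d <- c(outer = 60, inner = 20, lateral1 = 10, lateral2 = 10)
  fr <- growth_contributions(d)
  expect_equal(unname(fr["outer"]), 0.6)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(growth_contributions(c(a = 5, b = 0))["a"]), 1)
  expect_warning(fr0 <- growth_contributions(c(a = 0, b = 0)), "undefined")
  expect_true(all(is.na(fr0)))
  expect_error(growth_contributions(c(a = 1)), "2 sepals")
})

test_that("noiseless exponential growth reproduces closed-form contribution shares", {
  sim <- simulate_growth(n_buds = 3, noise_sd = 0, seed = 1)
  rec <- growth_records(sim$series)
  rates <- c(outer = 0.06, inner = 0.02, lateral1 = 0.03, lateral2 = 0.03)
  a0 <- c(outer = 100, inner = 100, lateral1 = 100, lateral2 = 100)
  expected <- exp_growth_contributions(rates, a0, 0, 12)
  first <- rec$contributions[rec$contributions$bud_id == "bud01" &
                               rec$contributions$t0 == 0, ]
  got <- first$contribution[match(names(expected),
                                  sub("bud01_", "", first$sepal_id))]
  expect_equal(got, unname(expected), tolerance = 1e-9)
  # equal rates -> constant outer/inner area ratio over time
  sim_eq <- simulate_growth(rates = c(outer = 0.04, inner = 0.04, lateral = 0.04),
                            n_buds = 1, noise_sd = 0)
  r <- growth_records(sim_eq$series)$ratios
  oi <- r$value[r$ratio == "outer_inner"]
  expect_equal(oi, rep(oi[1], length(oi)), tolerance = 1e-12)
})

test_that("area ratios merge two inner sepals before dividing", {
  expect_equal(unname(area_ratios(c(o = 100, i = 50),
                                  c("outer", "inner"))["outer_inner"]), 2.0)
  # the split of inner area between two inner sepals must not matter
  r1 <- area_ratios(c(o = 100, i1 = 30, i2 = 20), c("outer", "inner", "inner"))
  r2 <- area_ratios(c(o = 100, i1 = 45, i2 = 5), c("outer", "inner", "inner"))
  expect_equal(unname(r1["outer_inner"]), 2.0)
  expect_equal(r1["outer_inner"], r2["outer_inner"])
  lat <- area_ratios(c(o = 100, l1 = 40, l2 = 25),
                     c("outer", "lateral", "lateral"))
  expect_equal(unname(lat[c("outer_lateral_l1", "outer_lateral_l2")]),
               c(2.5, 4.0))
  expect_true(is.na(area_ratios(c(o = 10), "outer")["outer_inner"]))
  expect_error(area_ratios(c(a = 1, b = 2), c("inner", "inner")), "outer")
})

test_that("per-cell growth ratios keep raw values and clamp only the display", {
  t0 <- c(p1 = 10, p2 = 20, p3 = 8)
  t1 <- c(c1 = 10, c2 = 40, c3 = 24.8)
  lin <- c(c1 = "p1", c2 = "p2", c3 = "p3")
  r <- cell_growth_ratios(t0, t1, lin)
  expect_equal(r$ratio, c(1, 2, 3.1))
  expect_equal(r$ratio_display, c(1, 2, 2.5))
  # untracked cells excluded with a warning; duplicate parents rejected
  expect_warning(r2 <- cell_growth_ratios(t0, c(t1, c4 = 5), lin), "untracked")
  expect_equal(nrow(r2), 3)
  expect_error(cell_growth_ratios(t0, t1, c(c1 = "p1", c2 = "p1", c3 = "p3")),
               "bijection")
})

test_that("noisy growth simulation stays near the closed-form outer share", {
  sim <- simulate_growth(n_buds = 20, noise_sd = 0.02, seed = 10)
  rec <- growth_records(sim$series)
  rates <- c(outer = 0.06, inner = 0.02, lateral1 = 0.03, lateral2 = 0.03)
  a0 <- rep(100, 4); names(a0) <- names(rates)
  expected <- exp_growth_contributions(rates, a0, 0, 12)[["outer"]]
  outer <- rec$contributions[rec$contributions$position == "outer" &
                               rec$contributions$t0 == 0, ]
  expect_lt(abs(mean(outer$contribution) - expected), 0.02)
})
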