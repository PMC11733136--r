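test_that("generation surrogate attains the printed envelope endpoints", {
  env <- generation_envelope()
  oil <- env$oil_flow_range
  water <- env$water_flow_range
  corners <- expand.grid(oil = oil, water = water)
  d <- predict_generation(corners$oil, corners$water, env)$diameter_um
  r <- predict_generation(corners$oil, corners$water, env)$rate_hz
  expect_setequal(round(range(d), 9), c(95, 176))
  expect_setequal(round(range(r), 9), c(4, 368))
  # interior grid never exceeds the printed ranges
  g <- expand.grid(oil = exp(seq(log(oil[1]), log(oil[2]), length.out = 25)),
                   water = exp(seq(log(water[1]), log(water[2]),
                                   length.out = 25)))
  p <- predict_generation(g$oil, g$water, env)
  expect_true(all(p$diameter_um >= 95 & p$diameter_um <= 176))
  expect_true(all(p$rate_hz >= 4 & p$rate_hz <= 368))
})

test_that("generation surrogate is monotone along each flow axis", {
  env <- generation_envelope()
  oil <- exp(seq(log(4.16), log(166.7), length.out = 30))
  d_oil <- predict_generation(oil, 5, env)$diameter_um
  expect_true(all(diff(d_oil) < 0))      # more oil -> smaller droplets
  water <- exp(seq(log(0.2), log(16.66), length.out = 30))
  r_water <- predict_generation(50, water, env)$rate_hz
  expect_true(all(diff(r_water) > 0))    # more water -> faster generation
})

test_that("out-of-envelope flows raise errors naming the bound", {
  expect_error(predict_generation(200, 5), "oil flow above.*166.7")
  expect_error(predict_generation(1, 5), "oil flow below")
  expect_error(predict_generation(50, 20), "water flow above")
})

test_that("Poisson pmf and encapsulation statistics are exact", {
  expect_equal(encapsulation_stats(0)$p_empty, 1)
  expect_equal(encapsulation_stats(0)$p_single, 0)
  expect_equal(encapsulation_stats(0.1)$p_single, 0.1 * exp(-0.1))
  s <- encapsulation_stats(0.3)
  expect_equal(s$single_fraction_of_occupied,
               s$p_single / (1 - s$p_empty))
  expect_equal(sum(poisson_pmf(0.7, 0:50)), 1, tolerance = 1e-12)
  expect_error(poisson_pmf(-1, 0), "lambda")
})

test_that("Monte-Carlo encapsulation converges to the closed form", {
  lam <- 0.3
  draws <- simulate_encapsulation(lam, 1e5, seed = 9)
  kmax <- max(draws)
  emp <- tabulate(draws + 1L, nbins = kmax + 1L) / length(draws)
  ana <- poisson_pmf(lam, 0:kmax)
  tv <- 0.5 * (sum(abs(emp - ana)) + (1 - sum(ana)))
  expect_lte(tv, 0.01)
})

test_that("OD conversion uses the species factors", {
  expect_equal(od_to_cells(1, 1, "e_coli"), 2.88e8)
  expect_equal(od_to_cells(1, 1, "s_cerevisiae"), 1e7)
  expect_equal(od_to_cells(0, 10, "e_coli"), 0)
  expect_error(od_to_cells(1, 1, "b_subtilis"))
  # lambda plumbing: 140 um droplet, 500 cells/uL
  v <- droplet_volume_uL(140)
  expect_equal(v, pi / 6 * 140^3 * 1e-9)
  expect_equal(loading_lambda(500, v), 500 * v)
})

test_that("picoinjection endpoints, monotonicity and volume conservation", {
  expect_equal(picoinjection_volume_change(0), 0)
  expect_equal(picoinjection_volume_change(1), 0.50)
  expect_equal(picoinjection_volume_change(-1), -0.03)
  p <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(picoinjection_volume_change(p)) > 0))
  expect_error(picoinjection_volume_change(1.2), "\\[-1, 1\\]")
  inj <- picoinject(2, 0.6)
  expect_equal(inj$droplet_volume, 2 + inj$injected_volume)
  expect_equal(inj$injected_volume, 2 * 0.6 * 0.5)
})

test_that("sorting regimes reproduce the 1 mL/hr brackets", {
  expect_equal(as.character(classify_sorting(1, 99)), "no_deflection")
  expect_equal(as.character(classify_sorting(1, 250)), "sorted")
  expect_equal(as.character(classify_sorting(1, 401)), "failure")
  # a voltage scan shows exactly three contiguous regimes at any flow
  for (flow in c(0.25, 0.5, 1, 2, 4)) {
    lab <- as.character(classify_sorting(flow, 0:3000))
    runs <- rle(lab)
    expect_equal(runs$values, c("no_deflection", "sorted", "failure"),
                 info = paste("flow", flow))
  }
  # boundaries scale up with flow
  expect_equal(as.character(classify_sorting(2, 150)), "no_deflection")
})

test_that("anchor outcomes partition the flow axis in order", {
  expect_equal(as.character(anchor_outcome(1)), "trap_and_knock")
  expect_equal(as.character(anchor_outcome(0.1)), "stuck")
  expect_equal(as.character(anchor_outcome(3)), "pass")
  f <- seq(0, 3, by = 0.05)
  lab <- rle(as.character(anchor_outcome(f)))$values
  expect_equal(lab, c("stuck", "trap_and_knock", "pass"))
})
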