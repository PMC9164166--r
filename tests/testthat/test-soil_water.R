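test_that("root restriction follows the saturating exponential", {
  expect_equal(root_restriction(0), 0)
  up <- uptake_params(shape = 0.3, variant = "rld_only")
  expect_equal(root_restriction(1, params = up), 1 - exp(-0.3))
  expect_equal(root_restriction(1, params = up), 0.2592, tolerance = 1e-4)
  # young roots are up-weighted by the age-weighted variant
  aw <- uptake_params(youth = 20, variant = "age_weighted")
  expect_gte(root_restriction(0.8, rl_age = 5, params = aw),
             root_restriction(0.8, params = up))
  # at ages beyond youth the two variants agree
  expect_equal(root_restriction(0.8, rl_age = 40, params = aw),
               root_restriction(0.8, params = up))
  # monotone in density
  rld <- sort(runif(20, 0, 4))
  expect_true(all(diff(root_restriction(rld, params = up)) >= 0))
})

test_that("infiltration cascades to field capacity and closes mass", {
  cells <- discretise_profile(toy_profile(), dz = 10)
  # equilibrium: everything at field capacity, no rain
  th_fc <- cells$theta_fc
  r <- infiltrate(th_fc, cells, 0)
  expect_equal(r$theta, th_fc)
  expect_equal(r$runoff, 0); expect_equal(r$drainage, 0)

  # 20 mm on a profile 5 mm short of FC in cell 1: cell 1 tops up, rest cascades
  th <- th_fc; th[1] <- th[1] - 5 / (10 * 10)   # 5 mm deficit in 10 cm cell
  r <- infiltrate(th, cells, 20)
  expect_equal(r$theta[1] >= th_fc[1], TRUE)
  stored <- sum((r$theta - th) * cells$dz * 10)
  expect_equal(stored + r$runoff + r$drainage, 20, tolerance = 1e-9)

  # precipitation beyond total pore space: positive drainage and closure
  big <- 500
  r <- infiltrate(th_fc, cells, big)
  expect_gt(r$drainage, 0)
  stored <- sum((r$theta - th_fc) * cells$dz * 10)
  expect_equal(stored + r$runoff + r$drainage, big, tolerance = 1e-9)
  expect_true(all(r$theta <= cells$theta_s + 1e-12))
})

test_that("soil evaporation is supply-limited and never passes air-dry", {
  cells <- discretise_profile(toy_profile(), dz = 10)
  air_dry <- cells$theta_pwp / 2
  r <- evaporate(air_dry, cells, 5)
  expect_equal(r$evap, 0)
  expect_equal(r$theta, air_dry)

  wet <- cells$theta_fc
  r <- evaporate(wet, cells, 2)
  expect_equal(r$evap, 2, tolerance = 1e-9)

  half <- air_dry + 0.5 * (cells$theta_fc - air_dry)
  r <- evaporate(half, cells, 2)
  expect_gt(r$evap, 0); expect_lt(r$evap, 2)
  expect_true(all(r$theta >= air_dry - 1e-12))
})

test_that("transpiration extraction matches the proportional hand oracle", {
  cells <- discretise_profile(toy_profile(), dz = 10)[1:2, ]
  # theta such that available water is 3 mm and 1 mm
  th <- cells$theta_pwp + c(3, 1) / (cells$dz * 10)
  r <- extract_transpiration(th, cells, ptran = 2, frr = c(0.5, 0.5))
  expect_equal(r$uptake, c(1.5, 0.5))
  expect_equal(r$tranrf, 1)

  r0 <- extract_transpiration(th, cells, ptran = 0, frr = c(0.5, 0.5))
  expect_equal(r0$tran, 0); expect_equal(r0$tranrf, 1)

  dry <- cells$theta_pwp
  rd <- extract_transpiration(dry, cells, ptran = 2, frr = c(0.9, 0.9))
  expect_equal(rd$tran, 0); expect_equal(rd$tranrf, 0)
})

test_that("daily water step conserves mass over a random month", {
  cells <- discretise_profile(toy_profile(), dz = 10)
  set.seed(12)
  theta <- init_water_state(cells, 0.25)
  storage0 <- sum(theta * cells$dz * 10)
  in_sum <- 0; out_sum <- 0
  for (d in 1:30) {
    precip <- rbinom(1, 1, 0.4) * rgamma(1, 0.8, scale = 6)
    pet <- runif(1, 0.5, 5)
    lai <- runif(1, 0, 4)
    rld <- runif(nrow(cells), 0, 2)
    st <- step_water(theta, cells, precip, pet, lai, rld)
    expect_lt(abs(st$fluxes$closure_error), 1e-9)
    theta <- st$theta
    expect_true(all(theta >= 0 & theta <= cells$theta_s + 1e-12))
    in_sum <- in_sum + precip
    out_sum <- out_sum + st$fluxes$runoff + st$fluxes$drainage +
      st$fluxes$evap + st$fluxes$tran
  }
  storage1 <- sum(theta * cells$dz * 10)
  expect_equal(storage1 - storage0, in_sum - out_sum, tolerance = 1e-6)
})

test_that("the loosened topsoil stores more water after a saturation event", {
  ctl <- discretise_profile(cka_soil_profile("control"), dz = 5)
  dl <- discretise_profile(cka_soil_profile("DL"), dz = 5)
  th_c <- init_water_state(ctl, 0.25)
  th_d <- init_water_state(dl, 0.25)
  rc <- infiltrate(th_c, ctl, 120)
  rd <- infiltrate(th_d, dl, 120)
  top <- which(ctl$z_bot <= 30)
  expect_gt(sum(rd$theta[top] * dl$dz[top]), sum(rc$theta[top] * ctl$dz[top]))
})
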