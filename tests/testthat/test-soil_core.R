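test_that("penetration resistance reproduces the power-law arithmetic", {
  pp <- penetrometer_params()
  # frozen from direct arithmetic evaluation: a * bd^b * theta^c
  expect_equal(penetration_resistance(1.3, 0.31, pp),
               0.00587 * 1.3^8.0772 * 0.31^-4.65)
  expect_equal(penetration_resistance(1.3, 0.31, pp), 11.3, tolerance = 0.01)
  expect_equal(penetration_resistance(1.5, 0.30, pp), 41.9, tolerance = 0.01)
  # unit water content collapses the theta term
  expect_equal(penetration_resistance(1.4, 1, pp), 0.00587 * 1.4^8.0772)
  expect_error(penetration_resistance(0, 0.3, pp), "bulk density")
  expect_error(penetration_resistance(1.3, 0, pp), "water content")
  expect_error(penetrometer_params(c = 1), "c")
})

test_that("penetration resistance is monotone in bulk density and water", {
  pp <- penetrometer_params()
  set.seed(101)
  for (i in 1:25) {
    bd <- sort(runif(2, 1.0, 1.8))
    th <- sort(runif(2, 0.08, 0.45))
    expect_gt(penetration_resistance(bd[2], th[1], pp),
              penetration_resistance(bd[1], th[1], pp))
    expect_lt(penetration_resistance(bd[1], th[2], pp),
              penetration_resistance(bd[1], th[1], pp))
  }
})

test_that("mechanical stress factor decays exponentially with strength", {
  expect_equal(alpha_strength(0, -0.4325), 1)
  expect_equal(alpha_strength(1, -0.4325), exp(-0.4325))
  expect_equal(alpha_strength(1, -0.4325), 0.6489, tolerance = 1e-4)
  # a small calibrated x compensates the large Qp values of the regression
  expect_equal(alpha_strength(41.9, -0.0025), 0.90, tolerance = 0.005)
  expect_error(alpha_strength(1, 0.1), "<= 0")
  expect_error(alpha_strength(-1, -0.1), ">= 0")
})

test_that("water-status factor is the expected trapezoid", {
  l <- list(pwp = 0.13, red = 0.22, s = 0.45)
  a <- function(th) alpha_water(th, l$pwp, l$red, l$s)
  expect_equal(a(l$pwp), 0)
  expect_equal(a(0.05), 0)
  expect_equal(a(l$red), 1)
  expect_equal(a((l$pwp + l$red) / 2), 0.5)
  expect_equal(a(0.30), 1)                       # plateau
  expect_equal(a(l$s), 0)                        # saturated: no aeration
  expect_equal(a(l$s - 0.04), 1)                 # aeration ramp onset
  expect_equal(a(l$s - 0.02), 0.5)
  expect_error(a(0.5), "theta_s")
})

test_that("packaged soil profiles reproduce the published table", {
  ctl <- cka_soil_profile("control")
  dl <- cka_soil_profile("DL")
  expect_equal(nrow(ctl), 8)
  expect_equal(max(ctl$z_bot_cm), 210)
  r1 <- ctl[ctl$z_top_cm == 0, ]
  expect_equal(r1$bd, 1.3)
  expect_equal(r1$theta_fc, 0.31)
  expect_equal(r1$theta_pwp, 0.13)
  expect_equal(dl$bd[dl$z_top_cm == 30], 1.33)
  expect_equal(ctl$bd[ctl$z_top_cm == 30], 1.56)
  # loosening reduced 30-45 cm bulk density by about 16 percent
  expect_equal(100 * (1.56 - 1.33) / 1.56, 14.7, tolerance = 0.1)
})

test_that("profile validation rejects broken inputs", {
  bad <- cka_soil_profile("control")
  bad$theta_fc[2] <- bad$theta_s[2] + 0.01
  expect_error(load_soil_profile(bad), "anchors")
  gap <- cka_soil_profile("control")
  gap$z_top_cm[3] <- gap$z_top_cm[3] + 1
  expect_error(load_soil_profile(gap), "contiguous")
  deep <- cka_soil_profile("control")
  deep$z_top_cm[1] <- 5
  expect_error(load_soil_profile(deep), "surface")
})

test_that("profile load -> write -> load round-trips losslessly", {
  ctl <- cka_soil_profile("control")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_soil_profile(ctl, tmp)
  again <- load_soil_profile(tmp)
  expect_equal(tibble::as_tibble(unclass(again)),
               tibble::as_tibble(unclass(ctl)))
})

test_that("stress field factorises and is bounded", {
  cells <- discretise_profile(cka_soil_profile("control"), dz = 5)
  set.seed(7)
  theta <- runif(nrow(cells), 0.05, 0.38)
  theta <- pmin(theta, cells$theta_s)
  sf <- stress_reduction_field(cells, theta, stressp = stress_params(x = -0.0025))
  expect_equal(sf$srf, sf$alpha_qp * sf$alpha_h)
  for (col in c("alpha_qp", "alpha_h", "srf")) {
    expect_true(all(sf[[col]] >= 0 & sf[[col]] <= 1))
  }
  # wilting point annihilates srf regardless of bulk density
  sf0 <- stress_reduction_field(cells, cells$theta_pwp,
                                stressp = stress_params(x = -0.0025))
  expect_true(all(sf0$srf == 0))
})

test_that("loosened subsoil is mechanically easier at equal water content", {
  sp <- stress_params(x = -0.0025)
  ctl <- discretise_profile(cka_soil_profile("control"), dz = 5)
  dl <- discretise_profile(cka_soil_profile("DL"), dz = 5)
  th <- rep(0.25, nrow(ctl))
  s_ctl <- stress_reduction_field(ctl, th, stressp = sp)
  s_dl <- stress_reduction_field(dl, th, stressp = sp)
  band <- which(ctl$z_top >= 30 & ctl$z_bot <= 45)
  expect_true(all(s_dl$srf[band] > s_ctl$srf[band]))
})
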