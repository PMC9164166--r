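test_that("carbon reconciliation follows the availability contract", {
  expect_equal(reconcile_carbon(2, 1), list(scale = 1, surplus = 1))
  expect_equal(reconcile_carbon(1, 2), list(scale = 0.5, surplus = 0))
  expect_equal(reconcile_carbon(3, 0), list(scale = 1, surplus = 3))
  expect_equal(reconcile_carbon(0, 0), list(scale = 1, surplus = 0))
  expect_error(reconcile_carbon(-1, 0))
})

test_that("stress limits root growth before carbon does", {
  # abundant carbon, srf < 1: growth equals the stress-limited potential
  types <- list(taproot = root_type_params("taproot", r = 3, lmax = 100,
                                           tropism_sigma = 0, srw = 2e-5))
  sys <- new_root_system(types, sowing_depth = 0, plant_area = 30)
  req <- required_carbon(sys, 1, function(z) 0.4)
  rec <- reconcile_carbon(1, req)           # 1 g >> req
  expect_equal(rec$scale, 1)
  grow_step(sys, 1, function(z) 0.4, rec$scale)
  expect_equal(sys$axes[[1]]$length,
               0.4 * target_length(1, 3, 100), tolerance = 1e-12)

  # no stress, scarce carbon: growth equals available / SRW
  sys2 <- new_root_system(types, sowing_depth = 0, plant_area = 30)
  req2 <- required_carbon(sys2, 1)
  avail <- req2 / 4
  rec2 <- reconcile_carbon(avail, req2)
  grow_step(sys2, 1, function(z) 1, rec2$scale)
  expect_equal(sys2$axes[[1]]$length * 2e-5, avail, tolerance = 1e-12)
})

test_that("a short coupled run is mass-closed, lagged and deterministic", {
  w <- toy_weather(45, precip = 2)
  cfg <- sim_config(crop_barley(), cka_soil_profile("control"), w,
                    root_model = "3d", seed = 5,
                    start_date = "2019-03-01", sowing_date = "2019-03-05")
  r1 <- run_season(cfg)
  r2 <- run_season(cfg)
  expect_identical(r1$daily, r2$daily)       # bit-reproducible
  expect_lt(r1$summary$water_closure_max, 1e-9)
  expect_lt(r1$summary$carbon_closure_max, 1e-9)
  # before sowing only the water balance moves
  pre <- r1$daily[r1$daily$date < as.Date("2019-03-05"), ]
  expect_true(all(pre$dw == 0 & pre$rooting_depth == 0 & pre$lai == 0))
  # root bookkeeping: spent carbon equals built length times SRW (per m2)
  s <- summarise_roots(r1$roots3d)
  dens <- crop_barley()$sowing_density
  expect_equal(s$carbon_spent * dens, sum(r1$daily$root_carbon_spent),
               tolerance = 1e-9)
})

test_that("season results carry tidy, glance and plot methods", {
  w <- toy_weather(40, precip = 2)
  res <- run_season(sim_config(crop_barley(), cka_soil_profile("control"), w,
                               root_model = "1d", seed = 2,
                               sowing_date = "2019-03-05"))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("grain", "agb", "cum_tran", "max_rooting_depth")
                  %in% names(gl)))
  expect_equal(gl$cum_tran, sum(td$tran))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_rld_profile(res$rld_final), "ggplot")
})

test_that("both root models run the same contract", {
  w <- toy_weather(40, precip = 2)
  r3 <- run_season(sim_config(crop_barley(), cka_soil_profile("control"), w,
                              root_model = "3d", seed = 2,
                              sowing_date = "2019-03-05"))
  r1 <- run_season(sim_config(crop_barley(), cka_soil_profile("control"), w,
                              root_model = "1d", seed = 2,
                              sowing_date = "2019-03-05"))
  expect_identical(names(r3$daily), names(r1$daily))
  expect_identical(names(r3$summary), names(r1$summary))
  expect_gt(r3$summary$max_rooting_depth, 3)
  expect_gt(r1$summary$max_rooting_depth, 3)
})

test_that("a season errors when the weather ends before the start", {
  w <- toy_weather(10, start = "2019-05-01")
  expect_error(run_season(sim_config(crop_barley(),
                                     cka_soil_profile("control"), w,
                                     start_date = "2019-03-01")),
               "weather|start")
})
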