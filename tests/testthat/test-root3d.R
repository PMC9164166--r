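test_that("the negative-exponential growth law has the right anchors", {
  expect_equal(target_length(0, 1, 50), 0)
  expect_equal(target_length(1e6, 1, 50), 50, tolerance = 1e-6)
  expect_equal(target_length(10, 1, 50), 50 * (1 - exp(-0.2)))
  expect_equal(target_length(10, 1, 50), 9.063, tolerance = 1e-3)
  # initial slope equals r
  eps <- 1e-6
  expect_equal(target_length(eps, 2.5, 80) / eps, 2.5, tolerance = 1e-4)
})

test_that("potential elongation telescopes and stops at lmax", {
  types <- list(taproot = root_type_params("taproot", r = 2, lmax = 40,
                                           tropism_sigma = 0))
  sys <- new_root_system(types, sowing_depth = 0, plant_area = 30)
  ax <- sys$axes[[1]]
  pe1 <- potential_elongation(ax, 1, sys)
  expect_equal(pe1, target_length(1, 2, 40))
  expect_lt(pe1, 2)
  total <- 0
  for (d in 1:400) {
    total <- total + potential_elongation(ax, 1, sys)
    grow_step(sys, 1)
  }
  expect_lte(total, 40 + 1e-9)
  expect_equal(ax$length, 40, tolerance = 1e-3)
  expect_equal(potential_elongation(ax, 1, sys), 0)
})

test_that("an unstressed straight-down root matches the closed form", {
  types <- list(taproot = root_type_params("taproot", r = 3, lmax = 120,
                                           tropism_sigma = 0))
  sys <- new_root_system(types, sowing_depth = 3, plant_area = 30)
  for (d in 1:60) grow_step(sys, 1)
  ax <- sys$axes[[1]]
  expect_equal(ax$length, target_length(60, 3, 120), tolerance = 1e-6)
  # perfectly vertical: depth = sowing depth + length
  expect_equal(ax$nodes[ax$n, 3], 3 + ax$length, tolerance = 1e-6)
  expect_equal(ax$nodes[ax$n, 1], 0)
  # segment resolution respected
  segs <- root_segments(sys)
  expect_true(all(segs$length <= sys$seg_max + 1e-9))
})

test_that("stress and carbon scale growth multiplicatively", {
  types <- list(taproot = root_type_params("taproot", r = 3, lmax = 120,
                                           tropism_sigma = 0))
  sys <- new_root_system(types, sowing_depth = 0, plant_area = 30)
  grow_step(sys, 1, srf_at = function(z) 0)
  expect_equal(sys$axes[[1]]$length, 0)        # srf 0 freezes geometry
  grow_step(sys, 1, srf_at = function(z) 0.5, carbon_scale = 0.5)
  expect_equal(sys$axes[[1]]$length,
               0.25 * (target_length(2, 3, 120) - target_length(1, 3, 120)))
})

test_that("growth is bit-reproducible under a fixed seed", {
  a <- toy_root_system(seed = 9, days = 15)
  b <- toy_root_system(seed = 9, days = 15)
  expect_identical(root_segments(a), root_segments(b))
  c <- toy_root_system(seed = 10, days = 15)
  expect_false(identical(root_segments(a), root_segments(c)))
})

test_that("tropism selects headings toward the vertical", {
  h0 <- c(1, 0, 0)                      # horizontal start
  set.seed(5)
  expect_equal(tropism_heading(h0, 2, 0), h0)   # sigma 0: unchanged
  mean_z <- function(n) {
    mean(vapply(1:300, function(i) tropism_heading(h0, n, 0.3)[3], numeric(1)))
  }
  z1 <- mean_z(1); z6 <- mean_z(6)
  expect_gt(z6, z1)                     # stronger selection, more downward
  expect_equal(abs(z1), 0, tolerance = 0.05)  # n = 1 is an unbiased walk
  h <- tropism_heading(c(0, 0, 1), 3, 0.4)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
})

test_that("laterals emerge at the documented arclength positions", {
  # grow a deterministic axis to a controlled length, then count branches
  types <- list(
    taproot = root_type_params("taproot", r = 4, lmax = 100, ln = 3,
                               lb = 2, la = 4, tropism_sigma = 0,
                               successor = "lateral"),
    lateral = root_type_params("lateral", r = 1, lmax = 10, tropism_sigma = 0.2))
  set.seed(2)
  sys <- new_root_system(types, sowing_depth = 0, plant_area = 30)
  grow_step(sys, 1)                     # length ~3.9: below lb + la
  emerge_laterals(sys)
  expect_equal(length(sys$axes), 1)
  while (sys$axes[[1]]$length < 2 + 4 + 2 * 3 + 0.3) grow_step(sys, 1)
  len <- sys$axes[[1]]$length
  emerge_laterals(sys)
  expected <- floor((len - 4 - 2) / 3) + 1    # positions lb, lb+ln, ...
  expect_equal(length(sys$axes) - 1L, expected)
  expect_gte(expected, 3)
  # laterals sit on the parent polyline at the right depths (vertical parent)
  for (i in 2:length(sys$axes)) {
    z0 <- sys$axes[[i]]$nodes[1, 3]
    expect_equal((z0 - 2) %% 3, 0, tolerance = 1e-9)
  }
})

test_that("basal roots appear on schedule and respect maxB", {
  types <- root_types_barley(maxB = 5)
  types$basal$basal_delay <- 2
  set.seed(4)
  sys <- new_root_system(types, sowing_depth = 3, plant_area = 30)
  emerge_basals(sys)
  expect_equal(unname(sys$n_basal["basal"]), 1)   # one at time 0
  for (d in 1:7) { grow_step(sys, 1); emerge_basals(sys) }
  expect_equal(unname(sys$n_basal["basal"]), 4)   # t = 0, 2, 4, 6
  for (d in 1:20) { grow_step(sys, 1); emerge_basals(sys) }
  expect_equal(unname(sys$n_basal["basal"]), 5)   # capped at maxB
  # maxB = 0 never emits basals
  t0 <- root_types_barley(maxB = 0)
  sys0 <- new_root_system(t0, sowing_depth = 3, plant_area = 30)
  for (d in 1:10) { emerge_basals(sys0); grow_step(sys0, 1) }
  expect_equal(unname(sys0$n_basal["basal"]), 0)
})

test_that("carbon demand is the stress-limited elongation times SRW", {
  types <- list(taproot = root_type_params("taproot", r = 2, lmax = 50,
                                           tropism_sigma = 0, srw = 2e-5))
  sys <- new_root_system(types, sowing_depth = 0, plant_area = 30)
  expect_equal(required_carbon(sys, 1, function(z) 0), 0)
  pe <- potential_elongation(sys$axes[[1]], 1, sys)
  expect_equal(required_carbon(sys, 1, function(z) 0.6), 0.6 * pe * 2e-5)
  types2 <- list(taproot = root_type_params("taproot", r = 2, lmax = 50,
                                            tropism_sigma = 0, srw = 4e-5))
  sys2 <- new_root_system(types2, sowing_depth = 0, plant_area = 30)
  expect_equal(required_carbon(sys2, 1), 2 * required_carbon(sys, 1))
})

test_that("carbon accounting matches grown length exactly", {
  sys <- toy_root_system(seed = 3, days = 20)
  s <- summarise_roots(sys)
  # single SRW across types: spent = total length * SRW
  expect_equal(s$carbon_spent, s$total_length * 2e-5, tolerance = 1e-12)
  expect_gt(s$total_length, 0)
  expect_gt(s$max_depth, 3)
})

test_that("voxelised RLD matches independent oracles", {
  # single vertical root spanning whole layers: RLD = 1 / plant_area
  types <- list(taproot = root_type_params("taproot", r = 5, lmax = 60,
                                           tropism_sigma = 0))
  sys <- new_root_system(types, sowing_depth = 0, plant_area = 25)
  for (d in 1:40) grow_step(sys, 1)
  prof <- rld_profile(sys, dz = 3)
  full <- prof$rld[prof$z_bot <= floor(sys$axes[[1]]$length / 3) * 3]
  expect_equal(full, rep(1 / 25, length(full)), tolerance = 1e-9)

  # empty system: all zeros
  empty <- new_root_system(types, sowing_depth = 3, plant_area = 25)
  expect_true(all(rld_profile(empty, dz = 3)$rld == 0))

  # random branched system vs fine-resampling oracle
  sys2 <- toy_root_system(seed = 21, days = 22)
  segs <- root_segments(sys2)
  expect_gt(nrow(segs), 400)
  z_max <- 3 * ceiling(max(segs$z1, segs$z2) / 3)
  prof2 <- rld_profile(sys2, dz = 3, z_max = z_max)
  oracle <- rld_bruteforce(segs, dz = 3, z_max = z_max,
                           plant_area = sys2$plant_area)
  expect_equal(prof2$rld, oracle, tolerance = 1e-6)
})

test_that("uniformly higher stress reduction never shortens the system", {
  grow_under <- function(srf) {
    set.seed(77)
    sys <- new_root_system(root_types_barley(), sowing_depth = 3,
                           plant_area = 30)
    for (d in 1:20) {
      emerge_basals(sys); emerge_laterals(sys)
      grow_step(sys, 1, srf_at = function(z) srf)
    }
    summarise_roots(sys)$total_length
  }
  expect_gte(grow_under(0.9), grow_under(0.4))
  expect_gte(grow_under(0.4), grow_under(0.1))
})

test_that("RSML export is well-formed and complete", {
  sys <- toy_root_system(seed = 2, days = 12)
  tmp <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(sys, tmp)
  doc <- xml2::read_xml(tmp)
  roots <- xml2::xml_find_all(doc, ".//root")
  expect_equal(length(roots), length(sys$axes))
  pts <- xml2::xml_find_all(doc, ".//polyline/point")
  expect_equal(length(pts), sum(vapply(sys$axes, function(a) a$n, integer(1))))
})
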