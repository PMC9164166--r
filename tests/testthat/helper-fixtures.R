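# Shared fixtures built in code.

# minimal 3-layer soil profile for hand-checkable water balance tests
toy_profile <- function() {
  load_soil_profile(tibble::tibble(
    treatment = "toy",
    z_top_cm = c(0, 10, 20), z_bot_cm = c(10, 20, 30),
    theta_fc = 0.30, theta_red = 0.22, theta_pwp = 0.13, theta_s = 0.45,
    bd = 1.4, clay = 17, sand = 8, silt = 75, soc = 0.8))
}

# short constant weather series (no rain by default)
toy_weather <- function(n = 30, start = "2019-03-01", tmin = 8, tmax = 18,
                        radiation = 15, precip = 0) {
  tibble::tibble(
    date = seq(as.Date(start), by = "day", length.out = n),
    tmin = tmin, tmax = tmax, radiation = radiation, precip = precip)
}

# a small stochastic root system grown for `days` under no stress
toy_root_system <- function(seed = 1, days = 25, types = NULL) {
  if (is.null(types)) types <- root_types_barley()
  set.seed(seed)
  sys <- new_root_system(types, sowing_depth = 3, plant_area = 30)
  for (d in seq_len(days)) {
    emerge_basals(sys)
    emerge_laterals(sys)
    grow_step(sys, 1)
  }
  sys
}

# Independent root-length-density oracle: parametric resampling of every
# segment into pieces at most `piece` long, pieces split exactly at layer
# boundaries, binned by midpoint.
rld_bruteforce <- function(segs, dz, z_max, plant_area, piece = 0.01) {
  n_bin <- ceiling(z_max / dz - 1e-9)
  acc <- numeric(n_bin)
  for (i in seq_len(nrow(segs))) {
    len <- segs$length[i]
    if (len <= 0) next
    np <- max(1L, ceiling(len / piece))
    tpar <- seq(0, 1, length.out = np + 1)
    za <- segs$z1[i] + tpar[-length(tpar)] * (segs$z2[i] - segs$z1[i])
    zb <- segs$z1[i] + tpar[-1] * (segs$z2[i] - segs$z1[i])
    plen <- rep(len / np, np)
    lo <- pmin(za, zb); hi <- pmax(za, zb)
    bin_lo <- floor(lo / dz); bin_hi <- floor((hi - 1e-15) / dz)
    same <- bin_lo == bin_hi | hi - lo < 1e-15
    for (j in seq_len(np)) {
      if (same[j]) {
        b <- bin_lo[j] + 1L
        if (b >= 1 && b <= n_bin) acc[b] <- acc[b] + plen[j]
      } else {
        zb_edge <- dz * bin_hi[j]          # the single boundary crossed
        f <- (zb_edge - lo[j]) / (hi[j] - lo[j])
        b1 <- bin_lo[j] + 1L; b2 <- bin_hi[j] + 1L
        if (b1 >= 1 && b1 <= n_bin) acc[b1] <- acc[b1] + plen[j] * f
        if (b2 >= 1 && b2 <= n_bin) acc[b2] <- acc[b2] + plen[j] * (1 - f)
      }
    }
  }
  acc / (plant_area * dz)
}
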