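#' Water-uptake restriction parameters
#'
#' Controls how root length density (and optionally root age) limits
#' per-layer water extraction through the root restriction factor
#' `FRR(i) = 1 - exp(-shape * RDA4AGE(i))`.
#'
#' @param youth Age (days) below which roots count as fully active.
#' @param shape Exponent coefficient of the restriction curve (default 0.3).
#' @param variant `"age_weighted"` uses
#'   `RDA4AGE = max(RLD, RLD * youth / RLAGE)` (young roots up-weighted);
#'   `"rld_only"` uses `RDA4AGE = RLD`. The 3D architectural root model runs
#'   with `"rld_only"` (its density is resolved per depth already); the 1D
#'   conceptual model uses `"age_weighted"`.
#' @return A list of class `uptake_params`.
#' @export
uptake_params <- function(youth = 20, shape = 0.3,
                          variant = c("age_weighted", "rld_only")) {
  stopifnot(youth > 0, shape > 0)
  structure(list(youth = youth, shape = shape, variant = match.arg(variant)),
            class = "uptake_params")
}

#' Root restriction factor for water uptake
#'
#' @param rld Per-cell root length density, cm cm-3.
#' @param rl_age Per-cell mean root age, days (used by the `age_weighted`
#'   variant; ignored otherwise).
#' @param params An [uptake_params()] object.
#' @return Per-cell FRR in [0, 1], monotone non-decreasing in `rld`.
#' @export
root_restriction <- function(rld, rl_age = NULL, params = uptake_params()) {
  stopifnot(all(rld >= 0))
  rda <- rld
  if (params$variant == "age_weighted" && !is.null(rl_age)) {
    age <- pmax(rl_age, 1e-9)
    rda <- pmax(rld, rld * params$youth / age)
  }
  pmin(1, 1 - exp(-params$shape * rda))
}

#' Initialise the soil water state
#'
#' @param cells Discretised profile from [discretise_profile()].
#' @param theta Initial per-cell volumetric water content: a single value, a
#'   vector of length `nrow(cells)`, or a function of cell mid depth (cm).
#' @return Numeric vector of per-cell theta, clamped to `[0, theta_s]`.
#' @export
init_water_state <- function(cells, theta = 0.25) {
  th <- if (is.function(theta)) theta(cells$z_mid) else rep(theta, length.out = nrow(cells))
  pmin(pmax(th, 0), cells$theta_s)
}

# mm of water held per cell at given theta: theta [cm3/cm3] * dz [cm] * 10 mm/cm
.cell_mm <- function(theta, dz) theta * dz * 10

#' Infiltration and drainage step
#'
#' Tipping-bucket cascade: incoming water fills cells to field capacity top
#' down; remaining excess fills toward saturation top down; anything beyond
#' total saturated capacity runs off. The transient store between field
#' capacity and saturation then drains downward at a first-order daily
#' fraction, the bottom cell's share leaving the profile as drainage.
#'
#' @param theta Per-cell water content, cm3 cm-3.
#' @param cells Discretised profile.
#' @param precip Incoming water at the surface, mm.
#' @param drain_frac Daily drainage fraction of the above-FC store.
#' @return List `theta`, `runoff`, `drainage` (mm).
#' @export
infiltrate <- function(theta, cells, precip, drain_frac = 0.5) {
  stopifnot(precip >= 0)
  dz <- cells$dz
  mm <- .cell_mm(theta, dz)
  fc_mm <- .cell_mm(cells$theta_fc, dz)
  s_mm <- .cell_mm(cells$theta_s, dz)
  n <- length(mm)
  inflow <- precip
  for (i in seq_len(n)) {       # fill to field capacity
    if (inflow <= 0) break
    take <- min(inflow, max(0, fc_mm[i] - mm[i]))
    mm[i] <- mm[i] + take
    inflow <- inflow - take
  }
  for (i in seq_len(n)) {       # excess fills toward saturation
    if (inflow <= 0) break
    take <- min(inflow, max(0, s_mm[i] - mm[i]))
    mm[i] <- mm[i] + take
    inflow <- inflow - take
  }
  runoff <- max(0, inflow)
  # first-order drainage of the FC..S store, cascading downward
  carry <- 0
  for (i in seq_len(n)) {
    mm[i] <- mm[i] + carry
    over_s <- max(0, mm[i] - s_mm[i])      # pushed-in water beyond saturation moves on
    mm[i] <- mm[i] - over_s
    drained <- drain_frac * max(0, mm[i] - fc_mm[i])
    mm[i] <- mm[i] - drained
    carry <- over_s + drained
  }
  drainage <- carry
  list(theta = mm / (dz * 10), runoff = runoff, drainage = drainage)
}

#' Soil evaporation step
#'
#' Extracts the evaporative demand from the cells above `evap_depth`,
#' linearly reduced to zero as the (surface-weighted) topsoil water content
#' approaches air-dryness (half the wilting point). Extraction is
#' concentrated near the surface (exponential decay with depth, e-folding
#' `z_decay`), so deeper topsoil dries more slowly than the immediate
#' surface. Water content never falls below air-dry.
#'
#' @param theta Per-cell water content.
#' @param cells Discretised profile.
#' @param pevap Potential soil evaporation, mm.
#' @param evap_depth Depth of the evaporating topsoil, cm.
#' @param z_decay E-folding depth of the extraction weight, cm.
#' @return List `theta`, `evap` (actual evaporation, mm).
#' @export
evaporate <- function(theta, cells, pevap, evap_depth = 15, z_decay = 7) {
  stopifnot(pevap >= 0)
  top <- which(cells$z_top < evap_depth)
  if (!length(top) || pevap == 0) return(list(theta = theta, evap = 0))
  dz <- cells$dz[top]
  air_dry <- cells$theta_pwp[top] / 2
  avail_mm <- pmax(0, .cell_mm(theta[top] - air_dry, dz))
  wz <- exp(-cells$z_mid[top] / z_decay) * dz
  fc_mean <- sum(cells$theta_fc[top] * wz) / sum(wz)
  ad_mean <- sum(air_dry * wz) / sum(wz)
  th_mean <- sum(theta[top] * wz) / sum(wz)
  wetness <- max(0, min(1, (th_mean - ad_mean) / (fc_mean - ad_mean)))
  demand <- pevap * wetness
  evap <- min(demand, sum(avail_mm))
  if (evap > 0) {
    w_ext <- avail_mm * exp(-cells$z_mid[top] / z_decay)
    w_ext <- w_ext / sum(w_ext)
    take <- pmin(evap * w_ext, avail_mm)
    rem <- evap - sum(take)                # redistribute if a cell capped
    for (k in 1:3) {
      if (rem <= 1e-12) break
      room <- avail_mm - take
      add <- pmin(rem * room / sum(room), room)
      take <- take + add
      rem <- rem - sum(add)
    }
    evap <- sum(take)
    theta[top] <- theta[top] - take / (dz * 10)
  }
  list(theta = theta, evap = evap)
}

#' Transpiration extraction and the transpiration reduction factor
#'
#' Distributes the transpiration demand over cells proportionally to
#' `FRR(i) * AW(i)` where `AW(i) = max(0, theta - theta_pwp) * dz` is the
#' plant-available water, and caps per-cell uptake at `FRR(i) * AW(i)` so
#' that sparse young root systems cannot exhaust a layer in one day. The
#' transpiration reduction factor is `TRANRF = min(1, TRAN / PTRAN)`, with
#' the convention `TRANRF = 1` when `PTRAN = 0`.
#'
#' @param theta Per-cell water content.
#' @param cells Discretised profile.
#' @param ptran Potential transpiration, mm.
#' @param frr Per-cell root restriction factor in [0, 1].
#' @return List `theta`, `uptake` (per-cell mm), `tran`, `ptran`, `tranrf`.
#' @export
extract_transpiration <- function(theta, cells, ptran, frr) {
  stopifnot(ptran >= 0, length(frr) == nrow(cells), all(frr >= 0), all(frr <= 1))
  aw <- pmax(0, .cell_mm(theta - cells$theta_pwp, cells$dz))
  cap <- frr * aw
  total_cap <- sum(cap)
  if (ptran == 0 || total_cap <= 0) {
    tran <- 0
    uptake <- rep(0, nrow(cells))
  } else {
    tran <- min(ptran, total_cap)
    uptake <- tran * cap / total_cap
    theta <- theta - uptake / (cells$dz * 10)
  }
  tranrf <- if (ptran == 0) 1 else min(1, tran / ptran)
  list(theta = theta, uptake = uptake, tran = tran, ptran = ptran,
       tranrf = tranrf)
}

#' One daily soil-water step
#'
#' Orchestrates infiltration (with drainage and runoff), soil evaporation
#' and root water extraction for one day, and checks mass closure.
#'
#' @param theta Per-cell water content at the start of the day.
#' @param cells Discretised profile.
#' @param precip Precipitation, mm.
#' @param pet Potential evapotranspiration, mm.
#' @param lai Leaf area index used to split the demand.
#' @param rld Per-cell root length density (cm cm-3).
#' @param rl_age Per-cell mean root age (days), optional.
#' @param up_params An [uptake_params()] object.
#' @param k_ext Canopy extinction coefficient.
#' @param evap_depth,drain_frac See [evaporate()] and [infiltrate()].
#' @return List `theta`, `fluxes` (one-row tibble), `stress`
#'   (`tran, ptran, tranrf`).
#' @export
step_water <- function(theta, cells, precip, pet, lai, rld,
                       rl_age = NULL, up_params = uptake_params(),
                       k_ext = 0.6, evap_depth = 15, drain_frac = 0.5) {
  storage0 <- sum(.cell_mm(theta, cells$dz))
  dem <- split_demand(pet, lai, k_ext)
  inf <- infiltrate(theta, cells, precip, drain_frac)
  ev <- evaporate(inf$theta, cells, dem$pevap, evap_depth)
  frr <- root_restriction(rld, rl_age, up_params)
  tr <- extract_transpiration(ev$theta, cells, dem$ptran, frr)
  storage1 <- sum(.cell_mm(tr$theta, cells$dz))
  closure <- storage1 - storage0 -
    (precip - inf$runoff - inf$drainage - ev$evap - tr$tran)
  fluxes <- tibble::tibble(
    precip = precip, runoff = inf$runoff, drainage = inf$drainage,
    evap = ev$evap, tran = tr$tran, ptran = dem$ptran, pevap = dem$pevap,
    tranrf = tr$tranrf, storage = storage1, closure_error = closure
  )
  list(theta = tr$theta, fluxes = fluxes, uptake = tr$uptake,
       stress = list(tran = tr$tran, ptran = dem$ptran, tranrf = tr$tranrf))
}
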