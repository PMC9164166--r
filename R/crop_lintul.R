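#' Crop parameter set
#'
#' Parameters of the light-use-efficiency shoot engine: thermal-time
#' phenology, Beer's-law light interception, biomass partitioning over
#' development stage, juvenile leaf-area dynamics and senescence. Defaults
#' follow standard LINTUL-2 practice for temperate cereals; `crop_barley()`
#' and `crop_wheat()` provide tuned presets.
#'
#' @param name Crop label.
#' @param tsum_emergence Thermal time from sowing to emergence, degC d.
#' @param tsum_anthesis,tsum_maturity Thermal time (degC d, from emergence)
#'   to anthesis (DVS = 1) and maturity (DVS = 2).
#' @param t_base Base temperature, degC.
#' @param lue Light use efficiency, g dry matter per MJ intercepted PAR.
#' @param k_ext Canopy extinction coefficient.
#' @param sla Specific leaf area, m2 per g leaf.
#' @param rgrl Juvenile relative LAI growth rate, (degC d)^-1.
#' @param lai_init LAI installed at emergence.
#' @param lai_juvenile LAI below which growth is exponential.
#' @param leaf_death_rate Post-anthesis first-order leaf/LAI decay, d^-1.
#' @param root_turnover First-order root biomass turnover, d^-1.
#' @param partitioning Tibble `dvs, root, leaf, stem, storage`; rows must
#'   each sum to 1; linear interpolation in DVS.
#' @param sowing_density Plants per m2.
#' @param seed_reserve Seed carbon available to the young root system,
#'   g m-2, released uniformly over `seed_days` after sowing (the radicle
#'   and seminal roots grow from the seed before the shoot feeds them).
#' @param seed_days Days over which the seed reserve is released.
#' @param frtmod_offset Offset of the drought partitioning response
#'   `FRTMOD = max(1, 1 / (TRANRF + offset))`; the default 0.5 puts the
#'   response onset at TRANRF = 0.5 and caps FRTMOD at 2.
#' @param stress_x Strength-sensitivity coefficient used in the root
#'   elongation stress function for this crop.
#' @param max_front_rate Maximum vertical rooting-front advance of the 1D
#'   conceptual root model, m d^-1.
#' @return A list of class `crop_params`.
#' @export
crop_params <- function(name = "cereal",
                        tsum_emergence = 90,
                        tsum_anthesis = 900,
                        tsum_maturity = 1550,
                        t_base = 0,
                        lue = 3.0,
                        k_ext = 0.6,
                        sla = 0.022,
                        rgrl = 0.009,
                        lai_init = 0.012,
                        lai_juvenile = 0.75,
                        leaf_death_rate = 0.03,
                        root_turnover = 0.01,
                        partitioning = default_partitioning(),
                        sowing_density = 330,
                        seed_reserve = 6,
                        seed_days = 10,
                        frtmod_offset = 0.5,
                        stress_x = -0.0025,
                        max_front_rate = 0.033) {
  stopifnot(tsum_anthesis < tsum_maturity, lue > 0, sowing_density > 0)
  p <- tibble::as_tibble(partitioning)
  stopifnot(all(c("dvs", "root", "leaf", "stem", "storage") %in% names(p)))
  sums <- p$root + p$leaf + p$stem + p$storage
  if (any(abs(sums - 1) > 1e-9))
    stop("each partitioning row must sum to 1")
  structure(list(
    name = name, tsum_emergence = tsum_emergence,
    tsum_anthesis = tsum_anthesis, tsum_maturity = tsum_maturity,
    t_base = t_base, lue = lue, k_ext = k_ext, sla = sla, rgrl = rgrl,
    lai_init = lai_init, lai_juvenile = lai_juvenile,
    leaf_death_rate = leaf_death_rate, root_turnover = root_turnover,
    partitioning = p, sowing_density = sowing_density,
    seed_reserve = seed_reserve, seed_days = seed_days,
    frtmod_offset = frtmod_offset, stress_x = stress_x,
    max_front_rate = max_front_rate), class = "crop_params")
}

#' Default development-stage partitioning table
#'
#' Dry-matter allocation fractions to root, leaf, stem and storage organs as
#' a function of development stage (0 emergence, 1 anthesis, 2 maturity),
#' following the usual LINTUL-2 shape for temperate cereals: half of the
#' assimilate goes below ground at emergence, allocation shifts to stems
#' towards anthesis, and all post-anthesis growth fills the storage organs.
#'
#' @return A tibble `dvs, root, leaf, stem, storage`.
#' @export
default_partitioning <- function() {
  tibble::tribble(
    ~dvs, ~root, ~leaf, ~stem, ~storage,
    0.00, 0.50, 0.33, 0.17, 0.00,
    0.30, 0.35, 0.40, 0.25, 0.00,
    0.50, 0.25, 0.38, 0.37, 0.00,
    0.70, 0.15, 0.25, 0.60, 0.00,
    0.95, 0.10, 0.10, 0.80, 0.00,
    1.05, 0.00, 0.00, 0.00, 1.00,
    2.00, 0.00, 0.00, 0.00, 1.00
  )
}

#' Spring barley preset
#' @param ... Overrides passed to [crop_params()].
#' @export
crop_barley <- function(...) {
  args <- list(name = "spring_barley", tsum_emergence = 90,
               tsum_anthesis = 900, tsum_maturity = 1550,
               sowing_density = 330, stress_x = -0.0025)
  do.call(crop_params, utils::modifyList(args, list(...)))
}

#' Winter wheat preset
#'
#' Vernalisation and photoperiod are not modelled; the anthesis thermal-time
#' requirement is calibrated to absorb the overwintering delay.
#' @param ... Overrides passed to [crop_params()].
#' @export
crop_wheat <- function(...) {
  args <- list(name = "winter_wheat", tsum_emergence = 120,
               tsum_anthesis = 1300, tsum_maturity = 2050,
               sowing_density = 300, stress_x = -0.005)
  do.call(crop_params, utils::modifyList(args, list(...)))
}

#' Initial crop state
#'
#' @param params A [crop_params()] object.
#' @return A list of class `crop_state`: thermal time, development stage,
#'   LAI, live biomass pools (g m-2), dead-pool accumulators.
#' @export
init_crop_state <- function(params) {
  structure(list(
    tsum_sowing = 0, tsum = 0, dvs = 0, lai = 0, emerged = FALSE,
    w_root = 0, w_leaf = 0, w_stem = 0, w_storage = 0,
    w_leaf_dead = 0, w_root_dead = 0), class = "crop_state")
}

#' Advance phenology by one day
#'
#' Accumulates degree days above the base temperature; before emergence the
#' sum counts towards the emergence requirement, afterwards towards the
#' anthesis/maturity requirements. Development stage is piecewise linear in
#' thermal time: 0..1 to anthesis, 1..2 to maturity, capped at 2.
#'
#' @param state A `crop_state`.
#' @param tmean Daily mean air temperature, degC.
#' @param params A `crop_params`.
#' @export
advance_phenology <- function(state, tmean, params) {
  dd <- max(0, tmean - params$t_base)
  if (!state$emerged) {
    state$tsum_sowing <- state$tsum_sowing + dd
    if (state$tsum_sowing >= params$tsum_emergence) {
      state$emerged <- TRUE
      state$lai <- params$lai_init
    }
    return(state)
  }
  state$tsum <- state$tsum + dd
  state$dvs <- if (state$tsum <= params$tsum_anthesis) {
    state$tsum / params$tsum_anthesis
  } else {
    min(2, 1 + (state$tsum - params$tsum_anthesis) /
          (params$tsum_maturity - params$tsum_anthesis))
  }
  state
}

#' Drought modification of the root partitioning fraction
#'
#' `FRTMOD = max(1, 1 / (TRANRF + 0.5))`: equal to 1 for TRANRF >= 0.5
#' (no or mild stress), rising to 2 as TRANRF falls to 0, so that moderate
#' to severe drought shifts assimilate towards the roots.
#'
#' @param tranrf Transpiration reduction factor in [0, 1]. Vectorised.
#' @param offset Response offset (default 0.5).
#' @export
frtmod <- function(tranrf, offset = 0.5) {
  stopifnot(all(tranrf >= 0), all(tranrf <= 1))
  pmax(1, 1 / (tranrf + offset))
}

#' Daily biomass growth
#'
#' `dW = LUE * PAR_intercepted * TRANRF`, with intercepted PAR
#' `0.5 * radiation * (1 - exp(-k_ext * LAI))` (half of global radiation is
#' photosynthetically active).
#'
#' @param lai Leaf area index.
#' @param radiation Daily global radiation, MJ m-2.
#' @param tranrf Transpiration reduction factor.
#' @param params A `crop_params`.
#' @return Daily total growth, g m-2.
#' @export
grow_biomass <- function(lai, radiation, tranrf, params) {
  stopifnot(lai >= 0, radiation >= 0, tranrf >= 0)
  par_int <- 0.5 * radiation * (1 - exp(-params$k_ext * lai))
  params$lue * par_int * tranrf
}

#' Interpolate the partitioning table at a development stage
#' @param dvs Development stage.
#' @param params A `crop_params`.
#' @return Named vector `root, leaf, stem, storage` summing to 1.
#' @export
partition_fractions <- function(dvs, params) {
  p <- params$partitioning
  d <- min(max(dvs, min(p$dvs)), max(p$dvs))
  f <- vapply(c("root", "leaf", "stem", "storage"), function(col)
    stats::approx(p$dvs, p[[col]], xout = d, rule = 2)$y, numeric(1))
  f / sum(f)
}

#' Partition daily growth into organ increments
#'
#' The tabulated root fraction is multiplied by the drought factor FRTMOD
#' (capped so the root share never exceeds 1); the remaining fractions are
#' scaled down equally so all fractions still sum to 1. Increments sum to
#' `dw` exactly.
#'
#' @param dw Daily growth, g m-2.
#' @param dvs Development stage.
#' @param frtmod_value Drought partitioning factor (>= 1).
#' @param params A `crop_params`.
#' @return Named numeric `root, leaf, stem, storage` increments (g m-2).
#' @export
partition <- function(dw, dvs, frtmod_value, params) {
  stopifnot(dw >= 0, frtmod_value >= 1)
  f <- partition_fractions(dvs, params)
  frt <- f[["root"]]
  frt2 <- min(1, frt * frtmod_value)
  if (frt >= 1) {
    if (frtmod_value > 1)
      warning("root fraction is already 1; FRTMOD has no effect")
    out <- c(root = 1, leaf = 0, stem = 0, storage = 0)
  } else {
    scale <- (1 - frt2) / (1 - frt)
    out <- c(root = frt2, leaf = f[["leaf"]] * scale,
             stem = f[["stem"]] * scale, storage = f[["storage"]] * scale)
  }
  inc <- dw * out
  resid <- dw - sum(inc)          # force exact carbon closure
  i <- which.max(inc)
  inc[i] <- inc[i] + resid
  inc
}

#' Update LAI, apply senescence
#'
#' Juvenile canopies (LAI below `lai_juvenile`, pre-anthesis) grow
#' exponentially with thermal time at rate `rgrl`; closed canopies gain
#' `sla * dLeaf`. After anthesis the leaf pool and LAI decay first-order at
#' `leaf_death_rate` (dead leaf is kept in a separate pool and still counts
#' towards above-ground biomass); roots turn over at `root_turnover`.
#'
#' @param state A `crop_state` (pools already incremented with today's
#'   shoot growth, root pool with today's root carbon).
#' @param inc Named increments from [partition()] (for the LAI source term).
#' @param tmean Daily mean temperature, degC.
#' @param params A `crop_params`.
#' @export
update_lai_and_senescence <- function(state, inc, tmean, params) {
  if (!state$emerged) return(state)
  dd <- max(0, tmean - params$t_base)
  if (state$dvs < 1 && state$lai < params$lai_juvenile) {
    state$lai <- state$lai * exp(params$rgrl * dd)
  } else {
    state$lai <- state$lai + params$sla * inc[["leaf"]]
  }
  if (state$dvs > 1) {
    died <- state$w_leaf * params$leaf_death_rate
    state$w_leaf <- state$w_leaf - died
    state$w_leaf_dead <- state$w_leaf_dead + died
    state$lai <- state$lai * (1 - params$leaf_death_rate)
    root_died <- state$w_root * params$root_turnover
    state$w_root <- state$w_root - root_died
    state$w_root_dead <- state$w_root_dead + root_died
  }
  state
}

#' Grain yield and above-ground biomass
#'
#' Converts g m-2 pools to t ha-1 (factor 0.01). Above-ground biomass
#' counts live and dead leaf, stem and storage.
#'
#' @param state A `crop_state`.
#' @return List `grain`, `agb` in t ha-1.
#' @export
yield_and_agb <- function(state) {
  grain <- state$w_storage * 0.01
  agb <- (state$w_leaf + state$w_leaf_dead + state$w_stem + state$w_storage) * 0.01
  list(grain = grain, agb = agb)
}
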