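#' Reconcile available and required root carbon
#'
#' Stress-limited potential root growth is costed first; if the shoot
#' provides less carbon than required, every root is limited equally by the
#' ratio, and if it provides more, the excess is returned to the shoot.
#'
#' @param available Carbon available for root growth, g per plant.
#' @param required Carbon required for stress-limited potential growth,
#'   g per plant.
#' @return List `scale` in [0, 1] and `surplus` (g per plant);
#'   `required = 0` gives `scale = 1`.
#' @export
reconcile_carbon <- function(available, required) {
  stopifnot(available >= 0, required >= 0)
  if (required <= available) {
    list(scale = 1, surplus = available - required)
  } else {
    list(scale = available / required, surplus = 0)
  }
}

#' Simulation configuration
#'
#' Assembles everything a season run needs. The weather series must cover
#' the whole run (start to maturity).
#'
#' @param crop A [crop_params()] object.
#' @param soil A `soil_profile` (e.g. [cka_soil_profile()]).
#' @param weather A weather tibble ([read_weather()] / [synth_weather()]).
#' @param root_model `"3d"` (architectural) or `"1d"` (conceptual).
#' @param seed Integer seed for the stochastic 3D root growth.
#' @param start_date,sowing_date Run start and sowing dates (Date or ISO
#'   string). Defaults: start 1 March, sow 27 March of the weather's year
#'   (spring crop convention); pass explicit dates for winter crops.
#' @param sowing_depth Seed depth, cm.
#' @param theta_init Initial water content: function of depth (cm) or
#'   vector/scalar; default 0.25 above 30 cm and 0.30 below.
#' @param dz_water Water/stress cell thickness, cm.
#' @param dz_rld Root length density reporting bin, cm.
#' @param root_types Named list of [root_type_params()]; defaults chosen by
#'   crop name.
#' @param pen_params [penetrometer_params()].
#' @param aeration_margin Margin of the hydric stress ramp, cm3 cm-3.
#' @param slim Optional [slimroots_params()] for the 1D model.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(crop, soil, weather, root_model = c("3d", "1d"),
                       seed = 1L, start_date = NULL, sowing_date = NULL,
                       sowing_depth = 3, theta_init = NULL, dz_water = 5,
                       dz_rld = 3, root_types = NULL,
                       pen_params = penetrometer_params(),
                       aeration_margin = 0.04, slim = NULL) {
  root_model <- match.arg(root_model)
  yr <- as.integer(format(weather$date[1], "%Y"))
  if (is.null(start_date)) start_date <- as.Date(sprintf("%d-03-01", yr))
  if (is.null(sowing_date)) sowing_date <- as.Date(sprintf("%d-03-27", yr))
  start_date <- as.Date(start_date); sowing_date <- as.Date(sowing_date)
  if (start_date < weather$date[1] || sowing_date < start_date)
    stop("dates must satisfy weather start <= start_date <= sowing_date")
  if (is.null(theta_init))
    theta_init <- function(z) ifelse(z < 30, 0.25, 0.30)
  if (is.null(root_types)) {
    root_types <- if (identical(crop$name, "winter_wheat"))
      root_types_wheat() else root_types_barley()
  }
  if (is.null(slim))
    slim <- slimroots_params(max_front_rate = crop$max_front_rate)
  structure(list(
    crop = crop, soil = soil, weather = weather, root_model = root_model,
    seed = as.integer(seed), start_date = start_date,
    sowing_date = sowing_date, sowing_depth = sowing_depth,
    theta_init = theta_init, dz_water = dz_water, dz_rld = dz_rld,
    root_types = root_types, pen_params = pen_params,
    stressp = stress_params(x = crop$stress_x,
                            aeration_margin = aeration_margin),
    slim = slim), class = "sim_config")
}

#' Run one growing season
#'
#' The daily loop couples shoot, soil water and roots: (1) phenology from
#' air temperature; (2) evaporative demand split with yesterday's LAI;
#' (3) soil water step with yesterday's root length density, yielding the
#' transpiration reduction factor; (4) biomass growth, drought-modified
#' partitioning; (5) root carbon reconciliation -- the stress field from
#' today's water state limits potential root growth first, then carbon
#' limits all roots equally; surplus carbon returns to the shoot pools;
#' (6) the new root length density is recorded for tomorrow.
#'
#' @param config A [sim_config()].
#' @return A `sim_result` list: `daily` records tibble, `summary` one-row
#'   tibble (yield, above-ground biomass, anthesis/maturity dates,
#'   cumulative transpiration), `rld_flowering` and `rld_final` profiles
#'   (at `dz_rld` resolution), plus final model states.
#' @export
run_season <- function(config) {
  cfg <- config
  crop <- cfg$crop
  cells <- discretise_profile(cfg$soil, cfg$dz_water)
  theta <- init_water_state(cells, cfg$theta_init)
  cstate <- init_crop_state(crop)
  old_seed <- .Random.seed_exists()
  on.exit(.restore_seed(old_seed), add = TRUE)
  set.seed(cfg$seed)

  use_3d <- cfg$root_model == "3d"
  plant_area <- 1e4 / crop$sowing_density
  roots3d <- NULL
  slim <- NULL
  up_par <- uptake_params(variant = if (use_3d) "rld_only" else "age_weighted")

  w <- cfg$weather[cfg$weather$date >= cfg$start_date, ]
  if (!nrow(w)) stop("weather does not cover the run start")
  n_cell <- nrow(cells)
  rld <- numeric(n_cell); rl_age <- numeric(n_cell)
  lai_prev <- 0
  records <- vector("list", nrow(w))
  anthesis_date <- as.Date(NA); maturity_date <- as.Date(NA)
  rld_flowering <- NULL
  cum_dw <- 0; cum_root_spent <- 0; cum_surplus <- 0
  carbon_err_max <- 0; water_err_max <- 0

  for (d in seq_len(nrow(w))) {
    day <- w[d, ]
    tmean <- (day$tmin + day$tmax) / 2
    sown <- day$date >= cfg$sowing_date
    if (sown && is.null(roots3d) && is.null(slim)) {
      if (use_3d) {
        roots3d <- new_root_system(cfg$root_types,
                                   sowing_depth = cfg$sowing_depth,
                                   plant_area = plant_area)
      } else {
        slim <- init_slimroots(cells, cfg$sowing_depth)
      }
    }
    emerged_before <- cstate$emerged
    if (sown) cstate <- advance_phenology(cstate, tmean, crop)
    if (cstate$emerged && !emerged_before) lai_prev <- cstate$lai

    pet <- potential_et(day)
    ws <- step_water(theta, cells, day$precip, pet, lai_prev, rld, rl_age,
                     up_params = up_par, k_ext = crop$k_ext)
    theta <- ws$theta
    tranrf <- ws$stress$tranrf
    water_err_max <- max(water_err_max, abs(ws$fluxes$closure_error))

    dw <- 0; inc <- c(root = 0, leaf = 0, stem = 0, storage = 0)
    frt_value <- 1; scale <- 1
    spent_m2 <- 0; surplus_m2 <- 0
    stress <- stress_reduction_field(cells, theta, cfg$pen_params, cfg$stressp)
    seed_flux <- if (sown &&
                     as.integer(day$date - cfg$sowing_date) < crop$seed_days)
      crop$seed_reserve / crop$seed_days else 0
    if (cstate$emerged && cstate$dvs < 2) {
      dw <- grow_biomass(cstate$lai, day$radiation, tranrf, crop)
      frt_value <- frtmod(tranrf, crop$frtmod_offset)
      inc <- partition(dw, cstate$dvs, frt_value, crop)
    }
    if (sown && cstate$dvs < 2) {
      avail_m2 <- inc[["root"]] + seed_flux
      srf_at <- stress_lookup(stress)
      if (use_3d) {
        emerge_basals(roots3d)
        emerge_laterals(roots3d)
        avail_plant <- avail_m2 / crop$sowing_density
        req_plant <- required_carbon(roots3d, 1, srf_at)
        rec <- reconcile_carbon(avail_plant, req_plant)
        scale <- rec$scale
        spent0 <- roots3d$carbon_spent
        grow_step(roots3d, 1, srf_at, scale)
        spent_plant <- roots3d$carbon_spent - spent0
        spent_m2 <- spent_plant * crop$sowing_density
        surplus_m2 <- max(0, avail_m2 - spent_m2)
        prof <- rld_profile(roots3d, dz = cfg$dz_water,
                            z_max = max(cells$z_bot))
        rld <- prof$rld; rl_age <- prof$mean_age
      } else {
        slim <- step_slimroots(slim, cells, avail_m2, stress$srf, tmean,
                               cfg$slim)
        spent_m2 <- slim$spent
        surplus_m2 <- slim$surplus
        rld <- slim$rld; rl_age <- slim$rl_age
      }
      # pools: root gets what was spent; shoots get their share plus any
      # surplus (pre-emergence surplus stays in the seed and is dropped)
      shoot_inc <- inc[c("leaf", "stem", "storage")]
      tot_shoot <- sum(shoot_inc)
      extra <- if (!cstate$emerged) {
        c(leaf = 0, stem = 0, storage = 0)
      } else if (tot_shoot > 0) {
        surplus_m2 * shoot_inc / tot_shoot
      } else if (cstate$dvs > 1) {
        c(leaf = 0, stem = 0, storage = surplus_m2)
      } else {
        c(leaf = surplus_m2, stem = 0, storage = 0)
      }
      cstate$w_root <- cstate$w_root + spent_m2
      cstate$w_leaf <- cstate$w_leaf + shoot_inc[["leaf"]] + extra[["leaf"]]
      cstate$w_stem <- cstate$w_stem + shoot_inc[["stem"]] + extra[["stem"]]
      cstate$w_storage <- cstate$w_storage + shoot_inc[["storage"]] + extra[["storage"]]
      cstate <- update_lai_and_senescence(cstate, inc, tmean, crop)
      cum_dw <- cum_dw + dw
      cum_root_spent <- cum_root_spent + spent_m2
      cum_surplus <- cum_surplus + surplus_m2
      carbon_err_max <- max(carbon_err_max,
                            abs(dw + seed_flux - spent_m2 - surplus_m2 - tot_shoot))
    } else if (use_3d && !is.null(roots3d)) {
      roots3d$time <- roots3d$time + 1   # keep the root clock on calendar time
    }
    if (is.na(anthesis_date) && cstate$dvs >= 1) {
      anthesis_date <- day$date
      rld_flowering <- .current_rld(use_3d, roots3d, slim, cells, cfg)
    }
    if (is.na(maturity_date) && cstate$dvs >= 2) maturity_date <- day$date
    lai_prev <- cstate$lai
    records[[d]] <- tibble::tibble(
      date = day$date, tmean = tmean, precip = day$precip, pet = pet,
      dvs = cstate$dvs, lai = cstate$lai,
      w_root = cstate$w_root, w_leaf = cstate$w_leaf,
      w_stem = cstate$w_stem, w_storage = cstate$w_storage,
      tran = ws$stress$tran, ptran = ws$stress$ptran, tranrf = tranrf,
      evap = ws$fluxes$evap, runoff = ws$fluxes$runoff,
      drainage = ws$fluxes$drainage, storage_mm = ws$fluxes$storage,
      dw = dw, frtmod = frt_value, carbon_scale = scale,
      root_carbon_available = unname(inc[["root"]]),
      root_carbon_spent = spent_m2, root_carbon_surplus = surplus_m2,
      rooting_depth = .front_depth(use_3d, roots3d, slim, rld, cells),
      total_rld = sum(rld * cells$dz))
    if (!is.na(maturity_date)) break
  }
  daily <- dplyr::bind_rows(records[!vapply(records, is.null, logical(1))])
  ya <- yield_and_agb(cstate)
  summary <- tibble::tibble(
    crop = crop$name, treatment = cfg$soil$treatment[1],
    root_model = cfg$root_model, seed = cfg$seed,
    grain = ya$grain, agb = ya$agb,
    anthesis = anthesis_date, maturity = maturity_date,
    cum_tran = sum(daily$tran), cum_dw = cum_dw,
    root_carbon_spent = cum_root_spent,
    max_rooting_depth = max(daily$rooting_depth),
    water_closure_max = water_err_max, carbon_closure_max = carbon_err_max)
  structure(list(
    daily = daily, summary = summary,
    rld_flowering = rld_flowering,
    rld_final = .current_rld(use_3d, roots3d, slim, cells, cfg),
    crop_state = cstate, theta = theta, cells = cells,
    roots3d = roots3d, slim = slim, config = cfg), class = "sim_result")
}

.current_rld <- function(use_3d, roots3d, slim, cells, cfg) {
  if (use_3d) {
    if (is.null(roots3d)) return(NULL)
    rld_profile(roots3d, dz = cfg$dz_rld, z_max = max(cells$z_bot))
  } else {
    if (is.null(slim)) return(NULL)
    tibble::tibble(z_top = cells$z_top, z_bot = cells$z_bot,
                   rld = slim$rld, mean_age = slim$rl_age)
  }
}

.front_depth <- function(use_3d, roots3d, slim, rld, cells) {
  if (use_3d) {
    if (is.null(roots3d)) return(0)
    mx <- 0
    for (ax in roots3d$axes) mx <- max(mx, max(ax$nodes[1:ax$n, 3]))
    mx
  } else {
    if (is.null(slim)) return(0)
    slim$front
  }
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sim_result> %s | %s | %s roots | seed %d\n",
              s$crop, s$treatment, s$root_model, s$seed))
  cat(sprintf("  grain %.2f t/ha, AGB %.2f t/ha, cum. transpiration %.0f mm\n",
              s$grain, s$agb, s$cum_tran))
  cat(sprintf("  anthesis %s, maturity %s, max rooting depth %.0f cm\n",
              format(s$anthesis), format(s$maturity), s$max_rooting_depth))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Daily records of a season run
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return The daily tibble (one row per simulated day).
#' @export
tidy.sim_result <- function(x, ...) x$daily

#' One-row season summary
#' @param x A `sim_result`.
#' @param ... Unused.
#' @export
glance.sim_result <- function(x, ...) x$summary

#' Plot a season run
#'
#' Time-series panels of above-ground biomass pools, LAI, the transpiration
#' reduction factor and rooting depth.
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, ...) {
  d <- object$daily
  long <- tidyr::pivot_longer(
    dplyr::transmute(d, date = date,
                     `AGB (g m-2)` = w_leaf + w_stem + w_storage,
                     `LAI` = lai, `TRANRF` = tranrf,
                     `rooting depth (cm)` = rooting_depth),
    -date, names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = date, y = value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot root length density profiles
#'
#' @param profiles A tibble with columns `z_top, z_bot, rld` and optionally
#'   a grouping column `label` (e.g. treatment).
#' @return A ggplot object (depth increasing downward).
#' @export
plot_rld_profile <- function(profiles) {
  if (!"label" %in% names(profiles)) profiles$label <- "profile"
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = rld, y = (z_top + z_bot) / 2,
                               colour = label)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "RLD (cm cm-3)", y = "depth (cm)", colour = NULL) +
    ggplot2::theme_minimal()
}
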