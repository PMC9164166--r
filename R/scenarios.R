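#' Observed yield tables of the deep-loosening field experiment
#'
#' Packaged observed (and, where available, previously simulated) dry
#' matter grain yield and above-ground biomass, t ha-1, for the strip-wise
#' deep loosening (DL) and control treatments.
#'
#' @param which `"seasons"` (main two-season table per crop) or
#'   `"cultivars"` (three-cultivar trial).
#' @return A tibble.
#' @export
observed_yields <- function(which = c("seasons", "cultivars")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "seasons") "cka_observed_yields.csv"
                   else "cka_cultivar_yields.csv",
                   package = "rhizosim", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}

#' Treatment contrasts from the observed yield tables
#'
#' Recomputes the relative treatment differences and cultivar means from
#' the printed observed values. Two denominator conventions are used in
#' the source tables and both are reported: `rel_dl_pct` expresses the
#' DL-minus-control difference relative to DL (the convention behind the
#' "18 percent higher at the strip" statement for the dry 2018 barley
#' season) and `rel_control_pct` relative to the control.
#'
#' @return A list of tibbles: `seasons` (per season and crop with both
#'   relative differences) and `cultivar_means` (per crop and treatment
#'   mean grain yield over cultivars).
#' @export
compute_observed_contrasts <- function() {
  obs <- observed_yields("seasons")
  wide <- tidyr::pivot_wider(obs[, c("season", "crop", "treatment", "grain_obs")],
                             names_from = "treatment",
                             values_from = "grain_obs")
  seasons <- dplyr::mutate(
    wide,
    diff = .data$DL - .data$control,
    rel_dl_pct = 100 * (.data$DL - .data$control) / .data$DL,
    rel_control_pct = 100 * (.data$DL - .data$control) / .data$control)
  cult <- observed_yields("cultivars")
  cultivar_means <- dplyr::summarise(
    dplyr::group_by(cult, .data$crop, .data$treatment),
    mean_grain = mean(.data$grain_obs), .groups = "drop")
  list(seasons = seasons, cultivar_means = cultivar_means)
}

#' Run the deep-loosening versus control treatment pair
#'
#' Runs the same crop, weather and seed on the control and DL soil
#' profiles and reports the contrasts the field experiment targets: grain
#' yield, root length density at flowering per depth bin, and maximum
#' rooting depth.
#'
#' @param crop A [crop_params()] object.
#' @param weather Weather tibble shared by both arms.
#' @param seed Shared seed.
#' @param root_model `"3d"` or `"1d"`.
#' @param soil_control,soil_dl Soil profiles (default packaged fixtures).
#' @param ... Further arguments to [sim_config()].
#' @return List of class `treatment_pair`: `control`, `dl` (`sim_result`s),
#'   `contrast` one-row tibble and `rld_contrast` per-bin tibble.
#' @export
run_treatment_pair <- function(crop, weather, seed = 1L,
                               root_model = "3d",
                               soil_control = cka_soil_profile("control"),
                               soil_dl = cka_soil_profile("DL"), ...) {
  res_c <- run_season(sim_config(crop, soil_control, weather,
                                 root_model = root_model, seed = seed, ...))
  res_d <- run_season(sim_config(crop, soil_dl, weather,
                                 root_model = root_model, seed = seed, ...))
  rc <- res_c$rld_flowering; rd <- res_d$rld_flowering
  rld_contrast <- NULL
  if (!is.null(rc) && !is.null(rd)) {
    n <- min(nrow(rc), nrow(rd))
    rld_contrast <- tibble::tibble(
      z_top = rc$z_top[1:n], z_bot = rc$z_bot[1:n],
      rld_control = rc$rld[1:n], rld_dl = rd$rld[1:n],
      delta_rld = rd$rld[1:n] - rc$rld[1:n])
  }
  contrast <- tibble::tibble(
    crop = crop$name, root_model = root_model, seed = seed,
    grain_control = res_c$summary$grain, grain_dl = res_d$summary$grain,
    delta_grain = res_d$summary$grain - res_c$summary$grain,
    rel_gain_pct = if (res_c$summary$grain > 0)
      100 * (res_d$summary$grain - res_c$summary$grain) / res_c$summary$grain
    else NA_real_,
    depth_control = res_c$summary$max_rooting_depth,
    depth_dl = res_d$summary$max_rooting_depth,
    cum_tran_control = res_c$summary$cum_tran,
    cum_tran_dl = res_d$summary$cum_tran)
  structure(list(control = res_c, dl = res_d, contrast = contrast,
                 rld_contrast = rld_contrast), class = "treatment_pair")
}

#' Mean root length density over a depth range at flowering
#'
#' @param pair A `treatment_pair`.
#' @param z_from,z_to Depth range, cm.
#' @return One-row tibble with the mean RLD of each arm over the range.
#' @export
rld_band_contrast <- function(pair, z_from = 30, z_to = 60) {
  rc <- pair$rld_contrast
  sel <- rc$z_top >= z_from & rc$z_bot <= z_to
  tibble::tibble(z_from = z_from, z_to = z_to,
                 rld_control = mean(rc$rld_control[sel]),
                 rld_dl = mean(rc$rld_dl[sel]),
                 delta = mean(rc$delta_rld[sel]))
}

#' Weather-ensemble treatment comparison
#'
#' Runs the treatment pair over an ensemble of synthetic weather years and
#' aggregates the deep-loosening yield effect: one row per year, plus the
#' fraction of years with a DL gain and the mean relative gain.
#'
#' @param crop A [crop_params()] object.
#' @param seeds Integer vector, one per ensemble year (also the weather
#'   seed of that year).
#' @param root_model `"3d"` or `"1d"`.
#' @param dry_spring Passed to [synth_weather()].
#' @param ... Further arguments to [sim_config()].
#' @return List: `years` tibble (one row per year), `gain_years`,
#'   `n_years`, `mean_rel_gain_pct`.
#' @export
run_weather_ensemble <- function(crop, seeds, root_model = "3d",
                                 dry_spring = FALSE, ...) {
  if (length(seeds) < 2) stop("an ensemble needs at least 2 seasons")
  rows <- purrr::map(seeds, function(s) {
    wx <- synth_weather(seed = s, dry_spring = dry_spring)
    pair <- run_treatment_pair(crop, wx, seed = s,
                               root_model = root_model, ...)
    dplyr::mutate(pair$contrast, weather_seed = s, .before = 1)
  })
  years <- dplyr::bind_rows(rows)
  list(years = years,
       gain_years = sum(years$delta_grain > 0),
       n_years = nrow(years),
       mean_rel_gain_pct = mean(years$rel_gain_pct))
}

#' Published phenotype sweep levels
#'
#' Low / default / high levels of the swept root parameters: inter-lateral
#' spacing `ln` (cm), maximal number of basal roots `maxB`, and initial tip
#' elongation rate `r` (cm d-1), per crop.
#'
#' @param crop_name `"spring_barley"` or `"winter_wheat"`.
#' @param param `"ln"`, `"maxB"` or `"r"`.
#' @return Named numeric vector `c(low = , default = , high = )`.
#' @export
phenotype_levels <- function(crop_name, param = c("ln", "maxB", "r")) {
  param <- match.arg(param)
  tab <- list(
    spring_barley = list(ln = c(low = 0.65, default = 0.85, high = 1),
                         maxB = c(low = 2, default = 5, high = 7),
                         r = c(low = 5, default = 7, high = 9)),
    winter_wheat = list(ln = c(low = 1.5, default = 2, high = 2.5),
                        maxB = c(low = 10, default = 20, high = 30),
                        r = c(low = 5, default = 7, high = 9)))
  if (!crop_name %in% names(tab)) stop("unknown crop: ", crop_name)
  tab[[crop_name]][[param]]
}

#' Virtual root-phenotype sweep
#'
#' Varies one root architectural parameter over the given levels (other
#' parameters at their defaults), runs one season per level with a shared
#' seed, and reports yield, maximum rooting depth, mean RLD and the RLD
#' profile at flowering.
#'
#' @param crop A [crop_params()] object.
#' @param weather Weather tibble.
#' @param param `"ln"`, `"maxB"` or `"r"`.
#' @param levels Numeric vector of parameter values; defaults to the
#'   published low/default/high levels for the crop.
#' @param soil Soil profile (default control).
#' @param seed Shared seed.
#' @param ... Further arguments to [sim_config()].
#' @return List: `table` (one row per level), `profiles` (RLD at flowering,
#'   stacked, with `level` column).
#' @export
run_phenotype_sweep <- function(crop, weather, param = c("ln", "maxB", "r"),
                                levels = NULL,
                                soil = cka_soil_profile("control"),
                                seed = 1L, ...) {
  param <- match.arg(param)
  if (is.null(levels)) levels <- unname(phenotype_levels(crop$name, param))
  maker <- if (identical(crop$name, "winter_wheat")) root_types_wheat
           else root_types_barley
  rows <- list(); profs <- list()
  for (v in levels) {
    types <- do.call(maker, stats::setNames(list(v), param))
    res <- run_season(sim_config(crop, soil, weather, root_model = "3d",
                                 seed = seed, root_types = types, ...))
    prof <- res$rld_flowering
    if (is.null(prof)) prof <- res$rld_final    # run ended before flowering
    rows[[length(rows) + 1]] <- tibble::tibble(
      param = param, level = v,
      grain = res$summary$grain,
      max_depth = res$summary$max_rooting_depth,
      mean_rld = mean(prof$rld),
      cum_rld = sum(prof$rld))
    pf <- prof; pf$param <- param; pf$level <- v
    profs[[length(profs) + 1]] <- pf
  }
  list(table = dplyr::bind_rows(rows), profiles = dplyr::bind_rows(profs))
}

#' @importFrom rlang .data
NULL
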