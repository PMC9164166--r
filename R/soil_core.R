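#' Penetrometer regression constants
#'
#' Constants of the non-linear soil strength regression
#' \eqn{Q_p = a \, \gamma^b \, \theta^c} relating penetration resistance
#' (MPa) to bulk density \eqn{\gamma} (Mg m\eqn{^{-3}}) and volumetric water
#' content \eqn{\theta} (cm\eqn{^3} cm\eqn{^{-3}}). Defaults are the widely
#' used values for structured loamy soils.
#'
#' @param a,b,c Regression constants; `b > 0` (strength increases with bulk
#'   density) and `c < 0` (strength decreases with water content).
#' @return A list of class `penetrometer_params`.
#' @export
penetrometer_params <- function(a = 0.00587, b = 8.0772, c = -4.65) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (b <= 0) stop("penetrometer 'b' must be > 0 (Qp increases with bulk density)")
  if (c >= 0) stop("penetrometer 'c' must be < 0 (Qp decreases with water content)")
  structure(list(a = a, b = b, c = c), class = "penetrometer_params")
}

#' Root elongation stress parameters
#'
#' @param x Strength-sensitivity coefficient of the exponential mechanical
#'   stress reduction \eqn{\alpha(Q_p) = \exp(x Q_p)}; must be \eqn{\le 0}.
#'   The literature default is -0.4325; field calibrations against
#'   volumetric-water-content driven penetration resistance are much smaller
#'   in magnitude (-0.0025 for spring barley, -0.005 for winter wheat).
#' @param aeration_margin Water content below saturation (cm3 cm-3) at which
#'   the aeration ramp of the water-status factor starts.
#' @return A list of class `stress_params`.
#' @export
stress_params <- function(x = -0.4325, aeration_margin = 0.04) {
  if (x > 0) stop("stress sensitivity 'x' must be <= 0: root growth cannot increase with soil strength")
  if (aeration_margin < 0) stop("'aeration_margin' must be >= 0")
  structure(list(x = x, aeration_margin = aeration_margin),
            class = "stress_params")
}

#' Soil penetration resistance
#'
#' Busscher-type power regression \eqn{Q_p = a\gamma^b\theta^c}. Strictly
#' increasing in bulk density and strictly decreasing in water content.
#'
#' @param bd Bulk density, Mg m-3 (> 0). Vectorised.
#' @param theta Volumetric water content, cm3 cm-3 (0 < theta <= 1). Vectorised.
#' @param params A [penetrometer_params()] object.
#' @return Penetration resistance in MPa.
#' @export
penetration_resistance <- function(bd, theta, params = penetrometer_params()) {
  if (any(bd <= 0)) stop("bulk density must be > 0")
  if (any(theta <= 0) || any(theta > 1)) stop("water content must be in (0, 1]")
  params$a * bd^params$b * theta^params$c
}

#' Mechanical stress reduction factor
#'
#' Exponential decrease of relative root elongation with penetration
#' resistance, \eqn{\alpha(Q_p) = \exp(x Q_p)}, for soil without continuous
#' macropores. Values lie in (0, 1].
#'
#' @param qp Penetration resistance, MPa (>= 0). Vectorised.
#' @param x Strength-sensitivity coefficient (<= 0).
#' @export
alpha_strength <- function(qp, x = -0.4325) {
  if (any(qp < 0)) stop("penetration resistance must be >= 0")
  if (length(x) != 1 || x > 0) stop("'x' must be a single value <= 0")
  exp(x * qp)
}

#' Water-status (hydric) stress reduction factor
#'
#' Feddes-type trapezoid on volumetric water content: zero at or below the
#' wilting point, linear ramp up to 1 at the reduced point, plateau at 1,
#' then linear ramp down to zero between `theta_s - aeration_margin` and
#' saturation `theta_s` (poor aeration).
#'
#' @param theta Volumetric water content, cm3 cm-3. Vectorised.
#' @param theta_pwp,theta_red,theta_s Wilting-point, reduced-point and
#'   saturation water contents of the host layer.
#' @param params A [stress_params()] object (supplies `aeration_margin`).
#' @return Dimensionless factor in [0, 1].
#' @export
alpha_water <- function(theta, theta_pwp, theta_red, theta_s,
                        params = stress_params()) {
  if (any(theta < 0) || any(theta > theta_s + 1e-12))
    stop("water content must lie in [0, theta_s]")
  up <- (theta - theta_pwp) / (theta_red - theta_pwp)
  down <- if (params$aeration_margin > 0) (theta_s - theta) / params$aeration_margin else 1
  pmax(0, pmin(1, pmin(up, down)))
}

#' Load a layered soil profile
#'
#' Reads a layered soil physical description (one row per horizon) and
#' validates it: contiguous layers starting at the surface, ordered water
#' retention anchors, positive bulk density, texture closing to 100 percent.
#'
#' @param source Path to a CSV file with columns `treatment, z_top_cm,
#'   z_bot_cm, theta_fc, theta_red, theta_pwp, theta_s, bd, clay, sand,
#'   silt, soc`, or a data frame with those columns.
#' @return A tibble of class `soil_profile` (depths in cm, positive
#'   downward; layers half-open `[z_top, z_bot)`).
#' @export
load_soil_profile <- function(source) {
  prof <- if (is.character(source)) {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(source)
  }
  needed <- c("treatment", "z_top_cm", "z_bot_cm", "theta_fc", "theta_red",
              "theta_pwp", "theta_s", "bd", "clay", "sand", "silt", "soc")
  missing <- setdiff(needed, names(prof))
  if (length(missing))
    stop("soil profile is missing columns: ", paste(missing, collapse = ", "))
  prof <- prof[needed]
  for (i in seq_len(nrow(prof))) {
    l <- prof[i, ]
    if (!(l$z_top_cm < l$z_bot_cm))
      stop(sprintf("layer %d: z_top must be < z_bot", i))
    if (!(0 < l$theta_pwp && l$theta_pwp < l$theta_red &&
          l$theta_red < l$theta_fc && l$theta_fc < l$theta_s && l$theta_s < 1))
      stop(sprintf("layer %d: water retention anchors must satisfy 0 < pwp < red < fc < s < 1", i))
    if (l$bd <= 0) stop(sprintf("layer %d: bulk density must be > 0", i))
    tex <- l$clay + l$sand + l$silt
    if (tex < 99 || tex > 101)
      stop(sprintf("layer %d: texture fractions sum to %.1f, expected ~100", i, tex))
  }
  if (prof$z_top_cm[1] != 0) stop("first layer must start at the surface (z_top = 0)")
  if (nrow(prof) > 1 &&
      any(abs(prof$z_top_cm[-1] - prof$z_bot_cm[-nrow(prof)]) > 1e-9))
    stop("layers must be contiguous (each z_bot equal to the next z_top)")
  class(prof) <- c("soil_profile", class(prof))
  prof
}

#' Packaged experimental soil profiles
#'
#' Layered soil physical properties of a loess-derived Haplic Luvisol field
#' experiment comparing strip-wise deep loosening (30-60 cm, treatment
#' `"DL"`) against an untilled `"control"`; 8 horizons down to 210 cm.
#'
#' @param treatment `"control"` or `"DL"`.
#' @return A `soil_profile` tibble.
#' @export
cka_soil_profile <- function(treatment = c("control", "DL")) {
  treatment <- match.arg(treatment)
  f <- system.file("extdata",
                   if (treatment == "control") "cka_control.csv" else "cka_dl.csv",
                   package = "rhizosim", mustWork = TRUE)
  load_soil_profile(f)
}

#' Discretise a soil profile into numerical cells
#'
#' Splits the profile into equal-thickness cells and attaches the host
#' layer's physical properties to each cell (layer of the cell midpoint).
#'
#' @param profile A `soil_profile`.
#' @param dz Cell thickness, cm (default 5).
#' @return A tibble with one row per cell: `z_top, z_bot, z_mid, dz` and the
#'   layer property columns.
#' @export
discretise_profile <- function(profile, dz = 5) {
  stopifnot(dz > 0)
  z_max <- max(profile$z_bot_cm)
  n <- ceiling(z_max / dz - 1e-9)
  z_top <- (seq_len(n) - 1) * dz
  z_bot <- pmin(z_top + dz, z_max)
  z_mid <- (z_top + z_bot) / 2
  idx <- findInterval(z_mid, profile$z_top_cm)
  cells <- tibble::tibble(
    z_top = z_top, z_bot = z_bot, z_mid = z_mid, dz = z_bot - z_top,
    theta_fc = profile$theta_fc[idx], theta_red = profile$theta_red[idx],
    theta_pwp = profile$theta_pwp[idx], theta_s = profile$theta_s[idx],
    bd = profile$bd[idx]
  )
  cells
}

#' Combined stress reduction field
#'
#' Per-cell mechanical and hydric stress reduction of root elongation:
#' `srf = alpha_strength(Qp) * alpha_water(theta)`, with `Qp` from the
#' Busscher regression on each cell's bulk density and current water
#' content.
#'
#' @param cells Discretised profile from [discretise_profile()].
#' @param theta Per-cell volumetric water content.
#' @param pen_params A [penetrometer_params()] object.
#' @param stressp A [stress_params()] object.
#' @return A tibble of class `stress_field`: `z_top, z_bot, qp, alpha_qp,
#'   alpha_h, srf`, all factors in [0, 1].
#' @export
stress_reduction_field <- function(cells, theta,
                                   pen_params = penetrometer_params(),
                                   stressp = stress_params()) {
  stopifnot(length(theta) == nrow(cells))
  theta_q <- pmax(theta, 1e-6)  # Qp diverges at theta -> 0; alpha_h is 0 there anyway
  qp <- penetration_resistance(cells$bd, pmin(theta_q, 1), pen_params)
  a_qp <- alpha_strength(qp, stressp$x)
  a_h <- alpha_water(pmin(theta, cells$theta_s), cells$theta_pwp,
                     cells$theta_red, cells$theta_s, stressp)
  out <- tibble::tibble(z_top = cells$z_top, z_bot = cells$z_bot,
                        qp = qp, alpha_qp = a_qp, alpha_h = a_h,
                        srf = a_qp * a_h)
  class(out) <- c("stress_field", class(out))
  out
}

#' Serialise a soil profile back to CSV
#'
#' Writes the profile with the same column schema accepted by
#' [load_soil_profile()], so that load -> write -> load is lossless.
#'
#' @param profile A `soil_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_soil_profile <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(unclass(profile))[, c(
    "treatment", "z_top_cm", "z_bot_cm", "theta_fc", "theta_red",
    "theta_pwp", "theta_s", "bd", "clay", "sand", "silt", "soc")], path)
  invisible(path)
}
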