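#' Read a daily weather series
#'
#' Reads a CSV with columns `date, tmin, tmax, radiation, precip` and an
#' optional `et0` column (reference evapotranspiration, mm, used verbatim
#' downstream when present). The series must be chronological and gap-free.
#'
#' @param path CSV path (ISO dates).
#' @return A tibble, one row per day.
#' @export
read_weather <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("date", "tmin", "tmax", "radiation", "precip")
  missing <- setdiff(needed, names(w))
  if (length(missing))
    stop("weather file is missing columns: ", paste(missing, collapse = ", "))
  w$date <- as.Date(w$date)
  if (any(is.na(w$date))) stop("unparseable dates in weather file")
  if (anyDuplicated(w$date)) {
    stop("duplicated date at row ", which(duplicated(w$date))[1])
  }
  w <- w[order(w$date), ]
  d <- diff(as.integer(w$date))
  if (any(d != 1))
    stop("gap in weather series after row ", which(d != 1)[1])
  bad <- which(w$tmin > w$tmax)
  if (length(bad)) stop("tmin > tmax at row ", bad[1])
  if (any(w$radiation < 0) || any(w$precip < 0))
    stop("radiation and precipitation must be >= 0")
  tibble::as_tibble(w)
}

#' Synthetic daily weather generator
#'
#' Generates one calendar year of daily weather emulating a temperate-humid
#' Central European site (long-term means roughly 10.5 degC and 601 mm):
#' sinusoidal annual temperature course with Gaussian day-to-day noise, a
#' seasonally modulated radiation curve, and two-state Markov precipitation
#' occurrence with gamma-distributed daily amounts. `dry_spring = TRUE`
#' suppresses March-April rainfall (to about 15 percent of normal),
#' emulating the dry spring seasons in which subsoil loosening pays off.
#'
#' @param seed Integer seed; identical seed and parameters give a
#'   byte-identical series.
#' @param year Calendar year of the series (controls leap days).
#' @param t_mean Annual mean air temperature, degC.
#' @param t_amplitude Half-range of the annual temperature cycle, degC.
#' @param annual_precip Expected annual precipitation, mm.
#' @param wet_day_prob Stationary probability that a day is wet.
#' @param dry_spring Suppress March-April precipitation?
#' @return A weather tibble (`date, tmin, tmax, radiation, precip`).
#' @export
synth_weather <- function(seed, year = 2019, t_mean = 10.5, t_amplitude = 8.2,
                          annual_precip = 601, wet_day_prob = 0.43,
                          dry_spring = FALSE) {
  stopifnot(t_amplitude > 0, annual_precip > 0,
            wet_day_prob > 0, wet_day_prob < 1)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.restore_seed(old), add = TRUE)

  phase <- cos(2 * pi * (doy - 15) / 365.25)           # coldest mid-January
  tmean <- t_mean - t_amplitude * phase + stats::rnorm(n, 0, 2)
  dtr <- pmax(2, 8 + stats::rnorm(n, 0, 1.5))          # diurnal range
  tmin <- tmean - dtr / 2
  tmax <- tmean + dtr / 2
  radiation <- pmax(0.5, 11.5 - 9.5 * phase + stats::rnorm(n, 0, 3))

  # two-state Markov occurrence with stationary probability wet_day_prob
  p11 <- min(0.9, wet_day_prob + 0.25)                 # wet persistence
  p01 <- wet_day_prob * (1 - p11) / (1 - wet_day_prob)
  wet <- logical(n)
  wet[1] <- stats::runif(1) < wet_day_prob
  u <- stats::runif(n)
  for (i in 2:n) wet[i] <- u[i] < (if (wet[i - 1]) p11 else p01)
  mu <- annual_precip / (365.25 * wet_day_prob)        # mean wet-day amount
  shape <- 0.8
  precip <- ifelse(wet, stats::rgamma(n, shape = shape, scale = mu / shape), 0)
  if (dry_spring) {
    mth <- as.integer(format(dates, "%m"))
    precip[mth %in% c(3, 4)] <- precip[mth %in% c(3, 4)] * 0.15
  }
  tibble::tibble(date = dates, tmin = tmin, tmax = tmax,
                 radiation = radiation, precip = precip)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Potential evapotranspiration of a weather day
#'
#' Reference evapotranspiration closed form. If the day carries an `et0`
#' value it is returned verbatim. Otherwise the default is Priestley-Taylor
#' (alpha = 1.26) on daily net radiation approximated from global radiation,
#' with a Hargreaves radiation-temperature fallback.
#'
#' @param day One weather row (list or one-row data frame with `tmin, tmax,
#'   radiation` and optionally `et0`, `date`).
#' @param method `"priestley_taylor"` or `"hargreaves"`.
#' @param latitude Site latitude in degrees (Hargreaves only).
#' @return Potential ET, mm (>= 0).
#' @export
potential_et <- function(day, method = c("priestley_taylor", "hargreaves"),
                         latitude = 50.6) {
  method <- match.arg(method)
  if ("et0" %in% names(day) && length(day[["et0"]]) && !is.na(day[["et0"]][1]))
    return(max(0, day[["et0"]][1]))
  tmean <- (day$tmin + day$tmax) / 2
  if (method == "priestley_taylor") {
    s <- 4098 * (0.6108 * exp(17.27 * tmean / (tmean + 237.3))) /
      (tmean + 237.3)^2                                # kPa / degC
    gamma <- 0.066
    rn <- pmax(0, 0.75 * day$radiation - 2.0)          # MJ m-2 d-1
    pet <- 1.26 * s / (s + gamma) * rn / 2.45
  } else {
    doy <- if (!is.null(day$date)) as.integer(format(as.Date(day$date), "%j")) else 180
    ra <- .extraterrestrial_radiation(latitude, doy)
    pet <- 0.0023 * ra / 2.45 * (tmean + 17.8) * sqrt(pmax(0, day$tmax - day$tmin))
  }
  pmax(0, pet)
}

# FAO-56 daily extraterrestrial radiation, MJ m-2 d-1
.extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Split potential ET into transpiration and soil evaporation demand
#'
#' Beer's-law canopy partition: the transpiration share equals the fraction
#' of radiation intercepted by the canopy, `1 - exp(-k_ext * lai)`; the
#' remainder is potential soil evaporation. The split conserves PET exactly.
#'
#' @param pet Potential evapotranspiration, mm.
#' @param lai Leaf area index, m2 m-2.
#' @param k_ext Canopy extinction coefficient (default 0.6).
#' @return A list with `pet`, `ptran`, `pevap` (all mm).
#' @export
split_demand <- function(pet, lai, k_ext = 0.6) {
  stopifnot(pet >= 0, lai >= 0, k_ext > 0)
  ptran <- pet * (1 - exp(-k_ext * lai))
  list(pet = pet, ptran = ptran, pevap = pet - ptran)
}
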