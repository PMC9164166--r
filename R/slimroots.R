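#' Parameters of the 1D conceptual root model
#'
#' @param max_front_rate Crop-specific maximum daily advance of the seminal
#'   rooting front, m d-1 (default 0.033).
#' @param seminal_cost Carbon cost of advancing the front, g m-2 per cm of
#'   advance (seminal axes of all plants in a square metre together).
#' @param srw_lateral Specific root weight converting the remaining
#'   assimilate into lateral root length, g per cm.
#' @param t_base,t_opt Soil temperature response anchors of the front
#'   advance, degC (0 below `t_base`, 1 above `t_opt`).
#' @param max_rld Ceiling on per-cell root length density, cm cm-3; carbon
#'   that cannot be placed below the ceiling returns to the shoot (guards
#'   the conceptual model against piling all season carbon into a few
#'   rooted cells when the front is blocked).
#' @return A list of class `slimroots_params`.
#' @export
slimroots_params <- function(max_front_rate = 0.033, seminal_cost = 0.033,
                             srw_lateral = 2e-5, t_base = 0, t_opt = 15,
                             max_rld = 5) {
  stopifnot(max_front_rate > 0, seminal_cost > 0, srw_lateral > 0,
            t_base < t_opt, max_rld > 0)
  structure(list(max_front_rate = max_front_rate,
                 seminal_cost = seminal_cost, srw_lateral = srw_lateral,
                 t_base = t_base, t_opt = t_opt, max_rld = max_rld),
            class = "slimroots_params")
}

#' Soil temperature response of front advance
#'
#' Linear ramp from 0 at `t_base` to 1 at `t_opt`.
#'
#' @param tmean Daily mean temperature, degC. Vectorised.
#' @param t_base,t_opt Anchors, degC.
#' @export
temperature_factor <- function(tmean, t_base = 0, t_opt = 15) {
  pmax(0, pmin(1, (tmean - t_base) / (t_opt - t_base)))
}

#' Initial state of the 1D root model
#'
#' @param cells Discretised profile from [discretise_profile()].
#' @param sowing_depth Initial front depth, cm.
#' @return List of class `slimroots_state`: per-cell root length density
#'   (cm cm-3), per-cell length-weighted mean root age (days), front depth
#'   (cm), carbon spent (g m-2).
#' @export
init_slimroots <- function(cells, sowing_depth = 3) {
  structure(list(rld = numeric(nrow(cells)),
                 rl_age = numeric(nrow(cells)),
                 front = sowing_depth, carbon_spent = 0),
            class = "slimroots_state")
}

#' One daily step of the 1D conceptual root model
#'
#' Assimilate is used first for seminal (front) advance: the front moves by
#' `min(max_front_rate * f_T(tmean) * srf(front cell), carbon-limited
#' advance)` and is charged `seminal_cost` per cm; seminal length is
#' credited to the cells the front traverses. Any remaining assimilate
#' becomes lateral root length, distributed over rooted cells
#' proportionally to `srf(cell)` (growth goes preferentially where soil
#' conditions allow it). Root ages age by one day; new length enters at age
#' zero (length-weighted mean age).
#'
#' @param state A `slimroots_state`.
#' @param cells Discretised profile.
#' @param root_carbon Assimilate available for roots today, g m-2.
#' @param srf Per-cell stress reduction factor in [0, 1].
#' @param tmean Daily mean temperature, degC.
#' @param params A [slimroots_params()] object.
#' @param dt Time step, days.
#' @return Updated `slimroots_state` with `spent` (g m-2) and `surplus`
#'   (g m-2, returned to the shoot) fields for the day.
#' @export
step_slimroots <- function(state, cells, root_carbon, srf, tmean,
                           params = slimroots_params(), dt = 1) {
  stopifnot(root_carbon >= 0, length(srf) == nrow(cells))
  z_max <- max(cells$z_bot)
  state$rl_age <- ifelse(state$rld > 0, state$rl_age + dt, 0)
  front_cell <- min(nrow(cells), max(1L, findInterval(min(state$front, z_max - 1e-9),
                                                      cells$z_top)))
  f_t <- temperature_factor(tmean, params$t_base, params$t_opt)
  pot_adv <- params$max_front_rate * 100 * dt * f_t * srf[front_cell]
  pot_adv <- min(pot_adv, z_max - state$front)
  carbon_adv <- root_carbon / params$seminal_cost
  adv <- min(pot_adv, carbon_adv)
  seminal_spent <- adv * params$seminal_cost
  remaining <- root_carbon - seminal_spent

  if (adv > 0) {
    # seminal length credited to traversed cells, one axis bundle per m2
    sem_len_per_cm <- params$seminal_cost / params$srw_lateral  # cm length per cm advance per m2
    z0 <- state$front; z1 <- state$front + adv
    ov <- pmax(0, pmin(cells$z_bot, z1) - pmax(cells$z_top, z0))
    add_len <- ov * sem_len_per_cm                  # cm per m2 ground
    add_rld <- add_len / (1e4 * cells$dz)           # cm per cm3 soil
    state$rl_age <- ifelse(state$rld + add_rld > 0,
                           state$rl_age * state$rld / (state$rld + add_rld), 0)
    state$rld <- state$rld + add_rld
    state$front <- z1
  }

  lateral_spent <- 0
  if (remaining > 1e-15) {
    rooted <- which(state$rld > 0 & cells$z_top < state$front &
                      state$rld < params$max_rld)
    if (length(rooted)) {
      w <- srf[rooted]
      if (sum(w) <= 0) w <- rep(1, length(rooted))  # nowhere favourable: spread evenly
      w <- w / sum(w)
      lat_len <- remaining / params$srw_lateral     # cm per m2
      add_rld <- pmin(lat_len * w / (1e4 * cells$dz[rooted]),
                      params$max_rld - state$rld[rooted])
      placed_len <- sum(add_rld * 1e4 * cells$dz[rooted])
      old <- state$rld[rooted]
      state$rl_age[rooted] <- ifelse(old + add_rld > 0,
                                     state$rl_age[rooted] * old / (old + add_rld),
                                     0)
      state$rld[rooted] <- old + add_rld
      lateral_spent <- placed_len * params$srw_lateral
    }
  }
  spent <- seminal_spent + lateral_spent
  state$carbon_spent <- state$carbon_spent + spent
  state$spent <- spent
  state$surplus <- root_carbon - spent
  state
}
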