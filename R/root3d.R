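#' Root type parameters
#'
#' Growth rules for one root type (order) of the stochastic 3D architecture
#' model. Axis length follows the negative-exponential growth law
#' `RL(t) = lmax * (1 - exp(-(r / lmax) * t))`, so the initial slope is `r`
#' and length saturates at `lmax`. Laterals of the `successor` type emerge
#' along the axis at arclength positions `lb, lb + ln, lb + 2 ln, ...` once
#' the tip has advanced `la` (the apical unbranched zone) beyond them.
#'
#' @param name Type label.
#' @param r Initial tip elongation rate, cm d-1.
#' @param lmax Maximum root length, cm.
#' @param ln Inter-lateral spacing along this axis, cm (0 = no branching).
#' @param lb Basal unbranched zone, cm.
#' @param la Apical unbranched zone, cm.
#' @param theta0 Insertion angle from the parent direction (or from the
#'   vertical for basal roots), rad.
#' @param tropism_n Number of trial reorientations per growth sub-step
#'   (best-of-n gravitropism; 0 or 1 = undirected random walk).
#' @param tropism_sigma Angular noise of a trial reorientation, rad
#'   (0 = perfectly straight growth).
#' @param radius Root radius, cm.
#' @param successor Type label of emerging laterals (NA = none).
#' @param maxB Maximum number of basal roots of this type (basal types
#'   only).
#' @param basal_delay Days between basal emergences.
#' @param srw Specific root weight, g per cm root length.
#' @return A list of class `root_type_params`.
#' @export
root_type_params <- function(name, r, lmax, ln = 0, lb = 1, la = 2,
                             theta0 = 1.2, tropism_n = 2,
                             tropism_sigma = 0.2, radius = 0.015,
                             successor = NA_character_, maxB = 0,
                             basal_delay = 2, srw = 2e-5) {
  stopifnot(r > 0, lmax > 0, ln >= 0, maxB >= 0, srw > 0)
  if (la + lb > lmax) stop("la + lb must not exceed lmax")
  structure(list(name = name, r = r, lmax = lmax, ln = ln, lb = lb, la = la,
                 theta0 = theta0, tropism_n = tropism_n,
                 tropism_sigma = tropism_sigma, radius = radius,
                 successor = successor, maxB = maxB,
                 basal_delay = basal_delay, srw = srw),
            class = "root_type_params")
}

#' Default root types for spring barley
#'
#' One taproot plus up to `maxB` basal (shoot-borne) axes, each bearing
#' first-order laterals; second-order laterals optional.
#'
#' @param r Initial tip elongation rate of the main axes, cm d-1.
#' @param ln Inter-lateral spacing on main axes, cm.
#' @param maxB Maximum number of basal roots.
#' @param second_order Enable second-order laterals?
#' @return Named list of [root_type_params()].
#' @export
root_types_barley <- function(r = 7, ln = 0.85, maxB = 5,
                              second_order = FALSE) {
  list(
    taproot = root_type_params("taproot", r = r, lmax = 160, ln = ln,
                               lb = 1, la = 2.5, theta0 = 0, tropism_n = 2,
                               tropism_sigma = 0.15, radius = 0.02,
                               successor = "lateral"),
    basal = root_type_params("basal", r = r, lmax = 140, ln = ln,
                             lb = 1, la = 2.5, theta0 = 1.1, tropism_n = 2,
                             tropism_sigma = 0.15, radius = 0.018,
                             successor = "lateral", maxB = maxB,
                             basal_delay = 2),
    lateral = root_type_params("lateral", r = 1.5, lmax = 12,
                               ln = if (second_order) 1.5 else 0,
                               lb = 0.8, la = 1.5, theta0 = 1.2,
                               tropism_n = 1, tropism_sigma = 0.3,
                               radius = 0.01,
                               successor = if (second_order) "lateral2" else NA),
    lateral2 = root_type_params("lateral2", r = 0.8, lmax = 4, ln = 0,
                                lb = 0.5, la = 1, theta0 = 1.2,
                                tropism_n = 1, tropism_sigma = 0.35,
                                radius = 0.007)
  )
}

#' Default root types for winter wheat
#' @inheritParams root_types_barley
#' @export
root_types_wheat <- function(r = 7, ln = 2, maxB = 20,
                             second_order = FALSE) {
  types <- root_types_barley(r = r, ln = ln, maxB = maxB,
                             second_order = second_order)
  types$taproot$lmax <- 200
  types$basal$lmax <- 180
  types$basal$basal_delay <- 4
  types
}

#' Create an empty 3D root system
#'
#' @param types Named list of [root_type_params()] (must contain a
#'   `"taproot"` type; any type with `maxB > 0` emits basal roots).
#' @param sowing_depth Seed depth, cm below the surface.
#' @param plant_area Ground area per plant, cm2 (for root length density).
#' @param seg_max Maximum segment length, cm (growth sub-sampling).
#' @return A mutable root system object (class `root_system`).
#' @export
new_root_system <- function(types, sowing_depth = 3,
                            plant_area = 1e4 / 330, seg_max = 0.5) {
  stopifnot("taproot" %in% names(types), plant_area > 0, seg_max > 0)
  sys <- new.env(parent = emptyenv())
  sys$types <- types
  sys$base <- c(0, 0, sowing_depth)
  sys$time <- 0
  sys$plant_area <- plant_area
  sys$seg_max <- seg_max
  sys$axes <- list()
  sys$n_basal <- stats::setNames(rep(0L, length(types)), names(types))
  sys$carbon_spent <- 0
  .add_axis(sys, "taproot", origin = sys$base, heading = c(0, 0, 1),
            birth = 0, parent = 0L)
  class(sys) <- c("root_system", "environment")
  sys
}

.add_axis <- function(sys, type, origin, heading, birth, parent) {
  tp <- sys$types[[type]]
  cap <- ceiling(tp$lmax / sys$seg_max) + 4L
  ax <- new.env(parent = emptyenv())
  ax$type <- type
  ax$nodes <- matrix(NA_real_, nrow = cap, ncol = 3)
  ax$nodes[1, ] <- origin
  ax$times <- c(birth, rep(NA_real_, cap - 1L))
  ax$n <- 1L
  ax$length <- 0
  ax$birth <- birth
  ax$heading <- heading
  ax$parent <- parent
  ax$order <- if (parent == 0L) 1L else sys$axes[[parent]]$order + 1L
  ax$next_branch <- 0L   # index j of next branch position lb + j*ln
  sys$axes[[length(sys$axes) + 1L]] <- ax
  invisible(ax)
}

#' Negative-exponential target root length
#'
#' `RL(t) = k (1 - exp(-(r/k) t))`: starts at 0 with slope `r` and
#' saturates at the maximum root length `k`.
#'
#' @param t Axis age, days. Vectorised.
#' @param r Initial elongation rate, cm d-1.
#' @param k Maximum root length, cm.
#' @export
target_length <- function(t, r, k) {
  stopifnot(all(t >= 0), r > 0, k > 0)
  k * (1 - exp(-(r / k) * t))
}

#' Potential (unstressed) tip elongation over a time step
#'
#' Increment of the growth law over `[age, age + dt]`, zero once the axis
#' has reached its maximum length.
#'
#' @param axis An axis of a `root_system` (or a list with `length`, `birth`,
#'   `type`).
#' @param dt Time step, days.
#' @param sys The host root system (for type parameters and current time).
#' @export
potential_elongation <- function(axis, dt, sys) {
  tp <- sys$types[[axis$type]]
  if (axis$length >= tp$lmax - 1e-12) return(0)
  age <- sys$time - axis$birth
  pe <- target_length(age + dt, tp$r, tp$lmax) - target_length(age, tp$r, tp$lmax)
  min(max(0, pe), tp$lmax - axis$length)
}

#' Gravitropic heading update
#'
#' Best-of-n gravitropism: among `n` random perturbations of the current
#' heading (polar angle `|N(0, sigma)|`, uniform azimuth), the candidate
#' closest to vertically downward is chosen. `sigma = 0` leaves the heading
#' unchanged; `n <= 1` is an undirected random walk.
#'
#' @param heading Unit 3-vector (z positive downward).
#' @param n Number of trials.
#' @param sigma Angular noise, rad.
#' @return Unit 3-vector.
#' @export
tropism_heading <- function(heading, n = 2, sigma = 0.2) {
  if (sigma == 0) return(heading)
  n <- max(1L, as.integer(n))
  ref <- if (abs(heading[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- .cross3(heading, ref); u <- u / sqrt(sum(u^2))
  v <- .cross3(heading, u)
  best <- NULL; best_z <- -Inf
  for (i in seq_len(n)) {
    a <- abs(stats::rnorm(1, 0, sigma))
    az <- stats::runif(1, 0, 2 * pi)
    cand <- cos(a) * heading + sin(a) * (cos(az) * u + sin(az) * v)
    if (cand[3] > best_z) { best <- cand; best_z <- cand[3] }
  }
  best / sqrt(sum(best^2))
}

.bin_sum <- function(bin, w, n_bin) {
  out <- numeric(n_bin)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Carbon required for stress-limited potential root growth
#'
#' Sum over growing tips of the locally stress-limited potential elongation
#' times the specific root weight of the tip's type.
#'
#' @param sys A `root_system`.
#' @param dt Time step, days.
#' @param srf_at Function of depth (cm) returning the combined stress
#'   reduction factor in [0, 1] (e.g. from [stress_lookup()]); defaults to
#'   no stress.
#' @return Carbon demand, g per plant.
#' @export
required_carbon <- function(sys, dt, srf_at = function(z) 1) {
  tot <- 0
  for (ax in sys$axes) {
    pe <- potential_elongation(ax, dt, sys)
    if (pe <= 0) next
    z <- ax$nodes[ax$n, 3]
    tot <- tot + srf_at(z) * pe * sys$types[[ax$type]]$srw
  }
  tot
}

#' Elongate every root tip for one time step
#'
#' Each tip elongates by `carbon_scale * srf(tip depth) * potential`,
#' sub-sampled into segments no longer than `seg_max`, with the heading
#' renewed by gravitropism per sub-segment. Tips are reflected at the soil
#' surface. Carbon spent (length times specific root weight) is
#' accumulated on the system. The system clock advances by `dt`.
#'
#' @param sys A `root_system` (modified in place and returned).
#' @param dt Time step, days.
#' @param srf_at Stress reduction lookup, function of depth (cm).
#' @param carbon_scale Uniform carbon limitation factor in [0, 1].
#' @return `sys`, with `sys$last_growth_cm` set to the total length grown.
#' @export
grow_step <- function(sys, dt, srf_at = function(z) 1, carbon_scale = 1) {
  stopifnot(carbon_scale >= 0, carbon_scale <= 1)
  grown <- 0
  t_new <- sys$time + dt
  for (ax in sys$axes) {
    pe <- potential_elongation(ax, dt, sys)
    if (pe <= 0) next
    tp <- sys$types[[ax$type]]
    z <- ax$nodes[ax$n, 3]
    dl <- carbon_scale * srf_at(z) * pe
    if (dl <= 1e-12) next
    ns <- ceiling(dl / sys$seg_max)
    sub <- dl / ns
    h <- ax$heading
    for (s in seq_len(ns)) {
      h <- tropism_heading(h, tp$tropism_n, tp$tropism_sigma)
      p <- ax$nodes[ax$n, ] + h * sub
      if (p[3] < 0) {            # reflect at the soil surface
        h[3] <- abs(h[3])
        p <- ax$nodes[ax$n, ] + h * sub
      }
      if (ax$n + 1L > nrow(ax$nodes)) {        # grow storage (short sub-segments)
        ax$nodes <- rbind(ax$nodes, matrix(NA_real_, nrow = nrow(ax$nodes), ncol = 3))
        ax$times <- c(ax$times, rep(NA_real_, length(ax$times)))
      }
      ax$n <- ax$n + 1L
      ax$nodes[ax$n, ] <- p
      ax$times[ax$n] <- t_new
      ax$length <- ax$length + sub
    }
    ax$heading <- h
    grown <- grown + dl
    sys$carbon_spent <- sys$carbon_spent + dl * tp$srw
  }
  sys$time <- t_new
  sys$last_growth_cm <- grown
  invisible(sys)
}

#' Emerge due lateral roots
#'
#' Creates laterals at arclength positions `lb, lb + ln, ...` on every axis
#' whose tip has advanced `la` beyond the position. Each lateral starts at
#' the interpolated 3D point with an insertion angle `theta0` from the
#' local parent direction and a uniformly random azimuth.
#'
#' @param sys A `root_system` (modified in place).
#' @export
emerge_laterals <- function(sys) {
  i <- 1L
  while (i <= length(sys$axes)) {      # new axes appended during the loop don't branch yet
    ax <- sys$axes[[i]]
    tp <- sys$types[[ax$type]]
    if (!is.na(tp$successor) && tp$ln > 0) {
      repeat {
        pos <- tp$lb + ax$next_branch * tp$ln
        if (pos > tp$lmax - tp$la || ax$length < pos + tp$la) break
        pt <- .point_at_arclength(ax, pos)
        dir <- .direction_at_arclength(ax, pos)
        h <- .insertion_heading(dir, sys$types[[tp$successor]]$theta0)
        .add_axis(sys, tp$successor, origin = pt, heading = h,
                  birth = sys$time, parent = i)
        ax$next_branch <- ax$next_branch + 1L
      }
    }
    i <- i + 1L
  }
  invisible(sys)
}

.point_at_arclength <- function(ax, pos) {
  if (ax$n < 2) return(ax$nodes[1, ])
  segs <- ax$nodes[2:ax$n, , drop = FALSE] - ax$nodes[1:(ax$n - 1L), , drop = FALSE]
  lens <- sqrt(rowSums(segs^2))
  cum <- cumsum(lens)
  j <- which(cum >= pos - 1e-9)[1]
  if (is.na(j)) return(ax$nodes[ax$n, ])
  prev <- if (j == 1) 0 else cum[j - 1]
  f <- if (lens[j] > 0) (pos - prev) / lens[j] else 0
  ax$nodes[j, ] + f * segs[j, ]
}

.direction_at_arclength <- function(ax, pos) {
  if (ax$n < 2) return(ax$heading)
  segs <- ax$nodes[2:ax$n, , drop = FALSE] - ax$nodes[1:(ax$n - 1L), , drop = FALSE]
  lens <- sqrt(rowSums(segs^2))
  cum <- cumsum(lens)
  j <- which(cum >= pos - 1e-9)[1]
  if (is.na(j)) j <- length(lens)
  d <- segs[j, ]
  d / sqrt(sum(d^2))
}

.insertion_heading <- function(parent_dir, theta0) {
  ref <- if (abs(parent_dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- .cross3(parent_dir, ref); u <- u / sqrt(sum(u^2))
  v <- .cross3(parent_dir, u)
  az <- stats::runif(1, 0, 2 * pi)
  h <- cos(theta0) * parent_dir + sin(theta0) * (cos(az) * u + sin(az) * v)
  h / sqrt(sum(h^2))
}

#' Emerge due basal roots
#'
#' For every type with `maxB > 0`, basal roots appear at the plant base
#' every `basal_delay` days (one at time 0) until `maxB` are present.
#'
#' @param sys A `root_system` (modified in place).
#' @export
emerge_basals <- function(sys) {
  for (type in names(sys$types)) {
    tp <- sys$types[[type]]
    if (tp$maxB <= 0) next
    due <- min(tp$maxB, floor(sys$time / tp$basal_delay) + 1L)
    while (sys$n_basal[[type]] < due) {
      h <- .insertion_heading(c(0, 0, 1), tp$theta0)
      .add_axis(sys, type, origin = sys$base, heading = h,
                birth = sys$time, parent = 0L)
      sys$n_basal[[type]] <- sys$n_basal[[type]] + 1L
    }
  }
  invisible(sys)
}

# plain-vector segment arrays (hot path: called every simulated day)
.segment_arrays <- function(sys) {
  ns <- vapply(sys$axes, function(a) a$n - 1L, integer(1))
  tot <- sum(pmax(ns, 0L))
  x1 <- numeric(tot); y1 <- numeric(tot); z1 <- numeric(tot)
  x2 <- numeric(tot); y2 <- numeric(tot); z2 <- numeric(tot)
  len <- numeric(tot); tim <- numeric(tot)
  axid <- integer(tot); ord <- integer(tot); rad <- numeric(tot)
  typ <- character(tot)
  k <- 0L
  for (i in seq_along(sys$axes)) {
    ax <- sys$axes[[i]]
    if (ax$n < 2L) next
    m <- ax$n - 1L
    idx <- (k + 1L):(k + m)
    a <- ax$nodes[1:m, , drop = FALSE]
    b <- ax$nodes[2:ax$n, , drop = FALSE]
    x1[idx] <- a[, 1]; y1[idx] <- a[, 2]; z1[idx] <- a[, 3]
    x2[idx] <- b[, 1]; y2[idx] <- b[, 2]; z2[idx] <- b[, 3]
    len[idx] <- sqrt((b[, 1] - a[, 1])^2 + (b[, 2] - a[, 2])^2 +
                       (b[, 3] - a[, 3])^2)
    tim[idx] <- ax$times[2:ax$n]
    axid[idx] <- i; ord[idx] <- ax$order
    rad[idx] <- sys$types[[ax$type]]$radius
    typ[idx] <- ax$type
    k <- k + m
  }
  list(x1 = x1, y1 = y1, z1 = z1, x2 = x2, y2 = y2, z2 = z2,
       length = len, time = tim, axis = axid, order = ord,
       radius = rad, type = typ, n = tot)
}

#' Segment table of a root system
#'
#' @param sys A `root_system`.
#' @return Tibble with one row per segment: endpoints, length, creation
#'   time, axis id, type, order, radius.
#' @export
root_segments <- function(sys) {
  s <- .segment_arrays(sys)
  tibble::tibble(axis = s$axis, type = s$type, order = s$order,
                 x1 = s$x1, y1 = s$y1, z1 = s$z1,
                 x2 = s$x2, y2 = s$y2, z2 = s$z2,
                 length = s$length, time = s$time, radius = s$radius)
}

#' Root length density profile
#'
#' Bins segment length into horizontal depth layers of thickness `dz` and
#' divides by the soil volume per layer (`plant_area * dz`). Segments
#' crossing layer boundaries are split proportionally to their vertical
#' extent; per-layer mean root age is length-weighted.
#'
#' @param sys A `root_system`.
#' @param dz Layer thickness, cm (default 3).
#' @param z_max Profile depth, cm; defaults to the deepest node rounded up.
#' @param plant_area Ground area per plant, cm2; defaults to the system's.
#' @return Tibble `z_top, z_bot, rld, mean_age` (rld in cm cm-3).
#' @export
rld_profile <- function(sys, dz = 3, z_max = NULL, plant_area = NULL) {
  stopifnot(dz > 0)
  if (is.null(plant_area)) plant_area <- sys$plant_area
  s <- .segment_arrays(sys)
  if (is.null(z_max)) {
    z_deep <- if (s$n) max(s$z1, s$z2) else sys$base[3]
    z_max <- dz * ceiling(max(z_deep, dz) / dz)
  }
  n_bin <- ceiling(z_max / dz - 1e-9)
  z_top <- (seq_len(n_bin) - 1) * dz
  z_bot <- z_top + dz
  rld <- numeric(n_bin)
  age_wt <- numeric(n_bin)
  if (s$n) {
    zlo <- pmin(s$z1, s$z2)
    zhi <- pmax(s$z1, s$z2)
    dzseg <- zhi - zlo
    flat <- dzseg < 1e-12
    age <- sys$time - s$time
    wlen <- s$length
    wage <- wlen * age
    # vertical-extent clipping; segments inside one bin handled vectorised,
    # boundary-crossing segments individually
    lo_bin <- pmax(1L, pmin(n_bin, findInterval(zlo, z_top)))
    hi_bin <- pmax(1L, pmin(n_bin, findInterval(zhi - 1e-12, z_top)))
    same <- lo_bin == hi_bin | flat
    if (any(same)) {
      rld <- rld + .bin_sum(lo_bin[same], wlen[same], n_bin)
      age_wt <- age_wt + .bin_sum(lo_bin[same], wage[same], n_bin)
    }
    for (j in which(!same)) {
      for (b in lo_bin[j]:hi_bin[j]) {
        ov <- min(zhi[j], z_bot[b]) - max(zlo[j], z_top[b])
        if (ov <= 0) next
        f <- ov / dzseg[j]
        rld[b] <- rld[b] + wlen[j] * f
        age_wt[b] <- age_wt[b] + wage[j] * f
      }
    }
    vol <- plant_area * dz
    mean_age <- ifelse(rld > 0, age_wt / rld, 0)
    rld <- rld / vol
    return(tibble::tibble(z_top = z_top, z_bot = z_bot, rld = rld,
                          mean_age = mean_age))
  }
  tibble::tibble(z_top = z_top, z_bot = z_bot, rld = rld, mean_age = rld)
}

#' Whole-system summary
#'
#' @param sys A `root_system`.
#' @return One-row tibble: total length (cm), maximum rooting depth (cm),
#'   number of axes, per-order lengths, length-weighted mean radius, carbon
#'   spent (g).
#' @export
summarise_roots <- function(sys) {
  segs <- root_segments(sys)
  if (!nrow(segs)) {
    return(tibble::tibble(total_length = 0, max_depth = sys$base[3],
                          n_axes = length(sys$axes), length_order1 = 0,
                          length_order2 = 0, length_order3 = 0,
                          mean_radius = NA_real_,
                          carbon_spent = sys$carbon_spent))
  }
  by_ord <- function(o) sum(segs$length[segs$order == o])
  tibble::tibble(
    total_length = sum(segs$length),
    max_depth = max(segs$z1, segs$z2),
    n_axes = length(sys$axes),
    length_order1 = by_ord(1), length_order2 = by_ord(2),
    length_order3 = by_ord(3),
    mean_radius = sum(segs$length * segs$radius) / sum(segs$length),
    carbon_spent = sys$carbon_spent)
}

#' Stress lookup function from a stress field
#'
#' @param stress A `stress_field` from [stress_reduction_field()].
#' @return A function of depth (cm) returning `srf` of the containing cell
#'   (values beyond the profile use the deepest cell).
#' @export
stress_lookup <- function(stress) {
  z_top <- stress$z_top
  srf <- stress$srf
  n <- length(srf)
  function(z) srf[pmin(n, pmax(1L, findInterval(z, z_top)))]
}

#' Export a root system to RSML
#'
#' Writes the root system as Root System Markup Language: one scene, one
#' plant, nested `root` elements with polyline geometry and per-node
#' creation times.
#'
#' @param sys A `root_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(sys, path) {
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "last-modified", format(Sys.Date()))
  xml2::xml_add_child(meta, "software", "rhizosim")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1", label = "plant")
  children <- split(seq_along(sys$axes),
                    vapply(sys$axes, function(a) a$parent, integer(1)))
  add_root <- function(parent_node, i) {
    ax <- sys$axes[[i]]
    rt <- xml2::xml_add_child(parent_node, "root", id = as.character(i),
                              label = ax$type,
                              po..accession = as.character(ax$order))
    geom <- xml2::xml_add_child(rt, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    for (k in seq_len(ax$n)) {
      xml2::xml_add_child(poly, "point",
                          x = format(ax$nodes[k, 1], digits = 8),
                          y = format(ax$nodes[k, 2], digits = 8),
                          z = format(ax$nodes[k, 3], digits = 8))
    }
    fns <- xml2::xml_add_child(rt, "functions")
    fn <- xml2::xml_add_child(fns, "function", name = "creation_time",
                              domain = "polyline")
    for (k in seq_len(ax$n))
      xml2::xml_add_child(fn, "sample",
                          value = format(ax$times[k], digits = 8))
    for (j in children[[as.character(i)]] %||% integer(0))
      add_root(rt, j)
  }
  for (i in children[["0"]] %||% integer(0)) add_root(plant, i)
  xml2::write_xml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
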