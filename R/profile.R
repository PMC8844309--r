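#' Sphere-probe path profiles
#'
#' A `path_profile` records, at strictly increasing arc-length stations `s`
#' (Å), the center and radius of the largest probe sphere that fits the
#' structure in the plane normal to the path at `s`. For pore profiles `s`
#' is the signed distance along the channel axis from the axis origin; for
#' portal profiles `s` is the distance from the portal seed toward the axis
#' (negative = outward). Stations where the probe escaped laterally are
#' flagged `open_to_bulk`.
#'
#' @name path_profile
NULL

# Orthonormal in-plane basis perpendicular to a unit direction.
plane_basis <- function(dir) {
  e <- diag(3)[, which.min(abs(dir))]
  u <- e - sum(e * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  list(u = u, v = v)
}

# Generic probe walk along a straight path. Returns stations in both
# directions from the seed station, optimizing in-plane probe position per
# station by seeded multi-start Nelder-Mead under a lateral continuity
# constraint (|move| <= step).
profile_path <- function(structure, origin, direction, seed_point,
                         step = 0.25, bounds = NULL, rng_seed = 1,
                         escape_radius = 12, n_starts = 8,
                         direction_mode = "axis-aligned") {
  a <- structure$atoms
  if (nrow(a) == 0) stop_usage("structure has no atoms")
  if (any(is.na(a$vdw)))
    stop_usage("vdW radii must be assigned before profiling; ",
               "see assign_vdw_radii()")
  if (step <= 0) stop_usage("step must be positive")
  dir <- direction / sqrt(sum(direction^2))
  bb <- plane_basis(dir)
  X <- coords(structure)
  Xr <- sweep(X, 2, origin)
  ax <- drop(Xr %*% dir)           # axial coordinate of each atom
  pu <- drop(Xr %*% bb$u)          # in-plane coordinates
  pv <- drop(Xr %*% bb$v)
  r  <- a$vdw
  s0 <- sum((seed_point - origin) * dir)
  if (is.null(bounds)) bounds <- range(ax) + c(-2, 2)
  if (s0 < bounds[1] || s0 > bounds[2])
    stop_usage("seed point lies outside the station bounds")
  seed_uv <- c(sum((seed_point - origin) * bb$u),
               sum((seed_point - origin) * bb$v))

  # clearance at in-plane point p for station s, over slab-prefiltered atoms
  clearance_fun <- function(s) {
    keep <- abs(ax - s) - r <= escape_radius + 1
    if (!any(keep)) return(NULL)   # no atoms can touch: open to bulk
    du <- pu[keep]; dv <- pv[keep]; dz2 <- (ax[keep] - s)^2; rr <- r[keep]
    function(p) min(sqrt((p[1] - du)^2 + (p[2] - dv)^2 + dz2) - rr)
  }

  optimize_station <- function(s, prev) {
    f <- clearance_fun(s)
    if (is.null(f))
      return(list(p = prev, radius = escape_radius, open = TRUE))
    obj <- function(p) {
      d <- sqrt(sum((p - prev)^2))
      -f(p) + if (d > step) 1e4 * (d - step)^2 else 0
    }
    starts <- matrix(rep(prev, n_starts), ncol = 2, byrow = TRUE)
    if (n_starts > 1) {
      ang <- runif(n_starts - 1, 0, 2 * pi)
      rad <- step / 2 * sqrt(runif(n_starts - 1))
      starts[-1, 1] <- prev[1] + rad * cos(ang)
      starts[-1, 2] <- prev[2] + rad * sin(ang)
    }
    best <- NULL
    for (k in seq_len(n_starts)) {
      fit <- optim(starts[k, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-9))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    p <- best$par
    d <- sqrt(sum((p - prev)^2))
    if (d > step) p <- prev + (p - prev) * (step / d)  # clamp to constraint
    rad <- f(p)
    list(p = p, radius = rad, open = rad >= escape_radius)
  }

  walk <- function(s_seq, start_uv) {
    out <- vector("list", length(s_seq))
    prev <- start_uv
    for (i in seq_along(s_seq)) {
      st <- optimize_station(s_seq[i], prev)
      out[[i]] <- c(s = s_seq[i], u = st$p[1], v = st$p[2],
                    radius = min(st$radius, escape_radius),
                    open = as.numeric(st$open))
      if (st$open) { out <- out[seq_len(i)]; break }
      prev <- st$p
    }
    do.call(rbind, out)
  }

  res <- with_seed(rng_seed, {
    st0 <- optimize_station(s0, seed_uv)
    up <- if (s0 + step <= bounds[2] && !st0$open)
      walk(seq(s0 + step, bounds[2], by = step), st0$p) else NULL
    dn <- if (s0 - step >= bounds[1] && !st0$open)
      walk(seq(s0 - step, bounds[1], by = -step), st0$p) else NULL
    dn <- if (is.null(dn)) NULL else dn[rev(seq_len(nrow(dn))), , drop = FALSE]
    rbind(dn,
          matrix(c(s0, st0$p, min(st0$radius, escape_radius),
                   as.numeric(st0$open)), nrow = 1,
                 dimnames = list(NULL, c("s", "u", "v", "radius", "open"))),
          up)
  })

  centers <- origin +
    res[, "s", drop = FALSE] %*% rbind(dir) +
    res[, "u", drop = FALSE] %*% rbind(bb$u) +
    res[, "v", drop = FALSE] %*% rbind(bb$v)
  prof <- data.frame(s = res[, "s"],
                     cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                     radius = res[, "radius"],
                     flag = ifelse(res[, "open"] > 0, "open_to_bulk", ""),
                     hydrophobicity = NA_real_)
  structure(prof,
            class = c("path_profile", "data.frame"),
            seed_point = seed_point, direction_mode = direction_mode,
            path_origin = origin, path_direction = dir,
            step = step, rng_seed = rng_seed, escape_radius = escape_radius,
            barrier_flag = NA)
}

#' Radius profile of the central pore
#'
#' Walks a probe sphere along the channel axis from a seed point (by
#' convention the center of the pore-gate ring, e.g. F572) outward in both
#' directions. At each station the probe center maximizes the van der Waals
#' clearance `min_i(|p - x_i| - r_i)` within the plane normal to the axis,
#' moving at most `step` laterally per station (continuity); the maximized
#' clearance is the pore radius at that station. The in-plane maximization
#' uses seeded multi-start Nelder-Mead (default 8 starts: previous center
#' plus jittered copies) and is reproducible given `rng_seed`. If the
#' clearance reaches `escape_radius` the station is flagged open to bulk
#' and the walk stops in that direction.
#'
#' @param structure A [mol_structure] with vdW radii assigned.
#' @param axis A [channel_axis]; stations are signed distances along
#'   `axis$direction` from `axis$origin`.
#' @param seed 3-vector starting point (default: the axis origin).
#' @param step Station spacing, Å.
#' @param bounds Station range `c(s_min, s_max)`; default: atom extent ± 2 Å.
#' @param rng_seed Integer seed for the multi-start optimizer.
#' @param escape_radius Clearance (Å) at which the probe is considered in
#'   bulk solvent.
#' @param n_starts Local-search starts per station.
#' @return A [path_profile] (a data.frame with columns `s`, `cx`, `cy`,
#'   `cz`, `radius`, `flag`, `hydrophobicity`).
#' @examples
#' toy <- make_toy_channel(ring_z = seq(-5, 5, 0.5), ring_radius = 6,
#'                         atoms_per_ring = 24)
#' p <- profile_pore(toy$structure, channel_axis(c(0, 0, 0), c(0, 0, 1)),
#'                   bounds = c(-4, 4))
#' min_radius(p)
#' @export
profile_pore <- function(structure, axis, seed = NULL, step = 0.25,
                         bounds = NULL, rng_seed = 1, escape_radius = 12,
                         n_starts = 8) {
  stopifnot(inherits(axis, "channel_axis"))
  if (is.null(seed)) seed <- axis$origin
  profile_path(structure, axis$origin, axis$direction, as.numeric(seed),
               step = step, bounds = bounds, rng_seed = rng_seed,
               escape_radius = escape_radius, n_starts = n_starts,
               direction_mode = "axis-aligned")
}

#' Radius profile of a cytoplasmic side portal
#'
#' Seeds the probe at the geometric center of the portal-defining residues
#' (e.g. W622, F715, N719 and F705 of the adjacent subunit) and walks it
#' along the horizontal direction from that seed toward the channel axis
#' (in the membrane plane). Stations are distances from the portal seed
#' toward the axis; negative `s` points outward.
#'
#' @inheritParams profile_pore
#' @param portal_residues Residue selectors for [residue_center()]; the
#'   portal seed is their geometric center. Alternatively pass `seed`
#'   directly.
#' @param seed Optional explicit 3-vector seed (used when
#'   `portal_residues` is `NULL`).
#' @param bounds Station range; default `c(-12, distance to the axis)`.
#' @return A [path_profile] with `direction_mode = "toward-axis"`.
#' @export
profile_portal <- function(structure, axis, portal_residues = NULL,
                           seed = NULL, step = 0.25,
                           bounds = NULL, rng_seed = 1, escape_radius = 12,
                           n_starts = 8) {
  stopifnot(inherits(axis, "channel_axis"))
  if (is.null(portal_residues) && is.null(seed))
    stop_usage("supply portal_residues or an explicit seed")
  if (!is.null(portal_residues))
    seed <- residue_center(structure, portal_residues)
  seed <- as.numeric(seed)
  rel <- seed - axis$origin
  foot <- axis$origin + sum(rel * axis$direction) * axis$direction
  d <- foot - seed                       # horizontal: perpendicular to axis
  dn <- sqrt(sum(d^2))
  if (dn < 1e-9)
    stop_usage("portal seed lies on the axis; direction undefined")
  if (is.null(bounds)) bounds <- c(-12, dn)
  profile_path(structure, seed, d / dn, seed,
               step = step, bounds = bounds, rng_seed = rng_seed,
               escape_radius = escape_radius, n_starts = n_starts,
               direction_mode = "toward-axis")
}

#' Minimum radius of a profile within a window
#'
#' @param profile A [path_profile].
#' @param window Optional `c(s_lo, s_hi)`; default: all stations.
#' @return List with `station` (Å) and `radius` (Å) of the minimum; ties
#'   resolve to the smallest station.
#' @export
min_radius <- function(profile, window = NULL) {
  s <- profile$s
  keep <- if (is.null(window)) rep(TRUE, length(s))
          else s >= window[1] & s <= window[2]
  if (!any(keep)) stop_usage("window does not overlap any station")
  o <- order(s[keep])
  ss <- s[keep][o]; rr <- profile$radius[keep][o]
  i <- which.min(rr)                     # first minimum = smallest s
  list(station = ss[i], radius = rr[i])
}

#' Hydrophobicity along a profile and hydration-barrier heuristic
#'
#' Scores each station by the mean hydropathy of the residues lining it (a
#' residue lines a station if any of its atoms is within `contact_cutoff`
#' of the station center). Stations with no lining residue are marked
#' undefined (`NA`), not interpolated. A simple wetting heuristic flags a
#' potential hydration barrier when any station is simultaneously narrow
#' (`radius < r_wet`) and hydrophobic (`hydrophobicity > h_crit`).
#'
#' @param structure A [mol_structure].
#' @param profile A [path_profile] computed on `structure`.
#' @param scale Named residue -> score map (default [hydropathy_scale()];
#'   positive = hydrophobic).
#' @param contact_cutoff Lining distance, Å.
#' @param r_wet Radius threshold (Å) below which a hydrophobic station is
#'   considered at risk of dewetting.
#' @param h_crit Hydrophobicity threshold.
#' @return The profile with `hydrophobicity` filled and attribute
#'   `barrier_flag` (`TRUE`/`FALSE`); read it with [barrier_flag()].
#' @export
hydrophobicity_profile <- function(structure, profile,
                                   scale = hydropathy_scale(),
                                   contact_cutoff = 6.0,
                                   r_wet = 3.5, h_crit = 0) {
  a <- structure$atoms
  X <- coords(structure)
  reskey <- paste(a$chain, a$resno, a$ins, sep = "\r")
  scores <- numeric(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    ctr <- c(profile$cx[i], profile$cy[i], profile$cz[i])
    d2 <- (X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2 + (X[, 3] - ctr[3])^2
    near <- d2 <= contact_cutoff^2
    if (!any(near)) { scores[i] <- NA_real_; next }
    res <- unique(reskey[near])
    vals <- scale[a$resname[match(res, reskey)]]
    vals <- vals[!is.na(vals)]
    scores[i] <- if (length(vals)) mean(vals) else NA_real_
  }
  profile$hydrophobicity <- scores
  hit <- !is.na(scores) & profile$radius < r_wet & scores > h_crit
  attr(profile, "barrier_flag") <- any(hit)
  profile
}

#' @rdname hydrophobicity_profile
#' @export
barrier_flag <- function(profile) attr(profile, "barrier_flag")

#' Per-station radius envelope over trajectory frames
#'
#' Profiles every frame with the same seeding and resamples each profile to
#' the first frame's station grid, then reports pointwise mean, standard
#' deviation (n-1 denominator), minimum and maximum radius, the statistics
#' drawn as the dark (min/max) and light (mean ± 1 s.d.) bands of a
#' radius-envelope plot.
#'
#' @param frames List of [mol_structure] with identical atom counts.
#' @inheritParams profile_pore
#' @return A `profile_envelope` data.frame with columns `s`, `mean`, `sd`,
#'   `min`, `max`, `n` and attribute `n_frames`.
#' @export
profile_envelope <- function(frames, axis, seed = NULL, step = 0.25,
                             bounds = NULL, rng_seed = 1,
                             escape_radius = 12, n_starts = 8) {
  if (!length(frames)) stop_usage("need at least one frame")
  n_atoms <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n_atoms)) != 1)
    stop_usage("frames have incompatible atom counts")
  profs <- lapply(seq_along(frames), function(i)
    profile_pore(frames[[i]], axis, seed = seed, step = step,
                 bounds = bounds, rng_seed = rng_seed,
                 escape_radius = escape_radius, n_starts = n_starts))
  s_ref <- profs[[1]]$s
  R <- vapply(profs, function(p) {
    if (nrow(p) == 1) {
      ifelse(abs(s_ref - p$s) < 1e-9, p$radius, NA_real_)
    } else {
      approx(p$s, p$radius, xout = s_ref, rule = 1)$y
    }
  }, numeric(length(s_ref)))
  R <- matrix(R, nrow = length(s_ref))
  n  <- rowSums(!is.na(R))
  mu <- rowMeans(R, na.rm = TRUE)
  sdv <- apply(R, 1, function(x) if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE) else 0)
  env <- data.frame(s = s_ref, mean = mu, sd = sdv,
                    min = apply(R, 1, min, na.rm = TRUE),
                    max = apply(R, 1, max, na.rm = TRUE),
                    n = n)
  structure(env, class = c("profile_envelope", "data.frame"),
            n_frames = length(frames))
}

#' @export
print.path_profile <- function(x, ...) {
  m <- min_radius(x)
  cat(sprintf("<path_profile> %d stations, s in [%.2f, %.2f] Å (%s)\n",
              nrow(x), min(x$s), max(x$s), attr(x, "direction_mode")))
  cat(sprintf("  minimum radius %.2f Å at s = %.2f Å\n", m$radius, m$station))
  if (any(x$flag == "open_to_bulk"))
    cat("  walk terminated open-to-bulk at one or both ends\n")
  if (isTRUE(attr(x, "barrier_flag")))
    cat("  hydration-barrier heuristic: FLAGGED\n")
  invisible(x)
}

#' @export
plot.path_profile <- function(x, ...) {
  plot(x$s, x$radius, type = "l", xlab = "s (Å)",
       ylab = "probe radius (Å)", ...)
  abline(v = min_radius(x)$station, lty = 3)
  invisible(x)
}

#' @export
print.profile_envelope <- function(x, ...) {
  cat(sprintf("<profile_envelope> %d stations over %d frames\n",
              nrow(x), attr(x, "n_frames")))
  i <- which.min(x$mean)
  cat(sprintf("  mean minimum radius %.2f ± %.2f Å (s.d.) at s = %.2f Å\n",
              x$mean[i], x$sd[i], x$s[i]))
  invisible(x)
}

#' @export
plot.profile_envelope <- function(x, ...) {
  plot(NA, xlim = range(x$s), ylim = c(0, max(x$max)),
       xlab = "s (Å)", ylab = "probe radius (Å)", ...)
  polygon(c(x$s, rev(x$s)), c(x$min, rev(x$max)),
          col = "gray40", border = NA)
  polygon(c(x$s, rev(x$s)),
          c(pmax(x$mean - x$sd, 0), rev(x$mean + x$sd)),
          col = adjustcolor("gray80", alpha.f = 0.8), border = NA)
  lines(x$s, x$mean, lwd = 2)
  invisible(x)
}
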