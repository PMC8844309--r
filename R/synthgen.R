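#' Toy channel solid with an analytic radius profile
#'
#' Places pseudo-atoms on stacked rings along z (uniform azimuths, no
#' jitter), giving a solid whose exact probe-radius profile is
#' `ring_radius(z) - atom_radius` for dense rings. Each ring is one residue
#' (so residue-level hydropathy can be attached), and `atoms_per_ring`
#' divisible by 7 yields C7-symmetric solids. Optional portal holes are cut
#' by omitting atoms within an aperture of a point on the wall.
#'
#' @param ring_z Ring stations along z, Å.
#' @param ring_radius Ring radius per station, Å (recycled); must exceed
#'   `atom_radius`.
#' @param atoms_per_ring Atoms per ring.
#' @param atom_radius Pseudo-atom vdW radius, Å.
#' @param resname Residue name per ring (recycled), for hydropathy scoring.
#' @param portal_holes Optional data.frame with columns `z`, `azimuth_deg`,
#'   `aperture` (Å): atoms within `aperture` of the wall point at that
#'   height/azimuth are omitted.
#' @return List with `structure` (a [mol_structure] with vdW assigned),
#'   `analytic` (data.frame `z`, `radius`) and the call parameters.
#' @examples
#' toy <- make_toy_channel(seq(-5, 5, 0.5), 6, atoms_per_ring = 28)
#' head(toy$analytic)   # radius 4.3 everywhere
#' @export
make_toy_channel <- function(ring_z, ring_radius, atoms_per_ring = 28,
                             atom_radius = 1.7, resname = "ALA",
                             portal_holes = NULL) {
  ring_radius <- rep_len(ring_radius, length(ring_z))
  resname <- rep_len(resname, length(ring_z))
  if (any(ring_radius <= atom_radius))
    stop_usage("ring radii must exceed the atom radius")
  rows <- lapply(seq_along(ring_z), function(i) {
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring
    data.frame(name = "C", element = "C", resname = resname[i],
               resno = i, chain = "A",
               x = ring_radius[i] * cos(ang),
               y = ring_radius[i] * sin(ang),
               z = ring_z[i], stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, rows)
  if (!is.null(portal_holes)) {
    keep <- rep(TRUE, nrow(a))
    for (k in seq_len(nrow(portal_holes))) {
      h <- portal_holes[k, ]
      R_h <- approx(ring_z, ring_radius, xout = h$z, rule = 2)$y
      ctr <- c(R_h * cos(h$azimuth_deg * pi / 180),
               R_h * sin(h$azimuth_deg * pi / 180), h$z)
      d2 <- (a$x - ctr[1])^2 + (a$y - ctr[2])^2 + (a$z - ctr[3])^2
      keep <- keep & d2 > h$aperture^2
    }
    a <- a[keep, , drop = FALSE]
  }
  a$serial <- seq_len(nrow(a))
  a$ins <- ""
  a$vdw <- atom_radius
  list(structure = mol_structure(a, label = "toy channel"),
       analytic = data.frame(z = ring_z, radius = ring_radius - atom_radius),
       atoms_per_ring = atoms_per_ring, atom_radius = atom_radius)
}

#' Brownian permeation simulation specification
#'
#' Conditions for the overdamped-Langevin ion simulation: free diffusion
#' coefficient, transmembrane driving potential applied across the channel
#' span, ion count/charge, timestep and duration. The default geometry is a
#' cytoplasmic cage (interior radius 8 Å, floor at z = -20 Å) with an
#' annular portal slit in its wall at z in \[-14, -6\] Å, a transmembrane
#' pore of wall radius 6 Å from z = 0 to 15 Å, and bulk reservoirs below
#' and above; the default box emulates a ~0.5 M reservoir at the default
#' ion count. The stability condition `sqrt(2 D dt) <= aperture/4` is
#' enforced.
#'
#' @param n_ions Number of tracked ions.
#' @param charge Ion charge, e (default -1, a chloride-like anion).
#' @param D Diffusion coefficient, Å²/ns (default 200, roughly aqueous
#'   Cl-).
#' @param potential Transmembrane potential (inside minus outside), mV;
#'   negative values drive anions outward (default -425).
#' @param dt Timestep, ns.
#' @param total_time Simulated time, ns.
#' @param temperature K (default 310).
#' @param seed RNG seed; the run is bit-reproducible given the seed.
#' @param geometry Optional list overriding the default geometry (see
#'   [brownian_geometry()]).
#' @return Object of class `brownian_spec`.
#' @export
brownian_spec <- function(n_ions = 60, charge = -1, D = 200,
                          potential = -425, dt = 0.002, total_time = 10,
                          temperature = 310, seed = 1, geometry = NULL) {
  geom <- geometry %||% brownian_geometry()
  if (dt <= 0 || total_time <= 0) stop_usage("dt and total_time must be positive")
  aperture <- 2 * geom$pore_wall_radius
  if (sqrt(2 * D * dt) > aperture / 4)
    stop_usage(sprintf(
      "unstable timestep: sqrt(2 D dt) = %.2f Å exceeds aperture/4 = %.2f Å",
      sqrt(2 * D * dt), aperture / 4))
  structure(list(n_ions = n_ions, charge = charge, D = D,
                 potential = potential, dt = dt, total_time = total_time,
                 temperature = temperature, seed = seed, geometry = geom),
            class = "brownian_spec")
}

#' Geometry for the Brownian simulation
#'
#' Bundles the solid-wall parameters of the toy channel and the matching
#' compartment [channel_geometry()] used for detection. `z_extracellular`
#' sits infinitesimally above the pore top so an ion is extracellular as
#' soon as it clears the pore.
#'
#' @param pore_wall_radius,cage_radius Interior radii, Å.
#' @param wall_thickness Solid wall thickness, Å.
#' @param z_pore_top,z_pore_bottom,z_cage_bottom Axial boundaries, Å.
#' @param portal_z Portal slit z range in the cage wall, Å.
#' @param box_xy Lateral half-width of the box, Å.
#' @param z_floor,z_top Bottom (reflecting) and top (reinjection) of the
#'   box, Å.
#' @param reinject_z Reinjection height in the cytosolic reservoir, Å.
#' @param reinject_jitter Half-width of the uniform reinjection-height
#'   jitter, Å (0 = deterministic height).
#' @param field_span Axial range over which the driving field acts, Å.
#' @param solid If `FALSE`, no walls (a "frictionless" column; only the
#'   box bounds act) — useful for ballistic-limit checks.
#' @param channel Optional [channel_geometry()] override for compartment
#'   labelling; default: derived from the wall parameters.
#' @return List with the solid parameters and `$channel`, the matching
#'   [channel_geometry()].
#' @export
brownian_geometry <- function(pore_wall_radius = 6, cage_radius = 8,
                              wall_thickness = 2,
                              z_pore_top = 15, z_pore_bottom = 0,
                              z_cage_bottom = -20, portal_z = c(-14, -6),
                              box_xy = 30, z_floor = -45, z_top = 33,
                              reinject_z = -30, reinject_jitter = 2,
                              field_span = c(z_cage_bottom, z_pore_top),
                              solid = TRUE, channel = NULL) {
  channel <- channel %||% channel_geometry(
    cylinder_radius = cage_radius,
    z_extracellular = z_pore_top + 1e-9,
    z_pore_top = z_pore_top, z_pore_bottom = z_pore_bottom,
    z_cage_bottom = z_cage_bottom,
    portals = data.frame(r_min = cage_radius - 0.5,
                         r_max = cage_radius + wall_thickness + 0.5,
                         z_min = portal_z[1], z_max = portal_z[2]))
  list(pore_wall_radius = pore_wall_radius, cage_radius = cage_radius,
       wall_thickness = wall_thickness,
       z_pore_top = z_pore_top, z_pore_bottom = z_pore_bottom,
       z_cage_bottom = z_cage_bottom, portal_z = portal_z,
       box_xy = box_xy, z_floor = z_floor, z_top = z_top,
       reinject_z = reinject_z, reinject_jitter = reinject_jitter,
       field_span = field_span, solid = solid,
       channel = channel)
}

#' Simulate Brownian ions through the toy channel
#'
#' Overdamped Langevin dynamics: per step, each ion moves by a drift
#' `mu q E dt` (Einstein mobility `mu = D/kT`, uniform field `E` from the
#' potential drop across `field_span`) plus Gaussian noise of variance
#' `2 D dt` per component. Moves into the solid walls are rejected
#' (axial-only and lateral-only fallbacks are tried first, approximating
#' reflection); ions leaving the top of the box are reinjected into the
#' cytosolic reservoir, keeping the ion count constant. The generator also
#' emits its own ground-truth log of completed portal -> pore -> bulk
#' passages, computed independently of [detect_crossings()].
#'
#' @param spec A [brownian_spec].
#' @return List with `traj` (an [ion_trajectory]), `passages` (data.frame
#'   `ion`, `portal`, `t_entry`, `t_exit`, `transit`), and `spec`.
#' @export
simulate_ions <- function(spec) {
  stopifnot(inherits(spec, "brownian_spec"))
  g <- spec$geometry
  n <- spec$n_ions
  n_steps <- round(spec$total_time / spec$dt)
  kT_mV <- 0.08617333262 * spec$temperature      # Boltzmann constant, meV/K
  L <- diff(g$field_span)
  drift_mag <- (spec$D * spec$dt / kT_mV) * spec$charge * spec$potential / L

  in_solid <- function(P) {
    z <- P[, 3]
    outside <- abs(P[, 1]) > g$box_xy | abs(P[, 2]) > g$box_xy |
      z < g$z_floor
    if (!isTRUE(g$solid)) return(outside)
    r <- sqrt(P[, 1]^2 + P[, 2]^2)
    membrane <- z > g$z_pore_bottom & z < g$z_pore_top &
      r > g$pore_wall_radius
    wall <- r > g$cage_radius & r < g$cage_radius + g$wall_thickness &
      z > g$z_cage_bottom & z < g$z_pore_bottom &
      !(z > g$portal_z[1] & z < g$portal_z[2])
    floorw <- z > g$z_cage_bottom - g$wall_thickness & z < g$z_cage_bottom &
      r < g$cage_radius + g$wall_thickness
    outside | membrane | wall | floorw
  }

  # independent labelling for the ground-truth log (same definition as
  # assign_compartments, coded separately)
  truth_label <- function(P) {
    ch <- g$channel
    r <- sqrt(P[, 1]^2 + P[, 2]^2); z <- P[, 3]
    lab <- rep("BULK_CYT", nrow(P))
    lab[z > ch$z_extracellular] <- "BULK_EXT"
    po <- ch$portals
    for (k in rev(seq_len(nrow(po))))   # first matching portal wins
      lab[r >= po$r_min[k] & r <= po$r_max[k] &
            z >= po$z_min[k] & z <= po$z_max[k]] <- "PORTAL"
    lab[r <= ch$cylinder_radius &
          z >= ch$z_cage_bottom & z < ch$z_pore_bottom] <- "CAGE"
    lab[r <= ch$cylinder_radius &
          z >= ch$z_pore_bottom & z <= ch$z_pore_top] <- "PORE"
    lab
  }

  reinject <- function(k) {
    jit <- if (g$reinject_jitter > 0)
      runif(k, -g$reinject_jitter, g$reinject_jitter) else 0
    cbind(runif(k, -g$box_xy + 1, g$box_xy - 1),
          runif(k, -g$box_xy + 1, g$box_xy - 1),
          g$reinject_z + jit)
  }

  res <- with_seed(spec$seed, {
    # initial positions: cytosolic reservoir, rejection-sampled off solids
    P <- reinject(n)
    bad <- in_solid(P)
    while (any(bad)) { P[bad, ] <- reinject(sum(bad)); bad <- in_solid(P) }
    frames <- array(NA_real_, dim = c(n_steps + 1, n, 3))
    frames[1, , ] <- P
    # ground-truth state machine
    entry <- rep(NA_real_, n); portal <- rep(NA_integer_, n)
    pore_seen <- rep(FALSE, n)
    passages <- list()
    step_truth <- function(time_ns) {
      lab <- truth_label(P)
      for (j in which(lab != "CAGE")) {
        lj <- lab[j]
        if (lj == "PORTAL") {
          if (is.na(entry[j])) {
            entry[j] <<- time_ns
            po <- g$channel$portals
            r <- sqrt(P[j, 1]^2 + P[j, 2]^2); z <- P[j, 3]
            portal[j] <<- which(r >= po$r_min & r <= po$r_max &
                                  z >= po$z_min & z <= po$z_max)[1]
          }
        } else if (lj == "PORE") {
          if (!is.na(entry[j])) pore_seen[j] <<- TRUE
        } else if (lj == "BULK_EXT") {
          if (!is.na(entry[j]) && pore_seen[j])
            passages[[length(passages) + 1]] <<- data.frame(
              ion = j, portal = portal[j], t_entry = entry[j],
              t_exit = time_ns, transit = time_ns - entry[j])
          entry[j] <<- NA_real_; portal[j] <<- NA_integer_
          pore_seen[j] <<- FALSE
        } else {  # BULK_CYT
          entry[j] <<- NA_real_; portal[j] <<- NA_integer_
          pore_seen[j] <<- FALSE
        }
      }
    }
    step_truth(0)
    sigma <- sqrt(2 * spec$D * spec$dt)
    for (i in seq_len(n_steps)) {
      in_field <- P[, 3] >= g$field_span[1] & P[, 3] <= g$field_span[2]
      noise <- matrix(rnorm(3 * n, sd = sigma), ncol = 3)
      prop <- P + noise
      prop[, 3] <- prop[, 3] + ifelse(in_field, drift_mag, 0)
      bad <- in_solid(prop)
      if (any(bad)) {            # axial-only fallback, then reject
        ax <- prop
        ax[bad, 1:2] <- P[bad, 1:2, drop = FALSE]
        still <- rep(FALSE, n)
        still[bad] <- in_solid(ax[bad, , drop = FALSE])
        prop[bad, ] <- ax[bad, , drop = FALSE]
        if (any(still)) {
          lat <- prop
          lat[still, 3] <- P[still, 3]
          s2 <- rep(FALSE, n)
          s2[still] <- in_solid(lat[still, , drop = FALSE])
          prop[still, ] <- lat[still, , drop = FALSE]
          prop[s2, ] <- P[s2, , drop = FALSE]
        }
      }
      P <- prop
      # reinjection from the top reservoir
      out <- which(P[, 3] > g$z_top)
      if (length(out)) {
        Q <- reinject(length(out))
        badq <- in_solid(Q)
        while (any(badq)) { Q[badq, ] <- reinject(sum(badq)); badq <- in_solid(Q) }
        P[out, ] <- Q
        entry[out] <- NA_real_; portal[out] <- NA_integer_
        pore_seen[out] <- FALSE
      }
      frames[i + 1, , ] <- P
      step_truth(i * spec$dt)
    }
    list(frames = frames,
         passages = if (length(passages)) do.call(rbind, passages) else
           data.frame(ion = numeric(0), portal = integer(0),
                      t_entry = numeric(0), t_exit = numeric(0),
                      transit = numeric(0)))
  })
  traj <- ion_trajectory(times = (0:n_steps) * spec$dt,
                         positions = res$frames,
                         charge = spec$charge,
                         axis = channel_axis(c(0, 0, 0), c(0, 0, 1)))
  list(traj = traj, passages = res$passages, spec = spec)
}

#' Markov-gating patch-clamp sweep specification
#'
#' Conditions for the two-state (closed/open) gating simulation behind
#' synthetic stretch-activated sweeps: during the pressure stimulus
#' channels open at `open_rate` (and close at `close_rate_during`); after
#' the stimulus they close at `1/tau_deact` and do not reopen. The open
#' current per channel is `gamma (V - erev) / 1000` pA and Gaussian noise
#' of `noise_sd` pA is added per sample.
#'
#' @param n_channels Channels in the patch.
#' @param gamma Single-channel conductance, pS.
#' @param erev Reversal potential, mV.
#' @param voltage Holding potential, mV.
#' @param open_rate Opening rate during stimulus, 1/s.
#' @param close_rate_during Closing rate during stimulus, 1/s.
#' @param tau_deact Deactivation time constant, s.
#' @param noise_sd Gaussian current noise, pA.
#' @param sampling_rate Hz.
#' @param t_total,stim_start,stim_end Sweep and stimulus timing, s
#'   (a 1 s pressure pulse by default).
#' @param pressure Stimulus amplitude, mmHg.
#' @param seed RNG seed.
#' @return Object of class `gating_spec`.
#' @export
gating_spec <- function(n_channels = 1, gamma = 100, erev = 0,
                        voltage = -80, open_rate = 50,
                        close_rate_during = 0, tau_deact = 0.5,
                        noise_sd = 0.5, sampling_rate = 5000,
                        t_total = 2, stim_start = 0.2, stim_end = 1.2,
                        pressure = -70, seed = 1) {
  if (any(c(n_channels, gamma, tau_deact, sampling_rate, t_total) <= 0) ||
      noise_sd < 0 || open_rate < 0 || close_rate_during < 0)
    stop_usage("rates, noise, sampling and durations must be positive")
  structure(as.list(environment()), class = "gating_spec")
}

#' Simulate a stretch-activated patch-clamp sweep
#'
#' Two-state Markov gating per channel under the spec's pressure-step
#' protocol; see [gating_spec()]. Returns the sweep together with
#' machine-readable ground truth (conductance, open-level current, tau,
#' and the open-channel count series).
#'
#' @param spec A [gating_spec].
#' @return List with `sweep` (a [sweep_trace]) and `truth`.
#' @examples
#' sw <- simulate_patch_sweep(gating_spec(noise_sd = 0, seed = 7))
#' range(sw$sweep$current_pA)   # 0 and -8 pA for 100 pS at -80 mV
#' @export
simulate_patch_sweep <- function(spec) {
  stopifnot(inherits(spec, "gating_spec"))
  dt <- 1 / spec$sampling_rate
  t <- seq(0, spec$t_total - dt / 2, by = dt)
  stim_on <- t >= spec$stim_start & t < spec$stim_end
  open_level <- spec$gamma * (spec$voltage - spec$erev) / 1000  # pA
  res <- with_seed(spec$seed, {
    state <- rep(FALSE, spec$n_channels)
    n_open <- integer(length(t))
    p_open_on <- 1 - exp(-spec$open_rate * dt)
    p_close_on <- 1 - exp(-spec$close_rate_during * dt)
    p_close_off <- 1 - exp(-dt / spec$tau_deact)
    for (i in seq_along(t)) {
      if (stim_on[i]) {
        u <- runif(spec$n_channels)
        state <- ifelse(state, u >= p_close_on, u < p_open_on)
      } else {
        u <- runif(spec$n_channels)
        state <- state & (u >= p_close_off)
      }
      n_open[i] <- sum(state)
    }
    current <- n_open * open_level +
      if (spec$noise_sd > 0) rnorm(length(t), sd = spec$noise_sd) else 0
    list(n_open = n_open, current = current)
  })
  sweep <- sweep_trace(time = t, current = res$current,
                       pressure = ifelse(stim_on, spec$pressure, 0),
                       voltage = spec$voltage,
                       sampling_rate = spec$sampling_rate)
  list(sweep = sweep,
       truth = list(gamma_pS = spec$gamma, erev_mV = spec$erev,
                    tau_deact_s = spec$tau_deact,
                    open_level_pA = open_level,
                    n_open = res$n_open))
}

#' Synthetic single-channel I-V dataset
#'
#' `i = gamma (V - erev)/1000 + N(0, sigma)` per voltage — the fixture for
#' slope-conductance recovery.
#'
#' @param gamma Single-channel conductance, pS.
#' @param erev Reversal potential, mV.
#' @param voltages Holding potentials, mV (>= 3).
#' @param sigma Current noise s.d., pA.
#' @param seed RNG seed.
#' @return data.frame with columns `v` (mV) and `i` (pA).
#' @export
make_iv_dataset <- function(gamma, erev = 0, voltages = seq(-80, 80, 20),
                            sigma = 0.2, seed = 1) {
  if (length(voltages) < 3) stop_usage("need at least 3 voltages")
  i <- gamma * (voltages - erev) / 1000
  if (sigma > 0) i <- i + with_seed(seed, rnorm(length(voltages), sd = sigma))
  data.frame(v = voltages, i = i)
}
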