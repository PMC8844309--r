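#' Ion trajectory container
#'
#' Frame series of tracked ion positions on a uniform time grid, with the
#' channel axis and (optionally) periodic box lengths and protein frames.
#'
#' @param times Frame times in ns, strictly increasing and uniform (within
#'   1e-6 ns).
#' @param positions Numeric array `[n_frames, n_ions, 3]` of positions, Å.
#' @param charge Per-ion charge in elementary-charge units (recycled).
#' @param axis A [channel_axis].
#' @param ids Optional ion identifiers (default `1:n_ions`).
#' @param box Optional periodic box lengths `c(Lx, Ly, Lz)`, Å.
#' @param protein_frames Optional: a single [mol_structure] (e.g. a
#'   restrained protein) or a list of one per frame.
#' @return An object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(times, positions, charge = -1, axis,
                           ids = NULL, box = NULL, protein_frames = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1 || is.unsorted(times, strictly = TRUE))
    stop_usage("times must be strictly increasing")
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop_usage("times must be uniformly spaced (within 1e-6 ns)")
  }
  d <- dim(positions)
  if (length(d) != 3 || d[3] != 3)
    stop_usage("positions must be an [n_frames, n_ions, 3] array")
  if (d[1] != length(times))
    stop_usage("positions and times disagree on the number of frames")
  stopifnot(inherits(axis, "channel_axis"))
  n_ions <- d[2]
  structure(list(times = times,
                 positions = positions,
                 charge = rep_len(charge, n_ions),
                 ids = ids %||% seq_len(n_ions),
                 axis = axis, box = box,
                 protein_frames = protein_frames),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("<ion_trajectory> %d ions x %d frames, dt = %g ns%s\n",
              dim(x$positions)[2], length(x$times),
              if (length(x$times) > 1) diff(x$times)[1] else NA,
              if (is.null(x$box)) "" else ", periodic"))
  invisible(x)
}

#' Channel compartment geometry
#'
#' Distance-based constraints to the channel axis that partition space into
#' the five permeation compartments: the transmembrane PORE (inside the
#' cylinder, between `z_pore_bottom` and `z_pore_top`), the cytoplasmic
#' CAGE below it, the side PORTAL annuli at the cage wall, and the two bulk
#' reservoirs. The z boundaries must be strictly ordered
#' `z_cage_bottom < z_pore_bottom < z_pore_top < z_extracellular`; placing
#' `z_extracellular` infinitesimally above `z_pore_top` makes an ion
#' extracellular as soon as it clears the pore.
#'
#' @param cylinder_radius Radial cutoff for PORE/CAGE, Å (default 8).
#' @param z_extracellular,z_pore_top,z_pore_bottom,z_cage_bottom Axial
#'   boundaries, Å along the axis.
#' @param portals data.frame with columns `r_min`, `r_max`, `z_min`,
#'   `z_max` (one row per portal annulus), or `NULL`.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(cylinder_radius = 8,
                             z_extracellular, z_pore_top,
                             z_pore_bottom, z_cage_bottom,
                             portals = NULL) {
  zs <- c(z_cage_bottom, z_pore_bottom, z_pore_top, z_extracellular)
  if (any(!is.finite(zs)) || is.unsorted(zs, strictly = TRUE))
    stop_usage("z boundaries must satisfy z_cage_bottom < z_pore_bottom ",
               "< z_pore_top < z_extracellular")
  if (cylinder_radius <= 0) stop_usage("cylinder_radius must be positive")
  if (!is.null(portals)) {
    stopifnot(all(c("r_min", "r_max", "z_min", "z_max") %in% names(portals)))
    if (any(portals$r_max <= portals$r_min) ||
        any(portals$z_max <= portals$z_min))
      stop_usage("portal annuli must have positive extents")
  }
  structure(list(cylinder_radius = cylinder_radius,
                 z_extracellular = z_extracellular,
                 z_pore_top = z_pore_top,
                 z_pore_bottom = z_pore_bottom,
                 z_cage_bottom = z_cage_bottom,
                 portals = portals),
            class = "channel_geometry")
}

# axial/radial coordinates of an [n, 3] position block relative to an axis
axial_radial <- function(P, axis) {
  rel <- sweep(P, 2, axis$origin)
  z <- drop(rel %*% axis$direction)
  perp <- rel - outer(z, axis$direction)
  list(z = z, r = sqrt(rowSums(perp^2)))
}

#' Assign permeation compartments per ion and frame
#'
#' Labels every (ion, frame) pair as one of `PORE`, `CAGE`, `PORTAL`,
#' `BULK_EXT`, `BULK_CYT` using the geometry's distance constraints.
#' Boundary ties resolve by precedence PORE > CAGE > PORTAL > bulk.
#'
#' @param traj An [ion_trajectory].
#' @param geom A [channel_geometry].
#' @return A `compartment_series`: character matrix `[n_frames, n_ions]`
#'   with attributes `times`, `ids`, `charge` and `portal_index` (matrix of
#'   the matching portal row, NA elsewhere).
#' @export
assign_compartments <- function(traj, geom) {
  stopifnot(inherits(traj, "ion_trajectory"),
            inherits(geom, "channel_geometry"))
  d <- dim(traj$positions)
  P <- matrix(traj$positions, nrow = d[1] * d[2], ncol = 3)
  if (any(!is.finite(P))) {
    bad <- which(!is.finite(rowSums(P)))[1]
    stop(sprintf("non-finite coordinate at frame %d",
                 ((bad - 1) %% d[1]) + 1), call. = FALSE)
  }
  ar <- axial_radial(P, traj$axis)
  z <- ar$z; r <- ar$r
  lab <- rep("BULK_CYT", length(z))
  pidx <- rep(NA_integer_, length(z))
  lab[z > geom$z_extracellular] <- "BULK_EXT"
  if (!is.null(geom$portals)) {
    for (k in rev(seq_len(nrow(geom$portals)))) {
      p <- geom$portals[k, ]
      hit <- r >= p$r_min & r <= p$r_max & z >= p$z_min & z <= p$z_max
      lab[hit] <- "PORTAL"
      pidx[hit] <- k
    }
  }
  in_cyl <- r <= geom$cylinder_radius
  cage <- in_cyl & z >= geom$z_cage_bottom & z < geom$z_pore_bottom
  pore <- in_cyl & z >= geom$z_pore_bottom & z <= geom$z_pore_top
  lab[cage] <- "CAGE"; pidx[cage] <- NA
  lab[pore] <- "PORE"; pidx[pore] <- NA
  m <- matrix(lab, nrow = d[1], ncol = d[2])
  structure(m, class = "compartment_series",
            times = traj$times, ids = traj$ids, charge = traj$charge,
            portal_index = matrix(pidx, nrow = d[1], ncol = d[2]))
}

#' Detect completed permeation (crossing) events
#'
#' A crossing event is one ion's complete passage: it enters a side portal,
#' later visits the pore, and then reaches the extracellular bulk without
#' returning to the cytoplasmic bulk in between. Returning to `BULK_CYT`
#' (or finishing in `BULK_EXT` without the portal-then-pore sequence)
#' restarts the state machine; partial passages yield no event. The entry
#' time is the first `PORTAL` frame of the completed passage and the exit
#' time the first `BULK_EXT` frame.
#'
#' @param series A `compartment_series` from [assign_compartments()].
#' @param charge Charge per event in e; default: each ion's own charge.
#' @return data.frame of class `crossing_events` with columns `ion`,
#'   `portal`, `t_entry`, `t_exit`, `transit`, `charge` (ns, e). May have
#'   zero rows.
#' @export
detect_crossings <- function(series, charge = NULL) {
  stopifnot(inherits(series, "compartment_series"))
  times <- attr(series, "times"); ids <- attr(series, "ids")
  qs <- attr(series, "charge"); pim <- attr(series, "portal_index")
  out <- list()
  for (j in seq_len(ncol(series))) {
    L <- series[, j]
    q <- if (is.null(charge)) qs[j] else charge
    entry <- NA_integer_; portal <- NA_integer_; pore_seen <- FALSE
    for (i in seq_along(L)) {
      lab <- L[i]
      if (lab == "PORTAL") {
        if (is.na(entry)) { entry <- i; portal <- pim[i, j] }
      } else if (lab == "PORE") {
        if (!is.na(entry)) pore_seen <- TRUE
      } else if (lab == "BULK_EXT") {
        if (!is.na(entry) && pore_seen) {
          out[[length(out) + 1]] <- data.frame(
            ion = ids[j], portal = portal,
            t_entry = times[entry], t_exit = times[i],
            transit = times[i] - times[entry], charge = q)
        }
        entry <- NA_integer_; portal <- NA_integer_; pore_seen <- FALSE
      } else if (lab == "BULK_CYT") {
        entry <- NA_integer_; portal <- NA_integer_; pore_seen <- FALSE
      }
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(ion = numeric(0), portal = integer(0), t_entry = numeric(0),
               t_exit = numeric(0), transit = numeric(0), charge = numeric(0))
  class(ev) <- c("crossing_events", "data.frame")
  ev
}

#' Conductance from counted permeation events
#'
#' Implements the charge-transfer estimator G = I/V = Q/(t x V): the total
#' transferred charge `Q = n_events x charge x e` over duration `t` at
#' driving potential `V`. The sign of the potential is discarded; the
#' magnitude is reported in pS.
#'
#' @param n_events Number of completed crossing events, or a
#'   `crossing_events` data.frame (its row count and mean |charge| are used).
#' @param charge Charge per event, elementary units.
#' @param duration Observation time, ns (> 0).
#' @param potential Driving potential, mV (non-zero).
#' @return Object of class `conductance_estimate` with field
#'   `conductance_pS`.
#' @examples
#' estimate_conductance(36, 1, 300, 425)  # ~45.2 pS
#' @export
estimate_conductance <- function(n_events, charge = 1, duration, potential) {
  if (inherits(n_events, "crossing_events")) {
    ev <- n_events
    n_events <- nrow(ev)
    if (n_events > 0) charge <- mean(abs(ev$charge))
  }
  if (!is.numeric(duration) || duration <= 0)
    stop_usage("duration must be positive")
  if (!is.numeric(potential) || potential == 0)
    stop_usage("potential must be non-zero")
  Q_C <- n_events * abs(charge) * .const$e_C
  G_S <- Q_C / ((duration * 1e-9) * abs(potential * 1e-3))
  structure(list(n_events = n_events, charge_per_event = abs(charge),
                 duration_ns = duration, potential_mV = potential,
                 conductance_pS = G_S * 1e12),
            class = "conductance_estimate")
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("<conductance_estimate> %.3g pS (%d events x %.3g e / %g ns / %g mV)\n",
              x$conductance_pS, x$n_events, x$charge_per_event,
              x$duration_ns, abs(x$potential_mV)))
  invisible(x)
}

#' Axial (z) coordinate tracks of tracked ions
#'
#' Signed projection of each ion's position onto the channel axis relative
#' to the axis origin. With a periodic box, per-step displacements are
#' unwrapped by the minimal-image convention before projection, so tracks
#' are continuous across box boundaries.
#'
#' @param traj An [ion_trajectory].
#' @param ions Optional subset of ion ids.
#' @return data.frame with columns `ion`, `t` (ns), `z` (Å).
#' @export
z_tracks <- function(traj, ions = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"))
  ids <- traj$ids
  sel <- if (is.null(ions)) seq_along(ids) else match(ions, ids)
  if (anyNA(sel))
    stop(sprintf("unknown ion id(s): %s",
                 paste(ions[is.na(sel)], collapse = ", ")), call. = FALSE)
  res <- lapply(sel, function(j) {
    P <- traj$positions[, j, , drop = FALSE]
    P <- matrix(P, ncol = 3)
    if (!is.null(traj$box) && nrow(P) > 1) {
      L <- rep_len(as.numeric(traj$box), 3)
      dP <- diff(P)
      cum <- matrix(0, nrow(P), 3)
      for (k in 1:3) {
        dP[, k] <- dP[, k] - L[k] * round(dP[, k] / L[k])
        cum[, k] <- c(0, cumsum(dP[, k])) + P[1, k]
      }
      P <- cum
    }
    z <- drop(sweep(P, 2, traj$axis$origin) %*% traj$axis$direction)
    data.frame(ion = ids[j], t = traj$times, z = z)
  })
  do.call(rbind, res)
}

#' First-contact ladder of a crossing event
#'
#' For one crossing event, reports the first time the permeating ion comes
#' within `cutoff` of each listed residue's basic/charged side-chain
#' nitrogens, ordered by contact time — the "interaction ladder" of portal
#' entry (e.g. K624 and R599 first, then K606). The handover is
#' unidirectional when, after the ion's first contact with the acceptor
#' residue (default: the last listed), it never re-contacts the donor
#' residue (default: the second-to-last listed) within the event.
#'
#' @param traj An [ion_trajectory] with `protein_frames`.
#' @param event One-row subset of a `crossing_events` data.frame.
#' @param residues data.frame with columns `chain`, `resno` and optionally
#'   `label`, in ladder order.
#' @param cutoff Contact distance, Å (default 4.0, a typical ion-amine
#'   contact).
#' @param contact_atoms Atom names considered charged-group contacts.
#' @param donor,acceptor Row indices into `residues` defining the handover
#'   pair (defaults: second-to-last and last).
#' @return List with `ladder` (data.frame `label`, `resno`, `t_first`,
#'   ordered, NA-contact residues last) and `unidirectional` (logical).
#' @export
contact_ladder <- function(traj, event, residues, cutoff = 4.0,
                           contact_atoms = c("NZ", "NH1", "NH2", "NE",
                                             "ND1", "NE2"),
                           donor = nrow(residues) - 1L,
                           acceptor = nrow(residues)) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (is.null(traj$protein_frames))
    stop_usage("trajectory has no protein frames")
  if (!"label" %in% names(residues))
    residues$label <- paste0("res", residues$resno)
  frames_idx <- which(traj$times >= event$t_entry &
                        traj$times <= event$t_exit)
  j <- match(event$ion, traj$ids)
  if (is.na(j)) stop_usage("event ion not found in trajectory")
  static <- inherits(traj$protein_frames, "mol_structure")
  get_frame <- function(i) if (static) traj$protein_frames
                           else traj$protein_frames[[i]]
  n_res <- nrow(residues)
  # per-residue atom indices (resolved on the first frame's structure)
  f0 <- get_frame(frames_idx[1])
  res_atoms <- lapply(seq_len(n_res), function(k) {
    idx <- select_atoms(f0, chain = if (is.na(residues$chain[k])) NULL
                                    else residues$chain[k],
                        resno = residues$resno[k], name = contact_atoms)
    if (!length(idx))  # fall back to all side-chain atoms of the residue
      idx <- select_atoms(f0, chain = if (is.na(residues$chain[k])) NULL
                                      else residues$chain[k],
                          resno = residues$resno[k])
    if (!length(idx))
      stop(sprintf("residue %s/%s resolves to no atoms",
                   residues$chain[k], residues$resno[k]), call. = FALSE)
    idx
  })
  contact <- matrix(FALSE, nrow = length(frames_idx), ncol = n_res)
  for (ii in seq_along(frames_idx)) {
    i <- frames_idx[ii]
    ion_p <- traj$positions[i, j, ]
    X <- coords(get_frame(i))
    for (k in seq_len(n_res)) {
      d2 <- (X[res_atoms[[k]], 1] - ion_p[1])^2 +
            (X[res_atoms[[k]], 2] - ion_p[2])^2 +
            (X[res_atoms[[k]], 3] - ion_p[3])^2
      contact[ii, k] <- any(d2 <= cutoff^2)
    }
  }
  first <- apply(contact, 2, function(col) {
    w <- which(col); if (length(w)) traj$times[frames_idx[w[1]]] else NA_real_
  })
  ladder <- data.frame(label = residues$label, resno = residues$resno,
                       t_first = first)
  ladder <- ladder[order(is.na(ladder$t_first), ladder$t_first), ]
  uni <- NA
  if (!is.na(donor) && !is.na(acceptor) && donor >= 1) {
    acc_first <- which(contact[, acceptor])
    if (length(acc_first)) {
      later_donor <- which(contact[, donor]) > acc_first[1]
      uni <- !any(later_donor)
    }
  }
  list(ladder = ladder, unidirectional = uni)
}

#' Chi1 rotamer series of a residue across frames
#'
#' Computes the side-chain chi1 dihedral (N-CA-CB-CG, degrees in
#' (-180, 180]) per frame and bins it into the standard rotamer classes:
#' trans for chi1 in \[120, 180\] or (-180, -120), gauche- for \[-120, 0),
#' gauche+ for \[0, 120).
#'
#' @param frames List of [mol_structure] (or a single structure).
#' @param residue Named list/selector with `chain` and `resno`.
#' @return data.frame of class `rotamer_series` with columns `frame`,
#'   `chi1`, `label`.
#' @export
chi1_series <- function(frames, residue) {
  if (inherits(frames, "mol_structure")) frames <- list(frames)
  need <- c("N", "CA", "CB", "CG")
  out <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    idx <- vapply(need, function(nm) {
      w <- select_atoms(f, chain = residue$chain %||% NULL,
                        resno = residue$resno, name = nm)
      if (!length(w))
        stop(sprintf("residue %s is missing atom %s",
                     residue$resno, nm), call. = FALSE)
      w[1]
    }, integer(1))
    X <- coords(f)[idx, ]
    ang <- bio3d::torsion.xyz(as.numeric(t(X)), atm.inc = 4)
    ang <- as.numeric(ang[1])
    ang <- ((ang + 180) %% 360) - 180
    if (ang == -180) ang <- 180
    data.frame(frame = i, chi1 = ang, label = chi1_label(ang))
  })
  res <- do.call(rbind, out)
  class(res) <- c("rotamer_series", "data.frame")
  res
}

chi1_label <- function(ang) {
  ifelse(ang >= 120 | ang < -120, "trans",
         ifelse(ang < 0, "gauche-", "gauche+"))
}

#' Wetting occupancy of a channel region
#'
#' Fraction of frames in which at least `min_waters` water oxygens occupy
#' the axial/radial region — the simple wetted/dewetted statistic used to
#' ask whether a constriction stays hydrated.
#'
#' @param waters An [ion_trajectory] of water-oxygen positions.
#' @param region List with `z = c(lo, hi)` and `r = c(lo, hi)` relative to
#'   the axis, Å.
#' @param min_waters Minimum occupancy count for a frame to be "wetted".
#' @return Wetted-frame fraction in \[0, 1\].
#' @export
wetting_occupancy <- function(waters, region, min_waters = 1) {
  stopifnot(inherits(waters, "ion_trajectory"))
  if (region$z[2] <= region$z[1] || region$r[2] <= region$r[1])
    stop_usage("region has empty extent")
  d <- dim(waters$positions)
  P <- matrix(waters$positions, nrow = d[1] * d[2], ncol = 3)
  ar <- axial_radial(P, waters$axis)
  inside <- matrix(ar$z >= region$z[1] & ar$z <= region$z[2] &
                     ar$r >= region$r[1] & ar$r <= region$r[2],
                   nrow = d[1], ncol = d[2])
  mean(rowSums(inside) >= min_waters)
}
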