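# Independent oracles and small geometry builders shared across tests.

# Brute-force maximal probe clearance in the plane z = z0 (axis along z):
# two-stage dense 2D grid search over min_i(|p - x_i| - r_i).
grid_clearance <- function(structure, z0, lim = 8, coarse = 0.2,
                           fine = 0.02) {
  a <- structure$atoms
  best <- function(gx, gy) {
    G <- expand.grid(x = gx, y = gy)
    cl <- vapply(seq_len(nrow(G)), function(i) {
      min(sqrt((a$x - G$x[i])^2 + (a$y - G$y[i])^2 + (a$z - z0)^2) - a$vdw)
    }, numeric(1))
    k <- which.max(cl)
    list(p = c(G$x[k], G$y[k]), clearance = cl[k])
  }
  b1 <- best(seq(-lim, lim, coarse), seq(-lim, lim, coarse))
  b2 <- best(seq(b1$p[1] - coarse, b1$p[1] + coarse, fine),
             seq(b1$p[2] - coarse, b1$p[2] + coarse, fine))
  b2$clearance
}

# Regular-expression oracle for crossing detection: per-ion label string,
# leftmost non-overlapping matches of PORTAL ... PORE ... BULK_EXT with no
# intervening BULK_CYT/BULK_EXT.
regex_crossings <- function(series) {
  times <- attr(series, "times"); ids <- attr(series, "ids")
  code <- c(BULK_CYT = "C", PORTAL = "P", CAGE = "G",
            PORE = "O", BULK_EXT = "E")
  out <- list()
  for (j in seq_len(ncol(series))) {
    s <- paste(code[series[, j]], collapse = "")
    m <- gregexpr("P[^CE]*O[^CE]*E", s)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      i0 <- m[k]; i1 <- m[k] + attr(m, "match.length")[k] - 1
      out[[length(out) + 1]] <- data.frame(
        ion = ids[j], t_entry = times[i0], t_exit = times[i1],
        transit = times[i1] - times[i0])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(ion = numeric(0), t_entry = numeric(0),
               t_exit = numeric(0), transit = numeric(0))
}

# Independent point-containment oracle for compartment labels (scalar,
# deliberately naive).
containment_oracle <- function(p, axis, geom) {
  rel <- p - axis$origin
  z <- sum(rel * axis$direction)
  r <- sqrt(sum((rel - z * axis$direction)^2))
  in_cyl <- r <= geom$cylinder_radius
  if (in_cyl && z >= geom$z_pore_bottom && z <= geom$z_pore_top) return("PORE")
  if (in_cyl && z >= geom$z_cage_bottom && z < geom$z_pore_bottom)
    return("CAGE")
  if (!is.null(geom$portals)) {
    for (k in seq_len(nrow(geom$portals))) {
      po <- geom$portals[k, ]
      if (r >= po$r_min && r <= po$r_max && z >= po$z_min && z <= po$z_max)
        return("PORTAL")
    }
  }
  if (z > geom$z_extracellular) return("BULK_EXT")
  "BULK_CYT"
}

# Closed-form OLS slope/intercept via the normal equations.
ols_oracle <- function(v, i) {
  n <- length(v)
  sxx <- sum(v^2) - sum(v)^2 / n
  sxy <- sum(v * i) - sum(v) * sum(i) / n
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(i) - slope * mean(v))
}

# Rotation matrix about a unit axis by angle (radians).
rot3 <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rotate_structure <- function(structure, R) {
  X <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- X[, 1]
  structure$atoms$y <- X[, 2]
  structure$atoms$z <- X[, 3]
  structure
}

# Place atom d with given bond length/angle (deg) and dihedral (deg)
# relative to atoms a-b-c (NeRF construction) - used to build side chains
# with a prescribed chi1.
place_dihedral <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Minimal mol_structure from a data.frame of atom fields with defaults.
quick_structure <- function(df, label = "test") {
  n <- nrow(df)
  defaults <- data.frame(serial = seq_len(n), name = "C", element = "C",
                         resname = "ALA", resno = 1L, ins = "",
                         chain = "A", vdw = NA_real_,
                         stringsAsFactors = FALSE)
  for (nm in names(df)) defaults[[nm]] <- df[[nm]]
  mol_structure(defaults, label = label)
}

# A compartment_series built directly from per-ion label sequences.
label_series <- function(labels_list, dt = 0.1) {
  m <- do.call(cbind, labels_list)
  n <- nrow(m)
  structure(m, class = "compartment_series",
            times = (seq_len(n) - 1) * dt,
            ids = seq_along(labels_list),
            charge = rep(-1, length(labels_list)),
            portal_index = matrix(ifelse(m == "PORTAL", 1L, NA_integer_),
                                  nrow = n))
}

# Uniform heptamer ring of single-atom residues.
make_ring_structure <- function(n = 7, R = 10, z = 0, center = c(0, 0, 0),
                                noise = 0, seed = 1) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  xyz <- cbind(center[1] + R * cos(ang), center[2] + R * sin(ang),
               center[3] + z)
  if (noise > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    xyz <- xyz + matrix(rnorm(3 * n, sd = noise), ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  quick_structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             resno = seq_len(n)))
}
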