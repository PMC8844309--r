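#' Molecular structure container
#'
#' A light container for (pseudo-)channel coordinates: one row per atom with
#' serial, atom name, element, residue identity (3-letter code, number,
#' insertion code), chain, Cartesian position in Å and, once assigned, a van
#' der Waals radius in Å. Serials must be unique and every atom belongs to
#' exactly one chain.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `ins`, `chain`, `x`, `y`, `z` and optionally `vdw`.
#' @param label Free-text label carried in output metadata.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, label = "") {
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_usage("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"vdw" %in% names(atoms)) atoms$vdw <- NA_real_
  if (anyDuplicated(atoms$serial))
    stop_usage("atom serial numbers must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_usage("atom coordinates must be finite")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 label = label),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<mol_structure> %s\n", if (nzchar(x$label)) x$label else ""))
  cat(sprintf("  %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              nrow(unique(a[, c("chain", "resno", "ins")]))))
  if (all(is.na(a$vdw))) cat("  vdW radii: not assigned\n")
  else cat(sprintf("  vdW radii: %.2f-%.2f Å\n",
                   min(a$vdw, na.rm = TRUE), max(a$vdw, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.mol_structure <- function(x, ...) x$atoms

# Coordinates as an n x 3 matrix.
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Read a channel structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM records into a [mol_structure] (coordinates in Å,
#' author residue numbering, insertion codes preserved). Alternate locations
#' are resolved to the highest-occupancy conformer (tie: first encountered).
#' Parsing is delegated to \pkg{bio3d}; malformed fixed-width ATOM records
#' are reported with their line number before bio3d is invoked.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param radius_from_b If `TRUE`, restore vdW radii from the B-factor
#'   column (the convention used by [write_structure()]).
#' @return A [mol_structure].
#' @seealso [assign_vdw_radii()], [write_structure()]
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"),
                           radius_from_b = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb",
                     cif = "cif", mmcif = "cif",
                     stop_usage("cannot infer format from extension '.",
                                ext, "'; pass format explicitly"))
  }
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    rec <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(rec)) stop_usage("no ATOM/HETATM records in ", path)
    bad <- which(rec & nchar(lines) < 54)
    if (length(bad))
      stop_usage(sprintf("truncated ATOM/HETATM record at line %d of %s",
                         bad[1], path))
    pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    pdb <- bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  }
  a <- pdb$atom
  # resolve altlocs: highest occupancy per (chain, resno, ins, name)
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- a$o
    occ[is.na(occ)] <- 1
    key <- paste(a$chain, a$resno, a$insert %||% "", a$elety, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i) {
      if (length(i) == 1) return(i)
      i[which.max(occ[i])]   # which.max takes the first on ties
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  ins <- a$insert
  ins[is.na(ins)] <- ""
  ch <- a$chain
  ch[is.na(ch)] <- "A"
  s <- mol_structure(data.frame(
    serial  = a$eleno,
    name    = trimws(a$elety),
    element = trimws(a$elesy %||% ""),
    resname = trimws(a$resid),
    resno   = a$resno,
    ins     = ins,
    chain   = ch,
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  ), label = basename(path))
  if (radius_from_b) s$atoms$vdw <- a$b
  s
}

#' Write a structure as PDB
#'
#' Fixed-width PDB output via \pkg{bio3d}. Assigned vdW radii are stored in
#' the B-factor column (two decimals, exact for the shipped table), so a
#' `load_structure(..., radius_from_b = TRUE)` round trip restores them.
#'
#' @param structure A [mol_structure].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  b <- a$vdw
  b[is.na(b)] <- 0
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   insert = ifelse(nzchar(a$ins), a$ins, ""),
                   elety = a$name, eleno = a$serial,
                   o = rep(1, nrow(a)), b = b, elesy = a$element)
  invisible(path)
}

#' Select atom indices by chain / residue / atom name
#'
#' @param structure A [mol_structure].
#' @param chain,resno,name,resname Optional filters; `NULL` means "any".
#' @return Integer vector of row indices into `structure$atoms`.
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL,
                         name = NULL, resname = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  which(keep)
}

#' Channel axis
#'
#' Origin and unit direction of the channel's symmetry (pore) axis;
#' `+direction` points to the extracellular side.
#'
#' @param origin 3-vector, Å.
#' @param direction 3-vector; normalised internally (must be non-zero).
#' @return An object of class `channel_axis`.
#' @export
channel_axis <- function(origin, direction) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  stopifnot(length(origin) == 3, length(direction) == 3)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) stop_usage("axis direction must be non-zero")
  structure(list(origin = origin, direction = direction / n),
            class = "channel_axis")
}

#' @export
print.channel_axis <- function(x, ...) {
  cat(sprintf("<channel_axis> origin (%.2f, %.2f, %.2f) Å, direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

resolve_selection <- function(structure, selection) {
  if (is.numeric(selection) && is.null(names(selection)))
    return(as.integer(selection))
  do.call(select_atoms, c(list(structure), as.list(selection)))
}

#' Symmetry (pore) axis of a channel
#'
#' Estimates the n-fold symmetry axis from a ring-like atom selection:
#' origin is the centroid of the selected positions and the direction is the
#' ring normal, i.e. the principal axis of smallest dispersion (a flat ring
#' spreads in-plane; its normal is the minimal-variance eigenvector of the
#' position covariance). The sign is fixed so that `+direction` points
#' toward an extracellular reference selection or point; without a
#' reference, the sign makes the largest-magnitude component positive.
#'
#' @param structure A [mol_structure].
#' @param selection Atom index vector or a named filter list passed to
#'   [select_atoms()] (e.g. `list(resno = 572, name = "CA")`).
#' @param extracellular_ref Optional: a 3-vector point, or a selection
#'   (indices / filter list) whose centroid fixes the axis sign.
#' @return A [channel_axis].
#' @export
symmetry_axis <- function(structure, selection, extracellular_ref = NULL) {
  idx <- resolve_selection(structure, selection)
  if (length(idx) < 3) stop_usage("selection must yield at least 3 atoms")
  X <- coords(structure)[idx, , drop = FALSE]
  origin <- colMeans(X)
  Xc <- sweep(X, 2, origin)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  # eigenvalues descending; a ring has two large in-plane values and one
  # small out-of-plane value. Collinear/coincident points leave the normal
  # undefined (second eigenvalue ~ 0).
  if (ev$values[1] < 1e-12 || ev$values[2] / ev$values[1] < 1e-10)
    stop("degenerate selection: points are collinear or coincident",
         call. = FALSE)
  dir <- ev$vectors[, 3]
  if (!is.null(extracellular_ref)) {
    ref <- if (is.numeric(extracellular_ref) &&
               length(extracellular_ref) == 3 &&
               is.null(names(extracellular_ref))) {
      as.numeric(extracellular_ref)
    } else {
      ridx <- resolve_selection(structure, extracellular_ref)
      if (!length(ridx)) stop_usage("extracellular_ref resolves to no atoms")
      colMeans(coords(structure)[ridx, , drop = FALSE])
    }
    if (sum((ref - origin) * dir) < 0) dir <- -dir
  } else if (dir[which.max(abs(dir))] < 0) {
    dir <- -dir
  }
  channel_axis(origin, dir)
}

#' Geometric center of one or more residues
#'
#' Unweighted mean of all atom positions of the selected residues, e.g. the
#' portal center defined by the W622/F715/N719/F705 ring of an adjacent
#' subunit. Selector order is irrelevant.
#'
#' @param structure A [mol_structure].
#' @param selectors data.frame with columns `chain` and `resno` (chain `NA`
#'   matches any chain), or a list of `c(chain, resno)` pairs.
#' @return Numeric 3-vector, Å.
#' @export
residue_center <- function(structure, selectors) {
  if (!is.data.frame(selectors)) {
    selectors <- do.call(rbind, lapply(selectors, function(s) {
      if (is.list(s)) data.frame(chain = s$chain %||% NA, resno = s$resno)
      else data.frame(chain = as.character(s[1]), resno = as.numeric(s[2]))
    }))
  }
  a <- structure$atoms
  idx <- integer(0)
  for (i in seq_len(nrow(selectors))) {
    ch <- selectors$chain[i]; rn <- selectors$resno[i]
    hit <- which(a$resno == rn & (is.na(ch) | a$chain == ch))
    if (!length(hit))
      stop(sprintf("selector (chain %s, residue %s) resolves to no atoms",
                   ifelse(is.na(ch), "*", ch), rn), call. = FALSE)
    idx <- c(idx, hit)
  }
  unname(colMeans(coords(structure)[idx, , drop = FALSE]))
}
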