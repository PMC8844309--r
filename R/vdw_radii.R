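#' Bondi-style van der Waals radii (Å) by element
#'
#' The element-to-radius table shipped with the package and used by
#' [assign_vdw_radii()] unless the caller supplies an override. Values are
#' the widely used Bondi set (with the common 1.2 Å hydrogen).
#'
#' @return Named numeric vector of radii in Å, names are element symbols.
#' @examples
#' vdw_table()[["C"]]  # 1.70
#' @export
vdw_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
    Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39, Fe = 2.00,
    Se = 1.90, B = 1.92)
}

# Infer an element symbol from the element column, falling back to
# atom-name heuristics (leading characters of the PDB atom name).
infer_element <- function(element, name) {
  el <- trimws(as.character(element))
  el <- ifelse(is.na(el), "", el)
  # normalise case: "CL" -> "Cl", "c" -> "C"
  el <- ifelse(nchar(el) > 0,
               paste0(toupper(substr(el, 1, 1)),
                      tolower(substr(el, 2, nchar(el)))),
               el)
  known <- names(vdw_table())
  fix <- !(el %in% known)
  if (any(fix)) {
    nm <- toupper(trimws(as.character(name[fix])))
    # two-letter halogens/metals first, else the first alphabetic character
    guess <- ifelse(substr(nm, 1, 2) %in% c("CL", "BR", "NA", "MG", "FE",
                                            "ZN", "SE", "CA") &
                      nchar(nm) == 2,
                    substr(nm, 1, 2),
                    substr(gsub("[^A-Z]", "", nm), 1, 1))
    guess <- paste0(substr(guess, 1, 1), tolower(substr(guess, 2, 2)))
    el[fix] <- guess
  }
  el
}

#' Assign van der Waals radii to a structure
#'
#' Adds a `vdw` radius (Å) to every atom, looked up by element in `table`;
#' elements absent from the table receive `default` with one warning that
#' lists them. Coordinates are untouched.
#'
#' @param structure A [mol_structure].
#' @param table Named numeric vector, element -> radius in Å. Defaults to the
#'   shipped Bondi-style table; a user table takes precedence element-wise.
#' @param default Fallback radius in Å for unknown elements (must be > 0).
#' @return The structure with `atoms$vdw` filled.
#' @examples
#' s <- make_toy_channel(ring_z = 0, ring_radius = 6, atoms_per_ring = 8)$structure
#' s <- assign_vdw_radii(s)
#' @export
assign_vdw_radii <- function(structure, table = vdw_table(), default = 1.5) {
  stopifnot(inherits(structure, "mol_structure"))
  if (length(table) == 0) stop_usage("radius table must be non-empty")
  if (!is.numeric(default) || default <= 0)
    stop_usage("default vdW radius must be positive")
  # user entries override shipped ones
  full <- vdw_table()
  full[names(table)] <- table
  el <- infer_element(structure$atoms$element, structure$atoms$name)
  r <- unname(full[el])
  miss <- is.na(r)
  if (any(miss)) {
    warning(sprintf("no vdW radius for element(s) %s; using default %.2f Å",
                    paste(unique(el[miss]), collapse = ", "), default))
    r[miss] <- default
  }
  structure$atoms$element <- el
  structure$atoms$vdw <- r
  structure
}

#' Kyte-Doolittle residue hydropathy scale
#'
#' Shipped residue-level hydrophobicity scale (positive = hydrophobic) used
#' by [hydrophobicity_profile()]. Covers the 20 standard amino acids.
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
hydropathy_scale <- function() {
  c(ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
    GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
    LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
    SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2)
}
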