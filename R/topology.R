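#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#' @importFrom stats setNames
NULL

# residue-name vocabularies used for role assignment
.aa_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "MSE"
)
.water_resnames <- c("HOH", "TIP3", "TIP4", "WAT", "SOL", "SPC")

#' Atom topology table
#'
#' A topology is a tibble with one row per atom, in file order, carrying the
#' metadata every downstream operation needs: identity, element, hydrogen
#' flag, residue, and a role (`protein`, `ligand`, `water` or `other`).
#'
#' @param atoms A data frame with columns `atom_id`, `name`, `element`,
#'   `is_hydrogen`, `residue_id`, `residue_name`, `role`.
#' @return A tibble of class `mltsa_topology`.
#' @export
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_id", "name", "element", "is_hydrogen",
              "residue_id", "residue_name", "role")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("topology is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(atoms$atom_id) > 0) {
    abort("topology atom_ids must be unique")
  }
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms$is_hydrogen <- as.logical(atoms$is_hydrogen)
  if (!all(atoms$role %in% c("protein", "ligand", "water", "other"))) {
    abort("topology roles must be one of protein/ligand/water/other")
  }
  class(atoms) <- c("mltsa_topology", class(atoms))
  atoms
}

#' @export
print.mltsa_topology <- function(x, ...) {
  counts <- table(factor(x$role, levels = c("protein", "ligand", "water", "other")))
  cat(sprintf(
    "<topology> %d atoms (%d protein, %d ligand, %d water, %d other), %d hydrogens\n",
    nrow(x), counts[["protein"]], counts[["ligand"]], counts[["water"]],
    counts[["other"]], sum(x$is_hydrogen)
  ))
  NextMethod()
}

#' Assign atom roles from residue names
#'
#' Waters are recognised by the common water residue names (HOH, TIP3, TIP4,
#' WAT, SOL, SPC), protein by the standard amino-acid three-letter codes
#' (plus CHARMM/AMBER histidine variants), and the ligand by a caller-supplied
#' residue-name list; everything else is `other`.
#'
#' @param residue_name Character vector of residue names.
#' @param ligand_resnames Character vector of residue names to treat as ligand.
#' @return Character vector of roles.
#' @export
assign_roles <- function(residue_name, ligand_resnames = character()) {
  rn <- toupper(residue_name)
  role <- rep("other", length(rn))
  role[rn %in% .aa_resnames] <- "protein"
  role[rn %in% .water_resnames] <- "water"
  role[rn %in% toupper(ligand_resnames)] <- "ligand"
  role
}

#' Infer the element from a PDB atom name
#'
#' Fallback for PDB files whose element column is absent: digits are
#' stripped and the leading alphabetic character is taken, so `"1HB"` and
#' `"HG12"` are hydrogens and `"CA"` is carbon (alpha carbon, not calcium,
#' which is the right call inside protein residues).
#'
#' @param name Character vector of atom names.
#' @return Character vector of element symbols.
#' @export
infer_element <- function(name) {
  stripped <- gsub("[0-9'\"]", "", trimws(name))
  el <- toupper(substr(stripped, 1, 1))
  el[el == ""] <- "X"
  el
}

#' Read a PDB structure
#'
#' Parses a PDB file (via bio3d) into a [topology()] and a one-frame
#' [trajectory()]. Roles are assigned by residue name; the ligand residue
#' name(s) must be supplied because ligands are arbitrary HETATM residues.
#'
#' @param path Path to a PDB file.
#' @param ligand_resnames Residue name(s) identifying the ligand.
#' @param require_ligand Error if no ligand atoms match (default `TRUE`).
#' @return A one-frame [trajectory()] (its `$topology` is the topology).
#' @export
read_structure <- function(path, ligand_resnames = character(),
                           require_ligand = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  element <- toupper(trimws(if ("elesy" %in% names(at)) at$elesy else ""))
  if (length(element) != nrow(at)) element <- rep("", nrow(at))
  blank <- is.na(element) | element == ""
  element[blank] <- infer_element(at$elety[blank])
  top <- topology(tibble(
    atom_id = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = element,
    is_hydrogen = element == "H",
    residue_id = at$resno,
    residue_name = trimws(at$resid),
    role = assign_roles(at$resid, ligand_resnames)
  ))
  if (require_ligand && length(ligand_resnames) > 0 && !any(top$role == "ligand")) {
    abort(paste0("no atoms matched ligand residue name(s): ",
                 paste(ligand_resnames, collapse = ", ")))
  }
  coords <- cbind(at$x, at$y, at$z)
  if (anyNA(coords)) abort(paste0("non-numeric coordinates in '", path, "'"))
  trajectory(top, coords)
}

#' Write a topology + coordinates as a PDB file
#'
#' Fixture-oriented writer (single frame) built on bio3d.
#'
#' @param traj A [trajectory()]; its first frame is written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path) {
  top <- traj$topology
  xyz <- as.numeric(t(frame_coords(traj, 1)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(top$role == "protein", "ATOM", "HETATM"),
    resno = top$residue_id, resid = top$residue_name,
    eleno = top$atom_id, elety = top$name, elesy = top$element
  )
  invisible(path)
}

#' Resolve an atom selection
#'
#' @param topology A [topology()].
#' @param role Optional role filter (one or more of protein/ligand/water/other).
#' @param heavy_only Drop hydrogens.
#' @param residue_range Optional inclusive `c(first, last)` residue-id window.
#' @param allow_empty Return `integer(0)` instead of erroring when nothing
#'   matches.
#' @return Integer vector of atom indices (positions in file order).
#' @export
select_atoms <- function(topology, role = NULL, heavy_only = FALSE,
                         residue_range = NULL, allow_empty = FALSE) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(role)) keep <- keep & topology$role %in% role
  if (heavy_only) keep <- keep & !topology$is_hydrogen
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2 || residue_range[1] > residue_range[2]) {
      abort("residue_range must be c(first, last) with first <= last")
    }
    keep <- keep & topology$residue_id >= residue_range[1] &
      topology$residue_id <= residue_range[2]
  }
  idx <- which(keep)
  if (!allow_empty && length(idx) == 0) {
    abort("atom selection is empty")
  }
  idx
}
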