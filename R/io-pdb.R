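# shared PDB atom-table cleanup: first model (bio3d multi = FALSE), one
# chain, altloc 'A' or blank, ATOM records only, insertion codes rejected
pdb_atoms <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) abort("no ATOM records found for the requested chain")
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported")
  }
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at
}

aa_three_to_one <- function(resid) {
  one <- bio3d::aa321(resid)
  if (any(one == "X")) {
    abort(sprintf(
      "unknown residue name(s): %s",
      paste(unique(resid[one == "X"]), collapse = ", ")
    ))
  }
  one
}

#' Read a C-alpha trace from a PDB file
#'
#' Takes one residue per CA atom from the first model of the file.  Residues
#' that lack a CA atom are skipped with a warning; a file without any CA
#' atoms is an error.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; `NULL` takes all chains (only sensible for
#'   single-chain files).
#' @return A tibble with columns `seq_index` (residue number, strictly
#'   increasing), `aa` (one-letter code) and `x`, `y`, `z` (Angstrom).
#' @export
read_calpha_structure <- function(path, chain = NULL) {
  at <- pdb_atoms(path, chain)
  resnos <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) abort("no CA atoms found")
  missing_ca <- setdiff(resnos, ca$resno)
  if (length(missing_ca) > 0) {
    warn(sprintf(
      "%d residue(s) without a CA atom skipped: %s",
      length(missing_ca), paste(head(missing_ca, 5), collapse = ", ")
    ))
  }
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out <- tibble(
    seq_index = as.integer(ca$resno),
    aa = aa_three_to_one(ca$resid),
    x = ca$x, y = ca$y, z = ca$z
  )
  if (any(diff(out$seq_index) <= 0)) {
    abort("residue numbers are not strictly increasing")
  }
  if (!all(is.finite(c(out$x, out$y, out$z)))) abort("non-finite coordinates")
  out
}

#' Read heavy atoms with van der Waals radii from a PDB file
#'
#' Parses all heavy (non-hydrogen) atoms of the first model, assigns a fixed
#' Bondi-style radius per element (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom)
#' and flags the backbone atoms N, CA, C, O.  Glycine legitimately has an
#' empty side-chain atom set.
#'
#' @inheritParams read_calpha_structure
#' @return A tibble with columns `seq_index`, `aa`, `atom` (PDB atom name),
#'   `x`, `y`, `z`, `radius` and `backbone` (logical).
#' @export
read_sidechain_structure <- function(path, chain = NULL) {
  at <- pdb_atoms(path, chain)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  } else {
    blank <- is.na(elem) | elem == ""
    elem[blank] <- substr(gsub("[0-9]", "", at$elety[blank]), 1, 1)
  }
  elem <- toupper(elem)
  keep <- elem != "H"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  unknown <- !(elem %in% names(VDW_RADII))
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(sprintf(
      "unknown element '%s' for atom '%s' of residue %s %d",
      elem[i], at$elety[i], at$resid[i], at$resno[i]
    ))
  }
  tibble(
    seq_index = as.integer(at$resno),
    aa = aa_three_to_one(at$resid),
    atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    radius = unname(VDW_RADII[elem]),
    backbone = at$elety %in% c("N", "CA", "C", "O")
  )
}

#' Write an atom structure to a PDB file
#'
#' Companion writer for the tibbles produced by [read_sidechain_structure()]
#' and the synthetic helix-bundle generator; round-trips coordinates, atom
#' names and residue identities (radii are re-derived from the element on
#' read).
#'
#' @param structure Tibble with columns `seq_index`, `aa`, `atom`, `x`, `y`,
#'   `z`.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, chain = "A") {
  if (!"atom" %in% names(structure)) structure$atom <- "CA"
  three <- vapply(structure$aa, bio3d::aa123, character(1))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
    resno = structure$seq_index,
    resid = three,
    elety = structure$atom,
    chain = rep(chain, nrow(structure))
  )
  invisible(path)
}
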