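#' Default element sets and the element-pair subsets
#'
#' The point clouds feeding persistent homology are restricted to one
#' protein element and one ligand element at a time. The default protein
#' set is \{C, N, O, S\} and the default ligand set
#' \{C, N, O, S, P, F, Cl, Br, I\}; their product gives the 36 standard
#' element-pair subsets. Both sets can be overridden.
#'
#' @return `protein_elements()` and `ligand_elements()` return character
#'   vectors; `element_pair_subsets()` returns a tibble with columns
#'   `protein_element` and `ligand_element`, one row per subset (36 by
#'   default), protein element varying slowest.
#' @export
protein_elements <- function() c("C", "N", "O", "S")

#' @rdname protein_elements
#' @export
ligand_elements <- function() c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

#' @rdname protein_elements
#' @param protein,ligand element vectors to cross; defaults give the 36
#'   standard subsets.
#' @export
element_pair_subsets <- function(protein = protein_elements(),
                                 ligand = ligand_elements()) {
  tidyr::expand_grid(protein_element = protein, ligand_element = ligand)
}

# canonical element symbol: "CL" -> "Cl", "c" -> "C"
normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

.known_elements <- c(
  "H", "D", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Se",
  "Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu", "Co", "Ni", "Cd", "Hg", "As"
)

# element from a PDB atom name when the element column is absent/blank:
# strip digits/primes, two-letter halogens first, else first letter
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- normalize_element(substr(nm, 1, 2))
  ifelse(two %in% c("Cl", "Br", "Se"), two, substr(nm, 1, 1))
}

new_atom_table <- function(id, element, x, y, z, affiliation) {
  tibble(
    id = as.character(id), element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    affiliation = as.character(affiliation)
  )
}

check_atom_table <- function(atoms, arg = "atoms") {
  need <- c("id", "element", "x", "y", "z", "affiliation")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(sprintf("`%s` lacks column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort(sprintf("`%s` has non-finite coordinates", arg))
  }
  if (!all(atoms$affiliation %in% c("protein", "ligand"))) {
    abort(sprintf("`%s` affiliation must be 'protein' or 'ligand'", arg))
  }
  if (anyDuplicated(atoms$id)) abort(sprintf("`%s` has duplicate atom ids", arg))
  invisible(atoms)
}

drop_hydrogens <- function(df) df[!(df$element %in% c("H", "D")), , drop = FALSE]

# resolve alternate locations: per (chain, resno, insert, resid, atom name)
# keep the highest-occupancy conformer, ties broken toward altloc "A"
resolve_altloc <- function(df) {
  key <- paste(df$chain, df$resno, df$insert, df$resid, df$elety, sep = "\r")
  occ <- ifelse(is.na(df$o), 1, df$o)
  alt <- ifelse(is.na(df$alt) | df$alt == "", "A", df$alt)
  ord <- order(key, -occ, alt)
  keep <- sort(ord[!duplicated(key[ord])]) # file order preserved
  df[keep, , drop = FALSE]
}

pdb_atom_tibble <- function(pdb_atom) {
  el <- pdb_atom$elesy
  if (is.null(el)) el <- NA_character_
  el <- ifelse(is.na(el) | trimws(el) == "",
    element_from_name(pdb_atom$elety), normalize_element(el)
  )
  tibble(
    chain = pdb_atom$chain %||% NA_character_,
    resno = pdb_atom$resno, insert = pdb_atom$insert %||% NA_character_,
    resid = pdb_atom$resid, elety = pdb_atom$elety,
    alt = pdb_atom$alt %||% NA_character_, o = pdb_atom$o %||% 1,
    type = pdb_atom$type,
    element = el, x = pdb_atom$x, y = pdb_atom$y, z = pdb_atom$z
  )
}

read_structure_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    # rm.alt = FALSE: alternate locations are resolved here by occupancy
    if (ext %in% c("cif", "mmcif")) {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
  )
  pdb_atom_tibble(pdb$atom)
}

pdb_atom_ids <- function(df) {
  sprintf(
    "%s/%s%s/%s", ifelse(is.na(df$chain), "_", df$chain), df$resid, df$resno,
    trimws(df$elety)
  )
}

# direct V2000 atom-block parse (counts line: atoms in cols 1-3; atom
# lines: x y z element). Deliberately ignores bonds, charges, properties.
read_sdf_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5) abort(sprintf("'%s' is too short to be an SDF", path))
  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  if (is.na(n_atoms) || n_atoms < 1 || length(lines) < 4 + n_atoms) {
    abort(sprintf("failed to parse '%s': bad V2000 counts line (line 4)", path))
  }
  at <- lines[5:(4 + n_atoms)]
  fields <- strsplit(trimws(at), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 4)
  if (length(bad) > 0) {
    abort(sprintf("failed to parse '%s': malformed atom record at line %d", path, 4 + bad[1]))
  }
  xyz <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  if (anyNA(xyz)) abort(sprintf("failed to parse '%s': non-numeric coordinates", path))
  el <- normalize_element(vapply(fields, `[[`, character(1), 4))
  tibble(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

read_mol2_atoms <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
    error = function(e) abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
  )
  at <- m$atom
  el <- normalize_element(gsub("\\..*$", "", at$elena))
  tibble(element = el, x = at$x, y = at$y, z = at$z)
}

#' Load a protein-ligand complex into an atom table
#'
#' Reads the protein from a PDB or mmCIF file and the ligand from an SDF,
#' MOL2 or PDB file — or from the protein file itself, selected by HETATM
#' residue name (and optionally chain). Only heavy atoms are kept:
#' hydrogens are dropped at parse time, waters (HOH/WAT/DOD) are excluded,
#' and on the protein side only ATOM records are used (so ions and
#' cofactors never leak in silently). Alternate locations keep the
#' highest-occupancy conformer, ties resolved toward altloc "A".
#'
#' @param protein_path PDB or mmCIF file with the protein.
#' @param ligand_path SDF, MOL2 or PDB file with the ligand, or `NULL` to
#'   select the ligand out of `protein_path` via `ligand_resname`.
#' @param ligand_resname,ligand_chain HETATM residue name (required when
#'   `ligand_path` is `NULL` or a PDB file with multiple residues) and
#'   optional chain used to pick the ligand out of a PDB file. Never
#'   inferred silently.
#' @return A tibble with one row per heavy atom and columns `id`,
#'   `element`, `x`, `y`, `z` (Angstrom) and `affiliation`
#'   (`"protein"`/`"ligand"`), protein atoms first, in file order.
#' @examples
#' cs <- make_square(9.75)
#' dplyr::count(cs, affiliation, element)
#' @export
load_complex <- function(protein_path, ligand_path = NULL,
                         ligand_resname = NULL, ligand_chain = NULL) {
  pdf <- read_structure_table(protein_path)
  pdf <- resolve_altloc(pdf)
  prot <- pdf[pdf$type == "ATOM" & !(pdf$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  prot_tbl <- new_atom_table(
    pdb_atom_ids(prot), prot$element, prot$x, prot$y, prot$z, "protein"
  )
  prot_tbl <- check_unique_suffix(drop_hydrogens_tbl(prot_tbl))

  if (is.null(ligand_path)) {
    if (is.null(ligand_resname)) {
      abort("supply `ligand_path` or `ligand_resname` to identify the ligand")
    }
    lig <- pdf[pdf$resid == ligand_resname, , drop = FALSE]
    if (!is.null(ligand_chain)) lig <- lig[lig$chain %in% ligand_chain, , drop = FALSE]
    lig_tbl <- new_atom_table(
      paste0("L:", pdb_atom_ids(lig)), lig$element, lig$x, lig$y, lig$z, "ligand"
    )
  } else {
    ext <- tolower(tools::file_ext(ligand_path))
    if (ext == "sdf") {
      la <- read_sdf_atoms(ligand_path)
      lig_tbl <- new_atom_table(
        sprintf("L:%s%d", la$element, seq_len(nrow(la))),
        la$element, la$x, la$y, la$z, "ligand"
      )
    } else if (ext == "mol2") {
      la <- read_mol2_atoms(ligand_path)
      lig_tbl <- new_atom_table(
        sprintf("L:%s%d", la$element, seq_len(nrow(la))),
        la$element, la$x, la$y, la$z, "ligand"
      )
    } else {
      ldf <- resolve_altloc(read_structure_table(ligand_path))
      ldf <- ldf[!(ldf$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
      if (!is.null(ligand_resname)) ldf <- ldf[ldf$resid == ligand_resname, , drop = FALSE]
      if (!is.null(ligand_chain)) ldf <- ldf[ldf$chain %in% ligand_chain, , drop = FALSE]
      lig_tbl <- new_atom_table(
        paste0("L:", pdb_atom_ids(ldf)), ldf$element, ldf$x, ldf$y, ldf$z, "ligand"
      )
    }
  }
  lig_tbl <- check_unique_suffix(drop_hydrogens_tbl(lig_tbl))

  if (nrow(prot_tbl) == 0) abort(sprintf("no protein heavy atoms parsed from '%s'", protein_path))
  if (nrow(lig_tbl) == 0) abort("no ligand heavy atoms parsed")
  out <- dplyr::bind_rows(prot_tbl, lig_tbl)
  check_atom_table(out)
  attr(out, "source") <- list(
    protein_path = protein_path, ligand_path = ligand_path,
    ligand_resname = ligand_resname, ligand_chain = ligand_chain
  )
  out
}

drop_hydrogens_tbl <- function(tbl) tbl[!(tbl$element %in% c("H", "D")), , drop = FALSE]

check_unique_suffix <- function(tbl) {
  if (anyDuplicated(tbl$id)) tbl$id <- make.unique(tbl$id, sep = "#")
  tbl
}

#' Restrict a complex to one element-pair point cloud
#'
#' Keeps the protein atoms of one element and the ligand atoms of another;
#' this is the point cloud on which one opposition-distance filtration is
#' computed. Either side may legitimately come back empty.
#'
#' @param atoms atom table (see [load_complex()]).
#' @param protein_element,ligand_element element symbols for the two sides.
#' @return A tibble of the matching atoms, file order preserved, with the
#'   subset recorded in attribute `"subset"`.
#' @export
extract_point_cloud <- function(atoms, protein_element, ligand_element) {
  check_atom_table(atoms)
  keep <- (atoms$affiliation == "protein" & atoms$element == protein_element) |
    (atoms$affiliation == "ligand" & atoms$element == ligand_element)
  out <- atoms[keep, , drop = FALSE]
  attr(out, "subset") <- c(
    protein_element = protein_element, ligand_element = ligand_element
  )
  out
}

#' Summarize and sanity-check a complex
#'
#' Report-only validation: per-element atom counts on each side, the
#' minimum interatomic distance, the bounding-box extent, and a clash flag
#' for any pair closer than `clash_floor`. A fixed positive lower bound on
#' interatomic distances is what makes the radius-truncation approximation
#' of the fingerprint provably accurate, so clashes are worth flagging.
#'
#' @param atoms atom table.
#' @param clash_floor distance (Angstrom) below which a pair counts as a
#'   clash.
#' @return A list with `counts` (tibble affiliation x element x n),
#'   `min_distance`, `bbox` (3x2 matrix), `n_clashes` and `clash`
#'   (logical).
#' @export
validate_complex <- function(atoms, clash_floor = 0.7) {
  check_atom_table(atoms)
  counts <- dplyr::count(
    as_tibble(atoms), .data$affiliation, .data$element,
    name = "n"
  )
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) >= 2) {
    dmat <- stats::dist(xyz)
    min_d <- min(dmat)
    n_clash <- sum(dmat < clash_floor)
  } else {
    min_d <- Inf
    n_clash <- 0L
  }
  list(
    counts = counts,
    min_distance = min_d,
    bbox = apply(xyz, 2, range),
    n_clashes = as.integer(n_clash),
    clash = n_clash > 0
  )
}
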