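# Synthetic complexes with analytically known persistence, random
# realistic-scale complexes, planted-response training tables, and
# plain-text structure-file fixtures. Everything is seed-deterministic.

#' Two-atom complex with known persistence
#'
#' One protein atom at the origin, one ligand atom at (d, 0, 0). Its
#' opposition-distance persistence is a single 0-dimensional death at `d`
#' and no 1-dimensional class.
#'
#' @param d separation, Angstrom (> 0).
#' @param elements length-2 character: protein and ligand element.
#' @return atom table; attribute `"expected_cv"` holds the known
#'   critical-value table.
#' @export
make_pair <- function(d, elements = c("C", "C")) {
  stopifnot(d > 0)
  out <- new_atom_table(
    c("P1", "L1"), elements, c(0, d), c(0, 0), c(0, 0),
    c("protein", "ligand")
  )
  attr(out, "expected_cv") <- tibble(dimension = c(0L), value = d)
  out
}

#' Four-atom square with one 1-dimensional class
#'
#' Protein atoms at (0,0,0) and (s,s,0), ligand atoms at (s,0,0) and
#' (0,s,0): all four cross distances equal s, so the filtration dies three
#' 0-dimensional classes at s and births one loop at s. Exercises the
#' 1-dimensional channel and equal-weight tie handling.
#'
#' @param scale side length s, Angstrom (> 0).
#' @param elements length-2 character: protein and ligand element.
#' @return atom table with attribute `"expected_cv"`.
#' @export
make_square <- function(scale, elements = c("C", "C")) {
  stopifnot(scale > 0)
  out <- new_atom_table(
    c("P1", "P2", "L1", "L2"), rep(elements, each = 2),
    c(0, scale, scale, 0), c(0, scale, 0, scale), c(0, 0, 0, 0),
    c("protein", "protein", "ligand", "ligand")
  )
  attr(out, "expected_cv") <- tibble(
    dimension = c(0L, 0L, 0L, 1L), value = rep(scale, 4)
  )
  out
}

#' 2x2 bipartite complex with four generic cross distances
#'
#' Two protein and two ligand atoms placed (in the plane) so the four
#' cross distances are exactly `weights`, with the largest closing the
#' cycle: deaths at the three smallest weights, one 1-dimensional birth at
#' the largest. Realizability requires the quadrilateral inequality; the
#' default \{1, 2, 3, 4\}-like set uses a trapezoid construction.
#'
#' @param weights four distinct positive cross distances; the construction
#'   places P1 at the origin, L1 on the x-axis at `weights[1]`, P2 on the
#'   x-axis so that |P2-L1| = `weights[2]`, and L2 above the axis with
#'   |P1-L2| = `weights[3]` and |P2-L2| as it falls (reported back).
#' @param elements length-2 character.
#' @return atom table with attribute `"expected_cv"` computed from the
#'   realized distances (sorted: three smallest are deaths, largest the
#'   birth).
#' @export
make_k22 <- function(weights = c(1, 2, 3), elements = c("C", "C")) {
  stopifnot(length(weights) >= 3, all(weights > 0))
  p1 <- c(0, 0, 0)
  l1 <- c(weights[1], 0, 0)
  p2 <- c(weights[1] + weights[2], 0, 0)
  # L2 off-axis: distance weights[3] from P1, elevated to keep genericity
  ang <- pi / 3
  l2 <- c(weights[3] * cos(ang), weights[3] * sin(ang), 0)
  out <- new_atom_table(
    c("P1", "P2", "L1", "L2"),
    rep(elements, each = 2),
    c(p1[1], p2[1], l1[1], l2[1]),
    c(p1[2], p2[2], l1[2], l2[2]),
    c(p1[3], p2[3], l1[3], l2[3]),
    c("protein", "protein", "ligand", "ligand")
  )
  d <- sort(c(
    weights[1], weights[2], weights[3],
    sqrt(sum((p2 - l2)^2))
  ))
  attr(out, "expected_cv") <- tibble(
    dimension = c(0L, 0L, 0L, 1L), value = d
  )
  out
}

sample_separated <- function(k, box, min_separation, origin = c(0, 0, 0),
                             existing = NULL, max_tries = 20000) {
  pts <- existing
  placed <- 0L
  tries <- 0L
  while (placed < k) {
    cand <- origin + runif(3, 0, box)
    ok <- is.null(pts) ||
      nrow(pts) == 0 ||
      min(sqrt(rowSums((t(t(pts) - cand))^2))) >= min_separation
    if (ok) {
      pts <- rbind(pts, cand)
      placed <- placed + 1L
    }
    tries <- tries + 1L
    if (tries > max_tries) abort("packing infeasible: raise box or lower min_separation")
  }
  pts[(nrow(pts) - k + 1):nrow(pts), , drop = FALSE]
}

#' Random protein-ligand complex with a minimum-separation floor
#'
#' Protein atoms are placed uniformly in a cubic box (rejection sampling
#' against a hard minimum separation, mimicking the fixed lower bound on
#' interatomic distances in real structures); ligand atoms go into a small
#' box at a configurable offset from the protein box center.
#'
#' @param n_protein,m_ligand atom counts.
#' @param element_frequencies named probabilities for element assignment
#'   on both sides (default a protein-like C/N/O/S mix).
#' @param box protein box edge, Angstrom; default scales with
#'   `n_protein` to keep packing comfortable.
#' @param min_separation hard floor on interatomic distances, Angstrom.
#' @param ligand_offset displacement of the ligand box from the protein
#'   box center (3-vector, Angstrom); 0 buries the ligand.
#' @param ligand_box ligand box edge, Angstrom.
#' @param seed mandatory seed.
#' @return atom table.
#' @export
make_random_complex <- function(n_protein = 50, m_ligand = 10,
                                element_frequencies = c(C = 0.62, N = 0.17, O = 0.18, S = 0.03),
                                box = NULL, min_separation = 1.0,
                                ligand_offset = c(0, 0, 0), ligand_box = 5,
                                seed = 1) {
  set.seed(seed)
  if (is.null(box)) box <- max(10, (n_protein * 18)^(1 / 3))
  prot <- sample_separated(n_protein, box, min_separation)
  center <- rep(box / 2, 3) + ligand_offset - ligand_box / 2
  lig <- sample_separated(m_ligand, ligand_box, min_separation,
    origin = center, existing = prot
  )
  el <- function(k) sample(names(element_frequencies), k,
    replace = TRUE, prob = element_frequencies
  )
  new_atom_table(
    c(sprintf("P%d", seq_len(n_protein)), sprintf("L%d", seq_len(m_ligand))),
    c(el(n_protein), el(m_ligand)),
    c(prot[, 1], lig[, 1]), c(prot[, 2], lig[, 2]), c(prot[, 3], lig[, 3]),
    rep(c("protein", "ligand"), c(n_protein, m_ligand))
  )
}

#' Synthetic training table with a planted tree response
#'
#' Features are uniform on [0, 1]; the response is a piecewise-constant
#' function of a few planted features plus Gaussian noise — exactly the
#' function class a shallow tree ensemble represents, so recovery is
#' checkable.
#'
#' @param n_rows rows.
#' @param n_features total feature columns (named `f1..fn` unless
#'   `feature_names` is given).
#' @param planted list describing the response; default a 2-split rule:
#'   `y = 1` when `f1 > 0.5` and `f2 > 0.5`, else 0. Supply
#'   `list(features=, thresholds=, values=)` where `values` has one entry
#'   per cell of the threshold box (all-pass cell last), or a function of
#'   the feature tibble.
#' @param noise_sd Gaussian noise standard deviation.
#' @param feature_names optional explicit column names.
#' @param seed mandatory seed.
#' @return tibble: `complex_id`, feature columns, `label`; the planted
#'   generator is stored in attribute `"planted"`.
#' @export
make_training_table <- function(n_rows = 500, n_features = 10,
                                planted = NULL, noise_sd = 0,
                                feature_names = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(feature_names)) feature_names <- sprintf("f%d", seq_len(n_features))
  n_features <- length(feature_names)
  X <- matrix(runif(n_rows * n_features), nrow = n_rows)
  colnames(X) <- feature_names
  Xt <- as_tibble(X)
  if (is.null(planted)) {
    planted <- list(
      features = feature_names[1:2], thresholds = c(0.5, 0.5), value = 1
    )
  }
  y0 <- if (is.function(planted)) {
    planted(Xt)
  } else {
    ind <- rep(TRUE, n_rows)
    for (k in seq_along(planted$features)) {
      ind <- ind & (Xt[[planted$features[k]]] > planted$thresholds[k])
    }
    ifelse(ind, planted$value, 0)
  }
  out <- dplyr::bind_cols(
    tibble(complex_id = sprintf("syn%04d", seq_len(n_rows))),
    Xt,
    tibble(label = y0 + rnorm(n_rows, sd = noise_sd))
  )
  attr(out, "planted") <- planted
  out
}

#' Synthetic binder/decoy screening set
#'
#' Generates labeled complexes for the discrimination benchmark: binders
#' have the ligand buried at the protein box center (many carbon-carbon
#' cross pairs in the 4-10 Angstrom shell), decoys have it displaced to
#' the box edge (sparse contacts). Both get 15-Angstrom-truncated
#' discretized IPC stacks.
#'
#' @param n_complexes total count (half binders, half decoys).
#' @param n_protein,m_ligand atom counts per complex.
#' @param decoy_offset displacement (Angstrom) applied to decoy ligands.
#' @param cutoff_radius truncation radius before stacking.
#' @param grid,sigma passed to [ipc_stack()].
#' @param subsets element pairs for the stack (defaults to the 36
#'   standard subsets).
#' @param seed mandatory seed.
#' @return wide tibble: `complex_id`, `label` (1 binder / 0 decoy), one
#'   column per stack feature.
#' @export
make_screening_set <- function(n_complexes = 100, n_protein = 40, m_ligand = 8,
                               decoy_offset = 14, cutoff_radius = 15,
                               grid = bin_grid(), sigma = 0.1,
                               subsets = element_pair_subsets(), seed = 1) {
  # alternate binder/decoy so contiguous train/test splits stay balanced
  labels <- rep_len(c(1, 0), n_complexes)
  purrr::map2_dfr(seq_len(n_complexes), labels, function(i, lab) {
    off <- if (lab == 1) c(0, 0, 0) else c(decoy_offset, 0, 0)
    cs <- make_random_complex(
      n_protein = n_protein, m_ligand = m_ligand,
      ligand_offset = off, seed = seed * 100000L + i
    )
    stk <- ipc_stack(truncate_complex(cs, cutoff_radius),
      subsets = subsets, grid = grid, sigma = sigma
    )
    dplyr::bind_cols(
      tibble(complex_id = sprintf("scr%04d", i), label = lab),
      stack_row(stk)[-1]
    )
  })
}

#' Write a complex out as plain-text structure files
#'
#' Emits a minimal valid PDB for the protein side and an SDF (V2000) for
#' the ligand side; [load_complex()] on the outputs reproduces the complex
#' to PDB coordinate precision (1e-3 Angstrom).
#'
#' @param atoms atom table.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named character vector with elements `protein` and `ligand`.
#' @export
write_fixture_files <- function(atoms, dir = tempdir(), name = "fixture") {
  check_atom_table(atoms)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prot <- atoms[atoms$affiliation == "protein", , drop = FALSE]
  lig <- atoms[atoms$affiliation == "ligand", , drop = FALSE]
  ppath <- file.path(dir, paste0(name, "_protein.pdb"))
  lpath <- file.path(dir, paste0(name, "_ligand.sdf"))
  writeLines(c(pdb_lines(prot), "END"), ppath)
  writeLines(sdf_lines(lig, name), lpath)
  c(protein = ppath, ligand = lpath)
}

pdb_lines <- function(tbl, record = "ATOM", resid = "GLY", altloc = " ",
                      occupancy = 1.00) {
  # one residue per atom keeps atom names unique within a residue
  sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, seq_len(nrow(tbl)),
    sprintf("%s%d", toupper(tbl$element), seq_len(nrow(tbl))), altloc,
    resid, "A", seq_len(nrow(tbl)),
    tbl$x, tbl$y, tbl$z, occupancy, 0.0, toupper(tbl$element)
  )
}

sdf_lines <- function(tbl, name = "LIG") {
  n <- nrow(tbl)
  c(
    name, "  topobind", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      tbl$x, tbl$y, tbl$z, tbl$element
    ),
    "M  END", "$$$$"
  )
}
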