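test_that("fixture structures round-trip through PDB + SDF files", {
  cs <- make_random_complex(
    n_protein = 20, m_ligand = 5,
    element_frequencies = c(C = 0.5, N = 0.2, O = 0.2, S = 0.1), seed = 6
  )
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(cs, dir, "rt")
  back <- load_complex(paths[["protein"]], paths[["ligand"]])
  expect_equal(nrow(back), nrow(cs))
  expect_equal(back$element, cs$element)
  expect_equal(back$affiliation, cs$affiliation)
  expect_equal(back$x, cs$x, tolerance = 1e-3)
  expect_equal(back$y, cs$y, tolerance = 1e-3)
  expect_equal(back$z, cs$z, tolerance = 1e-3)

  # writing the re-parsed complex again reproduces it exactly
  paths2 <- write_fixture_files(back, dir, "rt2")
  again <- load_complex(paths2[["protein"]], paths2[["ligand"]])
  expect_equal(again$x, back$x)
  expect_equal(again$element, back$element)
})

test_that("two-letter elements survive the SDF round trip", {
  cs <- make_pair(5, elements = c("C", "Cl"))
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(cs, dir, "cl")
  back <- load_complex(paths[["protein"]], paths[["ligand"]])
  expect_equal(back$element[back$affiliation == "ligand"], "Cl")
})

test_that("alternate locations collapse to one conformer (occupancy, then altloc A)", {
  dir <- withr::local_tempdir()
  ppath <- file.path(dir, "alt.pdb")
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, "ATOM", 1, "CA", "A", "GLY", "A", 1, 0, 0, 0, 0.4, 0, "C"),
    sprintf(fmt, "ATOM", 2, "CA", "B", "GLY", "A", 1, 5, 0, 0, 0.6, 0, "C"),
    sprintf(fmt, "ATOM", 3, "N", "A", "GLY", "A", 1, 1, 1, 0, 0.5, 0, "N"),
    sprintf(fmt, "ATOM", 4, "N", "B", "GLY", "A", 1, 2, 2, 0, 0.5, 0, "N"),
    "END"
  ), ppath)
  lpath <- file.path(dir, "lig.sdf")
  writeLines(topobind:::sdf_lines(make_pair(3)[2, ], "LIG"), lpath)
  cs <- load_complex(ppath, lpath)
  prot <- cs[cs$affiliation == "protein", ]
  expect_equal(nrow(prot), 2) # one CA, one N
  expect_equal(prot$x[prot$element == "C"], 5) # higher occupancy wins
  expect_equal(prot$x[prot$element == "N"], 1) # tie resolved toward altloc A
})

test_that("waters and hydrogens never reach the atom table; empty sides error", {
  dir <- withr::local_tempdir()
  ppath <- file.path(dir, "wat.pdb")
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    sprintf(fmt, "ATOM", 1, "CA", " ", "GLY", "A", 1, 0, 0, 0, 1, 0, "C"),
    sprintf(fmt, "ATOM", 2, "HA", " ", "GLY", "A", 1, 1, 0, 0, 1, 0, "H"),
    sprintf(fmt, "HETATM", 3, "O", " ", "HOH", "A", 2, 9, 9, 9, 1, 0, "O"),
    sprintf(fmt, "HETATM", 4, "C1", " ", "LIG", "B", 1, 3, 0, 0, 1, 0, "C"),
    "END"
  ), ppath)
  cs <- load_complex(ppath, ligand_resname = "LIG")
  expect_equal(nrow(cs), 2)
  expect_false(any(cs$element == "H"))
  expect_false(any(grepl("HOH", cs$id)))
  expect_equal(cs$affiliation, c("protein", "ligand"))

  expect_error(load_complex(ppath, ligand_resname = "XYZ"), "ligand")
  expect_error(load_complex(file.path(dir, "nope.pdb"), ppath), "parse")
  expect_error(load_complex(ppath), "ligand_resname|ligand_path")
})

test_that("point-cloud extraction filters by element and preserves order", {
  cs <- topobind:::new_atom_table(
    c("P1", "P2", "P3", "P4", "L1", "L2"),
    c("C", "C", "N", "O", "C", "S"),
    1:6, 0, 0, rep(c("protein", "ligand"), c(4, 2))
  )
  cc <- extract_point_cloud(cs, "C", "C")
  expect_equal(cc$id, c("P1", "P2", "L1"))
  sc <- extract_point_cloud(cs, "S", "C")
  expect_equal(sum(sc$affiliation == "protein"), 0)
  expect_equal(sum(sc$affiliation == "ligand"), 1)
  # idempotent
  expect_identical(extract_point_cloud(cc, "C", "C")$id, cc$id)
})

test_that("each atom appears in exactly as many subset clouds as name its element", {
  cs <- make_random_complex(n_protein = 30, m_ligand = 8, seed = 14)
  subsets <- element_pair_subsets()
  appearances <- integer(nrow(cs))
  for (s in seq_len(nrow(subsets))) {
    cl <- extract_point_cloud(cs, subsets$protein_element[s], subsets$ligand_element[s])
    appearances <- appearances + cs$id %in% cl$id
  }
  expected <- ifelse(
    cs$affiliation == "protein",
    vapply(cs$element, function(e) sum(subsets$protein_element == e), 1L),
    vapply(cs$element, function(e) sum(subsets$ligand_element == e), 1L)
  )
  expect_equal(appearances, unname(expected))
})

test_that("validation reports counts, min distance and clashes", {
  cs <- topobind:::new_atom_table(
    c(sprintf("P%d", 1:7), "L1", "L2"),
    c(rep("C", 5), "N", "N", "N", "N"),
    c(0, 2, 4, 6, 8, 10, 12, 0.3, 20), 0, 0,
    rep(c("protein", "ligand"), c(7, 2))
  )
  rep_ <- validate_complex(cs, clash_floor = 0.7)
  expect_equal(rep_$counts$n[rep_$counts$affiliation == "protein" & rep_$counts$element == "C"], 5L)
  expect_equal(rep_$counts$n[rep_$counts$affiliation == "ligand" & rep_$counts$element == "N"], 2L)
  expect_true(rep_$clash)
  # brute-force min distance
  xyz <- as.matrix(cs[, c("x", "y", "z")])
  brute <- min(dist(xyz))
  expect_equal(rep_$min_distance, brute)
  expect_equal(rep_$min_distance, 0.3)
})
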