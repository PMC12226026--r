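erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

test_that("the default feature specification has the canonical 10 rows", {
  sp <- default_feature_specs()
  expect_equal(nrow(sp), 10)
  expect_equal(
    unlist(sp[1, c("protein_element", "ligand_element")], use.names = FALSE),
    c("C", "C")
  )
  expect_equal(sp$dimension[1], 1L)
  expect_equal(sp$bin_lo[1], 9.5)
  expect_equal(sp$bin_hi[1], 10.0)
  expect_equal(sum(sp$dimension == 1), 6)
  expect_equal(sum(sp$dimension == 0), 4)
  expect_equal(sp$bin_hi - sp$bin_lo, rep(0.5, 10))
  expect_equal(max(sp$bin_hi), 10.5)
})

test_that("a lone atom pair has a zero fingerprint (no loops, no in-spec contacts)", {
  cs <- make_pair(9.75, elements = c("C", "C"))
  fp <- compute_fingerprint(cs)
  expect_equal(fp$value, rep(0, 10), tolerance = 1e-12)
  # a (C,N) pair at 9.75 is also outside every 0D spec bin
  fp2 <- compute_fingerprint(make_pair(9.75, elements = c("C", "N")))
  expect_lt(max(fp2$value), 1e-12)
  # but an in-bin contact registers: (C,N) at 8.75 hits the [8.5,9) spec
  fp3 <- compute_fingerprint(make_pair(8.75, elements = c("C", "N")))
  expect_equal(fp3$value[fp3$feature == "C_N_0_8.5_9"], erf(2.5 / sqrt(2)),
    tolerance = 1e-9
  )
  expect_equal(sum(fp3$value > 1e-6), 1)
})

test_that("a carbon square places one loop's mass in the matching bin", {
  fp <- compute_fingerprint(make_square(9.75))
  expect_equal(fp$value[1], erf(2.5 / sqrt(2)) , tolerance = 1e-3)
  expect_lt(max(fp$value[3:10]), 1e-6)

  fp4 <- compute_fingerprint(make_square(4.25))
  expect_equal(fp4$value[fp4$feature == "C_C_1_4_4.5"], erf(2.5 / sqrt(2)),
    tolerance = 1e-3
  )
  expect_lt(fp4$value[1], 1e-6)
})

test_that("fingerprints are rigid-motion invariant and Lipschitz-stable end to end", {
  cs <- make_random_complex(n_protein = 60, m_ligand = 10, seed = 8)
  fp <- compute_fingerprint(cs)
  fp_rot <- compute_fingerprint(apply_rigid_motion(cs, seed = 31))
  expect_equal(fp_rot$value, fp$value, tolerance = 1e-9)

  for (delta in c(0.01, 0.05)) {
    pert <- perturb_atoms(cs, delta, seed = 17)
    fp_p <- compute_fingerprint(pert)
    # each critical value moves <= 2*delta; one value's bin mass can change
    # by at most 2*delta*sup(gaussian) and a channel has at most p*q values
    cvs <- lapply(split(fp$value, seq_len(10)), identity)
    bound <- vapply(seq_len(10), function(i) {
      sp <- default_feature_specs()[i, ]
      cl <- extract_point_cloud(cs, sp$protein_element, sp$ligand_element)
      p <- sum(cl$affiliation == "protein")
      q <- sum(cl$affiliation == "ligand")
      max(p * q, 1) * 2 * delta * dnorm(0, 0, 0.1)
    }, numeric(1))
    expect_true(all(abs(fp_p$value - fp$value) <= bound + 1e-9))
  }
})

test_that("an empty side yields an all-zero fingerprint with a warning, not an error", {
  cs <- make_pair(5)
  lig_only <- cs[cs$affiliation == "ligand", ]
  expect_warning(fp <- compute_fingerprint(lig_only), "empty side")
  expect_equal(fp$value, rep(0, 10))
})

test_that("truncation keeps exactly the protein atoms near the ligand", {
  cs <- make_random_complex(n_protein = 80, m_ligand = 10, box = 30, seed = 12)
  cut <- truncate_complex(cs, 12)
  # brute-force min-distance filter
  lig <- cs[cs$affiliation == "ligand", ]
  keep_brute <- vapply(seq_len(nrow(cs)), function(i) {
    if (cs$affiliation[i] == "ligand") {
      return(TRUE)
    }
    min(sqrt((lig$x - cs$x[i])^2 + (lig$y - cs$y[i])^2 + (lig$z - cs$z[i])^2)) <= 12
  }, logical(1))
  expect_identical(cut$id, cs$id[keep_brute])

  expect_identical(truncate_complex(cs, 1e4)$id, cs$id)

  far <- dplyr::bind_rows(
    make_pair(5),
    topobind:::new_atom_table("Pfar", "C", 25, 0, 0, "protein")
  )
  expect_false("Pfar" %in% truncate_complex(far, 15)$id)
})

test_that("the truncated fingerprint matches the exact one within the tail bound", {
  cs <- make_random_complex(n_protein = 150, m_ligand = 12, box = 40, seed = 19)
  exact <- compute_fingerprint(cs)
  approx <- compute_fingerprint_approx(cs, cutoff_radius = 15)
  expect_lt(max(abs(approx$value - exact$value)), 1e-6)
  expect_lt(max(abs(approx$value - exact$value)), attr(approx, "error_bound") + 1e-12)

  # a complex already inside the cutoff is reproduced identically
  small <- make_random_complex(n_protein = 30, m_ligand = 5, seed = 23)
  expect_equal(
    compute_fingerprint_approx(small, cutoff_radius = 15)$value,
    compute_fingerprint(small)$value
  )

  expect_error(compute_fingerprint_approx(cs, cutoff_radius = 9), "bin edge")
})

test_that("attribution splits each class's bin mass across its critical edge", {
  # one pair, one 0D class: each endpoint gets exactly half
  cs <- make_pair(8.75, elements = c("C", "N"))
  specs <- default_feature_specs()
  att <- attribute_feature(cs, specs, feature_index = 8) # C_N_0_[8.5,9)
  expect_equal(nrow(att), 2)
  expect_equal(att$contribution[1], att$contribution[2])
  expect_equal(sum(att$contribution), attr(att, "feature_value"))

  # the square's loop: by symmetry all four atoms share equally
  sq <- make_square(9.75)
  att1 <- attribute_feature(sq, specs, feature_index = 1)
  expect_equal(length(unique(round(att1$contribution, 12))), 1)
  expect_equal(sum(att1$contribution), attr(att1, "feature_value"), tolerance = 1e-12)

  # conservation on random fixtures, every feature
  cs2 <- make_random_complex(n_protein = 50, m_ligand = 10, seed = 29)
  fp <- compute_fingerprint(cs2)
  for (i in seq_len(10)) {
    atti <- attribute_feature(cs2, specs, feature_index = i)
    expect_equal(sum(atti$contribution), fp$value[i], tolerance = 1e-9)
  }
})

test_that("attribution paints into PDB B-factors", {
  sq <- make_square(9.75)
  att <- attribute_feature(sq, feature_index = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_attribution_pdb(sq, att, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^(ATOM|HETATM)", lines)), 4)
  b <- as.numeric(substr(grep("^(ATOM|HETATM)", lines, value = TRUE), 61, 66))
  expect_equal(b, rep(round(att$contribution[1] * 100, 2), 4))
})
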