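test_that("heavy atoms are counted excluding hydrogens", {
  expect_equal(count_heavy_atoms(mol_benzene()), 6)
  expect_equal(count_heavy_atoms(mol_ethanol()), 3)
  expect_equal(count_heavy_atoms(mol_acetic_acid()), 4)
  expect_equal(count_heavy_atoms(mol_acetic_acid(deprotonated = TRUE)), 4)
})

test_that("rotatable bonds follow the documented definition", {
  expect_equal(count_rotatable_bonds(mol_nbutane()), 1)
  expect_equal(count_rotatable_bonds(mol_benzene()), 0)
  # ethanol: the C-O bond ends at a terminal heavy atom, so no rotor
  expect_equal(count_rotatable_bonds(mol_ethanol()), 0)

  # N-methylacetamide: the C-N amide bond is excluded, all else terminal
  nma <- pb_mol("nma",
    tibble::tibble(elem = c("C", "C", "O", "N", "C"),
                   x = c(0, 1.5, 2.1, 2.2, 3.6), y = c(0, 0, 1.2, -1.2, -1.3),
                   z = 0, charge = 0L),
    tibble::tibble(a1 = c(1, 2, 2, 4), a2 = c(2, 3, 4, 5),
                   order = c(1L, 2L, 1L, 1L)))
  expect_equal(count_rotatable_bonds(nma), 0)

  # a 16-carbon chain has 13 qualifying bonds under the stated rule;
  # cross-check by brute-force enumeration against the definition
  chain <- mol_chain(16)
  g_deg <- c(1, rep(2, 14), 1)
  brute <- 0
  for (i in 1:15) if (g_deg[i] >= 2 && g_deg[i + 1] >= 2) brute <- brute + 1
  expect_equal(brute, 13)
  expect_equal(count_rotatable_bonds(chain), 13)
})

test_that("protonation differences are detected through graph mapping", {
  acid <- mol_acetic_acid()
  ba <- mol_acetic_acid(deprotonated = TRUE)
  res <- detect_protonation_difference(acid, ba)
  expect_true(res$valid)
  expect_true(res$differs)
  # the differing atom is an oxygen
  expect_true(all(res$detail$elem[res$detail$differs] == "O"))

  same <- detect_protonation_difference(acid, mol_acetic_acid())
  expect_true(same$valid)
  expect_false(same$differs)

  # non-isomorphic skeletons flag the pair invalid
  bad <- detect_protonation_difference(acid, mol_ethanol())
  expect_false(bad$valid)

  # symmetry in the arguments
  expect_equal(detect_protonation_difference(ba, acid)$differs, res$differs)
})

test_that("tautomer pairs are separated from protomer pairs", {
  lactam <- mol_pyridinone(lactam = TRUE)
  hydroxy <- mol_pyridinone(lactam = FALSE)
  res <- detect_tautomer_difference(lactam, hydroxy)
  expect_true(res$valid)
  expect_true(res$differs)
  expect_true(detect_tautomer_difference(hydroxy, lactam)$differs)

  expect_false(detect_tautomer_difference(lactam, mol_pyridinone())$differs)

  # a pure protomer pair is never reported as a tautomer pair:
  # formula differs (one H), so the pair is invalid for tautomer typing
  acid <- mol_acetic_acid(); ba <- mol_acetic_acid(deprotonated = TRUE)
  tt <- detect_tautomer_difference(acid, ba)
  expect_false(isTRUE(tt$differs))
  # and the tautomer pair is not reported as a protomer pair
  expect_false(detect_protonation_difference(lactam, hydroxy)$differs)
})

test_that("ring conformation changes are measured by circular torsions", {
  planar <- mol_cyclopentane(apex_z = 0)
  envelope <- mol_cyclopentane(apex_z = 0.8)
  same <- detect_ring_conformation_difference(planar, mol_cyclopentane())
  expect_false(same$differs)

  diff <- detect_ring_conformation_difference(planar, envelope,
                                              torsion_threshold_deg = 30)
  expect_true(diff$differs)
  expect_gt(diff$detail, 30)
  # threshold above the deviation: no longer flagged
  lax <- detect_ring_conformation_difference(planar, envelope,
                                             torsion_threshold_deg = 90)
  expect_false(lax$differs)

  # exocyclic-only change: chain moves, ring torsions identical
  with_chain <- function(chain_y) {
    atoms <- dplyr::bind_rows(
      mol_cyclopentane()$atoms,
      tibble::tibble(elem = c("C", "C", "C"),
                     x = c(3.0, 4.3, 5.6), y = chain_y, z = c(0, 0.4, 1.0),
                     charge = 0L))
    bonds <- dplyr::bind_rows(
      mol_cyclopentane()$bonds,
      tibble::tibble(a1 = c(2L, 6L, 7L), a2 = c(6L, 7L, 8L), order = 1L))
    pb_mol("cp_chain", atoms, bonds)
  }
  exo <- detect_ring_conformation_difference(with_chain(c(0, 0.5, 0.2)),
                                             with_chain(c(0.9, 1.8, 2.9)))
  expect_false(exo$differs)

  flat2d <- pb_mol("flat", tibble::tibble(
    elem = rep("C", 5), x = 0, y = 0, z = 0, charge = 0L),
    tibble::tibble(a1 = 1:5, a2 = c(2:5, 1), order = 1L))
  expect_error(detect_ring_conformation_difference(flat2d, flat2d),
               "coordinates")
})

test_that("symmetry-aware RMSD is invariant to rigid motion and relabeling", {
  bench <- small_paired_benchmark()
  mols <- benchmark_molecules(bench, ids = bench$truth$molecule_id[1:4])
  for (i in 1:4) {
    m1 <- mols$first[[i]]
    moved <- procbench:::rigid_motion(m1, angles = c(0.4, 1.2, 2.2),
                                      translation = c(3, -2, 7))
    expect_lt(symmetry_aware_rmsd(m1, moved), 1e-6)
  }

  # benzene relabeled by a ring rotation: identity mapping is wrong,
  # automorphism minimization recovers zero (in place, no superposition)
  bz <- mol_benzene()
  rot <- bz
  perm <- c(2, 3, 4, 5, 6, 1)
  rot$atoms <- rot$atoms[perm, ]
  inv <- match(seq_len(6), perm)
  rot$bonds$a1 <- inv[rot$bonds$a1]
  rot$bonds$a2 <- inv[rot$bonds$a2]
  naive <- sqrt(mean(rowSums((as.matrix(bz$atoms[, c("x", "y", "z")]) -
                                as.matrix(rot$atoms[, c("x", "y", "z")]))^2)))
  expect_gt(naive, 0.1)
  expect_lt(symmetry_aware_rmsd(bz, rot, superimpose = FALSE), 1e-9)

  # minimized value never exceeds the identity mapping
  m1 <- mols$first[[2]]; m2 <- mols$second[[2]]
  ident <- procbench:::mapped_rmsd(procbench:::heavy_coords(m1),
                                   procbench:::heavy_coords(m2), TRUE)
  expect_lte(symmetry_aware_rmsd(m1, m2), ident + 1e-12)

  expect_error(symmetry_aware_rmsd(mol_benzene(), mol_ethanol()),
               "not isomorphic")
})

test_that("superposed RMSD matches an independent quaternion oracle", {
  # asymmetric 3-atom toy with printed coordinates
  t1 <- pb_mol("t1", tibble::tibble(
    elem = c("C", "N", "O"), x = c(0, 1, 0), y = c(0, 0, 1), z = 0,
    charge = 0L), tibble::tibble(a1 = c(1, 1), a2 = c(2, 3), order = 1L))
  t2 <- pb_mol("t2", tibble::tibble(
    elem = c("C", "N", "O"), x = c(0, 1, 0), y = c(0, 0, -1), z = 0,
    charge = 0L), tibble::tibble(a1 = c(1, 1), a2 = c(2, 3), order = 1L))
  expected <- oracle_superposed_rmsd(
    matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
    matrix(c(0, 0, 0, 1, 0, 0, 0, -1, 0), 3, byrow = TRUE))
  expect_equal(symmetry_aware_rmsd(t1, t2), expected, tolerance = 1e-8)
  # the planar flip is a 180-degree rotation about x: both routes find 0
  expect_lt(expected, 1e-8)

  # larger random pair, no symmetry: package vs oracle
  set.seed(41)
  n <- 8
  xyz1 <- matrix(stats::rnorm(3 * n), n, 3)
  xyz2 <- xyz1 + 0.3 * matrix(stats::rnorm(3 * n), n, 3)
  mk <- function(xyz) pb_mol("r", tibble::tibble(
    elem = c("C", "N", "O", "S", "P", "F", "Cl", "Br"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = 0L),
    tibble::tibble(a1 = 1:7, a2 = 2:8, order = 1L))
  expect_equal(symmetry_aware_rmsd(mk(xyz1), mk(xyz2)),
               oracle_superposed_rmsd(xyz1, xyz2), tolerance = 1e-8)
})

test_that("tautomer keys are invariant under atom reordering", {
  m <- mol_pyridinone(lactam = TRUE)
  key1 <- mol_descriptor(m)$tautomer_key
  perm <- c(3, 1, 2, 6, 5, 4, 7, 8)
  m2 <- m
  m2$atoms <- m2$atoms[perm, ]
  inv <- match(seq_along(perm), perm)
  m2$bonds$a1 <- inv[m2$bonds$a1]
  m2$bonds$a2 <- inv[m2$bonds$a2]
  expect_identical(mol_descriptor(m2)$tautomer_key, key1)
  # the two tautomers have different keys
  expect_false(identical(
    mol_descriptor(mol_pyridinone(lactam = FALSE))$tautomer_key, key1))
})

test_that("property correlation handles planted slopes and degenerate input", {
  expect_equal(correlate_property(1:10, 2 * (1:10) + 3), 1)
  flat <- correlate_property(1:10, rep(5, 10))
  expect_true(is.na(flat))
  expect_true(attr(flat, "undefined"))

  set.seed(43)
  x <- stats::rnorm(50)
  y <- 2 * x + stats::rnorm(50, 0, 0.5)
  # direct formula oracle
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_property(y, x), r^2, tolerance = 1e-12)
})

test_that("SD files round-trip molecules with charges and coordinates", {
  mols <- list(mol_acetic_acid("m1"), mol_acetic_acid("m2", TRUE),
               mol_pyridinone("m3"))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_mols_sdf(mols, path)
  back <- read_mols_sdf(path)
  expect_equal(names(back), c("m1", "m2", "m3"))
  expect_equal(back$m2$atoms$charge, c(0L, 0L, 0L, -1L))
  expect_equal(back$m1$atoms$elem, mols[[1]]$atoms$elem)
  expect_equal(back$m1$atoms$x, mols[[1]]$atoms$x, tolerance = 1e-4)
  expect_equal(back$m3$bonds$order, mols[[3]]$bonds$order)
})

test_that("paired SD reading reports unmatched ids instead of dropping them", {
  a <- list(mol_acetic_acid("m1"), mol_acetic_acid("m2"),
            mol_pyridinone("m3"), mol_benzene("m4"))
  b <- list(mol_acetic_acid("m1", TRUE), mol_acetic_acid("m2"),
            mol_pyridinone("m3", lactam = FALSE))
  pa <- withr::local_tempfile(fileext = ".sdf")
  pb <- withr::local_tempfile(fileext = ".sdf")
  write_mols_sdf(a, pa)
  write_mols_sdf(b, pb)
  paired <- read_paired_sdf(pa, pb)
  expect_equal(nrow(paired$pairs), 3)
  expect_equal(paired$unmatched_first, "m4")
  expect_equal(paired$unmatched_second, character(0))

  aud <- audit_prep_pairs(paired)
  expect_equal(aud$differs_protonation, c(TRUE, FALSE, FALSE))
  expect_equal(aud$differs_tautomer, c(FALSE, FALSE, TRUE))
})
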