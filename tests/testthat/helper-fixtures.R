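# shared fixtures and independent oracles for the test suite

tiny_table <- function(scores_active = c(12, 8), scores_decoy = 11:2) {
  score_table(
    tibble::tibble(
      molecule_id = c(sprintf("a%d", seq_along(scores_active)),
                      sprintf("d%02d", seq_along(scores_decoy))),
      role = rep(c("bioactive", "decoy"),
                 c(length(scores_active), length(scores_decoy))),
      score = c(scores_active, scores_decoy)
    ),
    orientation = "higher_is_better"
  )
}

random_table <- function(n_a, n_d, seed = NULL, orientation = "higher_is_better") {
  if (!is.null(seed)) set.seed(seed)
  score_table(
    tibble::tibble(
      molecule_id = sprintf("m%05d", seq_len(n_a + n_d)),
      role = rep(c("bioactive", "decoy"), c(n_a, n_d)),
      score = stats::runif(n_a + n_d)
    ),
    orientation = orientation
  )
}

# independent brute-force pROC-AUC oracle: walk the score-sorted list and
# count, for each bioactive, the decoys strictly above it (+ half of exact
# ties), floor at 1/N_d, average log10(1/f). Written against the definition,
# not against the package implementation.
oracle_proc_auc <- function(roles, scores, higher_is_better = TRUE) {
  s <- if (higher_is_better) scores else -scores
  n_d <- sum(roles == "decoy")
  f <- vapply(which(roles == "bioactive"), function(i) {
    above <- 0
    for (j in which(roles == "decoy")) {
      if (s[j] > s[i]) above <- above + 1
      if (s[j] == s[i]) above <- above + 0.5
    }
    max(above / n_d, 1 / n_d)
  }, numeric(1))
  mean(log10(1 / f))
}

# independent rigid-body superposition oracle (Horn's quaternion method,
# a different algorithm from the SVD route used in the package)
oracle_superposed_rmsd <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  m <- t(y0) %*% x0
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(n4, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  r <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)
  ), 3, 3, byrow = TRUE)
  yr <- y0 %*% t(r)
  sqrt(mean(rowSums((x0 - yr)^2)))
}

# small hand-built molecules ------------------------------------------------

mol_benzene <- function(id = "benzene", kekule_offset = 0) {
  th <- 2 * pi * (0:5) / 6
  atoms <- tibble::tibble(elem = rep("C", 6),
                          x = 1.4 * cos(th), y = 1.4 * sin(th), z = 0,
                          charge = 0L)
  orders <- rep(c(2L, 1L), 3)
  if (kekule_offset == 1) orders <- rep(c(1L, 2L), 3)
  bonds <- tibble::tibble(a1 = 1:6, a2 = c(2:6, 1), order = orders)
  pb_mol(id, atoms, bonds)
}

mol_ethanol <- function(id = "ethanol") {
  pb_mol(id,
         tibble::tibble(elem = c("C", "C", "O", "H"),
                        x = c(0, 1.5, 2.2, 3.1), y = c(0, 0, 1.1, 1.0),
                        z = 0, charge = 0L),
         tibble::tibble(a1 = c(1, 2, 3), a2 = c(2, 3, 4), order = 1L))
}

mol_nbutane <- function(id = "nbutane") {
  pb_mol(id,
         tibble::tibble(elem = rep("C", 4),
                        x = c(0, 1.3, 2.6, 3.9), y = c(0, 0.7, 0, 0.7),
                        z = 0, charge = 0L),
         tibble::tibble(a1 = 1:3, a2 = 2:4, order = 1L))
}

# straight chain of n carbons
mol_chain <- function(n, id = paste0("chain", n)) {
  pb_mol(id,
         tibble::tibble(elem = rep("C", n),
                        x = 1.3 * seq_len(n), y = 0.7 * (seq_len(n) %% 2),
                        z = 0, charge = 0L),
         tibble::tibble(a1 = seq_len(n - 1), a2 = 2:n, order = 1L))
}

mol_acetic_acid <- function(id = "hoac", deprotonated = FALSE) {
  atoms <- tibble::tibble(
    elem = c("C", "C", "O", "O"),
    x = c(0, 1.5, 2.1, 2.2), y = c(0, 0, 1.1, -1.15), z = 0,
    charge = c(0L, 0L, 0L, if (deprotonated) -1L else 0L)
  )
  bonds <- tibble::tibble(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                          order = c(1L, 2L, 1L))
  if (!deprotonated) {
    atoms <- tibble::add_row(atoms, elem = "H", x = 3.16, y = -1.09, z = 0,
                             charge = 0L)
    bonds <- tibble::add_row(bonds, a1 = 4L, a2 = 5L, order = 1L)
  }
  pb_mol(id, atoms, bonds)
}

# 2-pyridinone (lactam = TRUE) or 2-hydroxypyridine tautomer
mol_pyridinone <- function(id = "pyridinone", lactam = TRUE) {
  th <- 2 * pi * (0:5) / 6
  atoms <- tibble::tibble(
    elem = c("N", rep("C", 5)),
    x = 1.4 * cos(th), y = 1.4 * sin(th), z = 0, charge = 0L
  )
  atoms <- tibble::add_row(atoms, elem = "O",
                           x = atoms$x[2] + 1.2, y = atoms$y[2] + 0.4,
                           z = 0, charge = 0L)
  ring_orders <- if (lactam) c(1L, 1L, 2L, 1L, 2L, 1L) else
    c(2L, 1L, 2L, 1L, 2L, 1L)
  bonds <- tibble::tibble(a1 = 1:6, a2 = c(2:6, 1), order = ring_orders)
  bonds <- tibble::add_row(bonds, a1 = 2L, a2 = 7L,
                           order = if (lactam) 2L else 1L)
  if (lactam) {
    atoms <- tibble::add_row(atoms, elem = "H", x = atoms$x[1] - 0.8,
                             y = atoms$y[1] - 0.6, z = 0, charge = 0L)
    bonds <- tibble::add_row(bonds, a1 = 1L, a2 = 8L, order = 1L)
  } else {
    atoms <- tibble::add_row(atoms, elem = "H", x = atoms$x[7] + 0.8,
                             y = atoms$y[7] + 0.6, z = 0, charge = 0L)
    bonds <- tibble::add_row(bonds, a1 = 7L, a2 = 8L, order = 1L)
  }
  pb_mol(id, atoms, bonds)
}

# cyclopentane; apex_z puckers atom 1 out of plane
mol_cyclopentane <- function(id = "cpent", apex_z = 0) {
  th <- 2 * pi * (0:4) / 5
  r <- 1.5 / (2 * sin(pi / 5))
  atoms <- tibble::tibble(elem = rep("C", 5),
                          x = r * cos(th), y = r * sin(th),
                          z = c(apex_z, 0, 0, 0, 0), charge = 0L)
  pb_mol(id, atoms,
         tibble::tibble(a1 = 1:5, a2 = c(2:5, 1), order = 1L))
}

small_paired_benchmark <- function(seed = 11) {
  generate_benchmark(synthetic_config(
    n_actives = 10, n_decoys = 50,
    protomer_diff_fraction = c(2 / 10, 12 / 50),
    flexible_subset_size = 3, tautomer_diff_count = 2, ring_diff_count = 3,
    seed = seed
  ))
}
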