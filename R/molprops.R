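#' Count heavy (non-hydrogen) atoms
#'
#' @param mol A [pb_mol()].
#' @return Integer heavy-atom count N, the denominator base of score
#'   normalization.
#' @export
count_heavy_atoms <- function(mol) {
  stopifnot(inherits(mol, "pb_mol"))
  n <- length(heavy_indices(mol))
  if (n == 0) stop("molecule has no heavy atoms", call. = FALSE)
  n
}

#' Count rotatable bonds
#'
#' A bond counts as rotatable when it is a single-order acyclic bond between
#' two non-terminal heavy atoms, excluding amide C-N bonds (a C-N single
#' bond where the carbon carries a double bond to oxygen). This fixed,
#' documented definition makes flexibility regimes reproducible across
#' toolkits, which typically disagree in the details.
#'
#' @param mol A [pb_mol()].
#' @return Integer rotatable-bond count.
#' @export
count_rotatable_bonds <- function(mol) {
  stopifnot(inherits(mol, "pb_mol"))
  g <- heavy_graph(mol)
  if (igraph::ecount(g) == 0) return(0L)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ord <- igraph::E(g)$order
  in_ring <- rep(TRUE, nrow(el))
  in_ring[igraph::bridges(g)] <- FALSE
  elem <- igraph::V(g)$elem
  has_carbonyl <- function(c_idx) {
    nb <- as.integer(igraph::neighbors(g, c_idx))
    any(vapply(nb, function(o) {
      elem[o] == "O" &&
        igraph::E(g)$order[igraph::get_edge_ids(g, c(c_idx, o))] == 2
    }, logical(1)))
  }
  is_amide <- function(i) {
    e <- sort(c(elem[el[i, 1]], elem[el[i, 2]]))
    if (!identical(e, c("C", "N"))) return(FALSE)
    c_idx <- el[i, which(elem[el[i, ]] == "C")[1]]
    has_carbonyl(c_idx)
  }
  n <- 0L
  for (i in seq_len(nrow(el))) {
    if (ord[i] != 1 || in_ring[i]) next
    if (deg[el[i, 1]] < 2 || deg[el[i, 2]] < 2) next
    if (is_amide(i)) next
    n <- n + 1L
  }
  n
}

#' Structure descriptor of one molecule
#'
#' @param mol A [pb_mol()].
#' @return A list with `molecule_id`, `nha`, `n_rot`, `total_charge`,
#'   `formal_charges` (tibble of charged heavy atoms), `tautomer_key`
#'   (canonical string of the heavy-atom graph with bond orders and
#'   hydrogen counts, invariant under atom reordering), and `rings`
#'   (list of heavy-atom index cycles).
#' @export
mol_descriptor <- function(mol) {
  g <- heavy_graph(mol)
  hv <- heavy_indices(mol)
  chg <- igraph::V(g)$charge
  list(
    molecule_id = mol$id,
    nha = count_heavy_atoms(mol),
    n_rot = count_rotatable_bonds(mol),
    total_charge = sum(chg),
    formal_charges = tibble::tibble(
      atom = which(chg != 0), charge = chg[chg != 0]
    ),
    tautomer_key = tautomer_key(g),
    rings = find_rings(g)
  )
}

# canonical serialization of (elements, H counts, charges, bonds+orders);
# canonical labeling by element color, refined lexicographically over the
# residual automorphisms of small graphs
tautomer_key <- function(g) {
  cols <- match(igraph::V(g)$elem, sort(unique(igraph::V(g)$elem)))
  perm <- igraph::canonical_permutation(g, colors = cols)$labeling
  gp <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gp, names = FALSE)
  o <- order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  bonds <- if (nrow(el) > 0) {
    paste(pmin(el[, 1], el[, 2])[o], pmax(el[, 1], el[, 2])[o],
          igraph::E(gp)$order[o], sep = ":", collapse = ";")
  } else ""
  atoms <- paste(igraph::V(gp)$elem, igraph::V(gp)$nh, igraph::V(gp)$charge,
                 sep = ":", collapse = ";")
  paste(atoms, bonds, sep = "|")
}

# shared mapping machinery for the pairwise detectors --------------------------

pair_mappings <- function(mol_first, mol_second, cap = 10000L) {
  g1 <- heavy_graph(mol_first)
  g2 <- heavy_graph(mol_second)
  maps <- heavy_isomorphisms(g1, g2, cap = cap)
  list(g1 = g1, g2 = g2, maps = maps,
       capped = isTRUE(attr(maps, "capped")))
}

invalid_pair <- function(why) {
  structure(list(valid = FALSE, differs = NA, detail = why),
            class = "pair_flag")
}

pair_flag <- function(differs, detail = NULL) {
  structure(list(valid = TRUE, differs = differs, detail = detail),
            class = "pair_flag")
}

#' @export
print.pair_flag <- function(x, ...) {
  if (!x$valid) cat("invalid pair:", x$detail, "\n")
  else cat("differs:", x$differs, "\n")
  invisible(x)
}

#' Detect a protonation-state (protomer) difference between two preparations
#'
#' Two preparations of the same molecule differ in protonation when their
#' heavy-atom skeletons match including bond orders, but the total formal
#' charge or any mapped atom's (formal charge, attached-hydrogen count)
#' pair differs. Pairs whose heavy-atom graphs are not isomorphic are
#' flagged invalid rather than scored; pairs whose bond orders cannot be
#' matched are not protomer pairs (see [detect_tautomer_difference()]).
#'
#' @param mol_first,mol_second The two preparation variants ([pb_mol()]).
#' @return A `pair_flag`: list with `valid`, `differs` and a per-atom
#'   `detail` tibble (mapped charges and hydrogen counts) when valid.
#' @export
detect_protonation_difference <- function(mol_first, mol_second) {
  pm <- pair_mappings(mol_first, mol_second)
  if (length(pm$maps) == 0 && !pm$capped) {
    return(invalid_pair("heavy-atom graphs are not isomorphic"))
  }
  order_ok <- Filter(function(m) mapping_preserves_orders(pm$g1, pm$g2, m),
                     pm$maps)
  if (length(order_ok) == 0) return(pair_flag(FALSE))
  chg1 <- igraph::V(pm$g1)$charge; chg2 <- igraph::V(pm$g2)$charge
  nh1 <- igraph::V(pm$g1)$nh; nh2 <- igraph::V(pm$g2)$nh
  n_mismatch <- function(m) {
    sum(chg1 != chg2[m] | nh1 != nh2[m])
  }
  mism <- vapply(order_ok, n_mismatch, numeric(1))
  best <- order_ok[[which.min(mism)]]
  differs <- sum(chg1) != sum(chg2) || min(mism) > 0
  detail <- tibble::tibble(
    atom_first = seq_along(best), atom_second = best,
    elem = igraph::V(pm$g1)$elem,
    charge_first = chg1, charge_second = chg2[best],
    nh_first = nh1, nh_second = nh2[best]
  )
  detail$differs <- detail$charge_first != detail$charge_second |
    detail$nh_first != detail$nh_second
  pair_flag(differs, detail)
}

#' Detect a tautomer difference between two preparations
#'
#' Tautomers share the molecular formula and total charge but differ in
#' hydrogen placement and bond-order pattern. The pair is a tautomer pair
#' when the heavy-atom skeletons are isomorphic but no mapping preserves
#' bond orders; a pure protomer pair (orders match, charges/hydrogens
#' differ) is never reported as a tautomer pair. A formula or total-charge
#' mismatch flags the pair invalid. Hydrogen counts use the explicit
#' (polar) hydrogens written by the preparation schemes.
#'
#' @inheritParams detect_protonation_difference
#' @return A `pair_flag`.
#' @export
detect_tautomer_difference <- function(mol_first, mol_second) {
  f1 <- sort(table(mol_first$atoms$elem))
  f2 <- sort(table(mol_second$atoms$elem))
  if (!identical(as.vector(f1), as.vector(f2)) ||
      !identical(names(f1), names(f2))) {
    return(invalid_pair("molecular formula mismatch"))
  }
  if (sum(mol_first$atoms$charge) != sum(mol_second$atoms$charge)) {
    return(invalid_pair("total formal charge mismatch"))
  }
  pm <- pair_mappings(mol_first, mol_second)
  if (length(pm$maps) == 0 && !pm$capped) {
    return(invalid_pair("heavy-atom graphs are not isomorphic"))
  }
  order_ok <- any(vapply(pm$maps, function(m) {
    mapping_preserves_orders(pm$g1, pm$g2, m)
  }, logical(1)))
  pair_flag(!order_ok)
}

#' Detect a ring-conformation difference between two preparations
#'
#' Compares the torsion profile of every non-aromatic ring of size 5-7
#' after graph matching: the pair differs when, under the best atom
#' mapping, some ring torsion deviates by more than the threshold
#' (circular arithmetic). Exocyclic torsions are out of scope. Returns
#' `differs = FALSE` when no qualifying ring exists.
#'
#' @inheritParams detect_protonation_difference
#' @param torsion_threshold_deg Circular torsion-difference threshold in
#'   degrees (default 30).
#' @return A `pair_flag`; `detail` holds the minimal-over-mappings maximum
#'   torsion deviation in degrees.
#' @export
detect_ring_conformation_difference <- function(mol_first, mol_second,
                                                torsion_threshold_deg = 30) {
  if (all(abs(as.matrix(mol_first$atoms[, c("x", "y", "z")])) < 1e-12) ||
      all(abs(as.matrix(mol_second$atoms[, c("x", "y", "z")])) < 1e-12)) {
    stop("ring-conformation comparison requires 3D coordinates",
         call. = FALSE)
  }
  pm <- pair_mappings(mol_first, mol_second)
  if (length(pm$maps) == 0 && !pm$capped) {
    return(invalid_pair("heavy-atom graphs are not isomorphic"))
  }
  rings1 <- find_rings(pm$g1)
  aromatic <- vapply(rings1, function(r) ring_is_aromatic(pm$g1, r),
                     logical(1))
  rings1 <- rings1[!aromatic &
                     lengths(rings1) >= 5 & lengths(rings1) <= 7]
  if (length(rings1) == 0) return(pair_flag(FALSE, detail = 0))
  x1 <- heavy_coords(mol_first)
  x2 <- heavy_coords(mol_second)
  maps <- Filter(function(m) mapping_preserves_orders(pm$g1, pm$g2, m),
                 pm$maps)
  if (length(maps) == 0) maps <- pm$maps
  worst_per_map <- vapply(maps, function(m) {
    max(vapply(rings1, function(ring) {
      t1 <- ring_torsions(x1, ring)
      t2 <- ring_torsions(x2, m[ring])
      max(circular_diff_deg(t1, t2))
    }, numeric(1)))
  }, numeric(1))
  dev <- min(worst_per_map)
  pair_flag(dev > torsion_threshold_deg, detail = dev)
}

ring_is_aromatic <- function(g, ring) {
  k <- length(ring)
  ids <- igraph::get_edge_ids(
    g, t(cbind(ring, ring[c(2:k, 1)]))
  )
  all(igraph::E(g)$order[ids] == 4)
}

# consecutive intra-ring torsions (one per ring bond), degrees
ring_torsions <- function(coords, ring) {
  k <- length(ring)
  idx <- function(i) ring[((i - 1) %% k) + 1]
  vapply(seq_len(k), function(i) {
    dihedral_deg(coords[idx(i - 1), ], coords[idx(i), ],
                 coords[idx(i + 1), ], coords[idx(i + 2), ])
  }, numeric(1))
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

circular_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Symmetry-aware heavy-atom RMSD of two preparations
#'
#' The naive RMSD of two conformers depends on arbitrary atom numbering:
#' relabeling a benzene ring by one of its 12 graph symmetries changes
#' nothing chemically but everything numerically. This function minimizes
#' the heavy-atom RMSD over all element-preserving graph isomorphisms
#' between the two structures, optionally with optimal rigid-body
#' superposition (Kabsch) per mapping. Hydrogens are excluded: preparation
#' schemes differ in which hydrogens they write, which would otherwise
#' dominate the deviation.
#'
#' @inheritParams detect_protonation_difference
#' @param superimpose Optimally superimpose per mapping (`TRUE`, default)
#'   or compare coordinates in place (`FALSE`).
#' @param cap Maximum number of isomorphisms to enumerate exactly. Above
#'   the cap (highly symmetric molecules) the function falls back to a
#'   greedy within-element-class assignment after identity superposition
#'   and marks the result approximate.
#' @return The minimal RMSD in Angstrom, with attribute `approximate` when
#'   the fallback was used. Non-isomorphic pairs raise an error.
#' @export
symmetry_aware_rmsd <- function(mol_first, mol_second, superimpose = TRUE,
                                cap = 10000L) {
  pm <- pair_mappings(mol_first, mol_second, cap = cap)
  x1 <- heavy_coords(mol_first)
  x2 <- heavy_coords(mol_second)
  if (pm$capped) {
    return(structure(greedy_class_rmsd(pm, x1, x2, superimpose),
                     approximate = TRUE))
  }
  if (length(pm$maps) == 0) {
    stop("heavy-atom graphs are not isomorphic; RMSD undefined",
         call. = FALSE)
  }
  vals <- vapply(pm$maps, function(m) {
    mapped_rmsd(x1, x2[m, , drop = FALSE], superimpose)
  }, numeric(1))
  min(vals)
}

mapped_rmsd <- function(x, y, superimpose) {
  if (superimpose) y <- kabsch_align(y, x)
  sqrt(mean(rowSums((x - y)^2)))
}

# optimal rotation of P onto Q (least-squares, proper rotation only)
kabsch_align <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2, cp); q0 <- sweep(q, 2, cq)
  h <- t(p0) %*% q0
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(p0 %*% r, 2, cq, FUN = "+")
}

# fallback above the automorphism cap: greedy nearest-atom assignment within
# element classes after identity-mapping superposition (upper bound on the
# true symmetry-minimized RMSD)
greedy_class_rmsd <- function(pm, x1, x2, superimpose) {
  if (superimpose) x2 <- kabsch_align(x2, x1)
  elem1 <- igraph::V(pm$g1)$elem
  elem2 <- igraph::V(pm$g2)$elem
  map <- integer(nrow(x1))
  used <- rep(FALSE, nrow(x2))
  for (i in order(elem1)) {
    cand <- which(elem2 == elem1[i] & !used)
    d2 <- rowSums((x2[cand, , drop = FALSE] -
                     matrix(x1[i, ], length(cand), 3, byrow = TRUE))^2)
    j <- cand[which.min(d2)]
    map[i] <- j; used[j] <- TRUE
  }
  mapped_rmsd(x1, x2[map, , drop = FALSE], superimpose)
}

#' Squared Pearson correlation of a score divergence with a property
#'
#' @param delta_fitness Numeric vector of score differences.
#' @param property Numeric vector of equal length (>= 3), e.g. rotatable
#'   bonds or heavy atoms.
#' @return Squared Pearson correlation, or `NA` with attribute
#'   `undefined = TRUE` when either vector has zero variance.
#' @export
correlate_property <- function(delta_fitness, property) {
  stopifnot(length(delta_fitness) == length(property),
            length(property) >= 3)
  ok <- stats::complete.cases(delta_fitness, property)
  if (stats::sd(delta_fitness[ok]) == 0 || stats::sd(property[ok]) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(delta_fitness[ok], property[ok]) ^ 2
}

#' Audit paired preparations of a molecule set
#'
#' Runs all pairwise difference detectors and the symmetry-aware RMSD over
#' a set of molecule pairs (e.g. from [read_paired_sdf()]).
#'
#' @param pairs A tibble with columns `molecule_id`, `mol_first`,
#'   `mol_second` (list-columns of [pb_mol()]), or the list returned by
#'   [read_paired_sdf()].
#' @param torsion_threshold_deg Forwarded to
#'   [detect_ring_conformation_difference()].
#' @param superimpose Forwarded to [symmetry_aware_rmsd()].
#' @return A tibble, one row per pair: descriptors (`nha`, `n_rot_first`,
#'   `n_rot_second`), difference flags, `pairwise_rmsd`, `valid`.
#' @export
audit_prep_pairs <- function(pairs, torsion_threshold_deg = 30,
                             superimpose = TRUE) {
  if (is.list(pairs) && !is.data.frame(pairs) && "pairs" %in% names(pairs)) {
    pairs <- pairs$pairs
  }
  purrr::pmap_dfr(
    list(pairs$molecule_id, pairs$mol_first, pairs$mol_second),
    function(id, m1, m2) {
      prot <- detect_protonation_difference(m1, m2)
      if (!prot$valid) {
        return(tibble::tibble(
          molecule_id = id, valid = FALSE, nha = count_heavy_atoms(m1),
          n_rot_first = NA_integer_, n_rot_second = NA_integer_,
          differs_protonation = NA, differs_tautomer = NA,
          differs_ring_conformation = NA, pairwise_rmsd = NA_real_
        ))
      }
      taut <- detect_tautomer_difference(m1, m2)
      ring <- detect_ring_conformation_difference(
        m1, m2, torsion_threshold_deg = torsion_threshold_deg)
      tibble::tibble(
        molecule_id = id, valid = TRUE, nha = count_heavy_atoms(m1),
        n_rot_first = count_rotatable_bonds(m1),
        n_rot_second = count_rotatable_bonds(m2),
        differs_protonation = prot$differs,
        differs_tautomer = isTRUE(taut$differs),
        differs_ring_conformation = isTRUE(ring$differs),
        pairwise_rmsd = as.numeric(
          symmetry_aware_rmsd(m1, m2, superimpose = superimpose))
      )
    }
  )
}

#' Summarize a preparation audit
#'
#' @param audit The tibble returned by [audit_prep_pairs()].
#' @return One-row tibble with difference counts and mean pairwise RMSD.
#' @export
summarize_audit <- function(audit) {
  tibble::tibble(
    n_pairs = nrow(audit),
    n_invalid = sum(!audit$valid),
    n_protonation = sum(audit$differs_protonation, na.rm = TRUE),
    n_tautomer = sum(audit$differs_tautomer, na.rm = TRUE),
    n_ring_conformation = sum(audit$differs_ring_conformation, na.rm = TRUE),
    mean_rmsd = mean(audit$pairwise_rmsd, na.rm = TRUE)
  )
}
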