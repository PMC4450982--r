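#' Molecule container used by the preparation audit
#'
#' A light structure-with-coordinates representation: a tibble of atoms
#' (element, 3D coordinates in Angstrom, formal charge) and a tibble of
#' bonds (1-based atom indices, bond order). Explicit hydrogens are regular
#' atoms; heavy-atom views are derived on demand. Preparation schemes write
#' polar hydrogens explicitly, which is what the protonation and tautomer
#' detectors rely on.
#'
#' @param id Molecule identifier (SD title line).
#' @param atoms Tibble/data frame with columns `elem`, `x`, `y`, `z` and
#'   optionally `charge` (formal charge, default 0).
#' @param bonds Tibble/data frame with columns `a1`, `a2`, `order`.
#' @return An object of class `pb_mol`.
#' @export
pb_mol <- function(id, atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("elem", "x", "y", "z") %in% names(atoms)),
            all(c("a1", "a2", "order") %in% names(bonds)))
  if (nrow(atoms) == 0) stop("empty molecule", call. = FALSE)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  if (nrow(bonds) > 0 &&
      (max(bonds$a1, bonds$a2) > nrow(atoms) || min(bonds$a1, bonds$a2) < 1)) {
    stop("bond indices out of range", call. = FALSE)
  }
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "pb_mol")
}

#' @export
print.pb_mol <- function(x, ...) {
  cat(sprintf("<pb_mol %s: %d atoms (%d heavy), %d bonds>\n",
              x$id, nrow(x$atoms), count_heavy_atoms(x), nrow(x$bonds)))
  invisible(x)
}

# V2000 old-style charge field codes <-> formal charges
charge_to_code <- function(charge) {
  code <- integer(length(charge))
  code[charge == 3] <- 1L; code[charge == 2] <- 2L; code[charge == 1] <- 3L
  code[charge == -1] <- 5L; code[charge == -2] <- 6L; code[charge == -3] <- 7L
  code
}
code_to_charge <- function(code) {
  chg <- integer(length(code))
  chg[code == 1] <- 3L; chg[code == 2] <- 2L; chg[code == 3] <- 1L
  chg[code == 5] <- -1L; chg[code == 6] <- -2L; chg[code == 7] <- -3L
  chg
}

mol_to_chemmine_sdf <- function(mol) {
  n_at <- nrow(mol$atoms)
  n_bd <- nrow(mol$bonds)
  ab <- matrix(0, nrow = n_at, ncol = 15)
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  ab[, 1] <- mol$atoms$x
  ab[, 2] <- mol$atoms$y
  ab[, 3] <- mol$atoms$z
  ab[, "C6"] <- charge_to_code(mol$atoms$charge)
  rownames(ab) <- paste(mol$atoms$elem, seq_len(n_at), sep = "_")
  bb <- matrix(0L, nrow = n_bd, ncol = 7)
  colnames(bb) <- paste0("C", 1:7)
  if (n_bd > 0) {
    bb[, 1] <- mol$bonds$a1
    bb[, 2] <- mol$bonds$a2
    bb[, 3] <- mol$bonds$order
  }
  rownames(bb) <- if (n_bd > 0) as.character(seq_len(n_bd)) else character(0)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd)
  methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
               header = c(Molecule_Name = mol$id, Source = "procbench",
                          Comment = "", Counts_Line = counts),
               atomblock = ab, bondblock = bb,
               datablock = character(0))
}

chemmine_sdf_to_mol <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_\\d+$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) code_to_charge(ab[, "C6"]) else 0L
  atoms <- tibble::tibble(elem = unname(elem), x = unname(ab[, 1]),
                          y = unname(ab[, 2]), z = unname(ab[, 3]),
                          charge = as.integer(unname(charge)))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0)
  bonds <- if (nrow(bb) > 0) {
    tibble::tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  } else {
    tibble::tibble(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  pb_mol(id, atoms, bonds)
}

#' Write molecules to an SD file (V2000)
#'
#' @param mols A list of [pb_mol()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mols_sdf <- function(mols, path) {
  sdfs <- lapply(mols, mol_to_chemmine_sdf)
  ids <- vapply(mols, function(m) m$id, character(1))
  set <- methods::new(methods::getClass("SDFset",
                                        where = asNamespace("ChemmineR")),
                      SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(set, file = path, cid = TRUE)
  invisible(path)
}

#' Read molecules from an SD file (V2000)
#'
#' Unreadable SD blocks produce a per-molecule warning and are skipped (and
#' counted), never silently dropped.
#'
#' @param path SD file path.
#' @param id_property Optional SD data field to use as molecule id instead
#'   of the title line (fallback pairing key).
#' @return A named list of `pb_mol` with attribute `n_skipped`.
#' @export
read_mols_sdf <- function(path, id_property = NULL) {
  if (!file.exists(path)) stop("SD file not found: ", path, call. = FALSE)
  set <- ChemmineR::read.SDFset(path, skipErrors = TRUE)
  n_total <- length(set)
  valid <- ChemmineR::validSDF(set)
  n_skipped <- sum(!valid)
  if (n_skipped > 0) {
    warning(sprintf("%s: skipped %d unreadable SD block(s)", path, n_skipped),
            call. = FALSE)
    set <- set[valid]
  }
  ids <- as.character(ChemmineR::sdfid(set))
  if (!is.null(id_property)) {
    db <- ChemmineR::datablock(set)
    ids <- vapply(seq_along(set), function(i) {
      v <- db[[i]][id_property]
      if (is.na(v)) ids[i] else unname(v)
    }, character(1))
  }
  mols <- lapply(seq_along(set), function(i) {
    tryCatch(chemmine_sdf_to_mol(set[[i]], ids[i]), error = function(e) NULL)
  })
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    warning("skipped malformed molecule(s): ",
            paste(ids[bad], collapse = ", "), call. = FALSE)
    n_skipped <- n_skipped + sum(bad)
    mols <- mols[!bad]; ids <- ids[!bad]
  }
  names(mols) <- ids
  attr(mols, "n_skipped") <- n_skipped
  mols
}

#' Pair two SD files of the same molecules under different preparations
#'
#' Molecules are paired by title line (or a designated SD property). Ids
#' present in only one file are reported, not silently dropped.
#'
#' @param path_a,path_b SD files, one per preparation scheme.
#' @param id_property Optional SD data field used as the pairing key.
#' @return List with `pairs` (tibble: `molecule_id`, list-columns
#'   `mol_first`, `mol_second`), `unmatched_first`, `unmatched_second`,
#'   `n_skipped`.
#' @export
read_paired_sdf <- function(path_a, path_b, id_property = NULL) {
  a <- read_mols_sdf(path_a, id_property)
  b <- read_mols_sdf(path_b, id_property)
  common <- intersect(names(a), names(b))
  list(
    pairs = tibble::tibble(
      molecule_id = common,
      mol_first = unname(a[common]),
      mol_second = unname(b[common])
    ),
    unmatched_first = setdiff(names(a), names(b)),
    unmatched_second = setdiff(names(b), names(a)),
    n_skipped = attr(a, "n_skipped") + attr(b, "n_skipped")
  )
}

# ---- graph views ------------------------------------------------------------

heavy_indices <- function(mol) which(mol$atoms$elem != "H")

# igraph over heavy atoms; vertex attrs elem/charge/nh, edge attr order
heavy_graph <- function(mol) {
  hv <- heavy_indices(mol)
  remap <- match(seq_len(nrow(mol$atoms)), hv)
  b <- mol$bonds
  keep <- !is.na(remap[b$a1]) & !is.na(remap[b$a2])
  el <- cbind(remap[b$a1[keep]], remap[b$a2[keep]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(hv) - igraph::vcount(g)))
  igraph::V(g)$elem <- mol$atoms$elem[hv]
  igraph::V(g)$charge <- mol$atoms$charge[hv]
  igraph::V(g)$nh <- hydrogen_counts(mol)
  igraph::E(g)$order <- b$order[keep]
  g
}

# explicit-H neighbor count per heavy atom
hydrogen_counts <- function(mol) {
  hv <- heavy_indices(mol)
  is_h <- mol$atoms$elem == "H"
  nh <- integer(length(hv))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
      if (is_h[a1] && !is_h[a2]) nh[match(a2, hv)] <- nh[match(a2, hv)] + 1L
      if (is_h[a2] && !is_h[a1]) nh[match(a1, hv)] <- nh[match(a1, hv)] + 1L
    }
  }
  nh
}

heavy_coords <- function(mol) {
  hv <- heavy_indices(mol)
  as.matrix(mol$atoms[hv, c("x", "y", "z")])
}

element_colors <- function(g1, g2 = g1) {
  lv <- sort(unique(c(igraph::V(g1)$elem, igraph::V(g2)$elem)))
  list(c1 = match(igraph::V(g1)$elem, lv), c2 = match(igraph::V(g2)$elem, lv))
}

# all element-preserving isomorphisms between heavy-atom skeletons,
# as a list of integer mappings (index in g1 -> index in g2)
heavy_isomorphisms <- function(g1, g2, cap = 10000L) {
  if (igraph::vcount(g1) != igraph::vcount(g2)) return(list())
  cols <- element_colors(g1, g2)
  n <- igraph::count_isomorphisms(g1, g2, method = "vf2",
                                  vertex.color1 = cols$c1,
                                  vertex.color2 = cols$c2)
  if (n == 0) return(list())
  if (n > cap) return(structure(list(), capped = TRUE, n_found = n))
  maps <- igraph::isomorphisms(g1, g2, method = "vf2",
                               vertex.color1 = cols$c1,
                               vertex.color2 = cols$c2)
  lapply(maps, as.integer)
}

# does mapping preserve bond orders? (g1 edge orders vs mapped g2 edges)
mapping_preserves_orders <- function(g1, g2, map) {
  el <- igraph::as_edgelist(g1, names = FALSE)
  if (nrow(el) == 0) return(TRUE)
  ids2 <- igraph::get_edge_ids(g2, t(cbind(map[el[, 1]], map[el[, 2]])))
  if (any(ids2 == 0)) return(FALSE)
  all(igraph::E(g1)$order == igraph::E(g2)$order[ids2])
}

# enumerate rings of size 3..max_size as ordered atom index vectors
# (heavy-atom indices within the heavy graph); deduplicated
find_rings <- function(g, max_size = 7) {
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  rings <- list()
  seen <- character(0)
  # DFS from each vertex; record cycles closing back at the root
  path <- integer(max_size)
  dfs <- function(root, v, depth, blocked) {
    for (w in adj[[v]]) {
      if (w == root && depth >= 3) {
        cyc <- path[seq_len(depth)]
        key <- paste(sort(cyc), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- cyc
        }
      } else if (depth < max_size && !blocked[w] && w > root) {
        path[depth + 1L] <<- w
        blocked[w] <- TRUE
        dfs(root, w, depth + 1L, blocked)
        blocked[w] <- FALSE
      }
    }
  }
  for (root in seq_len(n)) {
    blocked <- rep(FALSE, n)
    blocked[root] <- TRUE
    path[1L] <- root
    dfs(root, root, 1L, blocked)
  }
  # keep only chordless cycles (actual rings, not sums of smaller rings)
  is_chordless <- function(cyc) {
    k <- length(cyc)
    if (k <= 3) return(TRUE)
    for (i in seq_len(k - 2)) {
      for (j in seq(i + 2, k)) {
        if (i == 1 && j == k) next
        if (igraph::are_adjacent(g, cyc[i], cyc[j])) return(FALSE)
      }
    }
    TRUE
  }
  Filter(is_chordless, rings)
}
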