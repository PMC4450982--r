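SYNTHETIC_VERSION <- "1"

#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates a DEKOIS-2.0-shaped benchmark (40 bioactives,
#' 1200 decoys, 30 decoys per bioactive) docked under two preparation
#' schemes, with an additive size-dependent score model
#' \deqn{s = b_0 + b_N \cdot \mathrm{NHA} + a \cdot [\mathrm{bioactive}] + \varepsilon}
#' mirroring the molecular-weight bias of empirical scoring functions. The
#' second preparation perturbs the first: small scheme noise for every
#' molecule, an extra zero-mean shift for molecules planted as
#' protomer/tautomer/ring-different, and a flexibility-coupled penalty for
#' a small subset of highly flexible bioactives (the mechanism that makes
#' one scheme win overall). Default magnitudes place decoy scores near
#' mean 77 / sd 12 and baseline pROC-AUC inside the 0.3-2.0 band observed
#' for real GOLD ChemPLP screens; the defaults are study conditions, not
#' tuning knobs.
#'
#' @param n_actives,n_decoys Set sizes (defaults 40 and 1200).
#' @param nha_mean_actives,nha_sd_actives,nha_mean_decoys,nha_sd_decoys
#'   Heavy-atom count distribution per role (defaults mean 27.6, sd 4.5;
#'   DEKOIS decoys are property-matched to the bioactives).
#' @param base_score Score intercept `b_0` (default 35).
#' @param bias_slope Score units per heavy atom `b_N` (default 1.5).
#' @param affinity_offset Size-independent bioactive bonus `a` (default 10).
#' @param noise_sd Score noise sd (default 8).
#' @param prep_noise_sd Sd of the scheme-to-scheme score noise applied to
#'   every molecule (default 2; paired decoy scores then correlate near
#'   the R^2 ~ 0.8-0.95 seen in real paired screens).
#' @param protomer_diff_fraction Length-2 vector: fraction of bioactives
#'   and of decoys whose protonation state differs between schemes
#'   (defaults 2/40 and 435/1200).
#' @param protomer_shift_sd Sd of the extra zero-mean score shift of
#'   difference-flagged molecules (default 4).
#' @param flexible_subset_size Number of highly flexible bioactives whose
#'   scores diverge between schemes (default 10).
#' @param flexibility_coupling Score penalty per rotatable bond per unit
#'   half-normal draw applied to the flexible subset in scheme two
#'   (default 0.4).
#' @param tautomer_diff_count,ring_diff_count Decoys planted with a
#'   tautomer / ring-conformation difference (defaults 1 and 2).
#' @param prep_labels Labels of the two schemes.
#' @param seed Integer seed; the whole benchmark is a deterministic
#'   function of the configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_actives = 40, n_decoys = 1200,
                             nha_mean_actives = 27.6, nha_sd_actives = 4.5,
                             nha_mean_decoys = 27.6, nha_sd_decoys = 4.5,
                             base_score = 35, bias_slope = 1.5,
                             affinity_offset = 10, noise_sd = 8,
                             prep_noise_sd = 2,
                             protomer_diff_fraction = c(2 / 40, 435 / 1200),
                             protomer_shift_sd = 4,
                             flexible_subset_size = 10,
                             flexibility_coupling = 0.4,
                             tautomer_diff_count = 1, ring_diff_count = 2,
                             prep_labels = c("prepA", "prepB"),
                             seed = 1L) {
  cfg <- list(
    n_actives = as.integer(n_actives), n_decoys = as.integer(n_decoys),
    nha_mean_actives = as.numeric(nha_mean_actives),
    nha_sd_actives = as.numeric(nha_sd_actives),
    nha_mean_decoys = as.numeric(nha_mean_decoys),
    nha_sd_decoys = as.numeric(nha_sd_decoys),
    base_score = as.numeric(base_score),
    bias_slope = as.numeric(bias_slope),
    affinity_offset = as.numeric(affinity_offset),
    noise_sd = as.numeric(noise_sd),
    prep_noise_sd = as.numeric(prep_noise_sd),
    protomer_diff_fraction = as.numeric(protomer_diff_fraction),
    protomer_shift_sd = as.numeric(protomer_shift_sd),
    flexible_subset_size = as.integer(flexible_subset_size),
    flexibility_coupling = as.numeric(flexibility_coupling),
    tautomer_diff_count = as.integer(tautomer_diff_count),
    ring_diff_count = as.integer(ring_diff_count),
    prep_labels = prep_labels, seed = as.integer(seed),
    version = SYNTHETIC_VERSION
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_actives >= 1, cfg$n_decoys >= 1,
            length(cfg$protomer_diff_fraction) == 2)
  if (any(cfg$protomer_diff_fraction < 0 | cfg$protomer_diff_fraction > 1)) {
    stop("protomer_diff_fraction must lie in [0, 1]", call. = FALSE)
  }
  n_prot_a <- round(cfg$protomer_diff_fraction[1] * cfg$n_actives)
  if (cfg$flexible_subset_size + n_prot_a > cfg$n_actives) {
    stop("flexible subset plus protomer-flagged bioactives exceed n_actives",
         call. = FALSE)
  }
  n_prot_d <- round(cfg$protomer_diff_fraction[2] * cfg$n_decoys)
  if (n_prot_d + cfg$tautomer_diff_count + cfg$ring_diff_count >
        cfg$n_decoys) {
    stop("planted decoy differences exceed n_decoys", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic paired-preparation benchmark
#'
#' Draws heavy-atom counts, rotatable-bond counts, difference flags and
#' scores for both preparation schemes from [synthetic_config()], entirely
#' determined by the configuration's seed. Structures (for the molecular
#' audit) are built on demand by [benchmark_molecules()].
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_benchmark`: list with
#'   `table_first`, `table_second` (best-pose-reduced [score_table()]s),
#'   `truth` (per-molecule tibble: role, `nha`, `n_rot`, difference flags,
#'   both scores and every generative component) and `config`.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  truth <- withr::with_seed(cfg$seed, {
    n_a <- cfg$n_actives; n_d <- cfg$n_decoys; n <- n_a + n_d
    id <- c(sprintf("bio%03d", seq_len(n_a)), sprintf("dec%04d", seq_len(n_d)))
    role <- rep(c("bioactive", "decoy"), c(n_a, n_d))
    nha <- pmax(9L, round(c(
      stats::rnorm(n_a, cfg$nha_mean_actives, cfg$nha_sd_actives),
      stats::rnorm(n_d, cfg$nha_mean_decoys, cfg$nha_sd_decoys)
    )))
    flex <- rep(FALSE, n)
    prot <- rep(FALSE, n)
    taut <- rep(FALSE, n)
    ring <- rep(FALSE, n)
    act_idx <- seq_len(n_a)
    n_prot_a <- round(cfg$protomer_diff_fraction[1] * n_a)
    prot[sample(act_idx, n_prot_a)] <- TRUE
    flex[sample(setdiff(act_idx, which(prot)), cfg$flexible_subset_size)] <- TRUE
    dec_idx <- n_a + seq_len(n_d)
    n_prot_d <- round(cfg$protomer_diff_fraction[2] * n_d)
    prot[sample(dec_idx, n_prot_d)] <- TRUE
    pool <- setdiff(dec_idx, which(prot))
    taut_pick <- sample(pool, cfg$tautomer_diff_count)
    taut[taut_pick] <- TRUE
    ring[sample(setdiff(pool, taut_pick), cfg$ring_diff_count)] <- TRUE

    n_rot <- pmax(0L, round(stats::rnorm(n, 0.35 * nha - 2, 2)))
    n_rot[flex] <- sample(9:13, sum(flex), replace = TRUE)

    eps <- stats::rnorm(n, 0, cfg$noise_sd)
    eta <- stats::rnorm(n, 0, cfg$prep_noise_sd)
    shift <- ifelse(prot | taut | ring,
                    stats::rnorm(n, 0, cfg$protomer_shift_sd), 0)
    flex_draw <- abs(stats::rnorm(n)) * flex
    bias <- cfg$bias_slope * nha
    offset <- cfg$affinity_offset * (role == "bioactive")
    score_first <- cfg$base_score + bias + offset + eps
    score_second <- score_first + eta + shift -
      cfg$flexibility_coupling * n_rot * flex_draw
    tibble::tibble(
      molecule_id = id, role = role, nha = as.integer(nha),
      n_rot = as.integer(n_rot),
      differs_protonation = prot, differs_tautomer = taut,
      differs_ring_conformation = ring, flexible = flex,
      bias = bias, offset = offset, noise = eps, prep_noise = eta,
      diff_shift = shift, flex_draw = flex_draw,
      score_first = score_first, score_second = score_second
    )
  })
  mk <- function(col, prep) {
    score_table(
      tibble::tibble(molecule_id = truth$molecule_id, role = truth$role,
                     score = truth[[col]]),
      orientation = "higher_is_better", program = "synthetic",
      target_prep = prep, dataset_prep = prep
    )
  }
  structure(
    list(table_first = mk("score_first", cfg$prep_labels[1]),
         table_second = mk("score_second", cfg$prep_labels[2]),
         truth = truth, config = cfg),
    class = "synthetic_benchmark"
  )
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(
    "synthetic benchmark: %d bioactives, %d decoys, seed %d\n",
    x$config$n_actives, x$config$n_decoys, x$config$seed))
  cat(sprintf(
    "planted differences: %d protomer, %d tautomer, %d ring; %d flexible\n",
    sum(x$truth$differs_protonation), sum(x$truth$differs_tautomer),
    sum(x$truth$differs_ring_conformation), sum(x$truth$flexible)))
  invisible(x)
}

#' Regenerate a benchmark from its stored configuration
#'
#' Every synthetic benchmark is a pure function of its configuration; this
#' rebuilds it bit-identically (used after serializing the truth sidecar).
#'
#' @param x A `synthetic_benchmark`, a `synthetic_config`, or the path of a
#'   YAML sidecar written by [write_benchmark()].
#' @return A fresh `synthetic_benchmark`.
#' @export
replay <- function(x) {
  cfg <- if (inherits(x, "synthetic_benchmark")) {
    x$config
  } else if (inherits(x, "synthetic_config")) {
    x
  } else if (is.character(x)) {
    read_truth_sidecar(x)
  } else {
    stop("cannot replay object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  if (!identical(cfg$version, SYNTHETIC_VERSION)) {
    stop("truth sidecar version ", cfg$version,
         " does not match generator version ", SYNTHETIC_VERSION,
         call. = FALSE)
  }
  generate_benchmark(cfg)
}

#' Write a synthetic benchmark to disk
#'
#' Emits the two score tables as TSV, a versioned YAML truth sidecar (the
#' full generator configuration, sufficient to [replay()] the benchmark),
#' and optionally paired SD files with the planted structures.
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory (created if needed).
#' @param structures Also write `molecules_<prep>.sdf` pairs.
#' @return Named character vector of written paths, invisibly.
#' @export
write_benchmark <- function(bench, dir, structures = FALSE) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- bench$config$prep_labels
  p1 <- file.path(dir, sprintf("scores_%s.tsv", labs[1]))
  p2 <- file.path(dir, sprintf("scores_%s.tsv", labs[2]))
  write_score_table(bench$table_first, p1)
  write_score_table(bench$table_second, p2)
  sidecar <- file.path(dir, "truth.yml")
  cfg <- unclass(bench$config)
  # serialize doubles at full precision so replay is bit-identical
  yaml::write_yaml(cfg, sidecar, handlers = list(
    numeric = function(x) {
      structure(sprintf("%.17g", x), class = "verbatim")
    }
  ))
  paths <- c(scores_first = p1, scores_second = p2, truth = sidecar)
  if (structures) {
    mols <- benchmark_molecules(bench)
    s1 <- file.path(dir, sprintf("molecules_%s.sdf", labs[1]))
    s2 <- file.path(dir, sprintf("molecules_%s.sdf", labs[2]))
    write_mols_sdf(mols$first, s1)
    write_mols_sdf(mols$second, s2)
    paths <- c(paths, sdf_first = s1, sdf_second = s2)
  }
  invisible(paths)
}

read_truth_sidecar <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$version)) stop("truth sidecar lacks a version", call. = FALSE)
  if (!identical(as.character(cfg$version), SYNTHETIC_VERSION)) {
    stop("truth sidecar version ", cfg$version,
         " does not match generator version ", SYNTHETIC_VERSION,
         call. = FALSE)
  }
  do.call(synthetic_config, cfg[setdiff(names(cfg), "version")])
}

# ---- planted structures -----------------------------------------------------

#' Build the planted structures of a synthetic benchmark
#'
#' Every molecule is assembled from a small template grammar of chemically
#' valid fragments -- alkyl chain with methyl decorations plus a flavor
#' head: carboxylic acid (protomer pairs: neutral acid vs carboxylate),
#' 2-pyridinone (tautomer pairs: lactam vs hydroxy-aromatic form),
#' cyclopentane (ring pairs: planar vs envelope pucker) -- sized so the
#' heavy-atom count equals the planted `nha` exactly. The second
#' preparation applies the planted structural change and a rigid rotation
#' plus translation (which no detector may react to). Geometries are
#' idealized (1.5 A bonds, tetrahedral chains); they carry the planted
#' differences, not force-field minima.
#'
#' @param bench A `synthetic_benchmark`.
#' @param ids Molecule ids to build (default: all).
#' @return List with `first` and `second`: named lists of [pb_mol()].
#' @export
benchmark_molecules <- function(bench, ids = NULL) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  truth <- bench$truth
  if (!is.null(ids)) truth <- truth[truth$molecule_id %in% ids, ]
  res <- withr::with_seed(bench$config$seed + 1L, {
    purrr::pmap(
      list(truth$molecule_id, truth$nha, truth$differs_protonation,
           truth$differs_tautomer, truth$differs_ring_conformation),
      function(id, nha, prot, taut, ring) {
        flavor <- if (prot) "protomer" else if (taut) "tautomer" else
          if (ring) "ring" else "plain"
        m1 <- build_template(id, nha, flavor, variant = 1L)
        m2 <- build_template(id, nha, flavor, variant = 2L)
        m2 <- rigid_motion(m2,
                           angles = stats::runif(3, 0, 2 * pi),
                           translation = stats::runif(3, -5, 5))
        list(first = m1, second = m2)
      })
  })
  list(first = stats::setNames(lapply(res, `[[`, "first"), truth$molecule_id),
       second = stats::setNames(lapply(res, `[[`, "second"), truth$molecule_id))
}

# head sizes: heavy atoms consumed by each flavor head
template_head_size <- function(flavor) {
  switch(flavor, plain = 0L, protomer = 3L, tautomer = 7L, ring = 5L)
}

# Assemble: [head] - C1 - C2 - ... - CL (+ methyl decorations).
# Exact heavy-atom count; at most one methyl per interior chain atom keeps
# the graph automorphism group small.
build_template <- function(id, nha, flavor, variant = 1L) {
  head_n <- template_head_size(flavor)
  rest <- nha - head_n
  if (rest < 3) {
    stop("infeasible template: nha ", nha, " too small for flavor '",
         flavor, "'", call. = FALSE)
  }
  # chain length L and methyl count m with m <= L - 2, L + m = rest
  chain_len <- max(3L, as.integer(ceiling((rest + 2) / 2)))
  m <- rest - chain_len
  atoms <- tibble::tibble(elem = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0),
                          charge = integer(0))
  bonds <- tibble::tibble(a1 = integer(0), a2 = integer(0), order = integer(0))
  add_atom <- function(elem, xyz, charge = 0L) {
    atoms <<- tibble::add_row(atoms, elem = elem, x = xyz[1], y = xyz[2],
                              z = xyz[3], charge = as.integer(charge))
    nrow(atoms)
  }
  add_bond <- function(a1, a2, order = 1L) {
    bonds <<- tibble::add_row(bonds, a1 = a1, a2 = a2,
                              order = as.integer(order))
  }
  # zig-zag chain along x
  step_x <- 1.5 * cos(pi / 6); step_y <- 1.5 * sin(pi / 6)
  chain_idx <- integer(chain_len)
  for (i in seq_len(chain_len)) {
    chain_idx[i] <- add_atom("C", c((i - 1) * step_x,
                                    step_y * (i %% 2), 0))
    if (i > 1) add_bond(chain_idx[i - 1], chain_idx[i])
  }
  # methyl decorations on the first m interior atoms
  if (m > 0) {
    hosts <- chain_idx[seq(2, length.out = m)]
    for (j in seq_along(hosts)) {
      h <- hosts[j]
      me <- add_atom("C", c(atoms$x[h], atoms$y[h] + 1.0, 1.2))
      add_bond(h, me)
    }
  }
  attach_at <- chain_idx[1]
  if (flavor == "protomer") {
    # carboxyl head: C(=O)(O[H|-]) bound to chain start
    cx <- add_atom("C", c(-1.3, 0.8, 0))
    o1 <- add_atom("O", c(-1.3, 2.2, 0))
    deprot <- variant == 2L
    o2 <- add_atom("O", c(-2.5, 0.1, 0), charge = if (deprot) -1L else 0L)
    add_bond(cx, attach_at); add_bond(cx, o1, 2L); add_bond(cx, o2, 1L)
    if (!deprot) {
      h <- add_atom("H", c(-3.3, 0.7, 0))
      add_bond(o2, h)
    }
  } else if (flavor == "tautomer") {
    # 2-pyridinone head attached at ring C4; variant 2 is the
    # 2-hydroxypyridine tautomer (H moves N -> O, orders shift)
    r <- ring_polygon(6, bond = 1.4, centre = c(-2.4, 0.6), phase = 0)
    ring_elems <- c("N", "C", "C", "C", "C", "C")
    ridx <- vapply(seq_len(6), function(i) {
      add_atom(ring_elems[i], c(r[i, ], 0))
    }, integer(1))
    lactam <- variant == 1L
    ring_orders <- if (lactam) c(1L, 1L, 2L, 1L, 2L, 1L) else
      c(2L, 1L, 2L, 1L, 2L, 1L)
    for (i in seq_len(6)) {
      add_bond(ridx[i], ridx[(i %% 6) + 1], ring_orders[i])
    }
    ox <- add_atom("O", c(r[2, 1] - 0.7, r[2, 2] - 1.2, 0))
    add_bond(ridx[2], ox, if (lactam) 2L else 1L)
    if (lactam) {
      h <- add_atom("H", c(r[1, 1], r[1, 2] + 1.0, 0))
      add_bond(ridx[1], h)
    } else {
      h <- add_atom("H", c(atoms$x[ox] - 0.6, atoms$y[ox] - 0.7, 0))
      add_bond(ox, h)
    }
    add_bond(ridx[4], attach_at)
  } else if (flavor == "ring") {
    # cyclopentane head; variant 2 puckered into an envelope
    r <- ring_polygon(5, bond = 1.5, centre = c(-2.0, 0.6), phase = pi / 5)
    pucker <- if (variant == 2L) 0.8 else 0
    ridx <- vapply(seq_len(5), function(i) {
      z <- if (i == 1) pucker else 0
      add_atom("C", c(r[i, ], z))
    }, integer(1))
    for (i in seq_len(5)) add_bond(ridx[i], ridx[(i %% 5) + 1])
    add_bond(ridx[3], attach_at)
  }
  pb_mol(id, atoms, bonds)
}

ring_polygon <- function(k, bond = 1.5, centre = c(0, 0), phase = 0) {
  r <- bond / (2 * sin(pi / k))
  th <- phase + 2 * pi * (seq_len(k) - 1) / k
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# proper rigid motion of all coordinates
rigid_motion <- function(mol, angles = c(0.3, 0.5, 0.7),
                         translation = c(1, 2, 3)) {
  rx <- rot3(angles[1], 1); ry <- rot3(angles[2], 2); rz <- rot3(angles[3], 3)
  r <- rz %*% ry %*% rx
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(r)
  xyz <- sweep(xyz, 2, translation, FUN = "+")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

rot3 <- function(theta, axis) {
  c_ <- cos(theta); s_ <- sin(theta)
  m <- diag(3)
  ij <- setdiff(1:3, axis)
  m[ij[1], ij[1]] <- c_; m[ij[2], ij[2]] <- c_
  m[ij[1], ij[2]] <- -s_; m[ij[2], ij[1]] <- s_
  m
}
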