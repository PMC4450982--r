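#' Match/mismatch grid over target, bioactive and decoy preparation
#'
#' Dissects a preparation effect by crossing the preparation scheme of the
#' three ingredients -- target structure, bioactive set, decoy set -- over
#' two schemes, yielding 8 docking experiments. A cell where all three
#' labels agree is a "matched" experiment. The marginal effect of each
#' factor is the mean pROC-AUC change when toggling that factor from the
#' second scheme to the first while holding the other two fixed.
#'
#' @param tables Named list of 8 best-pose-reduced `score_tbl`s. Names have
#'   the form `"target=MOE,bioactives=Maestro,decoys=MOE"`; alternatively
#'   pass any names and supply `key` columns via attributes
#'   `target_prep`/`dataset_prep` -- but the explicit naming is what the
#'   constructor [grid_key()] produces.
#' @param preps Character vector of the two scheme labels, first scheme
#'   first (its positive marginal means it is favored).
#' @return An object of class `mm_grid`: list with `cells` (tibble: the
#'   three factor labels, `matched`, `auc`) and `marginals` (tibble:
#'   `factor`, `mean_delta`).
#' @export
match_mismatch_grid <- function(tables, preps = c("MOE", "Maestro")) {
  stopifnot(length(preps) == 2)
  expected <- expand.grid(
    target = preps, bioactives = preps, decoys = preps,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  keys <- grid_key(expected$target, expected$bioactives, expected$decoys)
  missing <- setdiff(keys, names(tables))
  if (length(missing) > 0) {
    stop("missing grid combination(s): ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  cells <- expected
  cells$auc <- vapply(keys, function(k) proc_auc(tables[[k]])$auc, numeric(1))
  cells$matched <- cells$target == cells$bioactives &
    cells$bioactives == cells$decoys
  cells <- tibble::as_tibble(cells)

  marginal <- function(factor_col) {
    others <- setdiff(c("target", "bioactives", "decoys"), factor_col)
    joined <- merge(
      cells[cells[[factor_col]] == preps[1], c(others, "auc")],
      cells[cells[[factor_col]] == preps[2], c(others, "auc")],
      by = others, suffixes = c("_first", "_second")
    )
    mean(joined$auc_first - joined$auc_second)
  }
  marginals <- tibble::tibble(
    factor = c("target", "bioactives", "decoys"),
    mean_delta = vapply(c("target", "bioactives", "decoys"), marginal,
                        numeric(1), USE.NAMES = FALSE)
  )
  structure(list(cells = cells, marginals = marginals, preps = preps),
            class = "mm_grid")
}

#' @rdname match_mismatch_grid
#' @param target,bioactives,decoys Scheme labels for one grid cell.
#' @export
grid_key <- function(target, bioactives, decoys) {
  sprintf("target=%s,bioactives=%s,decoys=%s", target, bioactives, decoys)
}

#' @export
print.mm_grid <- function(x, ...) {
  cat("match/mismatch grid (", x$preps[1], " vs ", x$preps[2], ")\n", sep = "")
  print(x$cells)
  cat("marginal mean deltas (first - second):\n")
  print(x$marginals)
  invisible(x)
}

#' @export
tidy.mm_grid <- function(x, ...) x$cells

#' @export
glance.mm_grid <- function(x, ...) {
  tidyr::pivot_wider(x$marginals, names_from = "factor",
                     values_from = "mean_delta", names_prefix = "delta_")
}

#' Protomer shuffling experiment
#'
#' Replaces the scores of selected molecules in a base score table by the
#' scores the *other* preparation scheme assigned them (the donor table),
#' keeping everything else fixed, then re-ranks and recomputes the
#' pROC-AUC. Comparing the resulting delta to the full between-preparation
#' delta shows how much of a preparation effect the selected molecules (for
#' example, all molecules whose protonation state differs between schemes)
#' actually carry.
#'
#' @param base,donor Best-pose-reduced `score_tbl`s over the same molecules
#'   with identical role assignments.
#' @param ids Molecule ids whose scores are swapped in from `donor`.
#' @return An object of class `shuffle_result`: list with `auc_before`,
#'   `auc_after`, `delta` (= after - before), `swapped_ids`, `swapped_roles`.
#' @export
shuffle_protomers <- function(base, donor, ids) {
  stopifnot(inherits(base, "score_tbl"), inherits(donor, "score_tbl"))
  assert_best_pose(base); assert_best_pose(donor)
  ids <- as.character(ids)
  absent <- setdiff(ids, donor$molecule_id)
  if (length(absent) > 0) {
    stop("ids absent from donor table: ",
         paste(utils::head(absent, 10), collapse = ", "), call. = FALSE)
  }
  absent_base <- setdiff(ids, base$molecule_id)
  if (length(absent_base) > 0) {
    stop("ids absent from base table: ",
         paste(utils::head(absent_base, 10), collapse = ", "), call. = FALSE)
  }
  auc_before <- proc_auc(base)$auc
  shuffled <- tibble::as_tibble(base)
  idx <- match(ids, shuffled$molecule_id)
  shuffled$score[idx] <- donor$score[match(ids, donor$molecule_id)]
  shuffled <- restore_score_tbl(shuffled, base)
  auc_after <- proc_auc(shuffled)$auc
  structure(
    list(auc_before = auc_before, auc_after = auc_after,
         delta = auc_after - auc_before, swapped_ids = ids,
         swapped_roles = unique(base$role[idx])),
    class = "shuffle_result"
  )
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(
    "shuffled %d molecule(s): pROC-AUC %.4f -> %.4f (delta %+.4f)\n",
    length(x$swapped_ids), x$auc_before, x$auc_after, x$delta))
  invisible(x)
}

#' Delete molecules and recompute the pROC-AUC
#'
#' Removes the given molecules from the benchmark entirely -- set sizes,
#' decoy fractions and the `1/N_d` floor all update -- and recomputes the
#' area. Equivalent to computing [proc_auc()] on a freshly built table
#' without those molecules.
#'
#' @param table A best-pose-reduced `score_tbl`.
#' @param ids Molecule ids to delete; each must exist, and at least one
#'   bioactive and one decoy must remain.
#' @return A `proc_result` for the reduced set.
#' @export
delete_and_rescore <- function(table, ids) {
  stopifnot(inherits(table, "score_tbl"))
  assert_best_pose(table)
  ids <- as.character(ids)
  absent <- setdiff(ids, table$molecule_id)
  if (length(absent) > 0) {
    stop("ids not in table: ", paste(utils::head(absent, 10), collapse = ", "),
         call. = FALSE)
  }
  kept <- tibble::as_tibble(table)[!table$molecule_id %in% ids, ]
  if (sum(kept$role == "bioactive") < 1 || sum(kept$role == "decoy") < 1) {
    stop("deletion would empty a role class", call. = FALSE)
  }
  proc_auc(restore_score_tbl(kept, table))
}

#' Per-molecule rank and score shifts between two preparations
#'
#' Joins two score tables of the same benchmark under different preparation
#' schemes and reports, per molecule, the global docking rank (bioactives
#' and decoys pooled) in each, the rank shift, and the score (fitness)
#' shift. The summary gives preference fractions (share of molecules
#' scoring better in each scheme, exact ties counting half to each side),
#' five-number rank and score statistics per role (quartiles by linear
#' interpolation, R's default quantile definition), and squared Pearson
#' correlations of paired scores and paired ranks.
#'
#' @param first,second Best-pose-reduced `score_tbl`s over identical
#'   molecule ids and roles.
#' @return An object of class `rank_shift`: list with `records` (tibble:
#'   `molecule_id`, `role`, `score_first`, `score_second`, `delta_fitness`,
#'   `rank_first`, `rank_second`, `delta_rank`), `summary` (preference
#'   fractions and R^2 values) and `box_stats` (per role and preparation).
#' @export
rank_shift_analysis <- function(first, second) {
  stopifnot(inherits(first, "score_tbl"), inherits(second, "score_tbl"))
  assert_best_pose(first); assert_best_pose(second)
  only_first <- setdiff(first$molecule_id, second$molecule_id)
  only_second <- setdiff(second$molecule_id, first$molecule_id)
  if (length(only_first) > 0 || length(only_second) > 0) {
    stop("molecule id mismatch; only in first: ",
         paste(utils::head(only_first, 5), collapse = ", "),
         " | only in second: ",
         paste(utils::head(only_second, 5), collapse = ", "), call. = FALSE)
  }
  r1 <- rank_list(first)
  r2 <- rank_list(second)
  rec <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(r1), "molecule_id", "role",
                  score_first = "score", rank_first = "rank"),
    dplyr::select(tibble::as_tibble(r2), "molecule_id",
                  score_second = "score", rank_second = "rank"),
    by = "molecule_id"
  )
  role_first <- stats::setNames(first$role, first$molecule_id)
  if (!identical(unname(role_first[rec$molecule_id]), rec$role)) {
    stop("role assignments differ between the two tables", call. = FALSE)
  }
  rec$delta_fitness <- rec$score_first - rec$score_second
  rec$delta_rank <- rec$rank_first - rec$rank_second

  hib <- orientation(first) == "higher_is_better"
  better_first <- function(a, b) {
    d <- if (hib) a - b else b - a
    dplyr::case_when(is.na(d) ~ 0.5, d > 0 ~ 1, d < 0 ~ 0, TRUE ~ 0.5)
  }
  pref <- rec |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(
      frac_better_score_first =
        mean(better_first(.data$score_first, .data$score_second)),
      frac_better_rank_first =
        mean(dplyr::case_when(.data$delta_rank < 0 ~ 1,
                              .data$delta_rank > 0 ~ 0,
                              TRUE ~ 0.5)),
      .groups = "drop"
    )
  r2_of <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok]) ^ 2
  }
  summary <- tibble::tibble(
    r2_score = r2_of(rec$score_first, rec$score_second),
    r2_rank = r2_of(rec$rank_first, rec$rank_second)
  )
  five <- function(x) {
    q <- stats::quantile(x, probs = c(0, .25, .5, .75, 1), na.rm = TRUE,
                         type = 7, names = FALSE)
    tibble::tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }
  box_stats <- rec |>
    tidyr::pivot_longer(cols = c("rank_first", "rank_second",
                                 "score_first", "score_second"),
                        names_to = c("what", "prep"), names_sep = "_") |>
    dplyr::group_by(.data$role, .data$what, .data$prep) |>
    dplyr::reframe(five(.data$value))

  structure(list(records = rec, preference = pref, summary = summary,
                 box_stats = box_stats,
                 preps = c(attr(first, "dataset_prep"),
                           attr(second, "dataset_prep"))),
            class = "rank_shift")
}

#' @export
print.rank_shift <- function(x, ...) {
  cat(sprintf("rank/score shift over %d molecules (%s vs %s)\n",
              nrow(x$records), x$preps[1], x$preps[2]))
  print(x$preference)
  print(x$summary)
  invisible(x)
}

#' @export
tidy.rank_shift <- function(x, ...) x$records

#' @export
glance.rank_shift <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tidyr::pivot_wider(x$preference, names_from = "role",
                       values_from = c("frac_better_score_first",
                                       "frac_better_rank_first"))
  )
}

#' Flag molecules with large global rank shifts
#'
#' Selects molecules whose absolute global rank shift exceeds a cutoff
#' (default 500) and annotates each with the available structural causes:
#' a protonation, tautomer or ring-conformation difference between the two
#' preparations, high flexibility (rotatable-bond count above
#' `flexible_above`, default 8), or none of these.
#'
#' @param records The `records` tibble of a [rank_shift_analysis()] (or the
#'   `rank_shift` object itself).
#' @param cutoff Positive integer rank-shift cutoff.
#' @param causes Optional tibble with `molecule_id` and any of the logical
#'   columns `differs_protonation`, `differs_tautomer`,
#'   `differs_ring_conformation`, and numeric `n_rot`.
#' @param flexible_above Rotatable-bond count above which a molecule counts
#'   as highly flexible.
#' @return Tibble of flagged molecules with a `cause` column, one row per
#'   molecule and applicable cause (`"none"` when nothing applies).
#' @export
flag_rank_outliers <- function(records, cutoff = 500, causes = NULL,
                               flexible_above = 8) {
  if (inherits(records, "rank_shift")) records <- records$records
  stopifnot(cutoff >= 1)
  out <- records[abs(records$delta_rank) > cutoff, , drop = FALSE]
  out <- tibble::as_tibble(out)
  if (nrow(out) == 0) {
    out$cause <- character(0)
    return(out)
  }
  if (!is.null(causes)) {
    out <- dplyr::left_join(out, tibble::as_tibble(causes),
                            by = "molecule_id")
  }
  get_flag <- function(col) {
    if (col %in% names(out)) !is.na(out[[col]]) & out[[col]] else
      rep(FALSE, nrow(out))
  }
  prot <- get_flag("differs_protonation")
  taut <- get_flag("differs_tautomer")
  ring <- get_flag("differs_ring_conformation")
  flex <- if ("n_rot" %in% names(out)) {
    !is.na(out$n_rot) & out$n_rot > flexible_above
  } else {
    rep(FALSE, nrow(out))
  }
  cause_list <- purrr::pmap(list(prot, taut, ring, flex), function(p, t, r, f) {
    c("protonation"[p], "tautomer"[t], "ring_conformation"[r],
      "high_flexibility"[f]) %||na% "none"
  })
  out$cause <- vapply(cause_list, paste, character(1), collapse = "+")
  out
}

`%||na%` <- function(x, default) if (length(x) == 0) default else x

#' Isolate the worst outliers from a paired-score correlation
#'
#' Given paired scores of the same molecules under two preparations, fits
#' the identity-direction line (slope fixed at 1, intercept the mean of
#' second minus first), removes the point with the largest orthogonal
#' residual, refits, and repeats `k` times. This operationalizes the visual
#' "red dots" selection used in preparation studies: the removed points are
#' the molecules whose scores diverge most between schemes; the retained
#' core typically shows a much higher squared correlation. If properties
#' are supplied (e.g. rotatable-bond or heavy-atom counts), the outlier
#' subset's score divergence is correlated against each.
#'
#' @param paired A tibble with columns `molecule_id`, `score_first`,
#'   `score_second` (e.g. the records of [rank_shift_analysis()]).
#' @param k Number of outliers to remove (`0 < k < nrow(paired)`). Residual
#'   ties are broken by id order.
#' @param properties Optional tibble with `molecule_id` and numeric
#'   property columns.
#' @return List with `outlier_ids`, `core_ids`, `r2_core` (squared Pearson
#'   correlation of the retained pairs) and `r2_outlier_vs_property`
#'   (tibble, one row per property: squared correlation of |delta_fitness|
#'   of the outliers with the property).
#' @export
isolate_outlier_subset <- function(paired, k, properties = NULL) {
  stopifnot(all(c("molecule_id", "score_first", "score_second") %in%
                  names(paired)))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k >= nrow(paired)) stop("k must be smaller than the number of molecules",
                              call. = FALSE)
  keep <- tibble::as_tibble(paired)
  keep <- keep[order(keep$molecule_id), ]
  removed <- character(0)
  for (i in seq_len(k)) {
    intercept <- mean(keep$score_second - keep$score_first)
    res <- abs(keep$score_second - keep$score_first - intercept) / sqrt(2)
    worst <- which.max(res)  # first index on ties = id order
    removed <- c(removed, keep$molecule_id[worst])
    keep <- keep[-worst, ]
  }
  r2_core <- stats::cor(keep$score_first, keep$score_second) ^ 2
  r2_prop <- NULL
  if (!is.null(properties)) {
    out_df <- tibble::as_tibble(paired)
    out_df <- out_df[out_df$molecule_id %in% removed, ]
    out_df$delta_abs <- abs(out_df$score_first - out_df$score_second)
    out_df <- dplyr::left_join(out_df, tibble::as_tibble(properties),
                               by = "molecule_id")
    prop_cols <- setdiff(names(properties), "molecule_id")
    r2_prop <- tibble::tibble(
      property = prop_cols,
      r2 = vapply(prop_cols, function(p) {
        v <- out_df[[p]]
        if (stats::sd(v) == 0 || stats::sd(out_df$delta_abs) == 0) {
          return(NA_real_)
        }
        stats::cor(out_df$delta_abs, v) ^ 2
      }, numeric(1))
    )
  }
  list(outlier_ids = removed, core_ids = keep$molecule_id,
       r2_core = r2_core, r2_outlier_vs_property = r2_prop)
}
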