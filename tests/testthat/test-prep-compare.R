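grid_tables <- function(base, preps = c("P1", "P2"), bonus_bio = 0,
                        bonus_dec = 0, bonus_target = 0) {
  # build 8 tables from one base; a bonus raises bioactive (or decoy, or
  # everyone: target factor) scores whenever that factor is at preps[1]
  tabs <- list()
  for (t in preps) for (bi in preps) for (d in preps) {
    df <- tibble::as_tibble(base)
    if (bi == preps[1]) {
      df$score[df$role == "bioactive"] <-
        df$score[df$role == "bioactive"] + bonus_bio
    }
    if (d == preps[1]) {
      df$score[df$role == "decoy"] <- df$score[df$role == "decoy"] + bonus_dec
    }
    if (t == preps[1]) df$score <- df$score + bonus_target
    tabs[[grid_key(t, bi, d)]] <- score_table(
      df, orientation = "higher_is_better")
  }
  tabs
}

test_that("an all-identical grid has equal cells and zero marginals", {
  base <- random_table(8, 60, seed = 31)
  g <- match_mismatch_grid(grid_tables(base), preps = c("P1", "P2"))
  expect_equal(length(unique(round(g$cells$auc, 12))), 1)
  expect_equal(g$marginals$mean_delta, rep(0, 3))
  expect_equal(sum(g$cells$matched), 2)
})

test_that("a bioactives-only score bonus dominates the grid marginals", {
  base <- random_table(10, 100, seed = 32)
  g <- match_mismatch_grid(
    grid_tables(base, bonus_bio = 0.3, bonus_target = 0.0),
    preps = c("P1", "P2"))
  m <- stats::setNames(g$marginals$mean_delta, g$marginals$factor)
  expect_gt(m[["bioactives"]], 0)
  expect_gt(abs(m[["bioactives"]]), abs(m[["target"]]))
  expect_gt(abs(m[["bioactives"]]), abs(m[["decoys"]]))
  # a uniform target-side shift never changes within-cell ranking
  g2 <- match_mismatch_grid(
    grid_tables(base, bonus_target = 5), preps = c("P1", "P2"))
  m2 <- stats::setNames(g2$marginals$mean_delta, g2$marginals$factor)
  expect_equal(m2[["target"]], 0)
})

test_that("independent random tables give marginals near zero", {
  set.seed(33)
  tabs <- list()
  for (t in c("P1", "P2")) for (bi in c("P1", "P2")) for (d in c("P1", "P2")) {
    tabs[[grid_key(t, bi, d)]] <- random_table(40, 400)
  }
  g <- match_mismatch_grid(tabs, preps = c("P1", "P2"))
  expect_true(all(abs(g$marginals$mean_delta) < 0.25))
})

test_that("grid marginals agree between cell averaging and direct toggling", {
  bench <- small_paired_benchmark(seed = 34)
  base <- bench$table_first
  tabs <- grid_tables(base, bonus_bio = 0.4, bonus_dec = 0.2,
                      bonus_target = 0.1)
  g <- match_mismatch_grid(tabs, preps = c("P1", "P2"))
  aucs <- stats::setNames(g$cells$auc,
                          grid_key(g$cells$target, g$cells$bioactives,
                                   g$cells$decoys))
  # independent recomputation: average the 4 toggle pairs per factor
  toggle <- function(fac) {
    combos <- expand.grid(t = c("P1", "P2"), b = c("P1", "P2"),
                          d = c("P1", "P2"), stringsAsFactors = FALSE)
    combos <- combos[combos[[fac]] == "P1", ]
    mean(vapply(seq_len(nrow(combos)), function(i) {
      hi <- combos[i, ]
      lo <- hi; lo[[fac]] <- "P2"
      aucs[[grid_key(hi$t, hi$b, hi$d)]] - aucs[[grid_key(lo$t, lo$b, lo$d)]]
    }, numeric(1)))
  }
  expect_equal(g$marginals$mean_delta,
               c(toggle("t"), toggle("b"), toggle("d")))
  # missing combination is named in the error
  expect_error(match_mismatch_grid(tabs[-3], preps = c("P1", "P2")),
               "missing grid combination")
})

test_that("protomer shuffling swaps scores, and shuffling back restores", {
  bench <- small_paired_benchmark(seed = 35)
  base <- bench$table_first
  donor <- bench$table_second

  empty <- shuffle_protomers(base, donor, character(0))
  expect_identical(empty$delta, 0)

  full <- shuffle_protomers(base, donor, base$molecule_id)
  expect_equal(full$auc_after, proc_auc(donor)$auc)

  ids <- bench$truth$molecule_id[bench$truth$differs_protonation]
  once <- shuffle_protomers(base, donor, ids)
  # build the shuffled table and swap back from the original
  shuffled <- tibble::as_tibble(base)
  shuffled$score[match(ids, shuffled$molecule_id)] <-
    donor$score[match(ids, donor$molecule_id)]
  shuffled <- score_table(shuffled, orientation = "higher_is_better")
  back <- shuffle_protomers(shuffled, base, ids)
  expect_equal(back$auc_after, once$auc_before)

  expect_error(shuffle_protomers(base, donor, "nonexistent"), "absent")
})

test_that("deletion updates counts and floor and matches fresh computation", {
  tbl <- tiny_table(scores_active = c(12, 8.5), scores_decoy = 11:2)
  # delete nothing: identical result
  same <- delete_and_rescore(tbl, character(0))
  expect_equal(same$auc, proc_auc(tbl)$auc)

  # delete the last-ranked decoy: matches brute force on the reduced set
  last_decoy <- "d10"
  res <- delete_and_rescore(tbl, last_decoy)
  kept <- tibble::as_tibble(tbl)[tbl$molecule_id != last_decoy, ]
  expect_equal(res$auc, oracle_proc_auc(kept$role, kept$score))
  expect_equal(res$n_decoys, 9)

  # delete the top active of two: remaining area is one log term
  res2 <- delete_and_rescore(tbl, "a1")
  kept2 <- tibble::as_tibble(tbl)[tbl$molecule_id != "a1", ]
  f <- sum(kept2$score[kept2$role == "decoy"] > 8.5) / 10
  expect_equal(res2$auc, log10(1 / f))

  # construction-path independence on a larger set
  bench <- small_paired_benchmark(seed = 36)
  drop <- bench$truth$molecule_id[c(3, 20, 41)]
  direct <- delete_and_rescore(bench$table_first, drop)
  fresh <- proc_auc(score_table(
    tibble::as_tibble(bench$table_first)[
      !bench$table_first$molecule_id %in% drop, ],
    orientation = "higher_is_better"))
  expect_equal(direct$auc, fresh$auc)

  expect_error(delete_and_rescore(tbl, "zz"), "not in table")
  expect_error(delete_and_rescore(tbl, c("a1", "a2")), "empty a role")
})

test_that("identical inputs give zero shifts, even preferences and R2 = 1", {
  tbl <- random_table(6, 40, seed = 37)
  rs <- rank_shift_analysis(tbl, tbl)
  expect_true(all(rs$records$delta_rank == 0))
  expect_true(all(rs$records$delta_fitness == 0))
  expect_true(all(rs$preference$frac_better_score_first == 0.5))
  expect_true(all(rs$preference$frac_better_rank_first == 0.5))
  expect_equal(rs$summary$r2_score, 1)
  expect_equal(rs$summary$r2_rank, 1)
})

test_that("swapping two scores shifts exactly those molecules", {
  tbl <- tiny_table(scores_active = c(12, 8), scores_decoy = 11:2)
  swapped <- tibble::as_tibble(tbl)
  i <- match(c("d02", "d03"), swapped$molecule_id)
  swapped$score[i] <- swapped$score[rev(i)]
  swapped <- score_table(swapped, orientation = "higher_is_better")
  rs <- rank_shift_analysis(tbl, swapped)
  moved <- rs$records$molecule_id[rs$records$delta_rank != 0]
  expect_setequal(moved, c("d02", "d03"))
  expect_equal(sum(rs$records$delta_rank), 0)
})

test_that("rank shift analysis is antisymmetric in its inputs", {
  bench <- small_paired_benchmark(seed = 38)
  ab <- rank_shift_analysis(bench$table_first, bench$table_second)
  ba <- rank_shift_analysis(bench$table_second, bench$table_first)
  ord <- match(ab$records$molecule_id, ba$records$molecule_id)
  expect_equal(ab$records$delta_rank, -ba$records$delta_rank[ord])
  expect_equal(ab$records$delta_fitness, -ba$records$delta_fitness[ord])
  expect_equal(ab$summary$r2_score, ba$summary$r2_score)

  mismatched <- score_table(
    dplyr::mutate(tibble::as_tibble(bench$table_first)[-1, ]),
    orientation = "higher_is_better")
  expect_error(rank_shift_analysis(bench$table_first, mismatched),
               "mismatch")
})

test_that("rank outlier flagging applies the cutoff and cause annotations", {
  rec <- tibble::tibble(
    molecule_id = sprintf("m%02d", 1:20),
    role = "decoy",
    delta_rank = c(rep(10, 19), 0)
  )
  expect_equal(nrow(flag_rank_outliers(rec, cutoff = 500)), 0)

  rec$delta_rank[3] <- 600
  hit <- flag_rank_outliers(rec, cutoff = 500)
  expect_equal(hit$molecule_id, "m03")
  expect_equal(hit$cause, "none")

  # a 13-molecule census with mixed causes: 4 protonation, 1 tautomer,
  # 2 ring, 6 with no structural difference of which 3 are highly flexible
  rec2 <- tibble::tibble(
    molecule_id = sprintf("o%02d", 1:15), role = "decoy",
    delta_rank = c(rep(700, 13), 100, -200)
  )
  causes <- tibble::tibble(
    molecule_id = sprintf("o%02d", 1:15),
    differs_protonation = c(rep(TRUE, 4), rep(FALSE, 11)),
    differs_tautomer = c(rep(FALSE, 4), TRUE, rep(FALSE, 10)),
    differs_ring_conformation = c(rep(FALSE, 5), TRUE, TRUE, rep(FALSE, 8)),
    n_rot = c(rep(2L, 7), rep(12L, 3), rep(3L, 5))
  )
  flagged <- flag_rank_outliers(rec2, cutoff = 500, causes = causes)
  expect_equal(nrow(flagged), 13)
  tally <- table(flagged$cause)
  expect_equal(as.integer(tally[c("protonation", "tautomer",
                                  "ring_conformation", "high_flexibility",
                                  "none")]),
               c(4L, 1L, 2L, 3L, 3L))
})

test_that("outlier isolation removes planted divergent points exactly", {
  # perfectly correlated pairs: core R2 = 1, ties broken by id order
  perf <- tibble::tibble(
    molecule_id = sprintf("p%02d", 1:10),
    score_first = 1:10, score_second = 1:10 + 5
  )
  iso <- isolate_outlier_subset(perf, k = 2)
  expect_equal(iso$r2_core, 1)
  expect_equal(iso$outlier_ids, c("p01", "p02"))

  # 30 collinear points plus 10 planted offsets
  set.seed(39)
  core <- tibble::tibble(
    molecule_id = sprintf("c%02d", 1:30),
    score_first = seq(50, 110, length.out = 30)
  )
  core$score_second <- core$score_first + 3
  planted <- tibble::tibble(
    molecule_id = sprintf("x%02d", 1:10),
    score_first = stats::runif(10, 60, 100)
  )
  planted$score_second <- planted$score_first + 3 +
    sample(c(-1, 1), 10, TRUE) * stats::runif(10, 8, 20)
  all_pts <- dplyr::bind_rows(core, planted)
  iso2 <- isolate_outlier_subset(all_pts, k = 10)
  expect_setequal(iso2$outlier_ids, planted$molecule_id)
  expect_equal(iso2$r2_core, 1)

  # flexibility-coupled divergence: outliers correlate with rotor count
  props <- tibble::tibble(
    molecule_id = all_pts$molecule_id,
    n_rot = c(rep(3L, 30), 5:14)
  )
  planted$score_second <- planted$score_first + 3 - (5:14) * 1.5
  all_pts2 <- dplyr::bind_rows(core, planted)
  iso3 <- isolate_outlier_subset(all_pts2, k = 10, properties = props)
  expect_gt(iso3$r2_outlier_vs_property$r2[1], iso3$r2_core - 1e-9)
  expect_gt(iso3$r2_outlier_vs_property$r2[1], 0.9)

  expect_error(isolate_outlier_subset(perf, k = 0), "positive")
  expect_error(isolate_outlier_subset(perf, k = 10), "smaller")
})
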