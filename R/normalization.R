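#' Heavy-atom score normalization
#'
#' Empirical docking scoring functions are additive and tend to reward
#' molecular size, biasing score-ranked lists toward heavy molecules. A
#' standard correction divides the score by a power of the heavy-atom count
#' N: `sqrt_nha` divides by N^(1/2), `nha_two_thirds` by N^(2/3) (the cubic
#' root of the squared count, penalizing size more strongly), `none` leaves
#' scores untouched.
#'
#' @param score Numeric score(s); `NA` (failed docking) propagates.
#' @param nha Heavy-atom count(s), integer >= 1.
#' @param mode One of `"none"`, `"sqrt_nha"`, `"nha_two_thirds"`.
#' @return Normalized score(s).
#' @examples
#' normalize_score(100, 25, "sqrt_nha") # 20
#' @export
normalize_score <- function(score, nha,
                            mode = c("none", "sqrt_nha", "nha_two_thirds")) {
  mode <- match.arg(mode)
  if (any(!is.na(nha) & (nha < 1 | nha != round(nha)))) {
    stop("nha must be a positive integer", call. = FALSE)
  }
  score / nha ^ normalization_exponent(mode)
}

normalization_exponent <- function(mode) {
  switch(mode, none = 0, sqrt_nha = 1 / 2, nha_two_thirds = 2 / 3)
}

#' Normalize every score in a table by heavy-atom count
#'
#' Normalization always applies to the whole ranked set, bioactives and
#' decoys alike; normalizing a subset would not be a rank transformation of
#' anything meaningful and is not offered. Dividing a mixed-sign score
#' column changes relative order ambiguously, so tables whose scores span
#' zero are refused unless `force = TRUE` (fitness functions are positive,
#' docking energies negative; a mixture indicates an upstream problem).
#'
#' @param table A best-pose-reduced `score_tbl`.
#' @param nha_map Heavy-atom counts: a named numeric vector (names are
#'   molecule ids) or a data frame with columns `molecule_id` and `nha`.
#' @param mode Normalization mode, see [normalize_score()].
#' @param force Allow mixed-sign score columns.
#' @return A new `score_tbl` with normalized scores (column `score`) and the
#'   original scores preserved in `score_original`; the input is untouched.
#' @export
normalize_table <- function(table, nha_map,
                            mode = c("none", "sqrt_nha", "nha_two_thirds"),
                            force = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "score_tbl"))
  assert_best_pose(table)
  nha_map <- as_nha_lookup(nha_map)
  scored <- table$molecule_id[!is.na(table$score)]
  missing_nha <- setdiff(scored, names(nha_map))
  if (length(missing_nha) > 0) {
    stop("missing heavy-atom count for: ",
         paste(utils::head(missing_nha, 10), collapse = ", "),
         if (length(missing_nha) > 10) " ..." else "", call. = FALSE)
  }
  if (mode != "none" && !force) {
    rng <- range(table$score, na.rm = TRUE)
    if (rng[1] < 0 && rng[2] > 0) {
      stop("score column mixes signs; heavy-atom normalization would ",
           "reorder ambiguously (use force = TRUE to override)",
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(table)
  out$score_original <- out$score
  out$nha <- unname(nha_map[out$molecule_id])
  out$score <- normalize_score(out$score_original, out$nha, mode)
  restore_score_tbl(out, table)
}

as_nha_lookup <- function(nha_map) {
  if (is.data.frame(nha_map)) {
    stopifnot(all(c("molecule_id", "nha") %in% names(nha_map)))
    stats::setNames(nha_map$nha, nha_map$molecule_id)
  } else {
    stopifnot(!is.null(names(nha_map)))
    nha_map
  }
}

#' Normalization delta of two pROC-AUC values
#'
#' Defined as normalized minus original: positive values mean normalization
#' improved early enrichment.
#'
#' @param auc_normalized,auc_original pROC-AUC before/after normalization.
#' @return `auc_normalized - auc_original`.
#' @export
delta_proc_norm <- function(auc_normalized, auc_original) {
  stopifnot(is.finite(auc_normalized), is.finite(auc_original))
  auc_normalized - auc_original
}

#' Usage guideline for heavy-atom normalization
#'
#' Benchmark surveys of GOLD (ChemPLP) docking show that the benefit of
#' heavy-atom normalization depends on the mean size of the bioactive set:
#' N^(1/2) tends to help at a mean heavy-atom count of 30 or below and to
#' hurt above it; N^(2/3) tends to help below 28 with a high risk of harm
#' from 29 upward (means strictly between 28 and 29 fall in a gap with no
#' evidence either way).
#'
#' @param mean_nha Mean heavy-atom count of the bioactive set (> 0).
#' @return A tibble with one row per mode (`sqrt_nha`, `nha_two_thirds`) and
#'   a `recommendation` of `"recommend"`, `"risky"` or `"neutral"`.
#' @examples
#' recommend_mode(27.6)
#' @export
recommend_mode <- function(mean_nha) {
  stopifnot(is.finite(mean_nha), mean_nha > 0)
  sqrt_rec <- if (mean_nha <= 30) "recommend" else "risky"
  tt_rec <- if (mean_nha <= 28) {
    "recommend"
  } else if (mean_nha >= 29) {
    "risky"
  } else {
    "neutral"
  }
  tibble::tibble(
    mode = c("sqrt_nha", "nha_two_thirds"),
    mean_nha = mean_nha,
    recommendation = c(sqrt_rec, tt_rec)
  )
}

#' Full normalization report for one score table
#'
#' Computes pROC-AUC before and after normalization, the normalization
#' delta, the mean heavy-atom count of the bioactive set, and the usage
#' recommendation for the chosen mode.
#'
#' @inheritParams normalize_table
#' @return An object of class `norm_report`: tibble with one row
#'   (`auc_original`, `auc_normalized`, `delta_n`, `mean_nha`,
#'   `recommendation`, `mode`).
#' @export
normalization_report <- function(table, nha_map,
                                 mode = c("sqrt_nha", "nha_two_thirds"),
                                 force = FALSE) {
  mode <- match.arg(mode)
  normed <- normalize_table(table, nha_map, mode = mode, force = force)
  auc0 <- proc_auc(table)$auc
  auc1 <- proc_auc(normed)$auc
  lookup <- as_nha_lookup(nha_map)
  act_ids <- table$molecule_id[table$role == "bioactive"]
  mean_nha <- mean(unname(lookup[act_ids]), na.rm = TRUE)
  rec <- recommend_mode(mean_nha)
  out <- tibble::tibble(
    mode = mode,
    auc_original = auc0,
    auc_normalized = auc1,
    delta_n = delta_proc_norm(auc1, auc0),
    mean_nha = mean_nha,
    recommendation = rec$recommendation[rec$mode == mode]
  )
  class(out) <- c("norm_report", class(out))
  out
}
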