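#' Rank a score table best-to-worst
#'
#' Orders molecules under the table's score orientation and computes, for
#' every bioactive, the fraction of decoys ranked above it. Three
#' conventions, stated here because they matter for reproducibility:
#'
#' * Global ranks are a strict permutation `1..(N_a + N_d)`; exact score ties
#'   are broken by `molecule_id` order so results are deterministic.
#' * The decoy fraction `f_i` of bioactive `i` counts decoys *strictly*
#'   better than `i`, plus half of any decoys with exactly equal score
#'   (average-rank convention -- unbiased in expectation), divided by the
#'   number of decoys. Other bioactives never enter the denominator.
#' * `f_i` is floored at `1/N_d` so a bioactive beating every decoy
#'   contributes `log10(N_d)` to the pROC-AUC, and molecules that failed to
#'   dock (missing score) are ranked strictly worst, after all scored
#'   molecules, ties among them broken by id.
#'
#' @param table A best-pose-reduced `score_tbl`.
#' @param floor Lower bound applied to the decoy fraction; default `1/N_d`.
#' @return A tibble of class `pb_ranking` with columns `molecule_id`, `role`,
#'   `score`, `rank`, `decoy_fraction` (`NA` for decoys) and attributes
#'   `n_actives`, `n_decoys`, `orientation`, `floor`.
#' @export
rank_list <- function(table, floor = NULL) {
  stopifnot(inherits(table, "score_tbl"))
  assert_best_pose(table)
  if (nrow(table) == 0) stop("cannot rank an empty score table", call. = FALSE)
  n_a <- sum(table$role == "bioactive")
  n_d <- sum(table$role == "decoy")
  if (n_a < 1 || n_d < 1) {
    stop("ranking requires at least one bioactive and one decoy", call. = FALSE)
  }
  hib <- orientation(table) == "higher_is_better"
  # signed score: larger is always better; NA (failed docking) sorts last
  s <- if (hib) table$score else -table$score
  ord <- order(-s, is.na(s), table$molecule_id, na.last = TRUE)
  out <- tibble::as_tibble(table)[ord, c("molecule_id", "role", "score")]
  out$rank <- seq_len(nrow(out))

  floor <- floor %||% (1 / n_d)
  s_sorted <- s[ord]
  is_decoy <- out$role == "decoy"
  dec_scores <- s_sorted[is_decoy & !is.na(s_sorted)]
  n_missing_decoys_before <- function(i) {
    # missing-score decoys preceding position i in the strict order
    sum(is_decoy[seq_len(i - 1)] & is.na(s_sorted[seq_len(i - 1)]))
  }
  f <- rep(NA_real_, nrow(out))
  for (i in which(out$role == "bioactive")) {
    if (is.na(s_sorted[i])) {
      # failed active: all scored decoys beat it, plus missing decoys ahead
      above <- length(dec_scores) + n_missing_decoys_before(i)
    } else {
      above <- sum(dec_scores > s_sorted[i]) +
        0.5 * sum(dec_scores == s_sorted[i])
    }
    f[i] <- max(min(above / n_d, 1), floor)
  }
  out$decoy_fraction <- f
  attr(out, "n_actives") <- n_a
  attr(out, "n_decoys") <- n_d
  attr(out, "orientation") <- orientation(table)
  attr(out, "floor") <- floor
  class(out) <- c("pb_ranking", class(tibble::tibble()))
  out
}

#' pROC-AUC: semi-logarithmic ROC area with early-recognition emphasis
#'
#' The pROC curve is the ROC curve with its false-positive axis
#' log10-transformed, so bioactives recovered very early (tiny decoy
#' fraction) dominate the area. With `f_i` the (floored) fraction of decoys
#' ranked above bioactive `i`, the area is
#' \deqn{\mathrm{pROC\mbox{-}AUC} = \frac{1}{N_a} \sum_i \log_{10}(1/f_i).}
#' Random scoring gives an expectation of `log10(e)` (about 0.434) and
#' perfect separation attains `log10(N_d)` exactly (the `1/N_d` floor).
#'
#' @param ranked A `pb_ranking` from [rank_list()], or a best-pose-reduced
#'   `score_tbl` (ranked internally).
#' @param floor Optional decoy-fraction floor forwarded to [rank_list()]
#'   when `ranked` is a score table.
#' @return An object of class `proc_result`: list with `auc`, `curve`
#'   (tibble: `decoy_fraction`, `log10_fpr`, `tpr`, one point per recovered
#'   bioactive), `n_actives`, `n_decoys`, `floor`.
#' @examples
#' tbl <- score_table(tibble::tibble(
#'   molecule_id = c("a1", "a2", paste0("d", 1:10)),
#'   role = c("bioactive", "bioactive", rep("decoy", 10)),
#'   score = c(12, 8, 11:2)
#' ), orientation = "higher_is_better")
#' proc_auc(tbl)$auc
#' @export
proc_auc <- function(ranked, floor = NULL) {
  if (inherits(ranked, "score_tbl")) ranked <- rank_list(ranked, floor = floor)
  stopifnot(inherits(ranked, "pb_ranking"))
  act <- ranked[ranked$role == "bioactive", ]
  f <- act$decoy_fraction
  auc <- mean(log10(1 / f))
  curve <- tibble::tibble(
    molecule_id = act$molecule_id,
    decoy_fraction = f,
    log10_fpr = log10(f),
    tpr = seq_along(f) / nrow(act)
  )
  structure(
    list(auc = auc, curve = curve,
         n_actives = attr(ranked, "n_actives"),
         n_decoys = attr(ranked, "n_decoys"),
         floor = attr(ranked, "floor")),
    class = "proc_result"
  )
}

#' @export
print.proc_result <- function(x, ...) {
  cat(sprintf("pROC-AUC = %.4f  (N_a = %d, N_d = %d, floor = %.3g)\n",
              x$auc, x$n_actives, x$n_decoys, x$floor))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for pROC results
#'
#' `tidy()` returns the curve points (one row per recovered bioactive);
#' `glance()` a one-row summary with the area and set sizes.
#'
#' @param x A `proc_result`.
#' @param ... Unused.
#' @export
tidy.proc_result <- function(x, ...) x$curve

#' @rdname tidy.proc_result
#' @export
glance.proc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_actives = x$n_actives, n_decoys = x$n_decoys,
                 floor = x$floor, auc_max = log10(x$n_decoys),
                 auc_random = log10(exp(1)))
}

#' Preparation delta of two pROC-AUC values
#'
#' Defined as first minus second; by the conventions used throughout the
#' package the first scheme is the one whose positive delta means "favored".
#'
#' @param auc_first,auc_second pROC-AUC values of the same target/program
#'   under two preparation schemes.
#' @return `auc_first - auc_second`.
#' @export
delta_proc_prep <- function(auc_first, auc_second) {
  stopifnot(is.finite(auc_first), is.finite(auc_second),
            auc_first >= 0, auc_second >= 0)
  auc_first - auc_second
}

#' Classify a preparation delta against the safety margin
#'
#' Docking heuristics (notably GOLD's genetic algorithm) show run-to-run
#' pROC-AUC scatter; deltas within a safety margin of +/-0.05 are therefore
#' treated as noise. The boundary is inclusive: `|delta| == margin` is
#' non-significant.
#'
#' @param delta A preparation delta (first minus second), or a vector.
#' @param margin Non-negative safety margin (default 0.05).
#' @return A tibble with columns `delta`, `margin` and `class`
#'   (`"favors_first"`, `"favors_second"` or `"non_significant"`).
#' @export
classify_significance <- function(delta, margin = 0.05) {
  stopifnot(margin >= 0)
  # floating-point-safe inclusive boundary: 0.75 - 0.80 must classify as
  # exactly -0.05
  tol <- sqrt(.Machine$double.eps)
  cls <- dplyr::case_when(
    abs(delta) <= margin + tol ~ "non_significant",
    delta > margin ~ "favors_first",
    TRUE ~ "favors_second"
  )
  tibble::tibble(delta = delta, margin = margin, class = cls)
}

#' Count significance classes over a set of targets
#'
#' @param deltas Named numeric vector (names are targets) or a data frame
#'   with columns `target` and `delta`.
#' @param margin Safety margin passed to [classify_significance()].
#' @return A tibble with one row: `favors_first`, `favors_second`,
#'   `non_significant`, `n_targets`.
#' @export
summarize_delta_table <- function(deltas, margin = 0.05) {
  if (is.data.frame(deltas)) {
    stopifnot(all(c("target", "delta") %in% names(deltas)))
    d <- deltas$delta
  } else {
    d <- as.numeric(deltas)
  }
  if (length(d) < 1) stop("need at least one target", call. = FALSE)
  cls <- classify_significance(d, margin)$class
  tibble::tibble(
    favors_first = sum(cls == "favors_first"),
    favors_second = sum(cls == "favors_second"),
    non_significant = sum(cls == "non_significant"),
    n_targets = length(d)
  )
}
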