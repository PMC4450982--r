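#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pROC curve
#'
#' Semi-logarithmic ROC curve: decoy fraction (false-positive rate) on a
#' log10 x axis, fraction of bioactives recovered on y. The dotted
#' diagonal is random performance.
#'
#' @param object A `proc_result`.
#' @param ... Further `proc_result`s to overlay, named for the legend.
#' @return A ggplot object.
#' @export
autoplot.proc_result <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "proc_result")]
  runs <- c(list(pROC = object), extra)
  if (is.null(names(runs)) || any(names(runs) == "")) {
    names(runs) <- paste0("run", seq_along(runs))
  }
  plot_proc_curves(runs)
}

#' @rdname autoplot.proc_result
#' @param results Named list of `proc_result`s.
#' @export
plot_proc_curves <- function(results) {
  if (inherits(results, "proc_result")) results <- list(pROC = results)
  curves <- purrr::imap_dfr(results, function(r, nm) {
    dplyr::mutate(r$curve, run = nm)
  })
  floor_min <- min(purrr::map_dbl(results, "floor"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$decoy_fraction, y = .data$tpr,
                               color = .data$run)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey40") +
    ggplot2::scale_x_log10(limits = c(floor_min, 1)) +
    ggplot2::labs(x = "decoy fraction ranked above (log scale)",
                  y = "fraction of bioactives recovered",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired scores or ranks between two preparations
#'
#' @param x A `rank_shift` object.
#' @param what `"score"` or `"rank"`.
#' @param cutoff Optional rank-shift cutoff; molecules beyond it are
#'   highlighted.
#' @return A ggplot object.
#' @export
plot_rank_shift <- function(x, what = c("score", "rank"), cutoff = NULL) {
  what <- match.arg(what)
  rec <- x$records
  if (what == "score") {
    p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$score_second,
                                           y = .data$score_first,
                                           color = .data$role))
    labs <- c(paste("score,", x$preps[2]), paste("score,", x$preps[1]))
  } else {
    p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$rank_second,
                                           y = .data$rank_first,
                                           color = .data$role))
    labs <- c(paste("global rank,", x$preps[2]),
              paste("global rank,", x$preps[1]))
  }
  p <- p + ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey40") +
    ggplot2::labs(x = labs[1], y = labs[2], color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff) && what == "rank") {
    out <- rec[abs(rec$delta_rank) > cutoff, ]
    p <- p + ggplot2::geom_point(data = out, shape = 1, size = 3,
                                 color = "red")
  }
  p
}

#' Box plot of per-role ranks or scores by preparation
#'
#' @inheritParams plot_rank_shift
#' @return A ggplot object.
#' @export
plot_shift_box <- function(x, what = c("rank", "score")) {
  what <- match.arg(what)
  rec <- tidyr::pivot_longer(
    x$records,
    cols = dplyr::all_of(paste0(what, c("_first", "_second"))),
    names_to = "prep", values_to = "value"
  )
  rec$prep <- ifelse(grepl("_first$", rec$prep), x$preps[1], x$preps[2])
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$prep, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~ .data$role, scales = "free_y") +
    ggplot2::labs(x = NULL, y = what) +
    ggplot2::theme_minimal()
}

#' Scatter of score versus heavy-atom count, before and after normalization
#'
#' @param table A best-pose-reduced `score_tbl`.
#' @param nha_map Heavy-atom counts (see [normalize_table()]).
#' @param mode Normalization mode.
#' @param role Restrict to one role (default bioactives, where the size
#'   bias is judged).
#' @return A ggplot object with a dashed mean line per panel.
#' @export
plot_normalization <- function(table, nha_map, mode = "sqrt_nha",
                               role = "bioactive") {
  normed <- normalize_table(table, nha_map, mode = mode)
  df <- tibble::as_tibble(normed)
  df <- df[df$role == role & !is.na(df$score), ]
  long <- tidyr::pivot_longer(
    df, cols = c("score_original", "score"),
    names_to = "stage", values_to = "value")
  long$stage <- ifelse(long$stage == "score_original", "original",
                       paste0("normalized (", mode, ")"))
  means <- long |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$nha, y = .data$value)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$m),
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_wrap(~ .data$stage, scales = "free_y") +
    ggplot2::labs(x = "heavy atoms (N)", y = "docking score") +
    ggplot2::theme_minimal()
}

#' Normalization delta versus mean bioactive size across targets
#'
#' @param data Tibble with columns `nha_mean` and a delta column.
#' @param delta Name of the delta column (default `delta_n12`).
#' @param margin Shaded non-significance band (default 0.05).
#' @return A ggplot object.
#' @export
plot_delta_vs_nha <- function(data, delta = "delta_n12", margin = 0.05) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$nha_mean,
                                     y = .data[[delta]])) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -margin, ymax = margin,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "mean heavy atoms per bioactive set",
                  y = "pROC-AUC change by normalization") +
    ggplot2::theme_minimal()
}

#' Plot a match/mismatch grid
#'
#' Eight pROC-AUC values arranged by dataset-preparation combination, with
#' one line per target preparation.
#'
#' @param x An `mm_grid`.
#' @return A ggplot object.
#' @export
plot_mm_grid <- function(x) {
  cells <- x$cells
  cells$combo <- paste0("bio:", cells$bioactives, "\ndec:", cells$decoys)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$combo, y = .data$auc,
                                      color = .data$target,
                                      group = .data$target)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dataset preparation", y = "pROC-AUC",
                  color = "target prep") +
    ggplot2::theme_minimal()
}
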