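#' Compare two preparation schemes across targets
#'
#' Builds the standard survey table: per target the pROC-AUC of each
#' scheme, the preparation delta (first minus second) and its significance
#' class under the safety margin, plus the census line counting targets
#' favoring each scheme.
#'
#' @param aucs A tibble with columns `target`, `auc_first`, `auc_second`
#'   (one row per target), or a named list of two-element lists of
#'   `score_tbl`s (`list(first =, second =)`), in which case the areas are
#'   computed here.
#' @param margin Safety margin (default 0.05).
#' @param labels Length-2 scheme labels used in printing.
#' @return An object of class `prep_report`: list with `table` (per-target
#'   tibble) and `census` (one-row count tibble).
#' @export
compare_preps <- function(aucs, margin = 0.05, labels = c("first", "second")) {
  if (!is.data.frame(aucs)) {
    aucs <- purrr::imap_dfr(aucs, function(pair, target) {
      tibble::tibble(
        target = target,
        auc_first = proc_auc(pair$first)$auc,
        auc_second = proc_auc(pair$second)$auc
      )
    })
  }
  stopifnot(all(c("target", "auc_first", "auc_second") %in% names(aucs)))
  if (anyDuplicated(aucs$target)) {
    stop("duplicate target in preparation comparison", call. = FALSE)
  }
  tab <- tibble::as_tibble(aucs)
  tab$delta <- mapply(delta_proc_prep, tab$auc_first, tab$auc_second)
  tab$class <- classify_significance(tab$delta, margin)$class
  census <- summarize_delta_table(
    tibble::tibble(target = tab$target, delta = tab$delta), margin)
  structure(list(table = tab, census = census, margin = margin,
                 labels = labels),
            class = "prep_report")
}

#' @export
print.prep_report <- function(x, ...) {
  cat(sprintf("preparation comparison (%s vs %s, margin %.2f)\n",
              x$labels[1], x$labels[2], x$margin))
  tab <- x$table
  tab$auc_first <- sprintf("%.2f", tab$auc_first)
  tab$auc_second <- sprintf("%.2f", tab$auc_second)
  tab$delta <- sprintf("%+.2f", tab$delta)
  print(tab, n = nrow(tab))
  cat(sprintf("census: %d favor %s / %d favor %s / %d non-significant\n",
              x$census$favors_first, x$labels[1],
              x$census$favors_second, x$labels[2],
              x$census$non_significant))
  invisible(x)
}

#' @export
tidy.prep_report <- function(x, ...) x$table

#' @export
glance.prep_report <- function(x, ...) x$census

#' Write a report as aligned text and full-precision TSV
#'
#' Every report object prints human-readable (2-decimal) numbers; the TSV
#' twin keeps full precision so the two never disagree beyond rounding.
#'
#' @param report A `prep_report`, `norm_report`, `rank_shift` or `mm_grid`.
#' @param path_tsv Output TSV path.
#' @return `path_tsv`, invisibly.
#' @export
write_report_tsv <- function(report, path_tsv) {
  tab <- if (inherits(report, "prep_report")) report$table
    else if (inherits(report, "rank_shift")) report$records
    else if (inherits(report, "mm_grid")) report$cells
    else if (is.data.frame(report)) tibble::as_tibble(report)
    else stop("unsupported report type", call. = FALSE)
  readr::write_tsv(tab, path_tsv, progress = FALSE)
  invisible(path_tsv)
}
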