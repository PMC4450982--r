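#' Construct a docking score table
#'
#' A score table holds the per-molecule results of docking one benchmark set
#' (bioactives plus decoys) into one prepared target with one program. It is
#' an ordinary tibble carrying the metadata needed to interpret the scores:
#' most importantly the score *orientation*, which is never inferred from the
#' data. GOLD ChemPLP fitness is higher-is-better; Glide SP energies are
#' lower-is-better.
#'
#' @param data A data frame with columns `molecule_id` (character), `role`
#'   (`"bioactive"` or `"decoy"`), `score` (numeric; `NA` marks a molecule
#'   that failed to dock), and optionally `pose_index` (non-negative
#'   integer).
#' @param orientation `"higher_is_better"` or `"lower_is_better"`.
#' @param program Docking program label (e.g. `"GOLD"`).
#' @param target_prep,dataset_prep Preparation-scheme labels (e.g. `"MOE"`,
#'   `"Maestro"`). A score table carries exactly one dataset preparation;
#'   cross-preparation comparisons join two tables.
#' @return A tibble of class `score_tbl` with attributes `orientation`,
#'   `program`, `target_prep`, `dataset_prep`.
#' @examples
#' score_table(
#'   tibble::tibble(
#'     molecule_id = c("a1", "d1", "d2"),
#'     role = c("bioactive", "decoy", "decoy"),
#'     score = c(10, 5, 7.5)
#'   ),
#'   orientation = "higher_is_better"
#' )
#' @export
score_table <- function(data,
                        orientation = c("higher_is_better", "lower_is_better"),
                        program = "unknown",
                        target_prep = "default",
                        dataset_prep = "default") {
  orientation <- match.arg(orientation)
  data <- tibble::as_tibble(data)
  validate_score_records(data)
  out <- data
  attr(out, "orientation") <- orientation
  attr(out, "program") <- program
  attr(out, "target_prep") <- target_prep
  attr(out, "dataset_prep") <- dataset_prep
  class(out) <- c("score_tbl", class(tibble::tibble()))
  out
}

validate_score_records <- function(data, file = NULL) {
  req <- c("molecule_id", "role", "score")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("score table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(data$role), c("bioactive", "decoy"))
  if (length(bad_role) > 0) {
    rows <- which(data$role %in% bad_role)
    stop("unknown role token(s) ", paste(unique(bad_role), collapse = ", "),
         " (data row ", rows[1], ")", call. = FALSE)
  }
  if (!is.numeric(data$score)) {
    stop("score column must be numeric (NA marks failed docking)",
         call. = FALSE)
  }
  if (any(is.infinite(data$score))) {
    stop("scores must be finite or NA", call. = FALSE)
  }
  if ("pose_index" %in% names(data)) {
    key <- paste(data$molecule_id, data$pose_index, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- data$molecule_id[duplicated(key)][1]
      stop("duplicate (molecule_id, pose_index) for '", dup, "'",
           call. = FALSE)
    }
    if (any(!is.na(data$pose_index) & data$pose_index < 0)) {
      stop("pose_index must be non-negative", call. = FALSE)
    }
  }
  invisible(data)
}

#' @export
print.score_tbl <- function(x, ...) {
  cat(sprintf(
    "# score_tbl: %s / target %s / dataset %s / %s\n",
    attr(x, "program"), attr(x, "target_prep"), attr(x, "dataset_prep"),
    attr(x, "orientation")
  ))
  NextMethod()
}

# dplyr verbs strip subclasses; reattach metadata when we know it is intact
restore_score_tbl <- function(new, old) {
  out <- tibble::as_tibble(new)
  for (a in c("orientation", "program", "target_prep", "dataset_prep")) {
    attr(out, a) <- attr(old, a)
  }
  class(out) <- c("score_tbl", class(tibble::tibble()))
  out
}

#' Score-table metadata accessors
#'
#' @param table A `score_tbl`.
#' @return `orientation()` returns the score orientation string;
#'   `score_counts()` a named list with the number of bioactives (`n_actives`)
#'   and decoys (`n_decoys`) after best-pose reduction.
#' @export
orientation <- function(table) attr(table, "orientation")

#' @rdname orientation
#' @export
score_counts <- function(table) {
  ids <- !duplicated(table$molecule_id)
  list(
    n_actives = sum(table$role[ids] == "bioactive"),
    n_decoys = sum(table$role[ids] == "decoy")
  )
}

#' Read a docking score table from a delimited text file
#'
#' The expected format is tab-separated with a header row containing at least
#' `molecule_id`, `role` and `score`, optionally `pose_index`. An empty score
#' field (or `NA`) marks a molecule for which docking failed; such molecules
#' stay in the table and are ranked strictly worst downstream -- a benchmark
#' molecule never vanishes from the denominator.
#'
#' @param path Path to the TSV file.
#' @inheritParams score_table
#' @return A [score_table()].
#' @export
read_score_table <- function(path,
                             orientation = c("higher_is_better", "lower_is_better"),
                             program = "unknown",
                             target_prep = "default",
                             dataset_prep = "default") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("score table file not found: ", path, call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  req <- c("molecule_id", "role", "score")
  if (!all(req %in% header)) {
    stop("malformed score table ", path, ": header must contain ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  cols <- readr::cols(
    molecule_id = readr::col_character(),
    role = readr::col_character(),
    score = readr::col_character()
  )
  if ("pose_index" %in% header) {
    cols$cols$pose_index <- readr::col_integer()
  }
  data <- readr::read_tsv(path, col_types = cols, progress = FALSE,
                          na = c("", "NA"))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in %s at line %d: %s", path,
                 probs$row[1] + 1L, probs$expected[1]), call. = FALSE)
  }
  # convert scores through strtod for correctly rounded (round-trip safe)
  # doubles; reject non-numeric tokens with a line number
  bad <- !is.na(data$score) & is.na(suppressWarnings(as.numeric(data$score)))
  if (any(bad)) {
    stop(sprintf("parse error in %s at line %d: numeric score expected",
                 path, which(bad)[1] + 1L), call. = FALSE)
  }
  data$score <- as.numeric(data$score)
  score_table(data, orientation = orientation, program = program,
              target_prep = target_prep, dataset_prep = dataset_prep)
}

#' Write a score table as tab-separated text
#'
#' Scores are written with full precision so that a write/read round trip is
#' lossless.
#'
#' @param table A `score_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  df <- tibble::as_tibble(table)
  df$score <- format_full_precision(df$score)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

format_full_precision <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
}

#' Keep only the best-scored pose per molecule
#'
#' Docking programs emit several poses per molecule; every metric in this
#' package is defined on one score per molecule, keeping the best pose under
#' the table's orientation. Molecules whose every pose failed (all scores
#' `NA`) are retained with a missing score.
#'
#' @param table A `score_tbl`, possibly with several rows per `molecule_id`.
#' @return A `score_tbl` with one row per molecule. Idempotent.
#' @export
reduce_best_pose <- function(table) {
  stopifnot(inherits(table, "score_tbl"))
  hib <- orientation(table) == "higher_is_better"
  pick <- function(df) {
    if (nrow(df) == 1L) return(df[, , drop = FALSE])
    sc <- df$score
    if (all(is.na(sc))) return(df[1L, , drop = FALSE])
    i <- if (hib) which.max(sc) else which.min(sc)
    df[i, , drop = FALSE]
  }
  out <- table |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(table)))
  # preserve original (first-occurrence) molecule order
  out <- out[match(unique(table$molecule_id), out$molecule_id), , drop = FALSE]
  restore_score_tbl(out, table)
}

assert_best_pose <- function(table) {
  if (anyDuplicated(table$molecule_id)) {
    stop("table has multiple poses per molecule; call reduce_best_pose() first",
         call. = FALSE)
  }
  invisible(table)
}

#' Read a run manifest
#'
#' A run manifest is a small YAML file declaring which score-table files
#' belong to a comparison, the score orientation of each docking program, and
#' the two analysis constants: the significance safety margin for
#' preparation deltas (default 0.05) and the global rank-shift cutoff used
#' for decoy outlier flagging (default 500).
#'
#' @param path Path to a YAML manifest.
#' @return A list with elements `tables` (tibble: path, orientation, program,
#'   target_prep, dataset_prep, target), `safety_margin`, `rank_shift_cutoff`.
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- yaml::read_yaml(path)
  margin <- m$safety_margin %||% 0.05
  cutoff <- m$rank_shift_cutoff %||% 500L
  if (margin < 0) stop("safety_margin must be >= 0", call. = FALSE)
  if (cutoff < 1) stop("rank_shift_cutoff must be >= 1", call. = FALSE)
  tabs <- purrr::map_dfr(m$tables, function(t) {
    tibble::tibble(
      path = t$path,
      orientation = t$orientation %||% default_orientation(t$program),
      program = t$program %||% "unknown",
      target_prep = t$target_prep %||% "default",
      dataset_prep = t$dataset_prep %||% "default",
      target = t$target %||% "unknown"
    )
  })
  bad <- setdiff(unique(tabs$orientation),
                 c("higher_is_better", "lower_is_better"))
  if (length(bad) > 0) {
    stop("unknown orientation in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(tables = tabs, safety_margin = margin,
       rank_shift_cutoff = as.integer(cutoff))
}

# Fallback orientations for the two programs the package is usually fed.
default_orientation <- function(program) {
  if (is.null(program)) return("higher_is_better")
  switch(tolower(program),
         gold = "higher_is_better",
         glide = "lower_is_better",
         "higher_is_better")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
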