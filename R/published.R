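#' Published preparation-scheme comparison for 18 DEKOIS 2.0 targets
#'
#' pROC-AUC values reported in a published benchmark survey that docked 18
#' DEKOIS 2.0 sets (40 bioactives, 1200 decoys each) with GOLD (ChemPLP)
#' and Glide (SP) after preparing targets and datasets with two commercial
#' schemes, MOE and Maestro. These are reference inputs for the
#' significance census and delta computations; reproducing the absolute
#' values requires commercial docking and is out of scope here.
#'
#' @return Tibble with columns `target`, `program`, `auc_moe`,
#'   `auc_maestro`.
#' @export
published_prep_comparison <- function() {
  gold <- tibble::tribble(
    ~target, ~auc_moe, ~auc_maestro,
    "ACE", 1.55, 1.25,
    "ACHE", 0.72, 0.72,
    "ADRB2", 0.74, 0.65,
    "CATL", 0.78, 0.75,
    "DHFR", 0.75, 0.80,
    "ERBB2", 1.85, 2.12,
    "HDAC2", 1.02, 1.20,
    "HIVPR", 1.46, 1.64,
    "HSP90", 0.42, 0.33,
    "JAK3", 0.78, 0.91,
    "JNK2", 0.77, 0.74,
    "MDM2", 0.51, 0.44,
    "P38", 0.49, 0.56,
    "PI3KG", 1.01, 0.95,
    "PNP", 0.98, 1.04,
    "PPARg", 0.85, 0.92,
    "Thrombin", 1.22, 1.15,
    "TS", 1.27, 1.05
  )
  glide <- tibble::tribble(
    ~target, ~auc_moe, ~auc_maestro,
    "ACE", 1.73, 2.01,
    "ACHE", 0.71, 0.75,
    "ADRB2", 0.97, 0.89,
    "CATL", 0.72, 0.81,
    "DHFR", 1.12, 0.63,
    "ERBB2", 2.01, 1.80,
    "HDAC2", 1.74, 1.27,
    "HIVPR", 1.54, 1.40,
    "HSP90", 0.74, 0.61,
    "JAK3", 1.32, 1.13,
    "JNK2", 0.66, 0.70,
    "MDM2", 0.84, 0.80,
    "P38", 1.79, 1.48,
    "PI3KG", 1.14, 1.13,
    "PNP", 1.08, 1.41,
    "PPARg", 0.90, 1.11,
    "Thrombin", 2.00, 1.93,
    "TS", 1.22, 1.48
  )
  dplyr::bind_rows(
    dplyr::mutate(gold, program = "GOLD", .after = "target"),
    dplyr::mutate(glide, program = "Glide", .after = "target")
  )
}

#' Published heavy-atom normalization survey (GOLD, MOE preparation)
#'
#' pROC-AUC after normalizing GOLD ChemPLP scores by N^(2/3) and N^(1/2)
#' for the same 18 DEKOIS 2.0 targets, with the mean molecular weight and
#' mean heavy-atom count of each bioactive set. The normalization deltas
#' are relative to the original MOE-prepared GOLD values of
#' [published_prep_comparison()].
#'
#' @return Tibble with columns `target`, `auc_n23`, `delta_n23`,
#'   `auc_n12`, `delta_n12`, `mw_mean`, `nha_mean`.
#' @export
published_normalization <- function() {
  tibble::tribble(
    ~target, ~auc_n23, ~delta_n23, ~auc_n12, ~delta_n12, ~mw_mean, ~nha_mean,
    "ACE", 1.76, 0.21, 1.81, 0.26, 398.7, 27.6,
    "ACHE", 0.64, -0.07, 0.71, -0.01, 398.6, 28.6,
    "ADRB2", 0.76, 0.02, 0.80, 0.07, 425.5, 29.7,
    "CATL", 0.55, -0.23, 0.63, -0.16, 482.0, 33.9,
    "DHFR", 1.07, 0.32, 1.02, 0.27, 385.8, 26.8,
    "ERBB2", 1.00, -0.85, 1.34, -0.51, 473.8, 33.8,
    "HDAC2", 0.93, -0.09, 1.03, 0.00, 388.4, 27.5,
    "HIVPR", 0.75, -0.70, 0.97, -0.48, 584.3, 41.2,
    "HSP90", 0.58, 0.16, 0.55, 0.12, 424.1, 29.3,
    "JAK3", 0.76, -0.02, 0.82, 0.04, 404.1, 29.0,
    "JNK2", 0.68, -0.09, 0.71, -0.05, 413.5, 29.7,
    "MDM2", 0.35, -0.16, 0.40, -0.11, 554.7, 36.4,
    "P38", 0.53, 0.04, 0.53, 0.04, 383.1, 27.7,
    "PI3KG", 1.02, 0.02, 1.17, 0.16, 412.3, 29.4,
    "PNP", 1.22, 0.24, 1.24, 0.26, 269.1, 18.9,
    "PPARg", 0.83, -0.02, 0.89, 0.04, 463.6, 32.6,
    "Thrombin", 1.12, -0.11, 1.20, -0.03, 479.7, 33.5,
    "TS", 1.06, -0.21, 1.26, -0.01, 415.3, 29.5
  )
}
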