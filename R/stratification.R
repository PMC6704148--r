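# Marker derivation and the nine adjuvant clinical assessment groups.
#
# ER and PR positivity use the Swedish IHC convention: a stain of <= 10% is
# negative, > 10% positive. Assessment groups combine marker status, nodal
# status and the administered adjuvant treatment; records that fit no group
# (including any with missing required fields) fall to NONE, so the ten
# labels always partition the cohort.

#' Assessment group labels
#'
#' The nine adjuvant clinical assessment groups plus the `NONE` catch-all, in
#' canonical order.
#'
#' @return character vector of length 10.
#' @export
assessment_groups <- function() {
  c("TNBC_ACT", "TNBC_UNTREATED", "HER2_ERNEG_HER2ACT",
    "HER2_ERPOS_HER2ACT_ENDO", "ERPOS_LNNEG_ENDO", "ERPOS_LNNEG_ENDO_ACT",
    "ERPOS_LNPOS_ENDO", "ERPOS_LNPOS_ENDO_ACT", "ERPOS_LNNEG_UNTREATED",
    "NONE")
}

#' Derive marker flags from clinical records
#'
#' Adds logical columns `er_pos`, `pr_pos`, `her2_pos`, `tnbc` and `ln_pos`
#' to a clinical table. ER/PR positivity means IHC staining strictly above
#' 10%; `tnbc` requires all three receptors negative; `ln_pos` means at
#' least `ln_positive_min` positive nodes. Missing inputs propagate to NA
#' flags (a known-positive receptor still rules out TNBC).
#'
#' @param clinical tibble with `er_ihc_pct`, `pr_ihc_pct`, `her2`,
#'   `ln_pos_nodes`.
#' @param ln_positive_min node count from which a patient counts as
#'   node-positive; raise it to treat sub-micrometastases as node-negative.
#' @return the input tibble with the five flag columns appended.
#' @examples
#' derive_markers(tibble::tibble(
#'   sample_id = c("a", "b"), er_ihc_pct = c(10, 11), pr_ihc_pct = c(0, 80),
#'   her2 = c(0L, 0L), ln_pos_nodes = c(0L, 2L)))
#' @export
derive_markers <- function(clinical, ln_positive_min = 1) {
  clinical |>
    mutate(
      er_pos = .data$er_ihc_pct > 10,
      pr_pos = .data$pr_ihc_pct > 10,
      her2_pos = .data$her2 == 1,
      tnbc = !.data$er_pos & !.data$pr_pos & !.data$her2_pos,
      ln_pos = .data$ln_pos_nodes >= ln_positive_min
    )
}

#' Assign the nine clinical assessment groups
#'
#' Maps every record to exactly one of [assessment_groups()]. Untreated
#' means all three adjuvant flags zero; regimens outside the nine defined
#' combinations, and records whose markers or treatment flags are missing,
#' map to `NONE`.
#'
#' @inheritParams derive_markers
#' @return input tibble with marker flags and a factor column
#'   `assessment_group` (levels [assessment_groups()]).
#' @export
assign_assessment_group <- function(clinical, ln_positive_min = 1) {
  df <- derive_markers(clinical, ln_positive_min)
  endo <- df$treat_endo == 1
  act <- df$treat_act == 1
  ah <- df$treat_antiher2 == 1
  grp <- dplyr::case_when(
    df$tnbc & act & !endo & !ah ~ "TNBC_ACT",
    df$tnbc & !act & !endo & !ah ~ "TNBC_UNTREATED",
    df$her2_pos & !df$er_pos & ah & act & !endo ~ "HER2_ERNEG_HER2ACT",
    df$her2_pos & df$er_pos & ah & act & endo ~ "HER2_ERPOS_HER2ACT_ENDO",
    df$er_pos & !df$her2_pos & !df$ln_pos & endo & !act & !ah ~
      "ERPOS_LNNEG_ENDO",
    df$er_pos & !df$her2_pos & !df$ln_pos & endo & act & !ah ~
      "ERPOS_LNNEG_ENDO_ACT",
    df$er_pos & !df$her2_pos & df$ln_pos & endo & !act & !ah ~
      "ERPOS_LNPOS_ENDO",
    df$er_pos & !df$her2_pos & df$ln_pos & endo & act & !ah ~
      "ERPOS_LNPOS_ENDO_ACT",
    df$er_pos & !df$her2_pos & !df$ln_pos & !endo & !act & !ah ~
      "ERPOS_LNNEG_UNTREATED",
    TRUE ~ "NONE"
  )
  df$assessment_group <- factor(grp, levels = assessment_groups())
  df
}

#' Class proportions per stratum
#'
#' For each stratum and each label column, the fraction of every non-NA
#' class (fractions sum to 1 within stratum and signature) plus the NA rate
#' over all records in the stratum. Empty strata are dropped.
#'
#' @param data tibble containing the stratifier and label columns.
#' @param labels tidyselect of label columns (e.g. signature call columns).
#' @param by name of the stratifying column; use `NULL` for pooled
#'   proportions.
#' @return tibble with columns `group`, `signature`, `class`, `n`,
#'   `fraction`, `na_rate`.
#' @examples
#' proportions_by(
#'   tibble::tibble(g = c("x", "x", "x", "y"), s = c("A", "A", "B", NA)),
#'   labels = "s", by = "g")
#' @export
proportions_by <- function(data, labels, by = NULL) {
  long <- data |>
    select(all_of(c(by, labels))) |>
    tidyr::pivot_longer(all_of(labels), names_to = "signature",
                        values_to = "class") |>
    mutate(class = as.character(.data$class))
  if (is.null(by)) {
    long$group <- "all"
  } else {
    long <- rename(long, group = all_of(by))
    long$group <- as.character(long$group)
  }
  stats <- long |>
    group_by(.data$group, .data$signature) |>
    summarise(n_total = dplyr::n(), n_na = sum(is.na(.data$class)),
              .groups = "drop")
  long |>
    filter(!is.na(.data$class)) |>
    count(.data$group, .data$signature, .data$class, name = "n") |>
    group_by(.data$group, .data$signature) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    left_join(stats, by = c("group", "signature")) |>
    mutate(na_rate = .data$n_na / .data$n_total) |>
    select(-"n_total", -"n_na")
}
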