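# Pairwise agreement between risk classifiers, Bangdiwala-style agreement
# chart geometry, and consensus risk voting. All statistics are raw exact
# agreement (no chance correction) on pairwise-complete samples.

#' Contingency table of two ordered classifications
#'
#' Cross-tabulates two paired label vectors over a declared ordered class
#' set, dropping samples with a missing call in either vector
#' (pairwise-complete analysis; the number excluded is reported).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param classes ordered class labels; defaults to low < intermediate <
#'   high.
#' @return object of class `contingency_table` with fields `counts`
#'   (rows = `labels_a`, cols = `labels_b`), `classes`, `n`, `n_excluded`.
#' @export
contingency <- function(labels_a, labels_b, classes = risk_levels()) {
  if (length(labels_a) != length(labels_b))
    abort("label vectors must have equal length")
  bad <- setdiff(stats::na.omit(unique(c(labels_a, labels_b))), classes)
  if (length(bad))
    abort(paste("label(s) outside declared classes:",
                paste(bad, collapse = ", ")))
  keep <- !is.na(labels_a) & !is.na(labels_b)
  if (!any(keep))
    abort("no pairwise-complete samples")
  counts <- table(factor(labels_a[keep], levels = classes),
                  factor(labels_b[keep], levels = classes))
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  structure(list(counts = counts, classes = classes, n = sum(counts),
                 n_excluded = sum(!keep)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> n =", x$n, "(", x$n_excluded, "excluded )\n")
  print(x$counts)
  invisible(x)
}

#' Exact classification agreement (percent)
#'
#' The percentage of samples assigned identical classes by two classifiers:
#' `100 * sum(diagonal) / n`. Symmetric in its arguments.
#'
#' @param x a `contingency_table`, or a label vector (with `y` supplied).
#' @param y optional second label vector.
#' @param classes ordered classes used when tabulating vectors.
#' @return percentage in `[0, 100]`.
#' @examples
#' exact_agreement(c("low", "high"), c("low", "intermediate"))
#' @export
exact_agreement <- function(x, y = NULL, classes = risk_levels()) {
  tab <- if (inherits(x, "contingency_table")) x else contingency(x, y, classes)
  100 * sum(diag(tab$counts)) / tab$n
}

#' Exact agreement after omitting intermediate-risk calls
#'
#' Drops every sample with an intermediate call in either classifier, then
#' computes [exact_agreement()] on the retained low/high calls. Two-class
#' classifiers simply contribute all their samples.
#'
#' @param labels_a,labels_b paired label vectors.
#' @param classes ordered classes.
#' @param intermediate the class treated as intermediate.
#' @return percentage, or NA (with a warning) when no samples remain.
#' @export
agreement_excluding_intermediate <- function(labels_a, labels_b,
                                             classes = risk_levels(),
                                             intermediate = "intermediate") {
  drop <- (!is.na(labels_a) & labels_a == intermediate) |
    (!is.na(labels_b) & labels_b == intermediate)
  keep <- !drop & !is.na(labels_a) & !is.na(labels_b)
  if (!any(keep)) {
    warn("no samples retained after omitting intermediate-risk calls")
    return(NA_real_)
  }
  exact_agreement(labels_a[keep], labels_b[keep],
                  classes = setdiff(classes, intermediate))
}

#' Pairwise agreement between all signature pairs, per assessment group
#'
#' For every stratum and unordered signature pair, the exact agreement in
#' percent, either over all classes or after omitting intermediate calls.
#'
#' @param calls classification tibble (one label column per signature).
#' @param signatures character vector of label column names (>= 2).
#' @param groups optional vector (length `nrow(calls)`) of stratum labels;
#'   `NULL` pools everything into one stratum.
#' @param mode `"all_classes"` or `"low_high_only"`.
#' @param classes ordered classes.
#' @return tibble with `group`, `sig_a`, `sig_b`, `agreement`, `n_used`;
#'   strata where a pair has no usable samples are skipped with a warning.
#' @seealso [agreement_matrix()], [summarize_agreement()]
#' @export
pairwise_agreement <- function(calls, signatures, groups = NULL,
                               mode = c("all_classes", "low_high_only"),
                               classes = risk_levels()) {
  mode <- match.arg(mode)
  if (length(signatures) < 2) abort("need at least 2 signatures")
  groups <- groups %||% rep("all", nrow(calls))
  pairs <- utils::combn(signatures, 2, simplify = FALSE)
  out <- list()
  for (g in unique(as.character(groups))) {
    sub <- calls[as.character(groups) == g, , drop = FALSE]
    for (pr in pairs) {
      a <- sub[[pr[1]]]
      b <- sub[[pr[2]]]
      res <- tryCatch({
        if (mode == "all_classes") {
          agr <- exact_agreement(a, b, classes)
          n_used <- sum(!is.na(a) & !is.na(b))
        } else {
          agr <- agreement_excluding_intermediate(a, b, classes)
          keep <- !is.na(a) & !is.na(b) &
            a != "intermediate" & b != "intermediate"
          n_used <- sum(keep, na.rm = TRUE)
        }
        tibble(group = g, sig_a = pr[1], sig_b = pr[2],
               agreement = agr, n_used = n_used)
      }, error = function(e) {
        warn(paste0("skipping ", pr[1], " vs ", pr[2], " in group ", g,
                    ": ", conditionMessage(e)))
        NULL
      })
      out[[length(out) + 1]] <- res
    }
  }
  bind_rows(out)
}

#' Widen pairwise agreements into a symmetric matrix
#'
#' @param pa output of [pairwise_agreement()].
#' @param group stratum to extract (default: the first).
#' @return symmetric numeric matrix with 100 on the diagonal.
#' @export
agreement_matrix <- function(pa, group = pa$group[1]) {
  sub <- filter(pa, .data$group == !!group)
  sigs <- sort(unique(c(sub$sig_a, sub$sig_b)))
  m <- matrix(NA_real_, length(sigs), length(sigs),
              dimnames = list(sigs, sigs))
  diag(m) <- 100
  for (i in seq_len(nrow(sub))) {
    m[sub$sig_a[i], sub$sig_b[i]] <- sub$agreement[i]
    m[sub$sig_b[i], sub$sig_a[i]] <- sub$agreement[i]
  }
  m
}

#' Five-number summary of pairwise agreements per stratum
#'
#' @param pa output of [pairwise_agreement()].
#' @return tibble with min, quartiles, median, max and pair count per group.
#' @export
summarize_agreement <- function(pa) {
  pa |>
    filter(!is.na(.data$agreement)) |>
    group_by(.data$group) |>
    summarise(n_pairs = dplyr::n(),
              min = min(.data$agreement),
              q1 = unname(quantile(.data$agreement, 0.25)),
              median = median(.data$agreement),
              q3 = unname(quantile(.data$agreement, 0.75)),
              max = max(.data$agreement),
              .groups = "drop")
}

#' Agreement chart geometry
#'
#' Builds the Bangdiwala agreement-chart geometry for an ordered two-way
#' contingency table: one rectangle per class whose boundaries are the
#' cumulative row (x) and column (y) marginal totals; a black square of side
#' `counts[k, k]` (exact agreement) offset within its rectangle by the
#' within-margin cumulative totals of the previous levels; and a gray
#' partial-agreement zone spanning the cells at most one level off the
#' diagonal. White area inside a rectangle is disagreement by more than one
#' level. Coordinates are in counts (0..n), origin bottom-left.
#'
#' @param table a `contingency_table` with 2 or 3 ordered classes.
#' @return object of class `agreement_chart`: tibbles `rectangles`,
#'   `black_squares`, `gray_zones` (columns `class`, `x0`, `y0`, `x1`,
#'   `y1`), plus `n` and `classes`.
#' @seealso [autoplot.agreement_chart()]
#' @export
build_agreement_chart <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  k <- length(table$classes)
  if (!k %in% c(2, 3)) abort("agreement charts require 2 or 3 classes")
  cnt <- table$counts
  cum_a <- unname(c(0, cumsum(rowSums(cnt))))  # x axis: first classifier
  cum_b <- unname(c(0, cumsum(colSums(cnt))))  # y axis: second classifier

  # cells of row/col i strictly below level j, used as square offsets
  row_cum <- function(i, j) if (j < 1) 0 else sum(cnt[i, seq_len(j)])
  col_cum <- function(i, j) if (j < 1) 0 else sum(cnt[seq_len(j), i])

  rect <- tibble(class = table$classes,
                 x0 = cum_a[seq_len(k)], y0 = cum_b[seq_len(k)],
                 x1 = cum_a[-1], y1 = cum_b[-1])
  black <- tibble(
    class = table$classes,
    x0 = cum_a[seq_len(k)] + vapply(seq_len(k), function(i)
      row_cum(i, i - 1), numeric(1)),
    y0 = cum_b[seq_len(k)] + vapply(seq_len(k), function(i)
      col_cum(i, i - 1), numeric(1)))
  black$x1 <- black$x0 + unname(diag(cnt))
  black$y1 <- black$y0 + unname(diag(cnt))
  gray <- tibble(
    class = table$classes,
    x0 = cum_a[seq_len(k)] + vapply(seq_len(k), function(i)
      row_cum(i, i - 2), numeric(1)),
    y0 = cum_b[seq_len(k)] + vapply(seq_len(k), function(i)
      col_cum(i, i - 2), numeric(1)),
    x1 = cum_a[seq_len(k)] + vapply(seq_len(k), function(i)
      row_cum(i, min(i + 1, k)), numeric(1)),
    y1 = cum_b[seq_len(k)] + vapply(seq_len(k), function(i)
      col_cum(i, min(i + 1, k)), numeric(1)))
  structure(list(rectangles = rect, black_squares = black, gray_zones = gray,
                 n = table$n, classes = table$classes),
            class = "agreement_chart")
}

#' @export
print.agreement_chart <- function(x, ...) {
  cat("<agreement_chart>", length(x$classes), "classes, n =", x$n, "\n")
  print(x$rectangles)
  invisible(x)
}

#' Consensus risk voting across a signature panel
#'
#' A sample is `unanimous_low` (or `unanimous_high`) when every signature in
#' the panel calls it low (high); any disagreement is `discordant` and any
#' missing call gives NA.
#'
#' @param calls classification tibble.
#' @param signatures label columns forming the voting panel (>= 2).
#' @return tibble `sample_id`, `vote` with attribute `signatures`.
#' @seealso [consensus_summary()]
#' @export
consensus_vote <- function(calls, signatures) {
  if (length(signatures) < 2) abort("voting panel needs >= 2 signatures")
  lab <- as.matrix(calls[, signatures])
  vote <- apply(lab, 1, function(row) {
    if (anyNA(row)) return(NA_character_)
    if (all(row == "low")) return("unanimous_low")
    if (all(row == "high")) return("unanimous_high")
    "discordant"
  })
  out <- tibble(sample_id = calls$sample_id, vote = vote)
  attr(out, "signatures") <- signatures
  out
}

#' Consensus subgroup sizes per assessment group
#'
#' @param votes output of [consensus_vote()].
#' @param groups vector of assessment-group labels aligned with `votes`.
#' @return tibble of per-group vote fractions (over non-NA votes).
#' @export
consensus_summary <- function(votes, groups) {
  tibble(group = as.character(groups), vote = votes$vote) |>
    filter(!is.na(.data$vote)) |>
    count(.data$group, .data$vote) |>
    group_by(.data$group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}
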