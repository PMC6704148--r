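# Outcome analysis: Kaplan-Meier estimation, log-rank testing and
# Cox proportional-hazards modelling of overall survival per signature class
# within clinical assessment groups. Fits are delegated to the survival
# package (product-limit estimator, score test, Efron tie handling); this
# module owns the per-signature orchestration, the small-class exclusion
# rule, and tidy result containers.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator, overall or per group. Empty groups (after NA
#' removal) are skipped with a warning.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group_labels optional group labels.
#' @return tibble of class `km_curve`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, including a `time = 0`, `estimate = 1` anchor
#'   row per group.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
#' @export
km_estimate <- function(times, events, group_labels = NULL) {
  stopifnot(all(times >= 0, na.rm = TRUE),
            all(events %in% c(0, 1) | is.na(events)))
  grp <- if (is.null(group_labels)) rep("all", length(times))
         else as.character(group_labels)
  keep <- !is.na(times) & !is.na(events) & !is.na(grp)
  if (any(!keep)) warn(paste(sum(!keep), "records with missing data skipped"))
  times <- times[keep]; events <- events[keep]; grp <- grp[keep]
  out <- purrr::map(unique(grp), function(g) {
    i <- grp == g
    if (!any(i)) return(NULL)
    fit <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
    tibble(group = g,
           time = c(0, fit$time),
           n_risk = c(sum(i), fit$n.risk),
           n_event = c(0, fit$n.event),
           n_censor = c(0, fit$n.censor),
           estimate = c(1, fit$surv))
  })
  res <- bind_rows(out)
  class(res) <- c("km_curve", class(res))
  res
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square comparing survival between
#' groups, with `k - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group_labels group labels; at least two non-empty groups required.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `n`, `n_groups`.
#' @export
logrank <- function(times, events, group_labels) {
  keep <- !is.na(times) & !is.na(events) & !is.na(group_labels)
  times <- times[keep]; events <- events[keep]
  grp <- factor(as.character(group_labels[keep]))
  if (nlevels(droplevels(grp)) < 2)
    abort("log-rank test requires at least 2 non-empty groups")
  grp <- droplevels(grp)
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  df <- nlevels(grp) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
         n = length(times), n_groups = nlevels(grp))
}

#' Cox proportional-hazards fit per signature class
#'
#' Fits a partial-likelihood Cox model of overall survival on a class label
#' (reference = the low-risk class by convention) plus optional clinical
#' covariates, with Efron tie handling and complete-case covariate analysis.
#' Tumor grade enters as a categorical covariate with grade 1 reference;
#' covariates constant in the data (e.g. nodal status within an LN-
#' homogeneous group) are dropped with a note. Monotone-likelihood
#' separation and other convergence failures are flagged, never silent.
#'
#' @param data tibble with `os_years`, `os_event` and any covariate columns.
#' @param class_labels per-record class labels (NA records dropped).
#' @param covariates covariate column names; `nhg` is treated as
#'   categorical. Use `character(0)` for a univariable fit.
#' @param reference_class reference level for the class factor.
#' @param ties tie-handling method passed to the fitter.
#' @return object of class `cox_fit`; see [tidy()] and [glance()].
#' @examples
#' cohort <- generate_cohort(sim_params(n_samples = 300, seed = 11))
#' risk3 <- cut(cohort$truth$risk, c(-Inf, -0.5, 0.5, Inf),
#'              labels = c("low", "intermediate", "high"))
#' fit <- cox_fit(cohort$clinical, risk3, covariates = "age_years")
#' tidy(fit)
#' @export
cox_fit <- function(data, class_labels,
                    covariates = c("size_mm", "age_years", "nhg", "ln_pos"),
                    reference_class = "low", ties = "efron") {
  labels <- as.character(class_labels)
  if (!reference_class %in% labels)
    abort(paste0("reference class '", reference_class,
                 "' absent from labels"))
  df <- tibble(time = data$os_years, event = data$os_event, class = labels)
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(paste("covariate not found:", cv))
    df[[cv]] <- if (cv == "nhg") factor(data$nhg, levels = c(1, 2, 3))
                else data[[cv]]
  }
  n_input <- nrow(df)
  df <- df[complete.cases(df), , drop = FALSE]
  n_dropped <- n_input - nrow(df)

  dropped_covariates <- character(0)
  for (cv in covariates) {
    v <- df[[cv]]
    if (length(unique(as.character(v))) < 2) {
      dropped_covariates <- c(dropped_covariates, cv)
      df[[cv]] <- NULL
    }
  }
  covariates <- setdiff(covariates, dropped_covariates)
  classes <- unique(df$class)
  if (length(classes) < 2)
    abort("Cox fit requires at least 2 classes after filtering")
  df$class <- factor(df$class,
                     levels = c(reference_class,
                                sort(setdiff(classes, reference_class))))
  n_events <- sum(df$event)
  if (n_events < 1) abort("Cox fit requires at least 1 event")

  rhs <- paste(c("class", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|loglik",
                conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > 15)) converged <- FALSE

  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  terms <- tibble(
    term = rownames(co),
    type = ifelse(startsWith(rownames(co), "class"), "class", "covariate"),
    class = ifelse(startsWith(rownames(co), "class"),
                   sub("^class", "", rownames(co)), NA_character_),
    estimate = co[, "coef"],
    hr = co[, "exp(coef)"],
    std_error = co[, "se(coef)"],
    ci_low = ci[, "lower .95"],
    ci_high = ci[, "upper .95"],
    p_value = co[, "Pr(>|z|)"]
  )
  structure(list(terms = terms, model = fit,
                 n = nrow(df), n_events = n_events, n_dropped = n_dropped,
                 reference = reference_class,
                 dropped_covariates = dropped_covariates,
                 converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, " events =", x$n_events,
      " reference =", x$reference,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  if (length(x$dropped_covariates))
    cat("  dropped constant covariate(s):",
        paste(x$dropped_covariates, collapse = ", "), "\n")
  print(x$terms)
  invisible(x)
}

#' @rdname sigcordance-tidiers
#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @rdname sigcordance-tidiers
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, n_dropped = x$n_dropped,
         converged = x$converged,
         concordance = unname(x$model$concordance["concordance"]),
         logLik = unname(x$model$loglik[2]))
}

#' Small-class exclusion rule
#'
#' Classes comprising strictly less than `min_fraction` of the non-NA labels
#' are excluded from multivariable analysis; a class at exactly the cutoff
#' is retained.
#'
#' @param class_labels label vector.
#' @param min_fraction exclusion cutoff as a fraction (default 8%).
#' @return list with `retained`, `dropped` and a `fractions` tibble.
#' @export
class_size_filter <- function(class_labels, min_fraction = 0.08) {
  lab <- class_labels[!is.na(class_labels)]
  if (!length(lab)) abort("no non-missing class labels")
  tab <- table(lab)
  fr <- as.numeric(tab) / sum(tab)
  fractions <- tibble(class = names(tab), n = as.integer(tab), fraction = fr)
  list(retained = names(tab)[fr >= min_fraction],
       dropped = names(tab)[fr < min_fraction],
       fractions = fractions)
}

#' Outcome suite per assessment group and signature
#'
#' For every assessment group: counts events and checks eligibility
#' (configurable minimum event count); then, per signature, applies the
#' small-class exclusion rule, estimates Kaplan-Meier curves and the
#' log-rank test across retained classes, and fits univariable and
#' multivariable Cox models (the nodal-status covariate drops automatically
#' in LN-homogeneous groups). Ineligible groups and degenerate
#' single-class signatures are reported, not fitted.
#'
#' @param clinical clinical tibble including `assessment_group` (see
#'   [assign_assessment_group()]).
#' @param calls classification tibble aligned by `sample_id`.
#' @param signatures label columns to analyse.
#' @param groups assessment groups to analyse; defaults to all non-`NONE`
#'   groups present.
#' @param min_events minimum events for a group to be eligible.
#' @param min_fraction small-class exclusion cutoff.
#' @param covariates multivariable covariates (`ln_pos` is derived from
#'   `ln_pos_nodes`).
#' @param reference_class Cox reference class; if absent from a signature's
#'   retained classes, the first retained class is used.
#' @return tibble of class `outcome_suite`: one row per group x signature
#'   with event counts, eligibility, dropped classes, and list-columns
#'   `km`, `logrank`, `cox_uni`, `cox_multi`.
#' @export
run_outcome_suite <- function(clinical, calls, signatures,
                              groups = NULL, min_events = 10,
                              min_fraction = 0.08,
                              covariates = c("size_mm", "age_years", "nhg",
                                             "ln_pos"),
                              reference_class = "low") {
  if (!"assessment_group" %in% names(clinical))
    abort("clinical table lacks assessment_group; run assign_assessment_group()")
  df <- left_join(clinical, calls, by = "sample_id")
  if ("ln_pos" %in% covariates && !"ln_pos" %in% names(df))
    df$ln_pos <- df$ln_pos_nodes >= 1
  present <- as.character(unique(df$assessment_group))
  groups <- groups %||% setdiff(assessment_groups(), "NONE")
  groups <- intersect(groups, present)

  rows <- list()
  for (g in groups) {
    sub <- filter(df, .data$assessment_group == g)
    n_events <- sum(sub$os_event, na.rm = TRUE)
    eligible <- n_events >= min_events
    for (sig in signatures) {
      labels <- sub[[sig]]
      row <- tibble(group = g, signature = sig, n = nrow(sub),
                    n_events = n_events, eligible = eligible,
                    dropped_classes = list(character(0)),
                    km = list(NULL), logrank = list(NULL),
                    cox_uni = list(NULL), cox_multi = list(NULL))
      if (eligible && sum(!is.na(labels)) > 0) {
        filt <- class_size_filter(labels, min_fraction)
        keep <- !is.na(labels) & labels %in% filt$retained
        row$dropped_classes <- list(filt$dropped)
        if (length(filt$retained) >= 2 && sum(sub$os_event[keep]) >= 1) {
          ref <- if (reference_class %in% filt$retained) reference_class
                 else sort(filt$retained)[1]
          row$km <- list(km_estimate(sub$os_years[keep], sub$os_event[keep],
                                     labels[keep]))
          row$logrank <- list(logrank(sub$os_years[keep], sub$os_event[keep],
                                      labels[keep]))
          row$cox_uni <- list(tryCatch(
            cox_fit(sub[keep, ], labels[keep], covariates = character(0),
                    reference_class = ref),
            error = function(e) NULL))
          row$cox_multi <- list(tryCatch(
            cox_fit(sub[keep, ], labels[keep], covariates = covariates,
                    reference_class = ref),
            error = function(e) NULL))
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  res <- bind_rows(rows)
  class(res) <- c("outcome_suite", class(res))
  res
}

#' Forest-plot-ready hazard ratio table
#'
#' Flattens the multivariable (or univariable) Cox fits of an outcome suite
#' into one row per signature class with HR, 95% CI and p-value.
#'
#' @param suite an `outcome_suite`.
#' @param which `"multi"` or `"uni"`.
#' @return tibble `group`, `signature`, `class`, `reference`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`, `converged`.
#' @export
forest_table <- function(suite, which = c("multi", "uni")) {
  which <- match.arg(which)
  col <- if (which == "multi") "cox_multi" else "cox_uni"
  purrr::pmap(list(suite$group, suite$signature, suite[[col]]),
              function(g, sig, fit) {
    if (is.null(fit)) return(NULL)
    tidy(fit) |>
      filter(.data$type == "class") |>
      mutate(group = g, signature = sig, reference = fit$reference,
             n = fit$n, n_events = fit$n_events,
             converged = fit$converged) |>
      select("group", "signature", "class", "reference", "hr", "ci_low",
             "ci_high", "p_value", "n", "n_events", "converged")
  }) |> bind_rows()
}
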