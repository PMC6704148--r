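# Synthetic population-based breast cancer cohorts.
#
# The generator emulates the structure of a contemporary registry cohort:
# latent molecular subtypes drive correlated expression blocks (ER, HER2,
# proliferation and basal axes), IHC markers are drawn consistently with the
# latent subtype, adjuvant treatment is assigned from registry-style marginal
# percentages conditional on marker group, and overall survival follows a
# proportional-hazards model tied to a latent proliferation-based risk score.

# Adjuvant treatment assignment percentages conditional on marker group,
# following registry marginals for a population-based cohort. Columns are
# marker groups, rows treatment regimens; columns are renormalised at draw
# time.
treatment_profile <- function() {
  m <- rbind(
    endo_only     = c(48.0, 71.0, 17.0,  1.0,  1.0),
    act_only      = c( 1.0,  0.0,  0.0,  1.0, 70.0),
    endo_act      = c(49.0, 15.0,  2.5,  0.0,  1.0),
    her2_act      = c( 0.0,  0.0,  2.0, 79.0,  1.0),
    her2_act_endo = c( 0.7,  0.0, 74.0,  6.0,  0.0),
    untreated     = c( 1.6, 13.0,  3.0,  8.0, 24.0),
    other         = c( 0.0,  1.0,  1.5,  5.0,  3.0)
  )
  colnames(m) <- c("erpos_lnpos", "erpos_lnneg", "her2pos_erpos",
                   "her2pos_erneg", "tnbc")
  m
}

#' Simulation parameters for a synthetic breast cancer cohort
#'
#' Builds the parameter set consumed by [generate_cohort()]. Defaults target
#' the marginals of a population-based Swedish breast cancer series: median
#' age 65 (range 25-100), median tumor size 17 mm, 59% node-negative
#' patients, 84.2% ER-positive (IHC > 10%) and roughly 13% HER2-positive
#' tumors, with adjuvant treatment sampled conditional on marker group from
#' registry-style percentages.
#'
#' @param n_samples number of patients.
#' @param subtype_proportions named fractions over latent molecular subtypes;
#'   must sum to 1. Defaults approximate the subtype mix of unselected early
#'   breast cancer (LumA .45, LumB .20, HER2E .12, Basal .12, Normal .11).
#' @param n_genes total number of genes on the synthetic panel.
#' @param genes_per_axis named counts of genes in the ER, HER2, proliferation
#'   and basal expression axes; remaining genes are uninformative background.
#' @param axis_effect log2 expression shift added to an axis when the latent
#'   subtype activates it.
#' @param noise_sd per-gene Gaussian noise, log2 units.
#' @param er_pos_prob per-subtype probability of an ER IHC staining above the
#'   10% positivity cutoff.
#' @param her2_pos_prob per-subtype probability of HER2 positivity.
#' @param pr_pos_prob probability of PR positivity given ER status
#'   (named `er_pos`, `er_neg`).
#' @param clinical_marginals list of marginal targets for age, tumor size,
#'   grade, nodal status and missingness; see defaults.
#' @param baseline_hazard baseline event rate, events per year.
#' @param log_hazard_per_risk_unit Cox log hazard ratio per unit of the
#'   standardized latent risk score.
#' @param followup_years administrative censoring horizon.
#' @param log2_offset offset used on the FPKM scale, i.e. values represent
#'   log2(FPKM + offset); kept as metadata for file round-trips.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full parameter set.
#' @return an object of class `sim_params` (a named list).
#' @seealso [generate_cohort()], [expected_profiles()]
#' @examples
#' p <- sim_params(n_samples = 300, seed = 7)
#' p$clinical_marginals$er_pos_target
#' @export
sim_params <- function(n_samples = 3520,
                       subtype_proportions = c(LumA = 0.45, LumB = 0.20,
                                               HER2E = 0.12, Basal = 0.12,
                                               Normal = 0.11),
                       n_genes = 500,
                       genes_per_axis = c(er = 40, her2 = 30,
                                          proliferation = 40, basal = 30),
                       axis_effect = 2,
                       noise_sd = 1,
                       er_pos_prob = c(LumA = 0.99, LumB = 0.99, HER2E = 0.75,
                                       Basal = 0.05, Normal = 0.99),
                       her2_pos_prob = c(LumA = 0.03, LumB = 0.10,
                                         HER2E = 0.70, Basal = 0.05,
                                         Normal = 0.03),
                       pr_pos_prob = c(er_pos = 0.85, er_neg = 0.05),
                       clinical_marginals = list(),
                       baseline_hazard = 0.03,
                       log_hazard_per_risk_unit = 0.69,
                       followup_years = 8,
                       log2_offset = 0.1,
                       seed = 1L) {
  marginals <- modifyList(list(
    age_mean = 65, age_sd = 12, age_range = c(25, 100), age_target = 65,
    size_meanlog = log(17), size_sdlog = 0.55, size_range = c(1, 126),
    size_target = 17,
    grade_probs = c(`1` = 0.15, `2` = 0.47, `3` = 0.36),
    grade_na_prob = 0.02,
    her2_na_prob = 0.02,
    ln_neg_prob = 0.59,
    ln_extra_nodes_mean = 1.2,
    er_pos_target = 0.842,
    ihc_label_noise = 0.05
  ), clinical_marginals)

  params <- structure(list(
    n_samples = n_samples,
    subtype_proportions = subtype_proportions,
    n_genes = n_genes,
    genes_per_axis = genes_per_axis,
    axis_effect = axis_effect,
    noise_sd = noise_sd,
    er_pos_prob = er_pos_prob,
    her2_pos_prob = her2_pos_prob,
    pr_pos_prob = pr_pos_prob,
    clinical_marginals = marginals,
    baseline_hazard = baseline_hazard,
    log_hazard_per_risk_unit = log_hazard_per_risk_unit,
    followup_years = followup_years,
    log2_offset = log2_offset,
    seed = as.integer(seed)
  ), class = "sim_params")
  validate_sim_params(params)
  params
}

#' @rdname sim_params
#' @export
default_params <- function() sim_params()

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (abs(sum(p$subtype_proportions) - 1) > 1e-9)
    abort("subtype_proportions must sum to 1")
  if (any(p$subtype_proportions < 0))
    abort("subtype_proportions must be non-negative")
  if (p$n_samples < 1 || p$n_genes < 1 || any(p$genes_per_axis < 1))
    abort("all counts (n_samples, n_genes, genes_per_axis) must be positive")
  if (sum(p$genes_per_axis) > p$n_genes)
    abort("genes_per_axis exceeds n_genes")
  if (p$noise_sd < 0) abort("noise_sd must be non-negative")
  if (p$followup_years <= 0) abort("followup_years must be positive")
  if (p$baseline_hazard <= 0) abort("baseline_hazard must be positive")
  subs <- names(p$subtype_proportions)
  for (f in c("er_pos_prob", "her2_pos_prob")) {
    if (!all(subs %in% names(p[[f]])))
      abort(paste0(f, " must name every subtype"))
  }
  invisible(p)
}

# Deterministic gene-level baseline (log2 scale), independent of the seed so
# that expected subtype profiles are a closed-form function of the parameters.
gene_baseline <- function(n_genes) {
  rep_len(seq(2, 10, length.out = 53), n_genes)
}

#' Gene axis membership for a parameter set
#'
#' Axis genes occupy the leading block of the panel in the order
#' ER, HER2, proliferation, basal; the remainder is background.
#'
#' @param params a [sim_params()] object.
#' @return named list of gene identifier vectors, one per axis plus
#'   `background`.
#' @export
gene_axes <- function(params) {
  ids <- sprintf("g%04d", seq_len(params$n_genes))
  k <- params$genes_per_axis
  starts <- cumsum(c(1, k))
  axes <- list()
  for (i in seq_along(k)) {
    axes[[names(k)[i]]] <- ids[seq(starts[i], starts[i] + k[i] - 1)]
  }
  axes$background <- ids[seq(starts[length(starts)], params$n_genes)]
  axes
}

# Which axes each latent subtype activates (multiplier on axis_effect).
subtype_activation <- function() {
  rbind(
    LumA   = c(er = 1, her2 = 0, proliferation = 0.0, basal = 0),
    LumB   = c(er = 1, her2 = 0, proliferation = 1.0, basal = 0),
    HER2E  = c(er = 0, her2 = 1, proliferation = 0.5, basal = 0),
    Basal  = c(er = 0, her2 = 0, proliferation = 1.0, basal = 1),
    Normal = c(er = 0, her2 = 0, proliferation = 0.0, basal = 0)
  )
}

#' Noise-free expected expression profile per subtype
#'
#' The subtype mean profiles implied by a parameter set: a deterministic gene
#' baseline plus `axis_effect`-scaled shifts on the axes each subtype
#' activates. These profiles are what [generate_cohort()] adds noise to, and
#' double as ground-truth centroids in recovery tests.
#'
#' @param params a [sim_params()] object.
#' @return subtypes x genes numeric matrix with dimnames.
#' @export
expected_profiles <- function(params) {
  axes <- gene_axes(params)
  act <- subtype_activation()
  subs <- names(params$subtype_proportions)
  missing_subs <- setdiff(subs, rownames(act))
  if (length(missing_subs))
    abort(paste("unknown subtype(s):", paste(missing_subs, collapse = ", ")))
  ids <- sprintf("g%04d", seq_len(params$n_genes))
  base <- gene_baseline(params$n_genes)
  prof <- matrix(rep(base, each = length(subs)), nrow = length(subs),
                 dimnames = list(subs, ids))
  for (ax in names(params$genes_per_axis)) {
    prof[, axes[[ax]]] <- prof[, axes[[ax]]] +
      params$axis_effect * act[subs, ax]
  }
  prof
}

#' Generate a synthetic cohort
#'
#' Draws latent subtypes, builds expression as subtype profile plus Gaussian
#' noise, derives IHC markers, grade, nodal status and treatment consistent
#' with the latent subtype, and simulates overall survival under a
#' proportional-hazards model on the standardized proliferation-axis mean
#' (the latent risk score). The same parameter set (including seed) always
#' yields a bit-identical cohort.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `bc_cohort`: a list with
#'   * `expression`: genes x samples matrix of log2(FPKM + offset) values,
#'   * `clinical`: tibble of per-patient records,
#'   * `truth`: tibble of latent subtype and risk (never used by analysis
#'     stages),
#'   * `gene_axes`, `params`.
#' @examples
#' cohort <- generate_cohort(sim_params(n_samples = 200, seed = 42))
#' dim(cohort$expression)
#' dplyr::glimpse(cohort$clinical)
#' @export
generate_cohort <- function(params = sim_params()) {
  validate_sim_params(params)
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n_samples
  subs <- names(p$subtype_proportions)
  subtype <- sample(subs, n, replace = TRUE, prob = p$subtype_proportions)
  tab <- table(subtype)
  if (any(tab == 1)) {
    abort(paste0("subtype(s) represented by a single sample (",
                 paste(names(tab)[tab == 1], collapse = ", "),
                 "); downstream centering is undefined - increase n_samples"))
  }

  axes <- gene_axes(p)
  prof <- expected_profiles(p)
  sample_ids <- sprintf("S%05d", seq_len(n))

  expr <- t(prof[subtype, , drop = FALSE])
  if (p$noise_sd > 0) {
    expr <- expr + matrix(rnorm(p$n_genes * n, 0, p$noise_sd),
                          nrow = p$n_genes)
  }
  dimnames(expr) <- list(colnames(prof), sample_ids)

  # latent risk: standardized per-sample mean over the proliferation axis
  prolif_mean <- colMeans(expr[axes$proliferation, , drop = FALSE])
  risk <- if (sd(prolif_mean) > 0) {
    as.numeric(scale(prolif_mean))
  } else {
    rep(0, n)
  }

  m <- p$clinical_marginals
  er_pos <- rbinom(n, 1, p$er_pos_prob[subtype]) == 1
  her2 <- rbinom(n, 1, p$her2_pos_prob[subtype])
  her2[runif(n) < m$her2_na_prob] <- NA_integer_
  pr_pos <- rbinom(n, 1, ifelse(er_pos, p$pr_pos_prob[["er_pos"]],
                                p$pr_pos_prob[["er_neg"]])) == 1
  # IHC percentages consistent with the positivity flag (>10 cutoff)
  er_ihc <- ifelse(er_pos, round(runif(n, 50, 100)), round(runif(n, 0, 10)))
  pr_ihc <- ifelse(pr_pos, round(runif(n, 30, 100)), round(runif(n, 0, 10)))

  age <- round(pmin(pmax(rnorm(n, m$age_mean, m$age_sd), m$age_range[1]),
                    m$age_range[2]))
  size <- round(pmin(pmax(exp(rnorm(n, m$size_meanlog, m$size_sdlog)),
                          m$size_range[1]), m$size_range[2]))
  grade <- sample(c(1L, 2L, 3L), n, replace = TRUE, prob = m$grade_probs)
  grade[runif(n) < m$grade_na_prob] <- NA_integer_
  ln_pos <- rbinom(n, 1, 1 - m$ln_neg_prob) == 1
  nodes <- ifelse(ln_pos, 1L + rpois(n, m$ln_extra_nodes_mean), 0L)

  marker_group <- dplyr::case_when(
    !er_pos & !pr_pos & !is.na(her2) & her2 == 0 ~ "tnbc",
    !is.na(her2) & her2 == 1 & er_pos ~ "her2pos_erpos",
    !is.na(her2) & her2 == 1 & !er_pos ~ "her2pos_erneg",
    er_pos & ln_pos ~ "erpos_lnpos",
    er_pos & !ln_pos ~ "erpos_lnneg",
    TRUE ~ "erpos_lnneg"
  )
  tp <- treatment_profile()
  regimen <- vapply(marker_group, function(g) {
    pr <- tp[, g]
    sample(rownames(tp), 1, prob = pr / sum(pr))
  }, character(1), USE.NAMES = FALSE)
  treat_endo <- as.integer(regimen %in% c("endo_only", "endo_act",
                                          "her2_act_endo", "other"))
  treat_act <- as.integer(regimen %in% c("act_only", "endo_act", "her2_act",
                                         "her2_act_endo"))
  treat_antiher2 <- as.integer(regimen %in% c("her2_act", "her2_act_endo",
                                              "other"))

  hazard <- p$baseline_hazard * exp(p$log_hazard_per_risk_unit * risk)
  t_event <- rexp(n, hazard)
  os_event <- as.integer(t_event <= p$followup_years)
  os_years <- pmin(t_event, p$followup_years)

  clinical <- tibble(
    sample_id = sample_ids,
    age_years = age,
    size_mm = size,
    nhg = grade,
    ln_pos_nodes = nodes,
    er_ihc_pct = er_ihc,
    pr_ihc_pct = pr_ihc,
    her2 = as.integer(her2),
    treat_endo = treat_endo,
    treat_act = treat_act,
    treat_antiher2 = treat_antiher2,
    os_years = os_years,
    os_event = os_event
  )
  truth <- tibble(sample_id = sample_ids, subtype = subtype, risk = risk)

  structure(list(expression = expr, clinical = clinical, truth = truth,
                 gene_axes = axes, params = p),
            class = "bc_cohort")
}

#' @export
print.bc_cohort <- function(x, ...) {
  cat("<bc_cohort>", ncol(x$expression), "samples x",
      nrow(x$expression), "genes\n")
  cat("  subtypes:",
      paste(names(table(x$truth$subtype)), table(x$truth$subtype),
            sep = "=", collapse = ", "), "\n")
  cat("  events:", sum(x$clinical$os_event), "/",
      nrow(x$clinical), "within", x$params$followup_years, "years\n")
  invisible(x)
}

#' Write or read a cohort as plain-text files
#'
#' `write_cohort()` writes `expression.tsv` (genes x samples, header row of
#' sample IDs), `clinical.csv` and `truth.csv` under `dir`; `read_cohort()`
#' reads them back. The truth table is never consumed by analysis stages.
#'
#' @param cohort a `bc_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `bc_cohort` (without `params`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_df <- as_tibble(cohort$expression, rownames = "gene_id")
  readr::write_tsv(expr_df, file.path(dir, "expression.tsv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  if (!is.null(cohort$truth))
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  expr_df <- readr::read_tsv(file.path(dir, "expression.tsv"),
                             show_col_types = FALSE)
  expr <- as.matrix(expr_df[, -1])
  rownames(expr) <- expr_df$gene_id
  clinical <- readr::read_csv(file.path(dir, "clinical.csv"),
                              show_col_types = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  }
  structure(list(expression = expr, clinical = clinical, truth = truth),
            class = "bc_cohort")
}
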