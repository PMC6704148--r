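# End-to-end orchestration: simulate -> classify -> stratify -> proportions
# -> concordance -> voting -> survival, driven by a single config, with a
# provenance manifest and a markdown report assembled from the written CSVs
# (the report never recomputes).

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Referenced input paths are checked at validation time so that a broken
#' config fails before any stage runs.
#'
#' @param out_dir output directory.
#' @param seed integer seed recorded in every output header and used for
#'   simulation.
#' @param stages stages to run, in pipeline order.
#' @param sim named list of [sim_params()] overrides (e.g. `n_samples`).
#' @param expression,clinical optional paths to an existing cohort; when
#'   given, the simulate stage is skipped.
#' @param model_files optional YAML model files; `NULL` uses the
#'   generator-aligned toy panel.
#' @param concordance_modes agreement modes to compute.
#' @param voting_panel label columns for consensus voting; `NULL` uses all
#'   risk-type signatures.
#' @param min_events,min_fraction outcome-suite thresholds.
#' @param write_expression whether to write the (large) expression TSV.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "classify", "stratify",
                                       "proportions", "concordance",
                                       "voting", "survival"),
                            sim = list(),
                            expression = NULL,
                            clinical = NULL,
                            model_files = NULL,
                            concordance_modes = c("all_classes",
                                                  "low_high_only"),
                            voting_panel = NULL,
                            min_events = 10,
                            min_fraction = 0.08,
                            write_expression = FALSE) {
  all_stages <- c("simulate", "classify", "stratify", "proportions",
                  "concordance", "voting", "survival")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  for (p in c(expression, clinical, model_files)) {
    if (!is.null(p) && !file.exists(p))
      abort(paste("referenced path does not exist:", p))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages[order(match(stages, all_stages))],
                 sim = sim, expression = expression, clinical = clinical,
                 model_files = model_files,
                 concordance_modes = concordance_modes,
                 voting_panel = voting_panel,
                 min_events = min_events, min_fraction = min_fraction,
                 write_expression = write_expression),
            class = "pipeline_config")
}

provenance_line <- function(seed, config_hash) {
  paste0("# sigcordance seed=", seed, " config=", config_hash)
}

write_output_csv <- function(df, path, seed, config_hash) {
  readr::write_lines(provenance_line(seed, config_hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline output CSV
#'
#' @param path a CSV written by [run_pipeline()] (provenance header lines
#'   start with `#`).
#' @return tibble.
#' @export
read_output_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing CSV outputs (each carrying
#' a provenance header with the seed and config hash) and a
#' `manifest.json`. Re-running with an identical config reproduces every
#' output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  seed <- config$seed
  stages <- config$stages
  results <- list()
  wcsv <- function(df, name) write_output_csv(df, file.path(out, name),
                                              seed, cfg_hash)

  manifest <- list(tool = "sigcordance",
                   version = as.character(utils::packageVersion("sigcordance")),
                   seed = seed, config_hash = cfg_hash, stages = stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!length(stages)) return(invisible(results))

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$expression)) {
    expr_df <- readr::read_tsv(config$expression, show_col_types = FALSE)
    expr <- as.matrix(expr_df[, -1])
    rownames(expr) <- expr_df[[1]]
    clinical <- readr::read_csv(config$clinical, show_col_types = FALSE)
    params <- do.call(sim_params, config$sim)  # model panel geometry
    cohort <- structure(list(expression = expr, clinical = clinical,
                             truth = NULL, params = params),
                        class = "bc_cohort")
  } else {
    params <- do.call(sim_params, modifyList(config$sim, list(seed = seed)))
    cohort <- generate_cohort(params)
    message("simulate: n=", ncol(cohort$expression), " seed=", seed)
  }
  results$cohort <- cohort
  if (config$write_expression) write_cohort(cohort, out)
  wcsv(cohort$clinical, "clinical.csv")

  models <- if (is.null(config$model_files)) {
    cohort_signature_models(cohort$params)
  } else {
    setNames(lapply(config$model_files, load_signature_model),
             vapply(config$model_files, function(p)
               load_signature_model(p)$name, character(1)))
  }
  risk_sigs <- names(models)[vapply(models, function(m)
    m$family %in% c("ror", "linear_risk", "correlation_risk"), logical(1))]
  three_class <- names(models)[vapply(models, function(m)
    m$family %in% c("ror", "linear_risk"), logical(1))]

  if ("classify" %in% stages) {
    calls <- classify_cohort(cohort$expression, cohort$clinical, models)
    results$calls <- calls
    wcsv(calls, "calls.csv")
    message("classify: ", length(models), " models")
  }
  if ("stratify" %in% stages) {
    groups <- assign_assessment_group(cohort$clinical)
    results$groups <- groups
    wcsv(select(groups, "sample_id", "er_pos", "pr_pos", "her2_pos",
                "tnbc", "ln_pos", "assessment_group"), "groups.csv")
    message("stratify: ",
            sum(groups$assessment_group != "NONE"), "/", nrow(groups),
            " records in the nine assessment groups")
  }
  grp_vec <- if (!is.null(results$groups))
    as.character(results$groups$assessment_group)

  if ("proportions" %in% stages && !is.null(results$calls)) {
    dat <- results$calls
    dat$assessment_group <- grp_vec %||% "all"
    props <- proportions_by(dat, labels = names(models),
                            by = "assessment_group")
    results$proportions <- props
    wcsv(props, "proportions.csv")
  }
  if ("concordance" %in% stages && !is.null(results$calls) &&
      length(three_class) >= 2) {
    for (mode in config$concordance_modes) {
      pa <- pairwise_agreement(results$calls, three_class,
                               groups = grp_vec, mode = mode)
      results[[paste0("agreement_", mode)]] <- pa
      wcsv(pa, paste0("agreement_", mode, ".csv"))
      wcsv(summarize_agreement(pa),
           paste0("agreement_", mode, "_summary.csv"))
    }
    # chart geometry for the first signature pair in each group
    charts <- list()
    for (g in unique(stats::na.omit(grp_vec %||% "all"))) {
      i <- if (is.null(grp_vec)) rep(TRUE, nrow(results$calls))
           else grp_vec == g
      geom <- tryCatch({
        tab <- contingency(results$calls[[three_class[1]]][i],
                           results$calls[[three_class[2]]][i])
        ch <- build_agreement_chart(tab)
        list(rectangles = ch$rectangles, black_squares = ch$black_squares,
             gray_zones = ch$gray_zones, n = ch$n)
      }, error = function(e) NULL)
      if (!is.null(geom)) charts[[g]] <- geom
    }
    jsonlite::write_json(charts, file.path(out, "agreement_charts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("voting" %in% stages && !is.null(results$calls)) {
    panel <- config$voting_panel %||% three_class
    if (length(panel) >= 2) {
      votes <- consensus_vote(results$calls, panel)
      results$votes <- votes
      wcsv(votes, "consensus_votes.csv")
      if (!is.null(grp_vec))
        wcsv(consensus_summary(votes, grp_vec), "consensus_summary.csv")
    }
  }
  if ("survival" %in% stages && !is.null(results$calls) &&
      !is.null(results$groups)) {
    suite <- run_outcome_suite(results$groups, results$calls,
                               signatures = risk_sigs,
                               min_events = config$min_events,
                               min_fraction = config$min_fraction)
    results$outcomes <- suite
    wcsv(select(suite, "group", "signature", "n", "n_events", "eligible"),
         "outcome_eligibility.csv")
    ft <- forest_table(suite, "multi")
    if (nrow(ft)) wcsv(ft, "forest_multivariable.csv")
    lr <- purrr::pmap(list(suite$group, suite$signature, suite$logrank),
                      function(g, s, x) {
                        if (is.null(x)) return(NULL)
                        mutate(x, group = g, signature = s)
                      }) |> bind_rows()
    if (nrow(lr)) wcsv(lr, "logrank.csv")
    message("survival: ", sum(suite$eligible), "/", nrow(suite),
            " group x signature analyses eligible")
  }
  invisible(results)
}

#' Render a markdown report from pipeline outputs
#'
#' Assembles `report.md` in the output directory from the written CSVs and
#' the manifest; every number in the report is read from those files, never
#' recomputed. Sections whose stage outputs are absent are marked as such.
#'
#' @param out_dir a directory populated by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
render_report <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  lines <- c("# sigcordance pipeline report", "",
             paste0("seed: ", manifest$seed,
                    "  config: ", manifest$config_hash), "")
  section <- function(title, file, fmt) {
    path <- file.path(out_dir, file)
    if (!file.exists(path))
      return(c(paste("##", title), "", "_stage output absent_", ""))
    c(paste("##", title), "", fmt(read_output_csv(path)), "")
  }
  md_table <- function(df, digits = 3) {
    df <- mutate(df, across(dplyr::where(is.numeric), ~ round(.x, digits)))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|"),
        character(1)))
  }
  lines <- c(lines,
    section("Assessment groups", "groups.csv", function(df) {
      md_table(count(df, .data$assessment_group, name = "n"))
    }),
    section("Class proportions", "proportions.csv", function(df) {
      md_table(head(arrange(df, .data$group, .data$signature,
                            dplyr::desc(.data$fraction)), 40))
    }),
    section("Pairwise agreement (all classes)",
            "agreement_all_classes_summary.csv", md_table),
    section("Pairwise agreement (low/high only)",
            "agreement_low_high_only_summary.csv", md_table),
    section("Consensus voting", "consensus_summary.csv", md_table),
    section("Outcome eligibility", "outcome_eligibility.csv", md_table),
    section("Multivariable hazard ratios", "forest_multivariable.csv",
            md_table))
  path <- file.path(out_dir, "report.md")
  readr::write_lines(lines, path)
  invisible(path)
}
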