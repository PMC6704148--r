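# Parameterized signature models: loading, validation and per-family
# classification. Four mathematical families cover the published signature
# taxonomy: nearest-centroid subtype calls, weighted-module linear risk
# scores, the ROR family (centroid correlations plus optional proliferation
# and tumor-size terms with lymph-node-dependent cutoffs), decision-tree
# module subtyping, and correlation-to-template two-class risk calls.

model_families <- function() {
  c("centroid_subtype", "linear_risk", "ror", "module_subtype",
    "correlation_risk")
}

#' Load a signature model from a YAML file
#'
#' Model files declare a `family` which determines the required fields.
#' Centroids may be given inline (class -> gene -> value) or as the path of a
#' TSV (first column class, remaining columns genes) relative to the model
#' file. Thresholds may be a plain increasing vector or a map keyed
#' `LN-`/`LN+` for lymph-node-dependent cutoffs. Unknown fields are rejected
#' so that typos fail loudly.
#'
#' @param path path to a YAML model file.
#' @return a validated `signature_model`.
#' @examples
#' path <- system.file("extdata", "models", "centroid_toy.yaml",
#'                     package = "sigcordance")
#' load_signature_model(path)
#' @export
load_signature_model <- function(path) {
  if (!file.exists(path)) abort(paste("model file not found:", path))
  spec <- yaml::read_yaml(path)
  if (is.character(spec$centroids) && length(spec$centroids) == 1) {
    tsv <- file.path(dirname(path), spec$centroids)
    if (!file.exists(tsv)) abort(paste("centroid TSV not found:", tsv))
    df <- readr::read_tsv(tsv, show_col_types = FALSE)
    mat <- as.matrix(df[, -1])
    rownames(mat) <- df[[1]]
    spec$centroids <- mat
  }
  signature_model(spec)
}

#' Construct a signature model from a list
#'
#' Programmatic equivalent of [load_signature_model()]; validates the same
#' schema.
#'
#' @param spec named list of model fields.
#' @return a `signature_model`.
#' @export
signature_model <- function(spec) {
  allowed <- list(
    common = c("name", "family", "description", "classes", "genes",
               "correlation_method", "centering"),
    centroid_subtype = "centroids",
    ror = c("centroids", "weights", "proliferation_genes", "coefficients",
            "thresholds", "variant"),
    linear_risk = c("modules", "intercept", "rescale", "thresholds"),
    correlation_risk = c("centroids", "thresholds"),
    module_subtype = c("modules", "class_map")
  )
  fam <- spec$family
  if (is.null(fam) || !fam %in% model_families())
    abort(paste("field 'family' must be one of:",
                paste(model_families(), collapse = ", ")))
  unknown <- setdiff(names(spec), c(allowed$common, allowed[[fam]]))
  if (length(unknown))
    abort(paste0("unknown field(s) for family ", fam, ": ",
                 paste(unknown, collapse = ", ")))
  if (is.null(spec$name)) abort("field 'name' is required")

  spec$correlation_method <- spec$correlation_method %||%
    if (fam == "centroid_subtype") "spearman" else "pearson"
  if (!spec$correlation_method %in% c("spearman", "pearson"))
    abort("field 'correlation_method' must be 'spearman' or 'pearson'")
  spec$centering <- spec$centering %||% "none"
  if (!spec$centering %in% c("none", "reference_set"))
    abort("field 'centering' must be 'none' or 'reference_set'")

  if (!is.null(spec$centroids)) {
    spec$centroids <- as_centroid_matrix(spec$centroids)
  }
  req <- function(field) {
    if (is.null(spec[[field]]))
      abort(paste0("family ", fam, " requires field '", field, "'"))
  }
  if (fam %in% c("centroid_subtype", "ror", "correlation_risk"))
    req("centroids")

  if (fam == "centroid_subtype") {
    spec$classes <- spec$classes %||% rownames(spec$centroids)
    if (!setequal(spec$classes, rownames(spec$centroids)))
      abort("field 'classes' must match the centroid classes")
    spec$centroids <- spec$centroids[spec$classes, , drop = FALSE]
  }
  if (fam == "ror") {
    req("weights"); req("coefficients"); req("thresholds")
    spec$classes <- spec$classes %||% risk_levels()
    w <- unlist(spec$weights)
    if (!setequal(names(w), rownames(spec$centroids)))
      abort("field 'weights' must name every centroid class")
    spec$weights <- w[rownames(spec$centroids)]
    spec$coefficients <- modifyList(
      list(a = 1, b = 0, c = 0, intercept = 0),
      as.list(spec$coefficients))
    spec$variant <- spec$variant %||% "PT"
    if (!spec$variant %in% c("S", "P", "T", "PT", "Tot"))
      abort("field 'variant' must be one of S, P, T, PT, Tot")
    if (spec$variant %in% c("P", "PT", "Tot") &&
        is.null(spec$proliferation_genes))
      abort(paste0("variant ", spec$variant,
                   " requires field 'proliferation_genes'"))
  }
  if (fam == "linear_risk") {
    req("modules"); req("thresholds")
    spec$classes <- spec$classes %||% risk_levels()
    spec$intercept <- spec$intercept %||% 0
    spec$modules <- lapply(spec$modules, function(m) {
      if (is.null(m$genes) || is.null(m$beta))
        abort("each linear_risk module requires 'genes' and 'beta'")
      m$clip <- isTRUE(m$clip)
      if (m$clip && is.null(m$tau))
        abort("clipped modules require field 'tau'")
      m
    })
    if (!is.null(spec$rescale)) {
      if (!all(c("slope", "intercept") %in% names(spec$rescale)))
        abort("field 'rescale' requires 'slope' and 'intercept'")
    }
  }
  if (fam == "correlation_risk") {
    req("thresholds")
    if (nrow(spec$centroids) != 1)
      abort("correlation_risk requires a single template centroid row")
    spec$classes <- spec$classes %||% c("low", "high")
    if (length(spec$classes) != 2)
      abort("correlation_risk models have exactly 2 classes")
    if (length(unlist(spec$thresholds)) != 1)
      abort("correlation_risk requires a single threshold")
  }
  if (fam == "module_subtype") {
    req("modules"); req("class_map")
    need <- c("er", "her2", "proliferation")
    if (!all(need %in% names(spec$modules)))
      abort("module_subtype requires modules named er, her2, proliferation")
    spec$modules <- lapply(spec$modules, function(m) {
      if (is.null(m$genes) || is.null(m$cutoff))
        abort("each module_subtype module requires 'genes' and 'cutoff'")
      m
    })
    cm <- spec$class_map
    need_cls <- c("her2", "luminal_low", "luminal_high", "basal")
    if (!all(need_cls %in% names(cm)))
      abort("class_map requires her2, luminal_low, luminal_high, basal")
    spec$classes <- spec$classes %||% unique(unlist(cm[need_cls]))
  }

  if (!is.null(spec$thresholds)) {
    spec$thresholds <- validate_thresholds(spec$thresholds)
  }

  model_genes <- unique(c(
    if (!is.null(spec$centroids)) colnames(spec$centroids),
    unlist(lapply(spec$modules, `[[`, "genes")),
    spec$proliferation_genes))
  if (!is.null(spec$genes)) {
    extra <- setdiff(model_genes, spec$genes)
    if (length(extra))
      abort(paste0("gene(s) used but absent from field 'genes': ",
                   paste(head(extra, 5), collapse = ", ")))
  } else {
    spec$genes <- model_genes
  }
  structure(spec, class = "signature_model")
}

as_centroid_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  genes <- unique(unlist(lapply(x, names)))
  mat <- t(vapply(x, function(row) unlist(row)[genes], numeric(length(genes))))
  colnames(mat) <- genes
  mat
}

validate_thresholds <- function(thr) {
  check_inc <- function(v, label) {
    v <- as.numeric(unlist(v))
    if (length(v) >= 2 && any(diff(v) <= 0))
      abort(paste0("field 'thresholds' (", label,
                   ") must be strictly increasing"))
    v
  }
  if (is.list(thr) && !is.null(names(thr)) &&
      any(names(thr) %in% c("LN-", "LN+"))) {
    if (!setequal(names(thr), c("LN-", "LN+")))
      abort("LN-keyed thresholds require both 'LN-' and 'LN+'")
    lapply(setNames(names(thr), names(thr)),
           function(k) check_inc(thr[[k]], k))
  } else {
    check_inc(thr, "global")
  }
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model>", x$name, " family:", x$family, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  genes:", length(x$genes),
      " correlation:", x$correlation_method,
      " centering:", x$centering, "\n")
  invisible(x)
}

#' Center genes on a reference set
#'
#' Subtracts, from every gene, its median over a reference subset of samples,
#' the standard device for making nearest-centroid subtype calls comparable
#' across cohorts of different composition. After centering, every gene's
#' median over the reference samples is exactly zero.
#'
#' @param x genes x samples numeric matrix with dimnames.
#' @param reference_samples character vector of sample IDs (>= 2) contained
#'   in `colnames(x)`.
#' @return the centered matrix.
#' @seealso [choose_reference_set()]
#' @export
center_genes <- function(x, reference_samples) {
  if (length(reference_samples) < 2)
    abort("reference set must contain at least 2 samples")
  missing <- setdiff(reference_samples, colnames(x))
  if (length(missing))
    abort(paste("reference sample(s) not in matrix:",
                paste(head(missing, 5), collapse = ", ")))
  med <- apply(x[, reference_samples, drop = FALSE], 1, median)
  x - med
}

#' Pick an ER-stratified reference set
#'
#' Selects a seeded subsample with a controlled ER-positive fraction, used as
#' the composition-controlled reference for [center_genes()].
#'
#' @param clinical clinical tibble with `sample_id` and `er_ihc_pct`.
#' @param n reference set size.
#' @param er_pos_fraction target fraction of ER-positive samples.
#' @param seed integer seed.
#' @return character vector of sample IDs.
#' @export
choose_reference_set <- function(clinical, n = 50, er_pos_fraction = 0.5,
                                 seed = 1L) {
  pos <- clinical$sample_id[!is.na(clinical$er_ihc_pct) &
                              clinical$er_ihc_pct > 10]
  neg <- clinical$sample_id[!is.na(clinical$er_ihc_pct) &
                              clinical$er_ihc_pct <= 10]
  n_pos <- min(length(pos), round(n * er_pos_fraction))
  n_neg <- min(length(neg), n - n_pos)
  withr::with_seed(seed, c(sample(pos, n_pos), sample(neg, n_neg)))
}

#' Correlation of one sample with each class centroid
#'
#' @param x named numeric vector: one sample's expression over (at least) the
#'   model genes.
#' @param centroids class x gene matrix.
#' @param method `"spearman"` or `"pearson"`.
#' @return named vector of correlations in `[-1, 1]`, one per class; all-NA
#'   (with a warning) when fewer than 3 genes are shared, NA per class where
#'   the correlation is undefined (constant profile).
#' @export
correlation_profile <- function(x, centroids,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(names(x), colnames(centroids))
  out <- setNames(rep(NA_real_, nrow(centroids)), rownames(centroids))
  if (length(shared) < 3) {
    warn(paste0("fewer than 3 genes shared with centroids (",
                length(shared), "); returning NA"))
    return(out)
  }
  xv <- x[shared]
  for (k in rownames(centroids)) {
    out[k] <- suppressWarnings(cor(xv, centroids[k, shared], method = method))
  }
  out
}

#' Nearest-centroid subtype classification
#'
#' Each sample is assigned the class whose centroid it correlates with most
#' strongly. Exact ties resolve to the first class in the model's declared
#' order; samples with undefined correlations for all classes get NA.
#'
#' @param x genes x samples matrix, already reference-centered if the model
#'   declares `centering: reference_set`.
#' @param model a `signature_model` of family `centroid_subtype`.
#' @return character vector of class labels, named by sample.
#' @export
classify_centroid <- function(x, model) {
  stopifnot(model$family == "centroid_subtype")
  cen <- model$centroids
  vapply(colnames(x), function(s) {
    r <- correlation_profile(x[, s], cen, model$correlation_method)
    if (all(is.na(r))) return(NA_character_)
    names(r)[which.max(r)]  # which.max takes the first maximum: declared order
  }, character(1))
}

#' Risk-of-recurrence (ROR) family scores
#'
#' ROR-S is the weighted sum of centroid correlations; the P/T/PT/Tot
#' variants add proliferation-module and tumor-size terms:
#' \deqn{ROR = intercept + a \sum_k w_k r_k + b P + c \cdot size}
#' where `r_k` are per-class correlations, `P` is the mean median-centered
#' expression of the proliferation module, and the size term is tumor size in
#' cm. Variant `S` uses only the correlation sum (`a = 1`), `P` drops the
#' size term, `T` the proliferation term, and `PT`/`Tot` use both (`Tot`
#' differs only in being scored against lymph-node-specific cutoffs by
#' [assign_risk()]).
#'
#' @param x genes x samples matrix.
#' @param model `signature_model` of family `ror`.
#' @param clinical clinical tibble (needs `size_mm` for size-using variants).
#' @param variant one of `"S"`, `"P"`, `"T"`, `"PT"`, `"Tot"`; defaults to
#'   the model's declared variant.
#' @return named numeric scores; NA (with a warning) where a required input
#'   is missing.
#' @export
score_ror <- function(x, model, clinical = NULL, variant = model$variant) {
  stopifnot(model$family == "ror")
  variant <- match.arg(variant, c("S", "P", "T", "PT", "Tot"))
  co <- model$coefficients
  samples <- colnames(x)

  ror_s <- vapply(samples, function(s) {
    r <- correlation_profile(x[, s], model$centroids,
                             model$correlation_method)
    if (any(is.na(r))) return(NA_real_)
    sum(model$weights * r)
  }, numeric(1))
  if (variant == "S") return(ror_s)

  score <- co$intercept + co$a * ror_s
  if (variant %in% c("P", "PT", "Tot")) {
    pg <- intersect(model$proliferation_genes, rownames(x))
    if (!length(pg)) abort("no proliferation-module genes found in matrix")
    centered <- x[pg, , drop = FALSE] -
      apply(x[pg, , drop = FALSE], 1, median)
    score <- score + co$b * colMeans(centered)
  }
  if (variant %in% c("T", "PT", "Tot")) {
    if (is.null(clinical))
      abort(paste0("variant ", variant, " requires clinical tumor size"))
    size_cm <- clinical$size_mm[match(samples, clinical$sample_id)] / 10
    if (anyNA(size_cm))
      warn("missing tumor size: NA score for affected samples")
    score <- score + co$c * size_cm
  }
  score
}

#' Weighted-module linear risk score
#'
#' Recurrence-score style form: each module contributes its mean expression
#' `f_m` (optionally clipped at a floor, `max(f_m - tau, 0)`), and the score
#' is `intercept + sum(beta_m * f_m)`, optionally affinely rescaled to a
#' declared output range.
#'
#' @param x genes x samples matrix.
#' @param model `signature_model` of family `linear_risk`.
#' @return named numeric scores; NA where all of a module's genes are absent.
#' @export
score_linear <- function(x, model) {
  stopifnot(model$family == "linear_risk")
  score <- rep(model$intercept, ncol(x))
  names(score) <- colnames(x)
  for (m in model$modules) {
    genes <- intersect(m$genes, rownames(x))
    if (!length(genes)) {
      warn(paste0("module '", m$name %||% "?",
                  "' has no genes in matrix; NA scores"))
      score[] <- NA_real_
      next
    }
    f <- colMeans(x[genes, , drop = FALSE])
    if (m$clip) f <- pmax(f - m$tau, 0)
    score <- score + m$beta * f
  }
  if (!is.null(model$rescale))
    score <- model$rescale$slope * score + model$rescale$intercept
  score
}

#' Correlation-to-template two-class risk call
#'
#' Samples correlating with the model's template profile at or above the
#' threshold take the first (good-prognosis) class, all others the second.
#'
#' @param x genes x samples matrix.
#' @param model `signature_model` of family `correlation_risk`.
#' @return list with `labels` (character, named) and `scores` (correlations).
#' @export
classify_correlation_risk <- function(x, model) {
  stopifnot(model$family == "correlation_risk")
  thr <- unlist(model$thresholds)[1]
  scores <- vapply(colnames(x), function(s) {
    correlation_profile(x[, s], model$centroids, model$correlation_method)[1]
  }, numeric(1))
  labels <- ifelse(is.na(scores), NA_character_,
                   ifelse(scores >= thr, model$classes[1], model$classes[2]))
  names(labels) <- colnames(x)
  list(labels = labels, scores = scores)
}

#' Module-score decision-tree subtyping
#'
#' Deterministic tree over ER/HER2/proliferation module means: HER2 module at
#' or above its cutoff takes the HER2 class regardless of ER; otherwise an ER
#' module at or above its cutoff takes a luminal class, split into
#' low/high-proliferation classes by the proliferation cutoff; everything
#' else is the basal-like class. Class names come from the model's
#' `class_map`.
#'
#' @param x genes x samples matrix.
#' @param model `signature_model` of family `module_subtype`.
#' @param clinical unused; accepted for interface uniformity.
#' @return named character vector of class labels.
#' @export
classify_modules <- function(x, model, clinical = NULL) {
  stopifnot(model$family == "module_subtype")
  score_of <- function(m) {
    genes <- intersect(m$genes, rownames(x))
    if (!length(genes)) return(rep(NA_real_, ncol(x)))
    colMeans(x[genes, , drop = FALSE])
  }
  er <- score_of(model$modules$er)
  her2 <- score_of(model$modules$her2)
  prolif <- score_of(model$modules$proliferation)
  cm <- model$class_map
  labels <- dplyr::case_when(
    is.na(her2) | is.na(er) | is.na(prolif) ~ NA_character_,
    her2 >= model$modules$her2$cutoff ~ cm$her2,
    er >= model$modules$er$cutoff &
      prolif >= model$modules$proliferation$cutoff ~ cm$luminal_high,
    er >= model$modules$er$cutoff ~ cm$luminal_low,
    TRUE ~ cm$basal
  )
  setNames(labels, colnames(x))
}

#' Map numeric risk scores to ordered risk classes
#'
#' Cutpoints are right-closed upward: a score equal to a cutpoint takes the
#' higher class (`low` if `s < t1`, `intermediate` if `t1 <= s < t2`, `high`
#' if `s >= t2`; two-class models use a single cutpoint). Models may declare
#' lymph-node-specific cutpoints (`LN-`/`LN+`), in which case the nodal
#' status of each patient selects the threshold vector.
#'
#' @param scores named numeric vector.
#' @param model `signature_model` carrying `thresholds` and `classes`.
#' @param clinical clinical tibble with `sample_id` and `ln_pos_nodes`;
#'   required for LN-keyed thresholds.
#' @return named character vector of risk labels; NA score or (for LN-keyed
#'   models) NA nodal status gives NA.
#' @export
assign_risk <- function(scores, model, clinical = NULL) {
  thr <- model$thresholds
  if (is.null(thr)) abort("model has no thresholds")
  classes <- model$classes
  label_one <- function(s, cuts) {
    if (is.na(s)) return(NA_character_)
    classes[findInterval(s, cuts) + 1]
  }
  if (is.list(thr)) {
    if (is.null(clinical))
      abort("LN-keyed thresholds require clinical nodal status")
    nodes <- clinical$ln_pos_nodes[match(names(scores), clinical$sample_id)]
    key <- ifelse(is.na(nodes), NA_character_,
                  ifelse(nodes >= 1, "LN+", "LN-"))
    out <- vapply(seq_along(scores), function(i) {
      if (is.na(key[i])) return(NA_character_)
      label_one(scores[i], thr[[key[i]]])
    }, character(1))
  } else {
    out <- vapply(scores, label_one, character(1), cuts = thr)
  }
  setNames(out, names(scores))
}

#' Classify a cohort with a set of signature models
#'
#' Dispatches each model by family and assembles one label column per model
#' (plus a `<name>_score` column for score-producing risk models) into a
#' classification table. A failing model yields an NA column and a warning,
#' never an aborted table. Models declaring `centering: reference_set` are
#' applied to a copy of the matrix centered on `reference_samples`.
#'
#' @param x genes x samples matrix (log2 scale).
#' @param clinical clinical tibble aligned with `colnames(x)`.
#' @param models list of `signature_model` objects.
#' @param reference_samples sample IDs used for reference-set centering;
#'   defaults to all samples.
#' @return tibble with `sample_id` and per-signature columns.
#' @examples
#' cohort <- generate_cohort(sim_params(n_samples = 100, seed = 3))
#' models <- cohort_signature_models(cohort$params)
#' calls <- classify_cohort(cohort$expression, cohort$clinical, models)
#' head(calls)
#' @export
classify_cohort <- function(x, clinical, models,
                            reference_samples = colnames(x)) {
  out <- tibble(sample_id = colnames(x))
  centered <- NULL
  for (model in models) {
    nm <- model$name
    res <- tryCatch({
      xm <- if (model$centering == "reference_set") {
        if (is.null(centered))
          centered <- center_genes(x, reference_samples)
        centered
      } else x
      switch(model$family,
        centroid_subtype = list(labels = classify_centroid(xm, model)),
        module_subtype = list(labels = classify_modules(xm, model, clinical)),
        correlation_risk = classify_correlation_risk(xm, model),
        linear_risk = {
          s <- score_linear(xm, model)
          list(labels = assign_risk(s, model, clinical), scores = s)
        },
        ror = {
          s <- score_ror(xm, model, clinical)
          list(labels = assign_risk(s, model, clinical), scores = s)
        })
    }, error = function(e) {
      warn(paste0("model '", nm, "' failed: ", conditionMessage(e)))
      list(labels = rep(NA_character_, ncol(x)))
    })
    out[[nm]] <- unname(res$labels)
    if (!is.null(res$scores)) out[[paste0(nm, "_score")]] <- unname(res$scores)
  }
  out
}

#' Generator-aligned toy signature models
#'
#' Builds a self-consistent panel of toy models whose parameters match the
#' synthetic generator's expected subtype profiles: a nearest-centroid
#' subtype model over the axis genes, a module-subtype tree, an ROR-style
#' risk model, a proliferation-based linear risk model, and a
#' correlation-to-template two-class model. These are demonstration
#' parameters, not published clinical coefficients.
#'
#' @param params a [sim_params()] object.
#' @return named list of `signature_model` objects.
#' @export
cohort_signature_models <- function(params) {
  prof <- expected_profiles(params)
  axes <- gene_axes(params)
  axis_genes <- unlist(axes[names(params$genes_per_axis)], use.names = FALSE)
  cen <- prof[, axis_genes, drop = FALSE]
  base <- setNames(gene_baseline(params$n_genes),
                   sprintf("g%04d", seq_len(params$n_genes)))
  half <- params$axis_effect / 2
  cut_of <- function(genes) mean(base[genes]) + half

  centroid <- signature_model(list(
    name = "centroid_toy5", family = "centroid_subtype",
    correlation_method = "spearman", centering = "none",
    centroids = cen))

  modules <- signature_model(list(
    name = "module_toy", family = "module_subtype",
    modules = list(
      er = list(genes = axes$er, cutoff = cut_of(axes$er)),
      her2 = list(genes = axes$her2, cutoff = cut_of(axes$her2)),
      proliferation = list(genes = axes$proliferation,
                           cutoff = cut_of(axes$proliferation))),
    class_map = list(her2 = "HER2E", luminal_low = "LumA",
                     luminal_high = "LumB", basal = "Basal")))

  # weights favour proliferative subtypes so the score tracks latent risk
  w_all <- c(LumA = -0.5, LumB = 0.5, HER2E = 0.3, Basal = 0.6,
             Normal = -0.3)
  ror <- signature_model(list(
    name = "ror_toy", family = "ror", variant = "Tot",
    correlation_method = "pearson",
    centroids = cen,
    weights = as.list(w_all[rownames(cen)]),
    proliferation_genes = axes$proliferation,
    coefficients = list(a = 1, b = 0.5, c = 0.05),
    thresholds = list(`LN-` = c(-0.15, 0.25), `LN+` = c(-0.25, 0.1))))

  linear <- signature_model(list(
    name = "linear_toy", family = "linear_risk",
    modules = list(
      list(name = "proliferation", genes = axes$proliferation, beta = 1),
      list(name = "er", genes = axes$er, beta = -0.25)),
    intercept = 0,
    thresholds = c(4.3, 5.3)))

  corr_risk <- signature_model(list(
    name = "template_toy", family = "correlation_risk",
    correlation_method = "pearson",
    centroids = cen["LumA", , drop = FALSE],
    thresholds = 0.9,
    classes = c("low", "high")))

  list(centroid_toy5 = centroid, module_toy = modules, ror_toy = ror,
       linear_toy = linear, template_toy = corr_risk)
}
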