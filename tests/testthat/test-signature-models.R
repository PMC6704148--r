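# Signature model loading, gene centering, and the five classification
# families, each checked against trivial cases and independent brute-force
# oracles.

toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes),
         dimnames = list(genes, samples))
}

test_that("bundled model fixtures load and validate field by field", {
  m <- load_signature_model(model_fixture("centroid_toy.yaml"))
  expect_s3_class(m, "signature_model")
  expect_equal(m$family, "centroid_subtype")
  expect_equal(m$classes, c("ClassA", "ClassB"))
  expect_equal(m$centroids["ClassA", c("g1", "g2", "g3")], c(g1 = 1, g2 = 2, g3 = 3))

  ror <- load_signature_model(model_fixture("ror_toy.yaml"))
  expect_equal(ror$family, "ror")
  expect_equal(ror$variant, "Tot")
  expect_named(ror$thresholds, c("LN-", "LN+"))
  expect_equal(ror$thresholds[["LN-"]], c(0.4, 1.2))
  expect_equal(ror$thresholds[["LN+"]], c(0.2, 0.9))
  expect_equal(unname(ror$weights[c("SubA", "SubB")]), c(1, -1))
  expect_equal(ror$centroids["SubA", "g3"], 3)  # from the centroid TSV
  expect_equal(ror$coefficients$a, 1)

  lin <- load_signature_model(model_fixture("linear_toy.yaml"))
  expect_true(lin$modules[[2]]$clip)
  expect_false(lin$modules[[1]]$clip)

  expect_equal(load_signature_model(model_fixture("template_toy.yaml"))$family,
               "correlation_risk")
  expect_equal(load_signature_model(model_fixture("module_toy.yaml"))$class_map$basal,
               "Basal")
})

test_that("schema violations fail with the offending field named", {
  base <- yaml::read_yaml(model_fixture("linear_toy.yaml"))
  bad <- base
  bad$thresholds <- c(2, 1)
  expect_error(signature_model(bad), "strictly increasing")
  bad <- base
  bad$bogus_field <- 1
  expect_error(signature_model(bad), "bogus_field")
  bad <- base
  bad$modules <- NULL
  expect_error(signature_model(bad), "modules")
  expect_error(signature_model(list(name = "x", family = "nope")), "family")
  bad <- base
  bad$genes <- "g1"  # g2, g3 used but undeclared
  expect_error(signature_model(bad), "absent from field 'genes'")
})

test_that("reference-set centering zeroes the reference medians", {
  x <- toy_matrix(c(1, 5, 2, 5, 3, 5, 10, 5), c("ga", "gb"),
                  paste0("s", 1:4))
  # constant gene over full reference becomes all zeros
  cx <- center_genes(x, paste0("s", 1:4))
  expect_equal(unname(cx["gb", ]), rep(0, 4))
  # stated example: [1,2,3,10] centered on first three -> [-1,0,1,8]
  cx2 <- center_genes(x, paste0("s", 1:3))
  expect_equal(unname(cx2["ga", ]), c(-1, 0, 1, 8))
  # random matrix: reference medians all zero afterwards
  set.seed(4)
  m <- matrix(rnorm(1000), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  ref <- sample(colnames(m), 10)
  cm <- center_genes(m, ref)
  meds <- apply(cm[, ref], 1, median)
  expect_equal(unname(meds), rep(0, 50), tolerance = 1e-12)
  expect_error(center_genes(m, character(0)), "at least 2")
  expect_error(center_genes(m, c("s1", "nope")), "nope")
})

test_that("correlation profiles match direct computation and edge rules", {
  cen <- rbind(k1 = c(g1 = 1, g2 = 2, g3 = 3, g4 = 5, g5 = 4),
               k2 = c(g1 = 5, g2 = 1, g3 = 2, g4 = 2, g5 = 3))
  x <- cen["k1", ]
  expect_equal(correlation_profile(x, cen, "spearman")[["k1"]], 1)
  expect_equal(correlation_profile(-x, cen, "pearson")[["k1"]], -1)
  # brute-force Spearman oracle on a 5-gene toy
  set.seed(9)
  for (i in 1:20) {
    xs <- setNames(rnorm(5), paste0("g", 1:5))
    got <- correlation_profile(xs, cen, "spearman")
    expect_equal(got[["k1"]], oracle_spearman(xs, cen["k1", ]),
                 tolerance = 1e-12)
    expect_equal(got[["k2"]], oracle_spearman(xs, cen["k2", ]),
                 tolerance = 1e-12)
  }
  expect_warning(r <- correlation_profile(setNames(1:2, c("g1", "g2")), cen),
                 "fewer than 3")
  expect_true(all(is.na(r)))
})

test_that("nearest-centroid calls recover planted subtypes and break ties", {
  # zero-noise cohort: every sample recovers its generating subtype
  p <- sim_params(n_samples = 60, noise_sd = 0, seed = 13)
  co <- generate_cohort(p)
  model <- cohort_signature_models(p)$centroid_toy5
  labels <- classify_centroid(co$expression, model)
  expect_equal(unname(labels), co$truth$subtype)

  # exact tie resolves to the first declared class
  cen <- rbind(first = c(g1 = 1, g2 = 2, g3 = 3),
               second = c(g1 = 1, g2 = 2, g3 = 3))
  tie_model <- signature_model(list(name = "tie", family = "centroid_subtype",
                                    centroids = cen))
  x <- toy_matrix(c(1, 2, 3), c("g1", "g2", "g3"), "s1")
  expect_equal(unname(classify_centroid(x, tie_model)), "first")

  # moderate noise: exact agreement with the brute-force argmax oracle
  p2 <- sim_params(n_samples = 500, noise_sd = 1, axis_effect = 2, seed = 17)
  co2 <- generate_cohort(p2)
  m2 <- cohort_signature_models(p2)$centroid_toy5
  got <- classify_centroid(co2$expression, m2)
  want <- vapply(seq_len(500), function(i)
    oracle_nearest_centroid(co2$expression[, i], m2$centroids, "spearman"),
    character(1))
  expect_equal(unname(got), want)
})

test_that("ROR variants follow the declared score formula", {
  ror <- load_signature_model(model_fixture("ror_toy.yaml"))
  # sample equal to SubA centroid: r = (1, r_ab); with w = (1, -1),
  # ROR-S = 1 - cor(SubA, SubB)
  x <- toy_matrix(ror$centroids["SubA", ], colnames(ror$centroids), "s1")
  r_ab <- oracle_pearson(ror$centroids["SubA", ], ror$centroids["SubB", ])
  expect_equal(unname(score_ror(x, ror, variant = "S")), 1 - r_ab,
               tolerance = 1e-12)

  # hand arithmetic: w = (1,-1), r = (0.8, 0.2), a = 1, b = 2, P = 0.5
  expect_equal(1 * (1 * 0.8 + (-1) * 0.2) + 2 * 0.5, 1.6)
  # the same arithmetic through the scorer: build a model whose correlations
  # and proliferation term are controlled, then check against an independent
  # evaluation of the formula
  set.seed(31)
  genes <- paste0("g", 1:6)
  cen <- rbind(SubA = setNames(rnorm(6), genes),
               SubB = setNames(rnorm(6), genes))
  m <- signature_model(list(
    name = "ror_ctrl", family = "ror", variant = "P",
    correlation_method = "pearson",
    centroids = cen, weights = list(SubA = 1, SubB = -1),
    proliferation_genes = c("g5", "g6"),
    coefficients = list(a = 1, b = 2),
    thresholds = c(0, 1)))
  xs <- matrix(rnorm(18), 6, 3, dimnames = list(genes, paste0("s", 1:3)))
  got <- score_ror(xs, m, variant = "P")
  pg <- xs[c("g5", "g6"), ] - apply(xs[c("g5", "g6"), ], 1, median)
  for (j in 1:3) {
    want <- (oracle_pearson(xs[, j], cen["SubA", ]) -
               oracle_pearson(xs[, j], cen["SubB", ])) +
      2 * mean(pg[, j])
    expect_equal(unname(got[j]), want, tolerance = 1e-12)
  }

  # monotone in the proliferation module for b > 0
  x_up <- xs
  x_up[c("g5", "g6"), 1] <- x_up[c("g5", "g6"), 1] + 1
  expect_gt(score_ror(x_up, m, variant = "P")[1] - got[1], 0)

  # size-using variant requires clinical size; NA size gives NA score
  clin <- tibble::tibble(sample_id = paste0("s", 1:3),
                         size_mm = c(20, NA, 10))
  m$coefficients$c <- 0.1
  expect_warning(st <- score_ror(xs, m, clin, variant = "PT"), "tumor size")
  expect_true(is.na(st[2]))
  expect_equal(unname(st[1] - got[1]), 0.1 * 2, tolerance = 1e-12)
})

test_that("linear risk scores apply weights, clipping and intercepts", {
  lin <- load_signature_model(model_fixture("linear_toy.yaml"))
  # modules at f = (1, 3): clipped m2 contributes -(3 - 0.5); score
  x <- toy_matrix(c(1, 1, 3), c("g1", "g2", "g3"), "s1")
  expect_equal(unname(score_linear(x, lin)), 2 * 1 - 1 * (3 - 0.5))
  # clipped module below threshold contributes 0
  x2 <- toy_matrix(c(1, 1, 0.2), c("g1", "g2", "g3"), "s1")
  expect_equal(unname(score_linear(x2, lin)), 2)
  # both modules at their floors -> intercept only
  x3 <- toy_matrix(c(0, 0, 0.5), c("g1", "g2", "g3"), "s1")
  expect_equal(unname(score_linear(x3, lin)), lin$intercept)
})

test_that("correlation-to-template calls flip exactly at the threshold", {
  m <- load_signature_model(model_fixture("template_toy.yaml"))
  tpl <- m$centroids["template", ]
  x <- toy_matrix(c(tpl, -tpl), names(tpl), c("same", "neg"))
  res <- classify_correlation_risk(x, m)
  expect_equal(unname(res$labels), c("low", "high"))
  # threshold sweep on a fixed sample: the label flips exactly once
  set.seed(12)
  xs <- toy_matrix(rnorm(4), names(tpl), "s")
  r <- oracle_pearson(xs[, 1], tpl)
  sweep <- seq(-1, 1, by = 0.01)
  labels <- vapply(sweep, function(th) {
    m2 <- m; m2$thresholds <- th
    unname(classify_correlation_risk(xs, m2)$labels)
  }, character(1))
  flips <- which(labels[-1] != labels[-length(labels)])
  expect_length(flips, 1)
  expect_true(sweep[flips] < r && r <= sweep[flips + 1] + 1e-12)
})

test_that("module-score trees follow leaf order and recover subtypes", {
  m <- load_signature_model(model_fixture("module_toy.yaml"))
  # er and her2 below cut -> basal leaf
  x <- toy_matrix(c(0, 0, 0, 0, 0), paste0("g", 1:5), "s1")
  expect_equal(unname(classify_modules(x, m)), "Basal")
  # her2 above cut wins regardless of er
  x2 <- toy_matrix(c(5, 5, 5, 0, 0), paste0("g", 1:5), "s1")
  expect_equal(unname(classify_modules(x2, m)), "HER2E")
  # luminal split by proliferation
  x3 <- toy_matrix(c(5, 5, 0, 0, 0), paste0("g", 1:5), "s1")
  expect_equal(unname(classify_modules(x3, m)), "LumA")
  x4 <- toy_matrix(c(5, 5, 0, 5, 5), paste0("g", 1:5), "s1")
  expect_equal(unname(classify_modules(x4, m)), "LumB")

  # zero-noise cohort without the normal-like class: module tree agrees with
  # the generating subtype at every sample
  p <- sim_params(n_samples = 80, noise_sd = 0, seed = 23,
                  subtype_proportions = c(LumA = 0.4, LumB = 0.25,
                                          HER2E = 0.15, Basal = 0.2))
  co <- generate_cohort(p)
  mod <- cohort_signature_models(p)$module_toy
  expect_equal(unname(classify_modules(co$expression, mod)),
               co$truth$subtype)
})

test_that("risk assignment respects cutpoints, LN keys and NA policy", {
  m <- list(classes = c("low", "intermediate", "high"),
            thresholds = c(1, 2))
  class(m) <- "signature_model"
  s <- c(a = 0.5, b = 1, c = 1.99, d = 2, e = 5, f = NA)
  expect_equal(unname(assign_risk(s, m)),
               c("low", "intermediate", "intermediate", "high", "high", NA))
  # LN-keyed: identical score, different label by nodal status
  ror <- load_signature_model(model_fixture("ror_toy.yaml"))
  clin <- tibble::tibble(sample_id = c("x", "y", "z"),
                         ln_pos_nodes = c(0L, 3L, NA))
  sc <- c(x = 0.3, y = 0.3, z = 0.3)
  expect_equal(unname(assign_risk(sc, ror, clin)),
               c("low", "intermediate", NA))
  # label multiset invariant under score ordering
  set.seed(2)
  sc2 <- setNames(runif(50, 0, 3), paste0("s", 1:50))
  l1 <- assign_risk(sc2, m)
  perm <- sample(50)
  l2 <- assign_risk(sc2[perm], m)
  expect_equal(sort(table(l1)), sort(table(l2)), ignore_attr = TRUE)
  expect_equal(unname(l1[perm]), unname(l2))
})

test_that("cohort classification composes single-model calls", {
  p <- sim_params(n_samples = 50, seed = 29)
  co <- generate_cohort(p)
  models <- cohort_signature_models(p)
  calls <- classify_cohort(co$expression, co$clinical, models)
  expect_equal(names(calls)[1], "sample_id")
  expect_equal(nrow(calls), 50)
  expect_equal(calls$centroid_toy5,
               unname(classify_centroid(co$expression,
                                        models$centroid_toy5)))
  sc <- score_linear(co$expression, models$linear_toy)
  expect_equal(calls$linear_toy_score, unname(sc))
  expect_equal(calls$linear_toy,
               unname(assign_risk(sc, models$linear_toy, co$clinical)))
  # rerun: identical
  expect_identical(calls,
                   classify_cohort(co$expression, co$clinical, models))
  # empty model list: table with sample IDs only
  expect_equal(names(classify_cohort(co$expression, co$clinical, list())),
               "sample_id")
  # a failing model yields an NA column, not an aborted table
  broken <- models$ror_toy
  broken$proliferation_genes <- c("nope1", "nope2")
  expect_warning(
    calls2 <- classify_cohort(co$expression, co$clinical,
                              list(ror_toy = broken,
                                   linear_toy = models$linear_toy)),
    "failed")
  expect_true(all(is.na(calls2$ror_toy)))
  expect_false(anyNA(calls2$linear_toy))
})

test_that("correlation calls are invariant to location/scale changes", {
  p <- sim_params(n_samples = 40, seed = 37)
  co <- generate_cohort(p)
  models <- cohort_signature_models(p)
  cm <- models$centroid_toy5
  base <- classify_centroid(co$expression, cm)
  # adding a constant per sample leaves Spearman calls unchanged
  expect_equal(classify_centroid(co$expression + 3, cm), base)
  # positive rescaling leaves both correlation families unchanged
  expect_equal(classify_centroid(co$expression * 2.5, cm), base)
  tm <- models$template_toy
  expect_equal(classify_correlation_risk(co$expression * 2.5, tm)$labels,
               classify_correlation_risk(co$expression, tm)$labels)
})

test_that("every scorer matches a naive re-computation on random instances", {
  set.seed(41)
  genes <- paste0("g", 1:8)
  for (i in 1:100) {
    cen <- rbind(A = setNames(rnorm(8), genes),
                 B = setNames(rnorm(8), genes))
    w <- c(A = rnorm(1), B = rnorm(1))
    co_ab <- list(a = rnorm(1), b = rnorm(1))
    x <- matrix(rnorm(8), 8, 1, dimnames = list(genes, "s"))
    m <- signature_model(list(
      name = "r", family = "ror", variant = "P",
      correlation_method = "pearson", centroids = cen,
      weights = as.list(w), proliferation_genes = genes[7:8],
      coefficients = co_ab, thresholds = c(0, 1)))
    got <- unname(score_ror(x, m, variant = "P"))
    want <- co_ab$a * (w["A"] * oracle_pearson(x[, 1], cen["A", ]) +
                         w["B"] * oracle_pearson(x[, 1], cen["B", ])) +
      co_ab$b * mean(x[7:8, 1] - apply(x[7:8, , drop = FALSE], 1, median))
    expect_equal(got, unname(want), tolerance = 1e-10)

    betas <- rnorm(2); taus <- rnorm(2); icpt <- rnorm(1)
    lm_ <- signature_model(list(
      name = "l", family = "linear_risk",
      modules = list(list(name = "m1", genes = genes[1:4], beta = betas[1]),
                     list(name = "m2", genes = genes[5:6], beta = betas[2],
                          clip = TRUE, tau = taus[2])),
      intercept = icpt, thresholds = c(0)))
    got_l <- unname(score_linear(x, lm_))
    want_l <- icpt + betas[1] * mean(x[1:4, 1]) +
      betas[2] * max(mean(x[5:6, 1]) - taus[2], 0)
    expect_equal(got_l, want_l, tolerance = 1e-10)
  }
})
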