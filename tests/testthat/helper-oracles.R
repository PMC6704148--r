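# Naive, loop-based reference implementations used as independent oracles.
# These deliberately avoid the package's own code paths (and vectorized
# shortcuts) so that agreement between the two is informative.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

# Spearman via the explicit rank transform (midranks for ties)
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- 1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }
    out
  }
  oracle_pearson(rk(x), rk(y))
}

oracle_nearest_centroid <- function(x, centroids, method = "spearman") {
  f <- if (method == "spearman") oracle_spearman else oracle_pearson
  best <- NA_character_; best_r <- -Inf
  for (k in rownames(centroids)) {
    r <- f(x[colnames(centroids)], centroids[k, ])
    if (!is.na(r) && r > best_r) { best_r <- r; best <- k }
  }
  best
}

oracle_exact_agreement <- function(a, b) {
  matches <- 0; total <- 0
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    total <- total + 1
    if (a[i] == b[i]) matches <- matches + 1
  }
  100 * matches / total
}

oracle_excluding_intermediate <- function(a, b) {
  ka <- character(0); kb <- character(0)
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    if (a[i] == "intermediate" || b[i] == "intermediate") next
    ka <- c(ka, a[i]); kb <- c(kb, b[i])
  }
  if (!length(ka)) return(NA_real_)
  oracle_exact_agreement(ka, kb)
}

oracle_contingency <- function(a, b, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    m[a[i], b[i]] <- m[a[i], b[i]] + 1L
  }
  m
}

# chart geometry from first principles: explicit cumulative sums
oracle_chart <- function(counts) {
  k <- nrow(counts)
  ra <- rowSums(counts); cb <- colSums(counts)
  cum_a <- c(0, cumsum(ra)); cum_b <- c(0, cumsum(cb))
  rect <- cbind(x0 = cum_a[1:k], y0 = cum_b[1:k],
                x1 = cum_a[2:(k + 1)], y1 = cum_b[2:(k + 1)])
  bx0 <- by0 <- numeric(k)
  for (i in seq_len(k)) {
    bx0[i] <- cum_a[i] + if (i > 1) sum(counts[i, 1:(i - 1)]) else 0
    by0[i] <- cum_b[i] + if (i > 1) sum(counts[1:(i - 1), i]) else 0
  }
  black <- cbind(x0 = bx0, y0 = by0,
                 x1 = bx0 + diag(counts), y1 = by0 + diag(counts))
  list(rect = rect, black = black)
}

# unweighted log-rank statistic via explicit O-E and hypergeometric variance
oracle_logrank_2group <- function(times, events, grp) {
  stopifnot(length(unique(grp)) == 2)
  g1 <- sort(unique(grp))[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

random_risk_labels <- function(n, na_rate = 0.05) {
  lab <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                prob = c(0.4, 0.35, 0.25))
  lab[runif(n) < na_rate] <- NA_character_
  lab
}

model_fixture <- function(name) {
  system.file("extdata", "models", name, package = "sigcordance")
}
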