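# Independent brute-force oracles used to cross-check the package's
# statistics, deliberately written as directly as possible.

# Spearman r and two-sided p: rank, then textbook Pearson, then t.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), n - 2)
  list(r = r, p = if (is.nan(p)) 0 else p)
}

# Pooled-variance two-sample t-test, textbook formulas.
oracle_ttest <- function(high, low) {
  nh <- length(high); nl <- length(low)
  sp2 <- ((nh - 1) * var(high) + (nl - 1) * var(low)) / (nh + nl - 2)
  tt <- (mean(high) - mean(low)) / sqrt(sp2 * (1 / nh + 1 / nl))
  list(t = tt, df = nh + nl - 2, p = 2 * pt(-abs(tt), nh + nl - 2),
       fc = mean(high) / mean(low))
}

# Uncorrected chi-squared: sum (O-E)^2 / E over the full table.
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Two-sided Fisher exact p on a 2x2 table by exhaustive enumeration of all
# tables with the observed margins, summing hypergeometric probabilities of
# tables at most as probable as the observed one (with the customary
# relative-error guard against ties in floating point).
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(k, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Product-limit estimator by hand; events precede censorings at ties.
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(times))
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# Two-group log-rank chi-squared from the O-E / V sums over event times.
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tm in times) {
    at1 <- sum(time >= tm & group == 1)
    at2 <- sum(time >= tm & group == 2)
    d1 <- sum(time == tm & event == 1 & group == 1)
    d2 <- sum(time == tm & event == 1 & group == 2)
    n_t <- at1 + at2
    d_t <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d_t * at1 / n_t
    if (n_t > 1)
      v <- v + d_t * (at1 / n_t) * (at2 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Plant substitutions into a reference; returns clone and the truth table.
mutate_reference <- function(reference, positions, alts) {
  chars <- strsplit(reference, "")[[1]]
  truth <- data.frame(position = positions, ref = chars[positions],
                      alt = alts, stringsAsFactors = FALSE)
  chars[positions] <- alts
  list(clone = paste(chars, collapse = ""), truth = truth)
}

# Small random mutation-record table for tally tests.
random_records <- function(n, samples = c("s1", "s2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  type <- sample(sub_types(), n, replace = TRUE)
  data.frame(
    sample = sample(samples, n, replace = TRUE),
    gene = sample(c("gA", "gB", "gC"), n, replace = TRUE),
    position = sample.int(1000, n, replace = TRUE),
    ref = substr(type, 1, 1), alt = substr(type, 3, 3),
    gene_strand = sample(c("+", "-", NA), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Normalized expression + profiles pair from a simulated cohort.
cohort_inputs <- function(spec, seed) {
  co <- simulate_cohort(spec, seed = seed)
  norm <- suppressMessages(tbp_normalize(co$expression))
  prof <- count_profiles(co$mutations, roster = colnames(norm))
  list(cohort = co, norm = norm, profiles = prof)
}
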