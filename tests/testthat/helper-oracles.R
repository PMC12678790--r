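# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# Moran's I by explicit double loop over the displayed formula.
oracle_moran <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  s2 <- mean((x - xb)^2)
  num <- 0
  sw <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    sw <- sw + w[i, j]
  }
  num / (s2 * sw)
}

# Region merging by quadratic scan: every maximal set of >= min_sites
# same-direction sites whose consecutive gaps are all <= max_gap.
oracle_merge <- function(pos, dir, max_gap = 250, min_sites = 3) {
  n <- length(pos)
  runs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && pos[j + 1] - pos[j] <= max_gap && dir[j + 1] == dir[i]) j <- j + 1
    if (j - i + 1 >= min_sites) {
      runs[[length(runs) + 1]] <- c(start = pos[i], end = pos[j], n = j - i + 1)
    }
    i <- j + 1
  }
  runs
}

# Kaplan-Meier product-limit estimate at each distinct event time.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Log-rank chi-squared statistic from the 2xK event table.
oracle_logrank <- function(time, event, group) {
  ts <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (tk in ts) {
    n1 <- sum(time >= tk & group)
    n2 <- sum(time >= tk & !group)
    d1 <- sum(time == tk & event & group)
    d2 <- sum(time == tk & event & !group)
    n <- n1 + n2
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Fisher-Jenks objective by exhaustive search over all partitions of the
# sorted values into k contiguous groups.
oracle_jenks_objective <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (c in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, c], n)
    obj <- 0
    for (g in seq_len(k)) obj <- obj + ssd(x[(bounds[g] + 1):bounds[g + 1]])
    if (obj < best) best <- obj
  }
  best
}

# Small deterministic survival fixture with tied and censored times.
survival_fixture <- function() {
  data.frame(
    time = c(2, 3, 3, 5, 7, 8, 8, 10, 12, 14),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    group = rep(c(TRUE, FALSE), 5))
}

# A small cohort_matrix built directly from a patients x regions value
# generator, bypassing the simulator (12 patients unless stated).
cohort_from_values <- function(value_fn, n_sites = 1, n_patients = 12,
                               coverage = 50L) {
  labs <- methgrad::region_labels()
  rows <- list()
  for (s in seq_len(n_sites)) {
    vals <- value_fn(s)  # n_patients x 7 matrix of fractions (NA = missing)
    for (p in seq_len(n_patients)) for (r in 1:7) {
      v <- vals[p, r]
      if (is.na(v)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", pos = 1000L * s,
        patient = sprintf("PT%02d", p), region = labs[r],
        meth_count = round(coverage * v),
        unmeth_count = coverage - round(coverage * v))
    }
  }
  df <- do.call(rbind, rows)
  methgrad::cohort_from_simulation(df, min_coverage = 1)
}
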