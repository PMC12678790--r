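#' Relative tumor-vs-adjacent methylation difference
#'
#' \code{d = 100 * (adjacent - tumor) / tumor} percent, clamped to
#' [-100, 100] with a warning when clamping occurs (the raw ratio is not
#' bounded above by +100; the clamp keeps the documented range). A tumor
#' methylation of zero leaves the difference undefined (NA, with warning).
#'
#' @param tumor,adjacent methylation fractions in [0, 1].
#' @return Signed percent difference(s) in [-100, 100].
#' @export
relative_difference <- function(tumor, adjacent) {
  stopifnot(all(tumor >= 0 & tumor <= 1, na.rm = TRUE),
            all(adjacent >= 0 & adjacent <= 1, na.rm = TRUE))
  d <- ifelse(tumor > 0, 100 * (adjacent - tumor) / tumor, NA_real_)
  if (any(tumor == 0, na.rm = TRUE)) {
    warning("tumor methylation 0: relative difference undefined for ",
            sum(tumor == 0, na.rm = TRUE), " value(s)")
  }
  if (any(abs(d) > 100, na.rm = TRUE)) {
    warning(sum(abs(d) > 100, na.rm = TRUE),
            " relative difference(s) clamped to +/-100%")
  }
  pmin(100, pmax(-100, d))
}

#' Classify a relative difference as low (shallow-like) or high
#'
#' \code{|d| < threshold} is a low-difference ("shallow") change; values at
#' or above the threshold are high-difference ("steep"); the boundary is
#' strict. Thresholds outside the studied 3-15 percent sweep are allowed
#' with a warning.
#'
#' @param d signed percent difference(s).
#' @param threshold percent threshold (default 5).
#' @return Character vector, \code{"low_difference"} or
#'   \code{"high_difference"} (NA preserved).
#' @export
classify_difference <- function(d, threshold = 5) {
  if (threshold < 3 || threshold > 15) {
    warning("threshold ", threshold, " outside the studied 3-15% range")
  }
  ifelse(is.na(d), NA_character_,
         ifelse(abs(d) < threshold, "low_difference", "high_difference"))
}

# Long records -> per-patient wide pieces used by the stratifiers.
prognosis_survival <- function(records) {
  surv <- unique(records[, c("patient", "time", "event",
                             intersect("stage", names(records)))])
  if (anyDuplicated(surv$patient)) stop("inconsistent survival rows per patient")
  surv
}

# Log-rank O/E hazard-ratio estimate: (O1/E1)/(O2/E2) for group 1 vs 2.
logrank_oe_hr <- function(time, event, group1) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group1)
  # row order of survdiff follows factor levels FALSE, TRUE
  o <- sd$obs; e <- sd$exp
  (o[2] / e[2]) / (o[1] / e[1])
}

# Shared KM / log-rank / Cox machinery for a binary risk indicator
# (TRUE = the group expected to carry the higher hazard).
stratify_survival <- function(time, event, risk, estimator = c("cox", "oe")) {
  estimator <- match.arg(estimator)
  if (length(unique(risk)) < 2) {
    return(list(hr = NA_real_, hr_ci = c(NA_real_, NA_real_),
                logrank_p = NA_real_, km = NULL,
                n = table(factor(risk, levels = c(FALSE, TRUE))),
                note = "one group empty: stratification undefined"))
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ risk)
  sd <- survival::survdiff(survival::Surv(time, event) ~ risk)
  logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(survival::Surv(time, event) ~ risk, ties = "efron")
  if (estimator == "cox") {
    hr <- unname(exp(stats::coef(cox)[1]))
    ci <- unname(exp(stats::confint(cox)[1, ]))
  } else {
    hr <- logrank_oe_hr(time, event, risk)
    ci <- c(NA_real_, NA_real_)
  }
  list(hr = hr, hr_ci = ci, logrank_p = logrank_p, km = sf,
       n = table(risk), cox = cox)
}

#' Single-site survival stratification
#'
#' Splits patients into low- versus high-difference groups at one target
#' CpG site and compares overall survival: Kaplan-Meier curves, the
#' log-rank (Mantel-Cox) chi-squared P value, and the hazard ratio of the
#' low-difference group from a univariate Cox fit (Efron ties; the log-rank
#' O/E estimator is available via \code{estimator = "oe"}).
#'
#' @param records long \code{data.frame} with columns \code{patient, site,
#'   tumor_meth, adjacent_meth, time, event} (one row per patient-site).
#' @param site site identifier to stratify on.
#' @param threshold percent difference threshold (default 5).
#' @param estimator \code{"cox"} or \code{"oe"}.
#' @return List of class \code{risk_stratification}: \code{hr} (hazard of
#'   low-difference relative to high-difference patients), \code{hr_ci},
#'   \code{logrank_p}, \code{km}, \code{groups} (per-patient classes),
#'   \code{n}.
#' @export
single_site_stratify <- function(records, site, threshold = 5,
                                 estimator = c("cox", "oe")) {
  rec <- records[records$site == site, ]
  if (nrow(rec) == 0) stop("no records for site ", site)
  d <- relative_difference(rec$tumor_meth, rec$adjacent_meth)
  cls <- classify_difference(d, threshold)
  ok <- !is.na(cls)
  res <- stratify_survival(rec$time[ok], rec$event[ok],
                           cls[ok] == "low_difference", estimator)
  res$groups <- data.frame(patient = rec$patient[ok], d = d[ok], class = cls[ok])
  res$site <- site; res$threshold <- threshold
  class(res) <- "risk_stratification"
  res
}

#' Hazard-ratio sweep over sites and thresholds
#'
#' Evaluates \code{\link{single_site_stratify}} on the full grid of target
#' sites and difference thresholds. Low-difference group membership is
#' monotone non-decreasing in the threshold (asserted).
#'
#' @param records long prognosis records.
#' @param sites site identifiers (default: all in \code{records}).
#' @param thresholds percent grid (default 3:15).
#' @param estimator passed through.
#' @return \code{data.frame} with columns \code{site, threshold, hr,
#'   hr_lo, hr_hi, logrank_p, n_low, n_high}.
#' @export
threshold_sweep <- function(records, sites = unique(records$site),
                            thresholds = 3:15, estimator = "cox") {
  stopifnot(length(thresholds) > 0)
  rows <- list()
  for (s in sites) {
    prev_low <- -1L
    for (th in sort(thresholds)) {
      st <- single_site_stratify(records, s, th, estimator)
      n_low <- sum(st$groups$class == "low_difference")
      stopifnot(n_low >= prev_low)  # monotone set inclusion
      prev_low <- n_low
      rows[[length(rows) + 1]] <- data.frame(
        site = s, threshold = th, hr = st$hr,
        hr_lo = st$hr_ci[1], hr_hi = st$hr_ci[2],
        logrank_p = st$logrank_p, n_low = n_low,
        n_high = sum(st$groups$class == "high_difference"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined multi-site risk model
#'
#' A patient is high-risk when at least \code{N} of the named target sites
#' show a low-difference (shallow-like) change at the given threshold;
#' otherwise low-risk. Survival comparison as in
#' \code{\link{single_site_stratify}}, with the hazard ratio reported for
#' high-risk relative to low-risk patients. Patients missing some sites are
#' counted over their available sites and flagged.
#'
#' @param records long prognosis records.
#' @param site_set sites entering the count (e.g. the 5-site panel).
#' @param N minimum low-difference sites for high risk (default 2).
#' @param threshold percent difference threshold (default 5).
#' @param estimator \code{"cox"} or \code{"oe"}.
#' @return List of class \code{risk_stratification} with \code{risk}
#'   (per-patient data.frame: patient, n_low, n_sites, high_risk,
#'   incomplete).
#' @export
combined_model <- function(records, site_set, N = 2, threshold = 5,
                           estimator = c("cox", "oe")) {
  stopifnot(N >= 1, N <= length(site_set))
  rec <- records[records$site %in% site_set, ]
  if (nrow(rec) == 0) stop("no records for the requested sites")
  d <- relative_difference(rec$tumor_meth, rec$adjacent_meth)
  low <- classify_difference(d, threshold) == "low_difference"
  n_low <- tapply(low, rec$patient, function(v) sum(v, na.rm = TRUE))
  n_sites <- tapply(!is.na(low), rec$patient, sum)
  per_pat <- data.frame(patient = names(n_low),
                        n_low = as.integer(n_low),
                        n_sites = as.integer(n_sites),
                        stringsAsFactors = FALSE)
  per_pat$high_risk <- per_pat$n_low >= N
  per_pat$incomplete <- per_pat$n_sites < length(site_set)
  if (any(per_pat$incomplete)) {
    warning(sum(per_pat$incomplete), " patient(s) missing sites; ",
            "counts use available sites")
  }
  surv <- prognosis_survival(rec)
  m <- merge(per_pat, surv, by = "patient")
  res <- stratify_survival(m$time, m$event, m$high_risk, match.arg(estimator))
  res$risk <- per_pat
  res$N <- N; res$threshold <- threshold; res$site_set <- site_set
  class(res) <- "risk_stratification"
  res
}

#' Risk-class by TNM-stage contingency table
#'
#' Cross-tabulates the combined model's risk classes against TNM stage and
#' reports an association P value: chi-squared when all expected cell
#' counts reach 5, Fisher's exact test otherwise. Patients without a stage
#' are excluded and their count reported.
#'
#' @param stratification a \code{risk_stratification} from
#'   \code{\link{combined_model}}.
#' @param stages \code{data.frame} with columns \code{patient, stage}.
#' @return List with \code{table}, \code{p}, \code{test},
#'   \code{n_missing_stage}.
#' @export
stage_crosstab <- function(stratification, stages) {
  stopifnot(inherits(stratification, "risk_stratification"),
            !is.null(stratification$risk))
  m <- merge(stratification$risk, stages, by = "patient", all.x = TRUE)
  n_missing <- sum(is.na(m$stage))
  m <- m[!is.na(m$stage), ]
  tab <- table(risk = ifelse(m$high_risk, "high_risk", "low_risk"),
               stage = m$stage)
  if (min(dim(tab)) < 2) {
    return(list(table = tab, p = NA_real_, test = "none",
                n_missing_stage = n_missing))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(tab, correct = FALSE)
    test <- "chisq"
  } else {
    ht <- stats::fisher.test(tab)
    test <- "fisher"
  }
  list(table = tab, p = ht$p.value, test = test, n_missing_stage = n_missing)
}
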