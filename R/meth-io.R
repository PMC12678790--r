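#' Read a Bismark-style coverage file
#'
#' Parses the 6-column coverage dialect (chrom, start, end, methylation
#' percentage, methylated count, unmethylated count; positions 1-based
#' inclusive). The percentage column is cross-checked against the counts;
#' disagreements beyond 0.5 percentage points raise a warning.
#'
#' @param path file path.
#' @return A \code{data.frame} with columns \code{chrom, pos, meth_count,
#'   unmeth_count}, sorted by (chrom, pos).
#' @export
read_bismark_coverage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(chrom = character(), pos = integer(),
                      meth_count = integer(), unmeth_count = integer())
  if (file.size(path) == 0) return(empty)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer", "integer",
                                     "numeric", "integer", "integer")),
    error = function(e) stop("malformed coverage file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(tab) != 6) stop("expected 6 columns in ", path, ", got ", ncol(tab))
  bad <- which(tab[[5]] < 0 | tab[[6]] < 0 | is.na(tab[[2]]))
  if (length(bad)) stop("malformed line ", bad[1], " in ", path)
  cov <- tab[[5]] + tab[[6]]
  pct <- ifelse(cov > 0, 100 * tab[[5]] / cov, 0)
  if (any(abs(pct - tab[[4]]) > 0.5)) {
    warning("methylation % disagrees with counts by > 0.5 in ", path)
  }
  out <- data.frame(chrom = tab[[1]], pos = tab[[2]],
                    meth_count = tab[[5]], unmeth_count = tab[[6]],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Assemble per-sample records into a cohort matrix
#'
#' Builds the sites-by-samples methylation-fraction and coverage matrices
#' over the union of all sites, applying the per-cell coverage floor: cells
#' with coverage strictly below \code{min_coverage} are set missing ("less
#' than 15x" is strict, so 15x is retained). Sites are keyed by
#' (chrom, 1-based position) on the forward strand.
#'
#' @param samples named list of record \code{data.frame}s as returned by
#'   \code{\link{read_bismark_coverage}}; names must match
#'   \code{layout$sample}.
#' @param layout \code{data.frame} with columns \code{sample, patient,
#'   region}; every region must be one of \code{\link{region_labels}} and
#'   (patient, region) must be unique.
#' @param min_coverage per-cell coverage floor (default 15 reads).
#' @return An object of class \code{cohort_matrix}: list with \code{sites}
#'   (data.frame chrom, pos), \code{samples} (the layout, ordered by patient
#'   then region), \code{meth} (fraction matrix, NA = missing) and
#'   \code{coverage}.
#' @export
assemble_cohort <- function(samples, layout, min_coverage = 15) {
  stopifnot(is.list(samples), all(c("sample", "patient", "region") %in% names(layout)))
  layout$region <- as.character(layout$region)
  region_ordinal(layout$region)  # errors on unknown labels
  if (anyDuplicated(layout[, c("patient", "region")])) {
    stop("duplicate (patient, region) in layout")
  }
  missing_src <- setdiff(layout$sample, names(samples))
  if (length(missing_src)) stop("no records for sample(s): ",
                                paste(missing_src, collapse = ", "))
  layout <- layout[order(layout$patient, region_ordinal(layout$region)), ]
  all_sites <- unique(do.call(rbind, lapply(unname(samples[layout$sample]),
                                            function(s) s[, c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos)
  n_sites <- nrow(all_sites)
  n_samp <- nrow(layout)
  meth <- matrix(NA_real_, n_sites, n_samp,
                 dimnames = list(key, layout$sample))
  coverage <- matrix(0L, n_sites, n_samp, dimnames = dimnames(meth))
  for (j in seq_len(n_samp)) {
    rec <- samples[[layout$sample[j]]]
    idx <- match(paste(rec$chrom, rec$pos), key)
    cov <- rec$meth_count + rec$unmeth_count
    coverage[idx, j] <- cov
    frac <- ifelse(cov > 0, rec$meth_count / cov, NA_real_)
    frac[cov < min_coverage] <- NA_real_
    meth[idx, j] <- frac
  }
  structure(list(sites = all_sites, samples = layout, meth = meth,
                 coverage = coverage, min_coverage = min_coverage),
            class = "cohort_matrix")
}

#' Build a cohort matrix directly from a simulated cohort
#'
#' Convenience path from \code{\link{simulate_methylation_cohort}} output to
#' a \code{cohort_matrix} without writing files; applies the same coverage
#' floor as \code{\link{assemble_cohort}}.
#'
#' @param cohort long simulated cohort \code{data.frame}.
#' @param min_coverage per-cell coverage floor.
#' @return A \code{cohort_matrix}.
#' @export
cohort_from_simulation <- function(cohort, min_coverage = 15) {
  sample_id <- paste(cohort$patient, cohort$region, sep = "_")
  layout <- unique(data.frame(sample = sample_id, patient = cohort$patient,
                              region = cohort$region, stringsAsFactors = FALSE))
  recs <- split(cohort[, c("chrom", "pos", "meth_count", "unmeth_count")],
                sample_id)
  assemble_cohort(recs, layout, min_coverage = min_coverage)
}

#' Detection-frequency filter over cohort sites
#'
#' Counts, per site, the samples in which it has data after the coverage
#' floor, then selects sites in the high-detection-frequency component.
#' \code{mode = "em"} fits a two-component one-dimensional Gaussian mixture
#' to the detection counts by EM (tolerance 1e-8, at most 500 iterations,
#' quantile initialisation) and sets the threshold at the smallest count
#' whose posterior for the high-mean component is at least 0.5;
#' \code{mode = "fixed"} uses \code{fixed_threshold} directly (e.g., 68 of
#' 84 samples). "Detected in at least N" is inclusive: detection >= threshold
#' is kept.
#'
#' @param cohort a \code{cohort_matrix}.
#' @param mode \code{"em"} or \code{"fixed"}.
#' @param fixed_threshold required when \code{mode = "fixed"}; also the
#'   fallback if EM degenerates (otherwise the fallback is 81\% of the
#'   sample count, the study's 68-of-84 proportion).
#' @return A list of class \code{detection_filter}: \code{detection_count}
#'   (per site), \code{threshold}, \code{kept} (logical per site),
#'   \code{mixture} (EM fit or NULL), \code{mode}.
#' @export
detection_frequency_filter <- function(cohort, mode = c("em", "fixed"),
                                       fixed_threshold = NULL) {
  stopifnot(inherits(cohort, "cohort_matrix"), nrow(cohort$meth) > 0)
  mode <- match.arg(mode)
  counts <- rowSums(!is.na(cohort$meth))
  n_samp <- ncol(cohort$meth)
  fit <- NULL
  if (mode == "fixed") {
    if (is.null(fixed_threshold)) stop("fixed mode requires fixed_threshold")
    threshold <- fixed_threshold
  } else {
    fit <- fit_gmm_em(counts, k = 2)
    if (is.null(fit)) {
      threshold <- if (!is.null(fixed_threshold)) fixed_threshold
                   else ceiling(n_samp * 68 / 84)
      warning("degenerate detection-count distribution; ",
              "falling back to fixed threshold ", threshold)
      mode <- "fixed"
    } else {
      support <- seq(0L, n_samp)
      post_high <- gmm_posterior(fit, support)[, 2]
      cross <- support[post_high >= 0.5]
      threshold <- if (length(cross)) min(cross) else n_samp + 1L
    }
  }
  stopifnot(threshold >= 0)
  structure(list(detection_count = counts, threshold = threshold,
                 kept = counts >= threshold, mixture = fit, mode = mode),
            class = "detection_filter")
}

#' Subset a cohort matrix to a set of sites
#'
#' @param cohort a \code{cohort_matrix}.
#' @param keep logical or integer index over rows of \code{cohort$sites}.
#' @return The subset \code{cohort_matrix}.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  cohort$sites <- cohort$sites[keep, , drop = FALSE]
  rownames(cohort$sites) <- NULL
  cohort$meth <- cohort$meth[keep, , drop = FALSE]
  cohort$coverage <- cohort$coverage[keep, , drop = FALSE]
  cohort
}

#' Extract one site's patients-by-regions methylation matrix
#'
#' @param cohort a \code{cohort_matrix}.
#' @param i site row index.
#' @return Numeric matrix, patients in rows, the 7 regions in fixed order in
#'   columns; NA marks missing cells.
#' @export
site_profile <- function(cohort, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nrow(cohort$meth))
  lay <- cohort$samples
  patients <- unique(lay$patient)
  m <- matrix(NA_real_, length(patients), 7,
              dimnames = list(patients, region_labels()))
  m[cbind(match(lay$patient, patients), region_ordinal(lay$region))] <-
    cohort$meth[i, ]
  m
}
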