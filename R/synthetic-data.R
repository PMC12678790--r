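#' Planted spatial methylation pattern
#'
#' Describes the true spatial behaviour of a group of simulated CpG sites
#' across the seven ordered sampling positions. "Rise" and "decline" describe
#' the tumor-to-normal (TC to PN) direction of methylation: a rise pattern
#' increases from TC to PN. Steep patterns place the entire effect at the
#' TE|P5 boundary (tumor-confined change); shallow patterns interpolate it
#' linearly across all seven positions; flat patterns have a constant mean;
#' fluctuating patterns draw each region mean independently.
#'
#' @param kind one of \code{"steep_rise"}, \code{"steep_decline"},
#'   \code{"shallow_rise"}, \code{"shallow_decline"}, \code{"flat"},
#'   \code{"fluctuating"}.
#' @param base_level methylation fraction at TC, in [0, 1].
#' @param effect_size total tumor-to-PN change in methylation fraction
#'   (non-negative; rise adds it toward PN, decline subtracts it).
#' @param per_patient_sd sd of a patient-level offset shared by all of a
#'   patient's regions at a site (fraction units).
#' @param per_cell_sd sd of the per-cell beta noise around the cell mean
#'   (fraction units); 0 makes counts deterministic given coverage.
#' @return An object of class \code{planted_pattern}.
#' @export
planted_pattern <- function(kind, base_level = 0.3, effect_size = 0.3,
                            per_patient_sd = 0.03, per_cell_sd = 0.05) {
  kinds <- c("steep_rise", "steep_decline", "shallow_rise", "shallow_decline",
             "flat", "fluctuating")
  kind <- match.arg(kind, kinds)
  stopifnot(effect_size >= 0, base_level >= 0, base_level <= 1,
            per_patient_sd >= 0, per_cell_sd >= 0)
  target <- if (grepl("decline", kind)) base_level - effect_size else base_level + effect_size
  if (target < 0 || target > 1) {
    warning("effect pushes region means outside [0, 1]; they will be clamped")
  }
  structure(list(kind = kind, base_level = base_level, effect_size = effect_size,
                 per_patient_sd = per_patient_sd, per_cell_sd = per_cell_sd),
            class = "planted_pattern")
}

#' Default planted-pattern set
#'
#' One pattern of each kind at the package's study-condition defaults.
#' Declining kinds start from a symmetric high baseline so the effect stays
#' inside [0, 1].
#'
#' @param effect_size total tumor-to-PN change (fraction).
#' @param per_patient_sd,per_cell_sd noise levels passed to
#'   \code{\link{planted_pattern}}.
#' @return Named list of \code{planted_pattern} objects.
#' @export
default_patterns <- function(effect_size = 0.3, per_patient_sd = 0.03,
                             per_cell_sd = 0.05) {
  kinds <- c("steep_rise", "steep_decline", "shallow_rise", "shallow_decline",
             "flat", "fluctuating")
  pats <- lapply(kinds, function(k) {
    base <- if (grepl("decline", k)) 0.6 else 0.3
    planted_pattern(k, base_level = base, effect_size = effect_size,
                    per_patient_sd = per_patient_sd, per_cell_sd = per_cell_sd)
  })
  names(pats) <- kinds
  pats
}

# True region mean profile (length 7, TC..PN order) for one site of a pattern.
# Fluctuating profiles consume randomness from the caller's RNG stream.
pattern_profile <- function(pattern) {
  base <- pattern$base_level
  eff <- pattern$effect_size
  signed <- if (grepl("decline", pattern$kind)) -eff else eff
  prof <- switch(pattern$kind,
    flat = rep(base, 7),
    steep_rise = ,
    steep_decline = c(base, base, rep(base + signed, 5)),
    shallow_rise = ,
    shallow_decline = base + signed * (0:6) / 6,
    fluctuating = stats::runif(7, min = base - eff, max = base + eff)
  )
  clamp01(prof)
}

#' Synthetic methylation cohort configuration
#'
#' Fixes the study conditions the generator emulates: 12 patients sampled at
#' the seven ordered positions, negative-binomial read coverage with mean
#' well above the 15x analysis floor, and uniform-at-random per-cell
#' missingness at a rate that makes the detection-frequency filter
#' non-trivial.
#'
#' @param n_patients number of patients (>= 3; default 12).
#' @param sites_per_pattern simulated CpG sites per planted pattern.
#' @param coverage_mean mean read coverage per cell (default 30).
#' @param coverage_dispersion negative-binomial dispersion of coverage
#'   (variance = mean + dispersion * mean^2).
#' @param missing_rate probability that a cell is dropped before output.
#' @param cluster_size sites per genomic locus; sites within a locus are
#'   \code{within_cluster_gap} bp apart (emulates the clustered CpG regions
#'   the region-merging stage targets).
#' @param within_cluster_gap,between_locus_gap spacing in bp.
#' @param seed integer seed fixing all randomness.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 12, sites_per_pattern = 100,
                          coverage_mean = 30, coverage_dispersion = 0.1,
                          missing_rate = 0.1, cluster_size = 3,
                          within_cluster_gap = 25, between_locus_gap = 10000,
                          seed = 1) {
  stopifnot(n_patients >= 3, coverage_mean >= 15, coverage_dispersion > 0,
            missing_rate >= 0, missing_rate < 1, cluster_size >= 1,
            sites_per_pattern >= 1)
  structure(list(n_patients = n_patients, region_labels = region_labels(),
                 sites_per_pattern = sites_per_pattern,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 missing_rate = missing_rate, cluster_size = cluster_size,
                 within_cluster_gap = within_cluster_gap,
                 between_locus_gap = between_locus_gap,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a methylation cohort with planted spatial trends
#'
#' Draws per-(site, patient, region) methylated/unmethylated read counts.
#' For each site, the region mean profile comes from its planted pattern; a
#' patient offset (shared across that patient's regions) adds biological
#' between-patient variation; when \code{per_cell_sd > 0} the cell's
#' methylation probability is drawn from a beta distribution with that sd
#' around the cell mean and counts are binomial given coverage
#' (beta-binomial overdispersion), while \code{per_cell_sd = 0} yields
#' deterministic counts \code{round(coverage * mean)}. Coverage is
#' negative-binomial (floored at 1 read) and cells are dropped uniformly at
#' random at \code{missing_rate}. Each site consumes a named RNG sub-stream
#' derived from the global seed, so output is invariant under re-run.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param patterns list of \code{\link{planted_pattern}} objects (default
#'   \code{\link{default_patterns}()}).
#' @return A long \code{data.frame} with columns \code{site_id, chrom, pos,
#'   patient, region, meth_count, unmeth_count} (one row per retained cell;
#'   \code{pos} 1-based), with a per-site truth table in
#'   \code{attr(, "truth")} (\code{site_id, chrom, pos, true_class}).
#' @export
simulate_methylation_cohort <- function(config = cohort_config(),
                                        patterns = default_patterns()) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(names(patterns))) names(patterns) <- vapply(patterns, `[[`, "", "kind")
  n_pat <- config$n_patients
  regions <- config$region_labels
  n_sites_total <- length(patterns) * config$sites_per_pattern

  # deterministic genomic layout: loci of cluster_size same-pattern sites
  # (emulating the clustered CpG regions real trends occur in), loci
  # interleaved round-robin across patterns along the chromosome
  site_tab <- do.call(rbind, lapply(seq_along(patterns), function(pi) {
    data.frame(pattern = names(patterns)[pi],
               site_in_pattern = seq_len(config$sites_per_pattern))
  }))
  locus_in_pattern <- ceiling(site_tab$site_in_pattern / config$cluster_size)
  offset_in_locus <- (site_tab$site_in_pattern - 1) %% config$cluster_size
  pattern_idx <- match(site_tab$pattern, names(patterns))
  locus_id <- (locus_in_pattern - 1) * length(patterns) + pattern_idx
  site_tab$pos <- locus_id * config$between_locus_gap +
    offset_in_locus * config$within_cluster_gap + 1L
  site_tab$chrom <- "chr1"
  site_tab <- site_tab[order(site_tab$pos), ]
  site_tab$site_id <- sprintf("%s:%d", site_tab$chrom, site_tab$pos)

  cells <- vector("list", nrow(site_tab))
  for (s in seq_len(nrow(site_tab))) {
    set.seed(derive_seed(config$seed, s))
    pat <- patterns[[site_tab$pattern[s]]]
    prof <- pattern_profile(pat)
    patient_off <- stats::rnorm(n_pat, 0, pat$per_patient_sd)
    mu <- clamp01(outer(patient_off, prof, `+`))  # patients x regions
    cov <- matrix(pmax(1L, stats::rnbinom(n_pat * 7, mu = config$coverage_mean,
                                          size = 1 / config$coverage_dispersion)),
                  n_pat, 7)
    if (pat$per_cell_sd > 0) {
      p_cell <- matrix(rbeta_meansd(as.vector(mu), pat$per_cell_sd), n_pat, 7)
      meth <- matrix(stats::rbinom(n_pat * 7, as.vector(cov), as.vector(p_cell)),
                     n_pat, 7)
    } else {
      meth <- round(cov * mu)
    }
    keep <- matrix(stats::runif(n_pat * 7) >= config$missing_rate, n_pat, 7)
    idx <- which(keep, arr.ind = TRUE)
    cells[[s]] <- data.frame(
      site_id = site_tab$site_id[s], chrom = site_tab$chrom[s],
      pos = site_tab$pos[s],
      patient = sprintf("PT%02d", idx[, 1]),
      region = regions[idx[, 2]],
      meth_count = meth[keep], unmeth_count = cov[keep] - meth[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  truth <- data.frame(site_id = site_tab$site_id, chrom = site_tab$chrom,
                      pos = site_tab$pos, true_class = site_tab$pattern,
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

# Beta draw with given mean vector and common sd; degenerate means (0/1) and
# sds too large for the mean are handled by clamping.
rbeta_meansd <- function(mu, sd) {
  out <- mu
  inner <- mu > 0 & mu < 1
  if (sd > 0 && any(inner)) {
    m <- mu[inner]
    max_sd <- sqrt(m * (1 - m)) * 0.95
    s <- pmin(sd, max_sd)
    nu <- m * (1 - m) / s^2 - 1
    out[inner] <- stats::rbeta(sum(inner), m * nu, (1 - m) * nu)
  }
  out
}

#' Write a simulated cohort as per-sample Bismark-style coverage files
#'
#' One TSV per (patient, region) sample in the 6-column Bismark coverage
#' dialect: chrom, start, end (1-based inclusive, start = end for a CpG),
#' methylation percentage, methylated count, unmethylated count. Also writes
#' \code{truth.tsv} (site truth labels) and \code{layout.tsv} (sample,
#' patient, region).
#'
#' @param cohort output of \code{\link{simulate_methylation_cohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the layout \code{data.frame}.
#' @export
write_bismark_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  key <- interaction(cohort$patient, cohort$region, drop = TRUE, sep = "_")
  layout <- unique(data.frame(sample = as.character(key),
                              patient = cohort$patient, region = cohort$region,
                              stringsAsFactors = FALSE))
  layout <- layout[order(layout$patient, region_ordinal(layout$region)), ]
  for (i in seq_len(nrow(layout))) {
    rows <- cohort[key == layout$sample[i], ]
    rows <- rows[order(rows$chrom, rows$pos), ]
    cov <- rows$meth_count + rows$unmeth_count
    tab <- data.frame(rows$chrom, rows$pos, rows$pos,
                      round(100 * rows$meth_count / cov, 6),
                      rows$meth_count, rows$unmeth_count)
    utils::write.table(tab, file.path(dir, paste0(layout$sample[i], ".cov")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(attr(cohort, "truth"), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(layout, file.path(dir, "layout.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(layout)
}

#' Synthetic survival-cohort configuration
#'
#' Emulates the prognosis validation setting: 59 patients with paired
#' tumor/adjacent methylation at a small panel of target CpG sites and
#' about 18 endpoint events over follow-up. Each patient-site is
#' independently "low-difference" (shallow-like) with probability
#' \code{p_shallow}; patients with at least \code{risk_min_sites} such sites
#' carry \code{planted_hr} times the baseline hazard.
#'
#' @param n_patients cohort size (default 59).
#' @param n_sites number of target CpG sites (default 6).
#' @param planted_hr hazard ratio of the high-risk group (> 0).
#' @param p_shallow per-site probability of a low-difference call.
#' @param risk_min_sites minimum low-difference sites defining the planted
#'   high-risk group (default 2).
#' @param censor_rate approximate probability of censoring (default 0.7,
#'   emulating ~18 events in 59 patients).
#' @param baseline_scale mean baseline survival time, in months.
#' @param shallow_band half-width (percent) of the relative-difference band
#'   low-difference sites are drawn inside; high-difference sites are drawn
#'   outside twice this band.
#' @param seed integer seed.
#' @return An object of class \code{prognosis_config}.
#' @export
prognosis_config <- function(n_patients = 59, n_sites = 6, planted_hr = 4,
                             p_shallow = 0.3, risk_min_sites = 2,
                             censor_rate = 0.7, baseline_scale = 60,
                             shallow_band = 4, seed = 1) {
  stopifnot(n_patients >= 2, n_sites >= 1, planted_hr > 0,
            p_shallow > 0, p_shallow < 1, censor_rate >= 0, censor_rate < 1,
            baseline_scale > 0, shallow_band > 0)
  structure(list(n_patients = n_patients, n_sites = n_sites,
                 planted_hr = planted_hr, p_shallow = p_shallow,
                 risk_min_sites = as.integer(risk_min_sites),
                 censor_rate = censor_rate, baseline_scale = baseline_scale,
                 shallow_band = shallow_band, seed = as.integer(seed)),
            class = "prognosis_config")
}

#' Simulate a paired tumor/adjacent survival cohort
#'
#' Tumor methylation at each target site is uniform on [0.2, 0.8]. At
#' low-difference (shallow-like) sites the adjacent value is placed within
#' \code{shallow_band} percent relative difference of the tumor value; at
#' high-difference sites it is placed between 2 and 10 bands away (sign
#' random), so a threshold anywhere between one and two bands recovers the
#' planted status. Survival is exponential with rate
#' \code{planted_hr^is_high_risk / baseline_scale}; censoring is an
#' independent exponential calibrated to \code{censor_rate}. TNM stage is
#' drawn with stage III/IV enriched in the high-risk group.
#'
#' @param config a \code{\link{prognosis_config}}.
#' @return A \code{data.frame} with one row per (patient, site):
#'   \code{patient, site, tumor_meth, adjacent_meth, time, event, stage},
#'   plus per-patient truth in \code{attr(, "truth")} (\code{patient,
#'   n_shallow_sites, high_risk}).
#' @export
simulate_prognosis_cohort <- function(config = prognosis_config()) {
  stopifnot(inherits(config, "prognosis_config"))
  set.seed(config$seed)
  n <- config$n_patients
  k <- config$n_sites
  band <- config$shallow_band
  shallow <- matrix(stats::runif(n * k) < config$p_shallow, n, k)
  tumor <- matrix(stats::runif(n * k, 0.2, 0.8), n, k)
  d_pct <- matrix(0, n, k)
  d_pct[shallow] <- stats::runif(sum(shallow), -0.9 * band, 0.9 * band)
  n_hi <- sum(!shallow)
  d_pct[!shallow] <- sample(c(-1, 1), n_hi, replace = TRUE) *
    stats::runif(n_hi, 2 * band, 10 * band)
  adjacent <- clamp01(tumor * (1 + d_pct / 100))
  high_risk <- rowSums(shallow) >= config$risk_min_sites
  rate <- ifelse(high_risk, config$planted_hr, 1) / config$baseline_scale
  t_event <- stats::rexp(n, rate)
  if (config$censor_rate > 0) {
    c_rate <- mean(rate) * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  if (!any(event)) warning("all patients censored; log-rank test undefined")
  stage_probs <- function(hr) if (hr) c(0.35, 0.2, 0.3, 0.15) else c(0.75, 0.15, 0.08, 0.02)
  stage <- vapply(high_risk, function(hr) {
    sample(c("I", "II", "III", "IV"), 1, prob = stage_probs(hr))
  }, character(1))
  patients <- sprintf("PT%02d", seq_len(n))
  sites <- sprintf("site%02d", seq_len(k))
  out <- data.frame(
    patient = rep(patients, each = k),
    site = rep(sites, times = n),
    tumor_meth = as.vector(t(tumor)),
    adjacent_meth = as.vector(t(adjacent)),
    time = rep(time, each = k),
    event = rep(event, each = k),
    stage = rep(stage, each = k),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(patient = patients,
                                   n_shallow_sites = rowSums(shallow),
                                   high_risk = high_risk,
                                   stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Write a synthetic GTF/BED annotation fixture
#'
#' Generates \code{n_genes} gene models on alternating strands laid over the
#' coordinate range the cohort generator uses, plus BED feature tracks
#' (CpG-island-like and TF-binding-like intervals), all byte-deterministic
#' given the seed. Files are labelled synthetic; they parse with
#' \code{\link{load_gene_models}} and \code{\link{feature_overlap_proportions}}.
#'
#' @param n_genes number of genes (>= 1).
#' @param dir output directory.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @param span total genomic span covered by the fixture.
#' @return Invisibly, a list with paths \code{gtf}, \code{cpg_bed},
#'   \code{tf_bed}.
#' @export
write_annotation_fixture <- function(n_genes, dir, seed = 1, chrom = "chr1",
                                     span = NULL) {
  stopifnot(n_genes >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(seed, 97))
  if (is.null(span)) span <- max(50000, n_genes * 30000)
  starts <- sort(sample.int(span - 25000, n_genes)) + 4000
  widths <- sample(5000:20000, n_genes, replace = TRUE)
  strand <- rep(c("+", "-"), length.out = n_genes)
  gene_id <- sprintf("SYNG%04d", seq_len(n_genes))
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in fixture")
  gtf_path <- file.path(dir, "synthetic_genes.gtf")
  lines <- sprintf(
    '%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    chrom, starts, starts + widths - 1, strand, gene_id,
    sprintf("Syng%04d", seq_len(n_genes)))
  writeLines(lines, gtf_path)
  mk_bed <- function(path, n, wmin, wmax) {
    s <- sort(sample.int(span, n))
    w <- sample(wmin:wmax, n, replace = TRUE)
    writeLines(sprintf("%s\t%d\t%d", chrom, s, s + w), path)
    path
  }
  cpg_bed <- mk_bed(file.path(dir, "synthetic_cpg_islands.bed"),
                    max(5, n_genes), 300, 1500)
  tf_bed <- mk_bed(file.path(dir, "synthetic_tf_sites.bed"),
                   max(10, 2 * n_genes), 50, 400)
  invisible(list(gtf = gtf_path, cpg_bed = cpg_bed, tf_bed = tf_bed))
}
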