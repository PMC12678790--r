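#' Run the discovery pipeline end to end
#'
#' Orchestrates the spatial-discovery stages on a cohort: coverage-floor
#' assembly, detection-frequency filtering, per-site significance matrices,
#' Moran's I with its shuffle null, trend classification, region merging
#' and (optionally) gene annotation, and Ward clustering of samples on
#' steep- and shallow-site features. Writes TSV outputs plus a JSON
#' manifest (parameters, seed, counts surviving each stage) and is
#' deterministic given the seed.
#'
#' @param cohort a \code{cohort_matrix}, or a directory of per-sample
#'   coverage files with a \code{layout.tsv} (as written by
#'   \code{\link{write_bismark_cohort}}).
#' @param outdir output directory, or NULL to skip writing.
#' @param params a \code{\link{classify_params}}.
#' @param min_coverage per-cell coverage floor (used when \code{cohort} is
#'   a directory).
#' @param detection \code{"em"}, \code{"fixed"} or \code{"none"}.
#' @param detection_threshold threshold for \code{detection = "fixed"}.
#' @param gtf optional gene-model GTF for region annotation.
#' @param n_shuffles shuffle-null draws per site (default 10).
#' @param max_gap,min_sites region-merging parameters.
#' @param seed integer seed for the shuffle null.
#' @return List with \code{classified}, \code{moran_null}, \code{regions},
#'   \code{gene_hits}, \code{clustering} (per feature kind), \code{filter},
#'   \code{manifest}.
#' @export
run_discovery <- function(cohort, outdir = NULL, params = classify_params(),
                          min_coverage = 15,
                          detection = c("none", "em", "fixed"),
                          detection_threshold = NULL, gtf = NULL,
                          n_shuffles = 10, max_gap = 250, min_sites = 3,
                          seed = 1) {
  detection <- match.arg(detection)
  if (is.character(cohort)) {
    layout <- utils::read.table(file.path(cohort, "layout.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
    samples <- lapply(stats::setNames(layout$sample, layout$sample), function(s) {
      read_bismark_coverage(file.path(cohort, paste0(s, ".cov")))
    })
    cohort <- assemble_cohort(samples, layout, min_coverage = min_coverage)
  }
  if (!is.null(gtf) && !file.exists(gtf)) {
    stop("configuration error: GTF not found: ", gtf)
  }
  stopifnot(inherits(cohort, "cohort_matrix"))
  n_input_sites <- nrow(cohort$meth)
  filter <- NULL
  if (detection != "none") {
    filter <- detection_frequency_filter(cohort, mode = detection,
                                         fixed_threshold = detection_threshold)
    cohort <- subset_cohort(cohort, filter$kept)
  }
  weights <- inverse_distance_weights()
  classified <- classify_sites(cohort, params, weights)
  mats <- attr(classified, "matrices")
  set.seed(seed)
  moran_null <- lapply(seq_along(mats), function(i) {
    if (mats[[i]]$n_significant_pairs == 0) return(numeric(0))
    shuffle_null(mats[[i]], weights, n_shuffles = n_shuffles)
  })
  regions <- merge_changing_sites(classified, max_gap = max_gap,
                                  min_sites = min_sites)
  gene_hits <- NULL
  if (!is.null(gtf)) {
    gene_hits <- map_regions_to_genes(regions, load_gene_models(gtf))
  }
  clustering <- list()
  for (kind in c("steep", "shallow")) {
    keep <- grepl(paste0("^", kind), classified$class)
    if (sum(keep) >= 2) {
      z <- suppressWarnings(zscore_rows(cohort$meth[keep, , drop = FALSE]))
      if (nrow(z) >= 2) clustering[[kind]] <- ward_cluster(z)
    }
  }
  manifest <- list(
    seed = seed, n_shuffles = n_shuffles,
    params = unclass(params),
    max_gap = max_gap, min_sites = min_sites,
    counts = list(
      input_sites = n_input_sites,
      after_detection_filter = nrow(cohort$meth),
      significant_sites = sum(classified$n_significant_pairs > 0),
      by_class = as.list(attr(classified, "summary")),
      regions = nrow(regions)))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(classified, file.path(outdir, "site_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flat <- regions[, c("chrom", "start", "end", "n_sites", "category")]
    utils::write.table(flat, file.path(outdir, "regions.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(gene_hits)) {
      utils::write.table(gene_hits, file.path(outdir, "gene_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (kind in names(clustering)) {
      writeLines(as_newick(clustering[[kind]]),
                 file.path(outdir, paste0("cluster_", kind, ".nwk")))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(classified = classified, moran_null = moran_null, regions = regions,
       gene_hits = gene_hits, clustering = clustering, filter = filter,
       manifest = manifest, cohort = cohort)
}

#' Run the prognosis pipeline
#'
#' Computes the threshold sweep, the combined risk model and the TNM-stage
#' cross-tabulation on a paired tumor/adjacent records table, writing TSV
#' and JSON outputs when \code{outdir} is given.
#'
#' @param records long prognosis records (see
#'   \code{\link{single_site_stratify}}); a \code{stage} column enables the
#'   cross-tab.
#' @param site_set sites entering the combined model (default: all sites).
#' @param N minimum low-difference sites for high risk.
#' @param threshold percent threshold for the combined model.
#' @param thresholds sweep grid.
#' @param outdir output directory or NULL.
#' @return List with \code{sweep}, \code{combined}, \code{crosstab},
#'   \code{manifest}.
#' @export
run_prognosis <- function(records, site_set = unique(records$site), N = 2,
                          threshold = 5, thresholds = 3:15, outdir = NULL) {
  needed <- c("patient", "site", "tumor_meth", "adjacent_meth", "time", "event")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sweep <- threshold_sweep(records, thresholds = thresholds)
  combined <- combined_model(records, site_set, N = N, threshold = threshold)
  crosstab <- NULL
  if ("stage" %in% names(records)) {
    stages <- unique(records[, c("patient", "stage")])
    crosstab <- stage_crosstab(combined, stages)
  }
  manifest <- list(N = N, threshold = threshold,
                   site_set = site_set,
                   n_patients = length(unique(records$patient)),
                   n_high_risk = sum(combined$risk$high_risk),
                   combined_hr = combined$hr,
                   combined_logrank_p = combined$logrank_p)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(sweep, file.path(outdir, "threshold_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(combined$risk, file.path(outdir, "risk_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(sweep = sweep, combined = combined, crosstab = crosstab,
       manifest = manifest)
}
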