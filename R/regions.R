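#' Merge classified sites into methylation-changing regions
#'
#' Scans each chromosome's sorted changed sites (steep_* / shallow_* only)
#' for maximal runs with inter-site gaps of at most \code{max_gap} bp
#' ("not exceeding" is inclusive: a 250 bp gap joins, 251 breaks). In the
#' default direction-aware mode a run also breaks where the rise/decline
#' direction changes; in direction-agnostic mode runs are gap-only and any
#' region containing both directions is flagged
#' \code{discarded_bidirectional}. Runs of at least \code{min_sites} sites
#' become regions.
#'
#' @param classified \code{data.frame} with columns \code{chrom, pos,
#'   class} (as from \code{\link{classify_sites}}), sorted by position
#'   within chromosome.
#' @param max_gap maximum gap between adjacent member sites (default 250).
#' @param min_sites minimum member sites (default 3).
#' @param direction_aware break runs at direction changes (default TRUE).
#' @return \code{data.frame} with one row per region: \code{chrom, start,
#'   end} (0-based half-open, spanning exactly the member sites),
#'   \code{n_sites, category}, and list-columns \code{member_pos},
#'   \code{member_class}.
#' @export
merge_changing_sites <- function(classified, max_gap = 250, min_sites = 3,
                                 direction_aware = TRUE) {
  stopifnot(all(c("chrom", "pos", "class") %in% names(classified)))
  eligible <- grepl("^(steep|shallow)_(rise|decline)$", classified$class)
  df <- classified[eligible, c("chrom", "pos", "class")]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$pos)) stop("sites must be sorted by position")
    if (nrow(sub) == 0) next
    dirs <- ifelse(grepl("rise", sub$class), 1L, -1L)
    breaks <- diff(sub$pos) > max_gap
    if (direction_aware) breaks <- breaks | diff(dirs) != 0
    run <- cumsum(c(0L, as.integer(breaks)))
    for (r in split(seq_len(nrow(sub)), run)) {
      if (length(r) < min_sites) next
      members <- sub[r, ]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(members$pos) - 1L, end = max(members$pos),
        n_sites = length(r),
        category = categorize_region(members$class),
        stringsAsFactors = FALSE)
      out[[length(out)]]$member_pos <- list(members$pos)
      out[[length(out)]]$member_class <- list(members$class)
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), category = character())
    res$member_pos <- list(); res$member_class <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Categorise a region from its member-site classes
#'
#' All-steep one direction gives steep_*; all-shallow one direction gives
#' shallow_*; both kinds in one direction give mixed_*; members of both
#' directions give \code{discarded_bidirectional} (excluded downstream).
#'
#' @param classes character vector of member trend classes.
#' @return One of \code{steep_rise, steep_decline, shallow_rise,
#'   shallow_decline, mixed_rise, mixed_decline, discarded_bidirectional}.
#' @export
categorize_region <- function(classes) {
  stopifnot(all(grepl("^(steep|shallow)_(rise|decline)$", classes)))
  dirs <- unique(sub("^.*_", "", classes))
  if (length(dirs) > 1) return("discarded_bidirectional")
  kinds <- unique(sub("_.*$", "", classes))
  kind <- if (length(kinds) > 1) "mixed" else kinds
  paste(kind, dirs, sep = "_")
}

#' Per-sample median methylation of a region
#'
#' The region's methylation level in each sample is the median over its
#' member sites' fractions, missing cells excluded; a sample with all
#' members missing gets NA. Medians of an even count are the midpoint of
#' the central pair (\code{stats::median}).
#'
#' @param region one row of \code{\link{merge_changing_sites}} output.
#' @param cohort a \code{cohort_matrix} containing the member sites.
#' @return Named numeric vector over samples.
#' @export
region_methylation_profile <- function(region, cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  pos <- region$member_pos[[1]]
  idx <- which(cohort$sites$chrom == region$chrom & cohort$sites$pos %in% pos)
  if (length(idx) < length(pos)) stop("member sites absent from cohort")
  apply(cohort$meth[idx, , drop = FALSE], 2, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
}

#' Load gene models from a GTF file
#'
#' Reads GENCODE/Ensembl-style GTF (1-based inclusive), keeps \code{gene}
#' features, and derives for each gene its gene body (the full gene span)
#' and promoter (the 2 kb immediately upstream of the strand-aware TSS).
#' Intervals are converted to 0-based half-open coordinates. Genes without
#' a strand are skipped with a warning.
#'
#' @param gtf path to a GTF file.
#' @param promoter_width upstream promoter width in bp (default 2000).
#' @return \code{data.frame} with columns \code{gene_id, gene_name, chrom,
#'   strand, body_start, body_end, prom_start, prom_end} (0-based
#'   half-open).
#' @export
load_gene_models <- function(gtf, promoter_width = 2000) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  gr <- gr[gr$type == "gene"]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    warning(sum(strand == "*"), " gene(s) without strand skipped")
    gr <- gr[strand != "*"]
    strand <- strand[strand != "*"]
  }
  start1 <- BiocGenerics::start(gr); end1 <- BiocGenerics::end(gr)
  z <- to_zero_based(start1, end1)
  plus <- strand == "+"
  prom_start <- ifelse(plus, z$start - promoter_width, z$end)
  prom_end <- ifelse(plus, z$start, z$end + promoter_width)
  gene_name <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  out <- data.frame(gene_id = gr$gene_id, gene_name = gene_name,
                    chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    strand = strand,
                    body_start = z$start, body_end = z$end,
                    prom_start = pmax(prom_start, 0L), prom_end = prom_end,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$body_end > out$body_start),
            # promoter abuts but never overlaps the gene body
            all(ifelse(out$strand == "+", out$prom_end <= out$body_start,
                       out$prom_start >= out$body_end)))
  rownames(out) <- NULL
  out
}

# Harmonise "chr1" vs "1" naming between two chromosome vectors; warns when
# a rewrite is needed.
normalize_chroms <- function(query, reference) {
  if (length(reference) == 0 || length(intersect(query, reference))) return(query)
  if (any(grepl("^chr", reference)) && !any(grepl("^chr", query))) {
    warning("adding 'chr' prefix to match annotation naming")
    return(paste0("chr", query))
  }
  if (!any(grepl("^chr", reference)) && any(grepl("^chr", query))) {
    warning("stripping 'chr' prefix to match annotation naming")
    return(sub("^chr", "", query))
  }
  query
}

#' Map changing regions onto gene bodies and promoters
#'
#' Emits one hit per (region, gene, compartment) whose intervals intersect;
#' a region may hit several genes and both compartments of one gene.
#'
#' @param regions output of \code{\link{merge_changing_sites}}.
#' @param genes output of \code{\link{load_gene_models}}.
#' @return \code{data.frame} with columns \code{region_index, gene_id,
#'   gene_name, compartment}.
#' @export
map_regions_to_genes <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(data.frame(region_index = integer(), gene_id = character(),
                      gene_name = character(), compartment = character()))
  }
  chrom <- normalize_chroms(regions$chrom, genes$chrom)
  rgr <- GenomicRanges::GRanges(chrom,
           IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  hit_one <- function(start0, end0, compartment) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
             IRanges::IRanges(start = start0 + 1L, end = end0))
    ov <- GenomicRanges::findOverlaps(rgr, ggr)
    data.frame(region_index = S4Vectors::queryHits(ov),
               gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
               gene_name = genes$gene_name[S4Vectors::subjectHits(ov)],
               compartment = rep(compartment, length(ov)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(hit_one(genes$body_start, genes$body_end, "gene_body"),
               hit_one(genes$prom_start, genes$prom_end, "promoter"))
  out[order(out$region_index, out$gene_id, out$compartment), , drop = FALSE]
}

#' Proportion of sites falling inside feature tracks
#'
#' For each labelled site set and each BED track, the fraction of the set's
#' sites whose position lies inside the track (intervals merged first;
#' membership is point-in-interval on 0-based half-open intervals).
#'
#' @param site_sets named list of \code{data.frame}s with columns
#'   \code{chrom, pos} (1-based CpG positions).
#' @param tracks named list of BED file paths or \code{data.frame}s with
#'   columns \code{chrom, start, end} (0-based half-open).
#' @return \code{data.frame} with columns \code{set, track, n_sites,
#'   proportion}.
#' @export
feature_overlap_proportions <- function(site_sets, tracks) {
  read_track <- function(tr) {
    if (is.character(tr)) {
      if (file.size(tr) == 0) {
        bed <- data.frame(chrom = character(), start = integer(), end = integer())
      } else {
        bed <- utils::read.table(tr, sep = "\t", header = FALSE)[, 1:3]
        names(bed) <- c("chrom", "start", "end")
      }
    } else bed <- tr
    gr <- GenomicRanges::GRanges(bed$chrom,
            IRanges::IRanges(start = bed$start + 1L, end = bed$end))
    GenomicRanges::reduce(gr)
  }
  rows <- list()
  for (tn in names(tracks)) {
    tgr <- read_track(tracks[[tn]])
    for (sn in names(site_sets)) {
      ss <- site_sets[[sn]]
      if (nrow(ss) == 0) {
        rows[[length(rows) + 1]] <- data.frame(set = sn, track = tn,
                                               n_sites = 0L, proportion = NA_real_)
        next
      }
      chrom <- normalize_chroms(ss$chrom, as.character(GenomeInfoDb::seqnames(tgr)))
      sgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ss$pos, width = 1))
      inside <- GenomicRanges::countOverlaps(sgr, tgr) > 0
      rows[[length(rows) + 1]] <- data.frame(set = sn, track = tn,
                                             n_sites = nrow(ss),
                                             proportion = mean(inside))
    }
  }
  do.call(rbind, rows)
}
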