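#' Pairwise region significance tests for one CpG site
#'
#' For every unordered pair of the seven regions, runs the paired one-tailed
#' Wilcoxon signed-rank test in both directions on patients with data in
#' both regions (zero differences dropped; exact distribution for small
#' tie-free samples, normal approximation with continuity correction
#' otherwise). A pair is significant when the smaller of the two one-tailed
#' P values is below \code{alpha}; its direction records which region is
#' lower. Pairs with fewer than \code{min_pairs} complete patient pairs are
#' untestable and marked not significant.
#'
#' @param site patients-by-regions methylation matrix (see
#'   \code{\link{site_profile}}); NA marks missing cells.
#' @param alpha per-pair significance level (default 0.05).
#' @param min_pairs minimum complete patient pairs per test (default 6).
#' @return An object of class \code{sig_matrix}: \code{sig} (7x7 logical,
#'   symmetric, FALSE diagonal), \code{dir} (7x7 in -1/0/+1, antisymmetric;
#'   \code{dir[i, j] = -1} means region i is significantly lower than j),
#'   \code{p_low}, \code{p_high}, \code{n_pairs},
#'   \code{n_significant_pairs}.
#' @export
pairwise_region_tests <- function(site, alpha = 0.05, min_pairs = 6) {
  stopifnot(is.matrix(site), ncol(site) == 7)
  if (sum(apply(site, 1, function(r) any(!is.na(r)))) < 3) {
    stop("fewer than 3 patients with data at this site")
  }
  labs <- region_labels()
  sig <- matrix(FALSE, 7, 7, dimnames = list(labs, labs))
  dir <- matrix(0L, 7, 7, dimnames = list(labs, labs))
  p_low <- p_high <- matrix(NA_real_, 7, 7, dimnames = list(labs, labs))
  n_pairs <- matrix(0L, 7, 7, dimnames = list(labs, labs))
  for (i in 1:6) for (j in (i + 1):7) {
    ok <- !is.na(site[, i]) & !is.na(site[, j])
    n_pairs[i, j] <- n_pairs[j, i] <- sum(ok)
    if (sum(ok) < min_pairs) next
    xi <- site[ok, i]; xj <- site[ok, j]
    if (all(xi == xj)) next  # all zero differences: nothing to rank
    pl <- suppressWarnings(stats::wilcox.test(xi, xj, paired = TRUE,
                                              alternative = "less")$p.value)
    ph <- suppressWarnings(stats::wilcox.test(xi, xj, paired = TRUE,
                                              alternative = "greater")$p.value)
    p_low[i, j] <- p_low[j, i] <- pl
    p_high[i, j] <- p_high[j, i] <- ph
    if (min(pl, ph) < alpha) {
      sig[i, j] <- sig[j, i] <- TRUE
      d <- if (pl < ph) -1L else 1L   # -1: region i lower than region j
      dir[i, j] <- d
      dir[j, i] <- -d
    }
  }
  stopifnot(identical(sig, t(sig)), all(dir == -t(dir)))
  structure(list(sig = sig, dir = dir, p_low = p_low, p_high = p_high,
                 n_pairs = n_pairs, n_significant_pairs = sum(sig[upper.tri(sig)])),
            class = "sig_matrix")
}

#' Flatten a significance matrix to its 42-dimensional status vector
#'
#' Row-major flattening of the off-diagonal cells of \code{sig}, in a fixed
#' cell order shared across all sites, so vectors are comparable.
#'
#' @param m a \code{sig_matrix} or plain 7x7 logical/numeric matrix.
#' @return Integer 0/1 vector of length 42.
#' @export
status_vector <- function(m) {
  s <- if (inherits(m, "sig_matrix")) m$sig else m
  stopifnot(is.matrix(s), nrow(s) == 7, ncol(s) == 7)
  off <- t(s)[t(upper.tri(s) | lower.tri(s))]  # row-major off-diagonal
  as.integer(off != 0)
}

#' Cosine similarity between two status vectors
#'
#' @param a,b equal-length binary (or non-negative) vectors; neither may be
#'   all zero.
#' @return \code{dot(a, b) / (||a|| ||b||)}, in [0, 1] for binary input.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Proportion of sites with a nearby significant site, per bin
#'
#' For each bin, the fraction of member sites that have at least one
#' *other* significant-difference site on the same chromosome within
#' \code{window} bp (the window is closed: a neighbour at exactly
#' \code{window} bp counts).
#'
#' @param sites \code{data.frame} with columns \code{chrom, pos,
#'   significant} (logical) and \code{bin}.
#' @param window half-width in bp (default 30).
#' @return \code{data.frame} with columns \code{bin, n_sites, proportion}
#'   (NA for empty bins is impossible; bins absent from \code{sites} are
#'   simply not reported).
#' @export
neighbor_significant_proportion <- function(sites, window = 30) {
  stopifnot(all(c("chrom", "pos", "significant", "bin") %in% names(sites)))
  has_nb <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    sig_pos <- sort(pos[sites$significant[idx]])
    if (!length(sig_pos)) next
    lo <- findInterval(pos - window - 0.5, sig_pos)
    hi <- findInterval(pos + window + 0.5 - 1e-9, sig_pos)
    n_nb <- hi - lo
    # a significant site finds itself in the window; discount it
    self <- sites$significant[idx] &
      (findInterval(pos, sig_pos) - findInterval(pos - 0.5, sig_pos) > 0)
    has_nb[idx] <- (n_nb - as.integer(self)) >= 1
  }
  agg <- stats::aggregate(has_nb, by = list(bin = sites$bin),
                          FUN = function(v) c(n = length(v), p = mean(v)))
  data.frame(bin = agg$bin, n_sites = agg$x[, "n"],
             proportion = agg$x[, "p"])
}

#' Bin sites by a per-site score
#'
#' Strategies: \describe{
#'   \item{fixed_width}{the study's scheme at defaults: an open start bin at
#'     or below \code{start}, interior bins of \code{width} on
#'     (\code{start}, \code{end}], and an open end bin above \code{end} —
#'     11 bins for width 0.025 on (-0.025, 0.2].}
#'   \item{quantile}{\code{k} equal-sized groups.}
#'   \item{gmm_em}{k-component 1-D Gaussian mixture by EM, assignment by
#'     maximum posterior, bins ordered by component mean.}
#'   \item{fisher_jenks}{natural-breaks optimisation minimising within-bin
#'     sum of squared deviations, by dynamic programming.}
#' }
#'
#' @param values finite numeric scores (e.g., per-site Moran's I).
#' @param strategy one of \code{"fixed_width"}, \code{"quantile"},
#'   \code{"gmm_em"}, \code{"fisher_jenks"}.
#' @param width,start,end fixed-width scheme parameters.
#' @param k number of bins for the other strategies.
#' @return Integer bin index per value (1 = lowest bin), with the break
#'   description in \code{attr(, "breaks")} where applicable.
#' @export
bin_sites <- function(values, strategy = c("fixed_width", "quantile",
                                           "gmm_em", "fisher_jenks"),
                      width = 0.025, start = -0.025, end = 0.2, k = 10) {
  stopifnot(all(is.finite(values)))
  strategy <- match.arg(strategy)
  if (strategy == "fixed_width") {
    breaks <- c(-Inf, seq(start, end, by = width), Inf)
    bin <- as.integer(cut(values, breaks, right = TRUE))
    attr(bin, "breaks") <- breaks
    return(bin)
  }
  if (strategy == "quantile") {
    if (k > length(unique(values))) stop("k exceeds distinct value count")
    qs <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1))
    qs[1] <- -Inf; qs[k + 1] <- Inf
    qs <- unique(qs)
    bin <- as.integer(cut(values, qs, right = TRUE))
    attr(bin, "breaks") <- qs
    return(bin)
  }
  if (strategy == "gmm_em") {
    if (k > length(unique(values))) stop("k exceeds distinct value count")
    fit <- fit_gmm_em(values, k = k)
    if (is.null(fit)) stop("EM degenerate for these values")
    post <- gmm_posterior(fit, values)
    bin <- max.col(post)  # components already ordered by mean
    attr(bin, "mixture") <- fit
    return(bin)
  }
  fisher_jenks(values, k)
}

# Fisher-Jenks natural breaks: exact DP minimising total within-bin sum of
# squared deviations over sorted values. O(k n^2).
fisher_jenks <- function(values, k) {
  n <- length(values)
  if (k > length(unique(values))) stop("k exceeds distinct value count")
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {  # within-SSD of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- ssd(1, j)
  if (k > 1) for (g in 2:k) for (j in g:n) {
    for (m in (g - 1):(j - 1)) {
      v <- cost[g - 1, m] + ssd(m + 1, j)
      if (v < cost[g, j]) { cost[g, j] <- v; split_at[g, j] <- m }
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (g in k:2) { j <- split_at[g, j]; bounds[g] <- j }
  bin_sorted <- rep(seq_len(k), times = diff(bounds))
  bin <- integer(n); bin[ord] <- bin_sorted
  attr(bin, "objective") <- cost[k, n]
  attr(bin, "breaks") <- x[bounds[2:k]]
  bin
}
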