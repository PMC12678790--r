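#' Row-wise z-scoring of a methylation matrix
#'
#' Standardises each row (site or region) to mean 0, sd 1 over its
#' non-missing cells, using the sample (n-1) sd convention, then imputes
#' missing cells with the row mean (0 after scaling). Rows with fewer than
#' two non-missing values or zero variance are dropped with a warning.
#'
#' @param m numeric matrix, features in rows, samples in columns.
#' @return The standardised matrix (possibly with fewer rows).
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  n_ok <- rowSums(!is.na(m))
  bad <- n_ok < 2 | is.na(sd) | sd == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance or near-empty row(s) dropped")
    m <- m[!bad, , drop = FALSE]; mu <- mu[!bad]; sd <- sd[!bad]
  }
  z <- (m - mu) / sd
  z[is.na(z)] <- 0
  z
}

#' Ward.D2 hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns under Euclidean distance
#' with the Ward.D2 criterion: the Lance-Williams update is applied to
#' squared dissimilarities and merge heights are their square roots. Ties
#' in the minimum merge cost are broken toward the lowest cluster index, so
#' the linkage is deterministic. The result is a standard \code{hclust}
#' object usable with \code{cutree} and \code{plot}.
#'
#' @param m numeric matrix, features in rows, samples in columns (usually
#'   \code{\link{zscore_rows}} output); all cells must be finite.
#' @return An object of classes \code{c("methgrad_hclust", "hclust")}.
#' @export
ward_cluster <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  if (!all(is.finite(m))) stop("non-finite cells; z-score/impute first")
  labels <- colnames(m)
  n <- ncol(m)
  d2 <- as.matrix(stats::dist(t(m)))^2
  size <- rep(1L, n)
  id <- -(1:n)                      # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  d2[!upper.tri(d2)] <- Inf
  work <- d2
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    # first minimum in column-major order: deterministic tie-break toward
    # the lowest (column, row) pair
    flat <- which.min(work)
    ab <- arrayInd(flat, dim(work))
    a <- ab[1]; b <- ab[2]
    pair <- sort(c(id[a], id[b]))
    merge[step, ] <- pair
    height[step] <- sqrt(work[a, b])
    # Lance-Williams Ward.D2 update on squared dissimilarities
    for (k in idx) {
      if (k == a || k == b) next
      dka <- work[min(k, a), max(k, a)]
      dkb <- work[min(k, b), max(k, b)]
      dab <- work[a, b]
      nk <- size[k]; na_ <- size[a]; nb <- size[b]
      newd <- ((na_ + nk) * dka + (nb + nk) * dkb - nk * dab) / (na_ + nb + nk)
      work[min(k, a), max(k, a)] <- newd
    }
    size[a] <- size[a] + size[b]
    id[a] <- step
    active[b] <- FALSE
    work[b, ] <- Inf
    work[, b] <- Inf
  }
  out <- list(merge = merge, height = height,
              order = hclust_order(merge), labels = labels,
              method = "ward.D2", dist.method = "euclidean",
              call = match.call())
  class(out) <- c("methgrad_hclust", "hclust")
  out
}

# Leaf order by left-to-right traversal of the merge tree.
hclust_order <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

# Sample index sets of all internal nodes of an hclust tree.
tree_clades <- function(hc) {
  n <- nrow(hc$merge) + 1
  clades <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- integer(0)
    for (side in 1:2) {
      v <- hc$merge[i, side]
      members <- c(members, if (v < 0) -v else clades[[v]])
    }
    clades[[i]] <- sort(members)
  }
  clades
}

#' Bootstrap clade support for a sample clustering
#'
#' Resamples the feature rows with replacement \code{B} times, reclusters,
#' and reports for each internal node of the base tree the fraction of
#' resamples in which its exact sample set reappears as a clade (ordinary
#' bootstrap probability; no multiscale correction).
#'
#' @param m standardised feature-by-sample matrix.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return List with \code{tree} (the base \code{hclust}) and
#'   \code{support} (numeric per internal node, in merge order).
#' @export
bootstrap_support <- function(m, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  base <- ward_cluster(m)
  base_clades <- tree_clades(base)
  keys <- vapply(base_clades, paste, "", collapse = ",")
  hits <- numeric(length(keys))
  set.seed(seed)
  for (b in seq_len(B)) {
    rows <- sample.int(nrow(m), replace = TRUE)
    hc <- ward_cluster(m[rows, , drop = FALSE])
    bk <- vapply(tree_clades(hc), paste, "", collapse = ",")
    hits <- hits + as.numeric(keys %in% bk)
  }
  list(tree = base, support = hits / B)
}

#' Newick serialisation of a clustering with supports
#'
#' @param hc an \code{hclust} object.
#' @param support optional per-internal-node supports (merge order).
#' @return A single Newick string.
#' @export
as_newick <- function(hc, support = NULL) {
  labels <- if (is.null(hc$labels)) as.character(seq_len(nrow(hc$merge) + 1)) else hc$labels
  rec <- function(node) {
    if (node < 0) return(labels[-node])
    lab <- if (!is.null(support)) format(support[node], digits = 3) else ""
    sprintf("(%s,%s)%s", rec(hc$merge[node, 1]), rec(hc$merge[node, 2]), lab)
  }
  paste0(rec(nrow(hc$merge)), ";")
}
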