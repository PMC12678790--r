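#' Ordered tissue-region labels
#'
#' The seven sampling positions in fixed tumor-to-normal order: tumor core
#' (TC), tumor edge (TE), adjacent tissue at 0-5, 5-10, 10-15 and 15-20 mm
#' beyond the visual tumor boundary (P5, P10, P15, P20), and paired-distal
#' normal tissue (PN). All modules index regions by this order.
#'
#' @return Character vector of length 7.
#' @export
region_labels <- function() {
  c("TC", "TE", "P5", "P10", "P15", "P20", "PN")
}

#' @rdname region_labels
#' @param x character vector of region names.
#' @return \code{region_ordinal}: integer ordinals 1-7 (TC = 1, PN = 7).
#' @export
region_ordinal <- function(x) {
  ord <- match(x, region_labels())
  if (anyNA(ord)) {
    stop("unknown region label(s): ", paste(unique(x[is.na(ord)]), collapse = ", "))
  }
  ord
}

# preserves dim attributes (pmin/pmax with a scalar first arg would not)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' All genomic intervals are held 0-based half-open in memory and in BED
#' output; Bismark coverage positions and GTF coordinates are 1-based
#' inclusive on disk. These two helpers are the single conversion point.
#'
#' @param start,end interval bounds.
#' @return A list with \code{start} and \code{end} in the target convention.
#' @export
to_zero_based <- function(start, end = start) {
  list(start = start - 1L, end = end)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  list(start = start + 1L, end = end)
}

# Deterministic per-unit sub-seed derived from one global seed, so a site or
# replicate can be regenerated in isolation. Kept below 2^31 - 1 and within
# double precision (products < 2^53).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647)
}

# One-dimensional k-component Gaussian mixture fitted by EM.
# Initialisation: component means at evenly spaced quantiles, common sd,
# equal weights. The log-likelihood is asserted non-decreasing each step.
fit_gmm_em <- function(x, k = 2, tol = 1e-8, max_iter = 500) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (length(unique(x)) < k) {
    return(NULL)  # degenerate support; caller decides the fallback
  }
  mu <- unname(stats::quantile(x, probs = seq(1, 2 * k - 1, by = 2) / (2 * k)))
  sigma <- rep(max(stats::sd(x), 1e-3), k)
  lambda <- rep(1 / k, k)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      lambda[j] * stats::dnorm(x, mu[j], sigma[j])
    }, numeric(n))
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rowsum_d))
    stopifnot(ll >= loglik - 1e-9)  # EM monotonicity
    if (is.finite(loglik) && ll - loglik < tol) {
      loglik <- ll
      break
    }
    loglik <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(NULL)  # emptied component
    lambda <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, 1e-6)
  }
  ord <- order(mu)
  list(mean = mu[ord], sd = sigma[ord], weight = lambda[ord],
       loglik = loglik, n_iter = iter)
}

gmm_posterior <- function(fit, x) {
  k <- length(fit$mean)
  dens <- vapply(seq_len(k), function(j) {
    fit$weight[j] * stats::dnorm(x, fit$mean[j], fit$sd[j])
  }, numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  dens / pmax(rowSums(dens), .Machine$double.xmin)
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(m) sum(m * (m - 1) / 2)
  sum_ij <- choose2(tab)
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n_pairs <- choose2(matrix(length(a)))
  expected <- sum_a * sum_b / n_pairs
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
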