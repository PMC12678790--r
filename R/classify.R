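#' Kendall tau-b trend of methylation along the region order
#'
#' Pools all patients' cells: x is the region ordinal (1 for TC through 7
#' for PN), y the methylation fraction. Computes Kendall's tau-b and a
#' two-sided P value from the normal approximation with the standard tie
#' corrections to the variance of S (ordinals are heavily tied by design).
#'
#' @param site patients-by-regions methylation matrix.
#' @param min_cells minimum non-missing cells required (default 20).
#' @return List with \code{tau}, \code{p}, \code{n}; \code{tau} is NA when
#'   all values are tied or too few cells are present.
#' @export
kendall_trend <- function(site, min_cells = 20) {
  stopifnot(is.matrix(site), ncol(site) == 7)
  ok <- !is.na(site)
  if (sum(ok) < min_cells) return(list(tau = NA_real_, p = NA_real_, n = sum(ok)))
  x <- col(site)[ok]
  y <- site[ok]
  kendall_tau_b(x, y)
}

# Kendall tau-b with tie-corrected normal approximation for P.
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(unique(y)) < 2 || length(unique(x)) < 2) {
    return(list(tau = NA_real_, p = NA_real_, n = n))
  }
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  S <- sum(dx[upper.tri(dx)] * dy[upper.tri(dy)])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  t1 <- sum(tx * (tx - 1) / 2)
  t2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - t1) * (n0 - t2))
  tau <- S / denom
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  list(tau = tau, p = p, n = n)
}

#' Classification parameters
#'
#' @param alpha_pair per-pair Wilcoxon level (default 0.05).
#' @param tau_p_max Kendall screening level (default 0.01).
#' @param steep_min_sig minimum significant pairs each tumor region (TC and
#'   TE) must show against the normal-side regions for a steep call
#'   (default 3).
#' @param min_pairs minimum complete patient pairs per Wilcoxon test.
#' @return A list of class \code{classify_params}.
#' @export
classify_params <- function(alpha_pair = 0.05, tau_p_max = 0.01,
                            steep_min_sig = 3, min_pairs = 6) {
  stopifnot(alpha_pair > 0, alpha_pair < 1, tau_p_max > 0, tau_p_max < 1,
            steep_min_sig >= 1, min_pairs >= 1)
  structure(list(alpha_pair = alpha_pair, tau_p_max = tau_p_max,
                 steep_min_sig = steep_min_sig, min_pairs = min_pairs),
            class = "classify_params")
}

# Direction convention (the single place it is defined): a site is *_rise
# iff methylation increases from TC to PN — equivalently the tumor side is
# lower (dir[tumor, normal] = -1) or tau > 0. *_decline is the mirror image.

#' Steep-change decision for a significance matrix
#'
#' Steep means the change is confined to the visual tumor boundary: every
#' significant pair lies between a tumor region (TC, TE) and a normal-side
#' region (P5..PN); TC and TE each show at least \code{steep_min_sig}
#' significant pairs against the normal side; and all significant
#' directions share one sign, which sets rise versus decline.
#'
#' @param m a \code{sig_matrix}.
#' @param params a \code{\link{classify_params}}.
#' @return List with \code{steep} (logical) and \code{direction} (+1 rise,
#'   -1 decline, 0 when not steep).
#' @export
is_steep <- function(m, params = classify_params()) {
  stopifnot(inherits(m, "sig_matrix"))
  tumor <- 1:2; normal <- 3:7
  sig <- m$sig
  up <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  not_steep <- list(steep = FALSE, direction = 0L)
  if (nrow(up) == 0) return(not_steep)
  cross <- up[, 1] %in% tumor & up[, 2] %in% normal
  if (!all(cross)) return(not_steep)
  if (sum(up[, 1] == 1) < params$steep_min_sig ||
      sum(up[, 1] == 2) < params$steep_min_sig) return(not_steep)
  dirs <- m$dir[up]
  if (length(unique(dirs)) != 1) return(not_steep)
  # dir[tumor, normal] = -1: tumor lower, methylation rises toward PN
  list(steep = TRUE, direction = if (dirs[1] < 0) 1L else -1L)
}

#' Shallow-change decision
#'
#' Applied to sites that are not steep. Shallow requires a significant
#' monotone trend along the region order (Kendall P below
#' \code{tau_p_max}); at least one significant pair between a tumor region
#' and PN; at least one significant pair among P5..PN (the gradient reaches
#' past the boundary); and no significant pair whose direction contradicts
#' the sign of tau (nonmonotonic significance excludes the site).
#'
#' @param m a \code{sig_matrix}.
#' @param tau,tau_p Kendall trend of the site (see
#'   \code{\link{kendall_trend}}).
#' @param params a \code{\link{classify_params}}.
#' @return List with \code{shallow} (logical) and \code{direction} (+1 rise
#'   when tau > 0, -1 decline, 0 when not shallow).
#' @export
is_shallow <- function(m, tau, tau_p, params = classify_params()) {
  stopifnot(inherits(m, "sig_matrix"))
  not_shallow <- list(shallow = FALSE, direction = 0L)
  if (is.na(tau) || is.na(tau_p) || tau_p >= params$tau_p_max || tau == 0) {
    return(not_shallow)
  }
  sig <- m$sig
  up <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(up) == 0) return(not_shallow)
  if (!any(up[, 1] %in% 1:2 & up[, 2] == 7)) return(not_shallow)
  if (!any(up[, 1] %in% 3:6 & up[, 2] %in% 4:7)) return(not_shallow)
  # monotone significance: for i < j, tau > 0 implies region i lower (dir -1)
  if (any(m$dir[up] != -sign(tau))) return(not_shallow)
  list(shallow = TRUE, direction = if (tau > 0) 1L else -1L)
}

#' Classify all cohort sites into trend classes
#'
#' Runs the per-site pipeline in the method's order: pairwise Wilcoxon
#' significance matrix, the steep rule first, then the Kendall screen and
#' shallow rule on the remainder. Every site receives exactly one class in
#' \{steep_rise, steep_decline, shallow_rise, shallow_decline, unordered\}.
#'
#' @param cohort a \code{cohort_matrix}.
#' @param params a \code{\link{classify_params}}.
#' @param weights grid weights for the optional Moran score.
#' @param moran logical: also score each matrix with Moran's I (default
#'   TRUE; sites whose matrix is constant score NA).
#' @return \code{data.frame} with one row per site: \code{site_id, chrom,
#'   pos, class, direction, tau, tau_p, n_significant_pairs, moran_i}; the
#'   per-site \code{sig_matrix} objects are attached as
#'   \code{attr(, "matrices")} and class counts as \code{attr(, "summary")}.
#' @export
classify_sites <- function(cohort, params = classify_params(),
                           weights = inverse_distance_weights(),
                           moran = TRUE) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  n <- nrow(cohort$meth)
  classes <- character(n); direction <- integer(n)
  tau <- tau_p <- moran_i <- rep(NA_real_, n)
  n_sig <- integer(n)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    site <- site_profile(cohort, i)
    m <- pairwise_region_tests(site, alpha = params$alpha_pair,
                               min_pairs = params$min_pairs)
    mats[[i]] <- m
    n_sig[i] <- m$n_significant_pairs
    if (moran && m$n_significant_pairs > 0) {
      moran_i[i] <- morans_i_matrix(m, weights)$I
    }
    st <- is_steep(m, params)
    if (st$steep) {
      classes[i] <- if (st$direction > 0) "steep_rise" else "steep_decline"
      direction[i] <- st$direction
      next
    }
    kt <- kendall_trend(site)
    tau[i] <- kt$tau; tau_p[i] <- kt$p
    sh <- is_shallow(m, kt$tau, kt$p, params)
    if (sh$shallow) {
      classes[i] <- if (sh$direction > 0) "shallow_rise" else "shallow_decline"
      direction[i] <- sh$direction
    } else {
      classes[i] <- "unordered"
    }
  }
  steep_set <- grepl("^steep", classes)
  shallow_set <- grepl("^shallow", classes)
  stopifnot(!any(steep_set & shallow_set))
  out <- data.frame(site_id = paste0(cohort$sites$chrom, ":", cohort$sites$pos),
                    chrom = cohort$sites$chrom, pos = cohort$sites$pos,
                    class = classes, direction = direction,
                    tau = tau, tau_p = tau_p,
                    n_significant_pairs = n_sig, moran_i = moran_i,
                    stringsAsFactors = FALSE)
  attr(out, "matrices") <- mats
  attr(out, "summary") <- table(factor(classes,
    levels = c("steep_rise", "steep_decline", "shallow_rise",
               "shallow_decline", "unordered")))
  out
}
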