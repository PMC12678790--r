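#' Relative expression profiles from RT-qPCR Ct values
#'
#' Computes per-(patient, gene, region) relative expression by the
#' 2^-dCt method against a reference gene (replicates aggregated by mean
#' Ct, the standard dCt practice), then standardises each profile to its
#' TC value. Replicate SD of dCt is propagated to the expression scale as
#' \code{ln(2) * expr * sd(dCt)}.
#'
#' @param ct long \code{data.frame} with columns \code{patient, region,
#'   gene, replicate, ct}; reference-gene rows carry
#'   \code{gene == reference}.
#' @param reference reference gene name (default \code{"ACTB"}).
#' @return \code{data.frame} with columns \code{patient, gene, region,
#'   rel_expr} (2^-dCt), \code{rel_to_tc} (NA with \code{tc_missing = TRUE}
#'   when the patient-gene has no TC measurement), \code{sd_rel},
#'   \code{tc_missing}.
#' @export
relative_expression <- function(ct, reference = "ACTB") {
  stopifnot(all(c("patient", "region", "gene", "ct") %in% names(ct)))
  region_ordinal(unique(ct$region))
  ref <- ct[ct$gene == reference, ]
  if (nrow(ref) == 0) stop("no rows for reference gene ", reference)
  targ <- ct[ct$gene != reference, ]
  agg <- function(df) {
    s <- stats::aggregate(ct ~ patient + region + gene, data = df,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v),
                                              n = length(v)))
    data.frame(s[1:3], ct_mean = s$ct[, "m"],
               ct_sd = ifelse(is.na(s$ct[, "s"]), 0, s$ct[, "s"]),
               n_rep = s$ct[, "n"])
  }
  ta <- agg(targ); ra <- agg(ref)
  m <- merge(ta, ra[, c("patient", "region", "ct_mean", "ct_sd", "n_rep")],
             by = c("patient", "region"), suffixes = c("", "_ref"))
  if (nrow(m) < nrow(ta)) warning("regions without reference Ct dropped")
  dct <- m$ct_mean - m$ct_mean_ref
  sd_dct <- sqrt(m$ct_sd^2 / m$n_rep + m$ct_sd_ref^2 / m$n_rep_ref)
  m$rel_expr <- 2^(-dct)
  m$sd_rel <- log(2) * m$rel_expr * sd_dct
  out <- do.call(rbind, lapply(split(m, list(m$patient, m$gene), drop = TRUE),
    function(g) {
      tc <- g$rel_expr[g$region == "TC"]
      g$tc_missing <- length(tc) == 0
      g$rel_to_tc <- if (length(tc)) g$rel_expr / tc[1] else NA_real_
      g
    }))
  out <- out[order(out$patient, out$gene, region_ordinal(out$region)),
             c("patient", "gene", "region", "rel_expr", "rel_to_tc",
               "sd_rel", "tc_missing")]
  rownames(out) <- NULL
  out
}

#' Classify a seven-region expression profile as steep, shallow or none
#'
#' A documented interpretation (the exact criteria behind the reported
#' steep/shallow/no-pattern mRNA categories are not fully specified, so the
#' rule is parameterised and isolated here): with the profile's total range
#' R and boundary step |TE - P5|, the profile is \emph{steep} when the step
#' is at least \code{step_frac} of R and both flanks (TC/TE and P5..PN) each
#' span less than \code{step_frac} of R; otherwise it is \emph{shallow}
#' when Kendall's |tau| over the region ordinals reaches \code{tau_min}
#' (0.62 is the two-sided P < 0.05 point for 7 untied values); otherwise
#' \emph{none}. Constant profiles and profiles with fewer than
#' \code{min_regions} values are \emph{none}.
#'
#' @param values named numeric vector over regions (names from
#'   \code{\link{region_labels}}).
#' @param tau_min monotone-trend threshold on |tau| (default 0.62).
#' @param step_frac boundary-step fraction of the range (default 0.5).
#' @param min_regions minimum regions required (default 5).
#' @return List with \code{category} ("steep", "shallow" or "none"),
#'   \code{tau}, \code{step_fraction}.
#' @export
classify_expression_trend <- function(values, tau_min = 0.62,
                                      step_frac = 0.5, min_regions = 5) {
  ord <- region_ordinal(names(values))
  values <- values[order(ord)]; ord <- sort(ord)
  ok <- !is.na(values)
  none <- list(category = "none", tau = NA_real_, step_fraction = NA_real_)
  if (sum(ok) < min_regions) return(none)
  v <- values[ok]; o <- ord[ok]
  rng <- max(v) - min(v)
  if (rng == 0) return(none)
  kt <- kendall_tau_b(o, v)
  step <- if (all(c(2, 3) %in% o)) abs(v[o == 3] - v[o == 2]) else NA_real_
  flank_t <- if (sum(o <= 2) > 1) diff(range(v[o <= 2])) else 0
  flank_n <- if (sum(o >= 3) > 1) diff(range(v[o >= 3])) else 0
  if (!is.na(step) && step >= step_frac * rng &&
      flank_t < step_frac * rng && flank_n < step_frac * rng) {
    return(list(category = "steep", tau = kt$tau, step_fraction = step / rng))
  }
  if (!is.na(kt$tau) && abs(kt$tau) >= tau_min) {
    return(list(category = "shallow", tau = kt$tau,
                step_fraction = if (is.na(step)) NA_real_ else step / rng))
  }
  list(category = "none", tau = kt$tau,
       step_fraction = if (is.na(step)) NA_real_ else step / rng)
}
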