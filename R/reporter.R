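# Enhancer-blocking insulator strength from reporter flow cytometry.

#' Per-replicate median log2(mCherry/EGFP)
#'
#' The per-cell fluorescence ratio summarizes how strongly the tested
#' fragment blocks the shared enhancer from the EGFP reporter. Cells with
#' non-positive intensities are dropped (their number is reported in the
#' `dropped_cells` attribute); medians of even-sized populations use the
#' midpoint convention. Taking the median of log2 ratios equals the log2 of
#' the median ratio, so the transform order is immaterial.
#'
#' @param cells data frame `fragment`, `replicate`, `egfp`, `mcherry`.
#' @return data frame `fragment`, `replicate`, `median_log2` with
#'   attribute `dropped_cells`.
#' @export
median_log2_ratio <- function(cells) {
  stopifnot(all(c("fragment", "replicate", "egfp", "mcherry") %in% names(cells)))
  ok <- cells$egfp > 0 & cells$mcherry > 0
  dropped <- sum(!ok)
  cells <- cells[ok, , drop = FALSE]
  if (!nrow(cells)) stop_invalid("no cells with positive intensities")
  out <- stats::aggregate(
    list(median_log2 = log2(cells$mcherry / cells$egfp)),
    by = list(fragment = cells$fragment, replicate = cells$replicate),
    FUN = stats::median
  )
  out <- out[order(out$fragment, out$replicate), ]
  rownames(out) <- NULL
  attr(out, "dropped_cells") <- dropped
  out
}

#' Insulator strength as percent of gypsy
#'
#' Normalizes per-replicate median log2 ratios to the two controls: the
#' mean of the neutral-spacer replicates is subtracted from every median,
#' then the mean of the gypsy replicates is set to 100% insulator
#' strength:
#' `strength = 100 * (median - mean(spacer)) / (mean(gypsy) - mean(spacer))`.
#' By construction, gypsy replicates average exactly 100 and spacer
#' replicates exactly 0. Strengths below 0 or above 100 are reported as-is,
#' not clipped.
#'
#' @param medians a [median_log2_ratio()] table containing the controls.
#' @param spacer,gypsy fragment names of the spacer and gypsy controls.
#' @return list with `per_replicate` (data frame `fragment`, `replicate`,
#'   `strength`) and `summary` (`fragment`, `mean`, `sd`, `n`).
#' @export
insulator_strength <- function(medians, spacer = "spacer", gypsy = "gypsy") {
  m_spacer <- medians$median_log2[medians$fragment == spacer]
  m_gypsy <- medians$median_log2[medians$fragment == gypsy]
  if (!length(m_spacer) || !length(m_gypsy)) {
    stop_invalid("need at least one replicate each of '%s' and '%s'", spacer, gypsy)
  }
  base <- mean(m_spacer)
  span <- mean(m_gypsy) - base
  if (span == 0) stop_invalid("gypsy and spacer means coincide; normalization undefined")
  per <- data.frame(
    fragment = medians$fragment,
    replicate = medians$replicate,
    strength = 100 * (medians$median_log2 - base) / span
  )
  agg <- stats::aggregate(per$strength, by = list(fragment = per$fragment),
                          FUN = function(x) c(mean(x), stats::sd(x), length(x)))
  summary <- data.frame(
    fragment = agg$fragment,
    mean = agg$x[, 1],
    sd = agg$x[, 2],
    n = as.integer(agg$x[, 3])
  )
  list(per_replicate = per, summary = summary)
}
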