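# A/B compartment calling: observed-over-expected, correlation matrix,
# leading eigenvector, TSS-based sign orientation.

#' Observed-over-expected matrix
#'
#' Divides a normalized contact matrix by the mean normalized contact
#' frequency at each genomic distance (over valid bin pairs), then clips
#' the result from above at its 99.9th percentile to avoid instabilities
#' from very large ratios. Undefined where the expected value is 0 or
#' either bin is masked.
#'
#' @param mat an ICE-normalized [contact_matrix()].
#' @param clip_quantile upper clipping quantile (default 0.999).
#' @return numeric matrix of O/E ratios (`NA` where undefined).
#' @export
observed_over_expected <- function(mat, clip_quantile = 0.999) {
  M <- norm_matrix(mat)
  valid <- mat$valid
  if (!any(valid)) stop_invalid("no valid bins")
  n <- nrow(M)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ok <- !is.na(M)
  expected_by_d <- vapply(0:(n - 1L), function(dist) {
    sel <- d == dist & ok
    if (!any(sel)) return(NA_real_)
    mean(M[sel])
  }, numeric(1))
  E <- matrix(expected_by_d[d + 1L], n, n)
  OE <- M / E
  OE[!is.finite(OE)] <- NA_real_
  cap <- stats::quantile(OE, clip_quantile, na.rm = TRUE, names = FALSE)
  OE[!is.na(OE) & OE > cap] <- cap
  OE
}

#' A/B compartment track from the leading eigenvector
#'
#' Computes the Pearson correlation matrix of the observed-over-expected
#' columns over valid bins, takes the eigenvector of the largest
#' eigenvalue, multiplies it by the sign of its Spearman correlation with
#' the number of TSSs per bin (compartment A is transcription-associated),
#' and centers the defined values on zero. Bins with positive values are
#' labelled `A`, negative `B`; masked or zero-variance bins are undefined.
#'
#' @param oe an [observed_over_expected()] matrix.
#' @param tss_counts per-bin TSS counts (same length as the arm).
#' @return data frame of class `compartment_track`: `bin`, `value`
#'   (zero-centered eigenvector), `label` ("A", "B" or `NA`); attribute
#'   `dropped_zero_variance` counts columns removed before the PCA.
#' @export
compartment_eigenvector <- function(oe, tss_counts) {
  n <- nrow(oe)
  stopifnot(length(tss_counts) == n)
  defined <- colSums(!is.na(oe)) > 1
  sds <- rep(NA_real_, n)
  sds[defined] <- apply(oe[, defined, drop = FALSE], 2, stats::sd, na.rm = TRUE)
  usable <- defined & !is.na(sds) & sds > 0
  n_dropped <- sum(defined & !usable)
  if (sum(usable) < 3) stop_invalid("need at least 3 usable bins")
  C <- stats::cor(oe[usable, usable, drop = FALSE],
                  use = "pairwise.complete.obs")
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  rho <- suppressWarnings(
    stats::cor(v, tss_counts[usable], method = "spearman")
  )
  if (is.na(rho) || rho == 0) {
    warning("Spearman correlation with TSS counts is 0; eigenvector sign unchanged")
  } else if (rho < 0) {
    v <- -v
  }
  v <- v - mean(v)
  value <- rep(NA_real_, n)
  value[usable] <- v
  label <- rep(NA_character_, n)
  label[!is.na(value) & value > 0] <- "A"
  label[!is.na(value) & value < 0] <- "B"
  out <- data.frame(bin = seq_len(n), value = value, label = label)
  class(out) <- c("compartment_track", "data.frame")
  attr(out, "dropped_zero_variance") <- n_dropped
  out
}
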