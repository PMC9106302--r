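#' Binned Hi-C contact matrix for one chromosome arm
#'
#' A `contact_matrix` bundles the symmetric raw count matrix for a single
#' chromosome arm with its bin table (0-based, half-open intervals), the
#' valid-bin mask produced by [mask_low_coverage()], and, once
#' [ice_normalize()] has been run, the balanced matrix. Bins are indexed
#' 1-based in R; bin `i` covers base pairs `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param counts symmetric numeric matrix of contact counts (non-negative).
#' @param bin_size bin width in bp.
#' @param chrom chromosome-arm identifier.
#' @param valid optional logical vector marking bins usable for
#'   normalization; defaults to all bins valid.
#'
#' @return An object of class `contact_matrix`: a list with elements
#'   `chrom`, `bin_size`, `n_bins`, `bins` (data frame with `start`, `end`),
#'   `counts`, `valid`, and `normalized` (`NULL` until balanced).
#' @seealso [bin_pairs()], [mask_low_coverage()], [ice_normalize()]
#' @export
contact_matrix <- function(counts, bin_size, chrom = "arm", valid = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop_invalid("`counts` must be a square matrix")
  }
  if (any(counts < 0, na.rm = TRUE)) stop_invalid("contact counts must be >= 0")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8) {
    stop_invalid("`counts` must be symmetric")
  }
  if (!is_count(bin_size)) stop_invalid("`bin_size` must be a positive integer")
  n <- nrow(counts)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(is.logical(valid), length(valid) == n)
  structure(
    list(
      chrom = chrom,
      bin_size = as.integer(bin_size),
      n_bins = n,
      bins = data.frame(
        start = (seq_len(n) - 1L) * as.integer(bin_size),
        end = seq_len(n) * as.integer(bin_size)
      ),
      counts = counts,
      valid = valid,
      normalized = NULL
    ),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %s, %d bins of %d bp (%d valid)%s\n",
    x$chrom, x$n_bins, x$bin_size, sum(x$valid),
    if (is.null(x$normalized)) ", raw" else ", ICE-normalized"
  ))
  invisible(x)
}

# Normalized matrix with masked bins set to NA; errors if not yet balanced.
norm_matrix <- function(mat) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (is.null(mat$normalized)) {
    stop_invalid("matrix has not been ICE-normalized yet; run ice_normalize()")
  }
  mat$normalized
}

#' Total contact count of a matrix
#'
#' Sums the upper triangle including the diagonal, so each pair of mates is
#' counted exactly once; equals the number of kept cis pairs binned into the
#' matrix.
#'
#' @param mat a [contact_matrix()].
#' @return single numeric count.
#' @export
matrix_total <- function(mat) {
  stopifnot(inherits(mat, "contact_matrix"))
  m <- mat$counts
  sum(m[upper.tri(m, diag = TRUE)])
}
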