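# Pair-level processing: fusion-read splitting, filtering, binning,
# low-coverage masking, ICE balancing, downsampling, replicate QC.

# The four 6-mer junction motifs created by re-ligation of the two 4-cutter
# half-sites; equivalently /[GT]TATA[CA]/.
FUSION_PATTERNS <- c("GTATAC", "TTATAA", "GTATAA", "TTATAC")

#' Split a sequencing read at Hi-C fusion junctions
#'
#' Hi-C chimeric reads carry re-ligation junctions matching one of the four
#' patterns `GTATAC`, `TTATAA`, `GTATAA`, `TTATAC`. The read is split at
#' every (leftmost, non-overlapping) occurrence; the split point is the
#' pattern midpoint so each side keeps its reconstituted half-site. Each
#' emitted sub-read is then truncated to at most `max_len` nucleotides from
#' its 5' end.
#'
#' @param read a DNA string over A, C, G, T, N.
#' @param max_len maximal sub-read length (default 60 nt).
#' @return character vector of sub-reads (empty for an empty read).
#' @export
split_fusion_read <- function(read, max_len = 60) {
  stopifnot(is.character(read), length(read) == 1L)
  if (!nzchar(read)) return(character(0))
  if (grepl("[^ACGTN]", read)) stop_invalid("read contains non-ACGTN characters")
  hits <- gregexpr("[GT]TATA[CA]", read)[[1]]
  if (hits[1L] == -1L) {
    pieces <- read
  } else {
    starts <- as.integer(hits)
    from <- c(1L, starts + 3L)
    to <- c(starts + 2L, nchar(read))
    pieces <- substring(read, from, to)
  }
  substr(pieces, 1L, max_len)
}

#' Filter Hi-C read pairs
#'
#' Applies the four rejection rules in order, tagging each rejected pair
#' with the first rule it violates:
#' \describe{
#'   \item{`non_unique` (i)}{either mate maps to a non-unique position;}
#'   \item{`mismatch` (ii)}{a read has an indel or more than two mismatches;}
#'   \item{`close_pair` (iii)}{mates on the same chromosome, opposite
#'     strands, less than 2 kb apart — likely an undigested fragment rather
#'     than a ligation product;}
#'   \item{`duplicate` (iv)}{both mates share the (chrom, pos, strand)
#'     tuple of a previously seen pair (mate order canonicalized), i.e. a
#'     likely PCR duplicate.}
#' }
#' Duplicates are detected among pairs surviving rules (i)-(iii); the first
#' occurrence of each pair is kept.
#'
#' @param pairs data frame of pair records as produced by
#'   [simulate_pairs()] or [read_pairs()].
#' @param close_dist distance threshold for rule (iii), bp (default 2000).
#' @return list with elements `kept` (data frame) and `rejected` (data
#'   frame with an extra `reason` column).
#' @export
filter_pairs <- function(pairs, close_dist = 2000) {
  required <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
                "is_unique", "n_mismatch", "has_indel")
  missing <- setdiff(required, names(pairs))
  if (length(missing)) {
    stop_invalid("pair table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(pairs$pos1) | !is.finite(pairs$pos2) |
                 pairs$pos1 < 0 | pairs$pos2 < 0)
  if (length(bad)) {
    stop_invalid("malformed pair record at line %d: invalid position", bad[1L])
  }
  n <- nrow(pairs)
  reason <- rep(NA_character_, n)
  reason[!pairs$is_unique] <- "non_unique"
  sel <- is.na(reason) & (pairs$has_indel | pairs$n_mismatch > 2)
  reason[sel] <- "mismatch"
  sel <- is.na(reason) &
    pairs$chrom1 == pairs$chrom2 &
    pairs$strand1 != pairs$strand2 &
    abs(pairs$pos1 - pairs$pos2) < close_dist
  reason[sel] <- "close_pair"
  surv <- which(is.na(reason))
  if (length(surv)) {
    swap <- pairs$chrom1[surv] > pairs$chrom2[surv] |
      (pairs$chrom1[surv] == pairs$chrom2[surv] & pairs$pos1[surv] > pairs$pos2[surv])
    m1 <- ifelse(swap,
                 paste(pairs$chrom2[surv], pairs$pos2[surv], pairs$strand2[surv]),
                 paste(pairs$chrom1[surv], pairs$pos1[surv], pairs$strand1[surv]))
    m2 <- ifelse(swap,
                 paste(pairs$chrom1[surv], pairs$pos1[surv], pairs$strand1[surv]),
                 paste(pairs$chrom2[surv], pairs$pos2[surv], pairs$strand2[surv]))
    reason[surv[duplicated(paste(m1, m2))]] <- "duplicate"
  }
  kept <- pairs[is.na(reason), , drop = FALSE]
  rejected <- pairs[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Bin filtered pairs into a raw contact matrix
#'
#' Counts each cis pair once in the symmetric matrix cell of its two bins
#' (`bin = floor(pos / bin_size)`); pairs with both mates in the same bin
#' land on the diagonal and contribute a single count. Trans pairs (mates on
#' different chromosomes) are dropped and reported in the
#' `trans_dropped` attribute of the result.
#'
#' @param pairs filtered pair records.
#' @param bin_size bin width, bp.
#' @param arm_length arm length, bp (must be a multiple of `bin_size`).
#' @param chrom arm identifier; pairs on other chromosomes count as trans.
#' @return a [contact_matrix()] of raw counts with attribute
#'   `trans_dropped`.
#' @export
bin_pairs <- function(pairs, bin_size, arm_length, chrom = NULL) {
  if (arm_length %% bin_size != 0) {
    stop_invalid("`bin_size` must divide `arm_length`")
  }
  if (is.null(chrom)) chrom <- pairs$chrom1[1]
  cis <- pairs$chrom1 == pairs$chrom2 & pairs$chrom1 == chrom
  n_trans <- sum(!cis)
  pairs <- pairs[cis, , drop = FALSE]
  if (nrow(pairs) && max(pairs$pos1, pairs$pos2) >= arm_length) {
    stop_invalid("pair position beyond arm end (%d bp)", arm_length)
  }
  n <- as.integer(arm_length %/% bin_size)
  bi <- pairs$pos1 %/% bin_size + 1L
  bj <- pairs$pos2 %/% bin_size + 1L
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  counts <- matrix(0, n, n)
  if (length(lo)) {
    tab <- tabulate((lo - 1L) * n + hi, nbins = n * n)
    upper <- matrix(tab, n, n, byrow = TRUE)
    counts <- upper + t(upper) - diag(diag(upper))
  }
  out <- contact_matrix(counts, bin_size, chrom = chrom)
  attr(out, "trans_dropped") <- n_trans
  out
}

#' Mask low-coverage bins
#'
#' Marks as invalid all bins with no contacts plus the 5% of non-empty bins
#' with the smallest total number of contacts (at least one contact),
#' rounding the 5% count up and breaking ties by bin index (lower index
#' masked first). Run before [ice_normalize()].
#'
#' @param mat a raw [contact_matrix()].
#' @param fraction fraction of non-empty bins to mask (default 0.05).
#' @return the matrix with its `valid` mask updated; the logical mask is
#'   also available as `$valid`.
#' @export
mask_low_coverage <- function(mat, fraction = 0.05) {
  stopifnot(inherits(mat, "contact_matrix"))
  marg <- rowSums(mat$counts)
  zero <- marg == 0
  if (all(zero)) {
    warning("all bins have zero contacts; the whole arm is masked")
    mat$valid <- rep(FALSE, mat$n_bins)
    return(mat)
  }
  nz <- which(!zero)
  n_low <- ceiling(fraction * length(nz))
  low <- nz[order(marg[nz], nz)][seq_len(n_low)]
  valid <- !zero
  valid[low] <- FALSE
  mat$valid <- valid
  mat
}

#' ICE matrix balancing
#'
#' Iterative correction of a masked raw contact matrix: rows and columns of
#' the valid submatrix are repeatedly divided by their relative marginals
#' until the coefficient of variation (CV) of the valid marginals drops
#' below `tol`, then the matrix is rescaled so the mean valid marginal is
#' exactly 1. Masked rows/columns are `NA` in the output.
#'
#' @param mat a [contact_matrix()], ideally after [mask_low_coverage()].
#' @param tol convergence tolerance on the marginal CV (default 1e-6).
#' @param max_iter iteration cap (default 200); non-convergence raises a
#'   warning carrying the final CV, and the current result is returned.
#' @return the matrix with `$normalized` filled in.
#' @export
ice_normalize <- function(mat, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(mat, "contact_matrix"))
  valid <- mat$valid
  if (sum(valid) < 2) stop_invalid("need at least 2 valid bins to balance")
  A <- mat$counts[valid, valid, drop = FALSE]
  cv <- Inf
  for (iter in seq_len(max_iter)) {
    m <- rowSums(A)
    mu <- mean(m)
    cv <- stats::sd(m) / mu
    if (is.finite(cv) && cv < tol) break
    # square-root damping: each entry is corrected through both its row and
    # its column factor, so the undamped update overshoots; sqrt keeps the
    # same fixed point with stable, fast convergence
    r <- sqrt(m / mu)
    A <- A / outer(r, r)
  }
  if (!(is.finite(cv) && cv < tol)) {
    warning(sprintf("ICE did not converge in %d iterations (marginal CV = %.3g)",
                    max_iter, cv))
  }
  A <- A / mean(rowSums(A))
  N <- matrix(NA_real_, mat$n_bins, mat$n_bins)
  N[valid, valid] <- A
  mat$normalized <- N
  mat
}

#' Downsample pairs without replacement
#'
#' @param pairs pair records.
#' @param n target pair count (`<= nrow(pairs)`).
#' @param seed RNG seed; the same seed reproduces the same sample.
#' @return data frame of `n` pair records (original order preserved).
#' @export
downsample_pairs <- function(pairs, n, seed = 1) {
  if (n > nrow(pairs)) stop_invalid("cannot downsample %d pairs to %d", nrow(pairs), n)
  if (n == nrow(pairs)) return(pairs)
  keep <- with_seed(seed, sort(sample.int(nrow(pairs), n)))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Short-range Pearson correlation between replicate matrices
#'
#' Flattens the upper-triangle entries of two ICE-normalized matrices over
#' jointly valid bins, keeping bin pairs at genomic distance strictly
#' between 0 and `max_dist`, and returns the Pearson correlation — the
#' replicate-agreement metric at contact-domain scale.
#'
#' @param mat_a,mat_b normalized [contact_matrix()] objects on the same arm
#'   and bin size.
#' @param max_dist maximal genomic distance, bp (default 1 Mb).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(mat_a, mat_b, max_dist = 1e6) {
  stopifnot(inherits(mat_a, "contact_matrix"), inherits(mat_b, "contact_matrix"))
  if (mat_a$n_bins != mat_b$n_bins || mat_a$bin_size != mat_b$bin_size) {
    stop_invalid("matrices must share arm and bin size")
  }
  A <- norm_matrix(mat_a); B <- norm_matrix(mat_b)
  valid <- mat_a$valid & mat_b$valid
  n <- mat_a$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * mat_a$bin_size
  sel <- upper.tri(A) & d > 0 & d < max_dist &
    outer(valid, valid, "&") & !is.na(A) & !is.na(B)
  if (sum(sel) < 2) stop_invalid("fewer than 2 usable entries for correlation")
  stats::cor(A[sel], B[sel])
}
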