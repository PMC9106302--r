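# Plain-text readers and writers for the formats the pipeline exchanges:
# pair tables, sparse matrix triplets with a bin-table sidecar, bedGraph
# and BED tracks.

#' Write / read Hi-C pair records
#'
#' Tab-separated text with a header:
#' `id chrom1 pos1 strand1 frag1 chrom2 pos2 strand2 frag2 is_unique
#' n_mismatch has_indel truth`.
#'
#' @param pairs pair records data frame.
#' @param path output file.
#' @return `write_pairs` the path invisibly; `read_pairs` the data frame.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a contact matrix as sparse triplets
#'
#' The matrix file holds upper-triangle `bin1 bin2 count` triplets
#' (1-based bins, zero cells omitted); the bin-table sidecar
#' (`<path>.bins`) is BED3-like: `chrom start end valid`.
#'
#' @param mat a [contact_matrix()].
#' @param path triplet file path; the bin table goes to `<path>.bins`.
#' @return `write_matrix_triplets` the path invisibly;
#'   `read_matrix_triplets` a [contact_matrix()].
#' @export
write_matrix_triplets <- function(mat, path) {
  stopifnot(inherits(mat, "contact_matrix"))
  up <- which(upper.tri(mat$counts, diag = TRUE) & mat$counts != 0, arr.ind = TRUE)
  trip <- data.frame(bin1 = up[, 1], bin2 = up[, 2],
                     count = mat$counts[up])
  trip <- trip[order(trip$bin1, trip$bin2), ]
  utils::write.table(trip, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- cbind(chrom = mat$chrom, mat$bins, valid = mat$valid)
  utils::write.table(bins, paste0(path, ".bins"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_triplets
#' @export
read_matrix_triplets <- function(path) {
  trip <- utils::read.table(path, header = TRUE, sep = "\t")
  bins <- utils::read.table(paste0(path, ".bins"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  counts[cbind(trip$bin1, trip$bin2)] <- trip$count
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, bin_size = bins$end[1] - bins$start[1],
                 chrom = bins$chrom[1], valid = as.logical(bins$valid))
}

#' Write a per-bin track as bedGraph
#'
#' Undefined bins (`NA`) are skipped, per bedGraph convention.
#'
#' @param values per-bin numeric vector.
#' @param chrom chromosome name.
#' @param bin_size bin width, bp.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(values, chrom, bin_size, path) {
  n <- length(values)
  keep <- !is.na(values)
  df <- data.frame(
    chrom = chrom,
    start = (seq_len(n)[keep] - 1L) * bin_size,
    end = seq_len(n)[keep] * bin_size,
    value = values[keep]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a boundary set as BED
#'
#' One line per boundary bin, with the mean insulation score in the score
#' column.
#'
#' @param boundaries a [merge_windows()] result.
#' @param chrom chromosome name.
#' @param bin_size bin width, bp.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_boundaries_bed <- function(boundaries, chrom, bin_size, path) {
  df <- data.frame(
    chrom = chrom,
    start = (boundaries$bin - 1L) * bin_size,
    end = boundaries$bin * bin_size,
    name = sprintf("boundary_%d", seq_len(nrow(boundaries))),
    score = boundaries$score
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
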