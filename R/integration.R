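# ChIP-peak / boundary / annotation integration and the summary statistics
# used to compare them.

#' Flag boundaries occupied by a ChIP peak
#'
#' A boundary counts as occupied when a peak summit lies within
#' `window` bp of the boundary position (the start coordinate of the
#' boundary bin). The nearest qualifying peak is linked; distance ties
#' resolve to the lower summit coordinate.
#'
#' @param boundaries a [merge_windows()] result (or any data frame with a
#'   `bin` column).
#' @param peaks data frame with at least a `pos` column of summit
#'   coordinates (bp).
#' @param bin_size bin width used to convert boundary bins to bp.
#' @param window maximal summit-boundary distance, bp (default 2000).
#' @param position `"start"` (default) measures to the boundary bin start,
#'   `"midpoint"` to the bin midpoint.
#' @return the boundary table with added `occupied` (logical),
#'   `peak_index` and `peak_distance` columns.
#' @export
assign_occupancy <- function(boundaries, peaks, bin_size = 2000, window = 2000,
                             position = c("start", "midpoint")) {
  position <- match.arg(position)
  bpos <- (boundaries$bin - 1) * bin_size +
    if (position == "midpoint") bin_size / 2 else 0
  out <- as.data.frame(boundaries)
  out$occupied <- FALSE
  out$peak_index <- NA_integer_
  out$peak_distance <- NA_real_
  if (nrow(peaks) == 0 || nrow(out) == 0) return(out)
  ord <- order(peaks$pos, seq_len(nrow(peaks)))
  ppos <- peaks$pos[ord]
  for (i in seq_along(bpos)) {
    dists <- abs(ppos - bpos[i])
    j <- which.min(dists)  # first minimum = lower coordinate on ties
    if (dists[j] <= window) {
      out$occupied[i] <- TRUE
      out$peak_index[i] <- ord[j]
      out$peak_distance[i] <- dists[j]
    }
  }
  out
}

#' Promoter-proximal vs promoter-distal peaks
#'
#' A peak is promoter-proximal when an actively transcribed TSS
#' (RPKM > `rpkm_threshold`) lies within `window` bp of its summit;
#' otherwise it is distal. Silent TSSs are ignored.
#'
#' @param peaks data frame with a `pos` summit column.
#' @param tss data frame with `pos` and `rpkm` columns.
#' @param window proximity window, bp (default 200).
#' @param rpkm_threshold expression cutoff; a TSS counts as transcribed
#'   when `rpkm > rpkm_threshold` (default 0).
#' @return logical vector, `TRUE` for proximal peaks.
#' @export
promoter_proximity <- function(peaks, tss, window = 200, rpkm_threshold = 0) {
  active <- tss$pos[tss$rpkm > rpkm_threshold]
  if (!length(active)) {
    warning("no transcribed TSS available; all peaks are promoter-distal")
    return(rep(FALSE, nrow(peaks)))
  }
  active <- sort(active)
  vapply(peaks$pos, function(p) min(abs(active - p)) <= window, logical(1))
}

#' Peak-motif overlap
#'
#' A peak region overlaps a motif class when it shares at least 1 bp with
#' any motif occurrence of that class (0-based half-open intervals).
#'
#' @param peaks data frame with `start` and `end` region columns.
#' @param motifs data frame with `motif`, `start`, `end` columns.
#' @return logical matrix, peaks x motif classes.
#' @export
motif_overlap <- function(peaks, motifs) {
  classes <- unique(motifs$motif)
  out <- matrix(FALSE, nrow(peaks), length(classes),
                dimnames = list(NULL, classes))
  if (nrow(peaks) == 0) return(out)
  # half-open [start, end) -> IRanges closed [start+1, end]
  pk <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  for (cl in classes) {
    mo <- motifs[motifs$motif == cl, , drop = FALSE]
    mr <- IRanges::IRanges(start = mo$start + 1L, end = mo$end)
    out[, cl] <- IRanges::overlapsAny(pk, mr)
  }
  out
}

#' Intronic peak location
#'
#' A peak is intronic when its summit falls inside at least one intron and
#' inside no exon across all overlapping gene models.
#'
#' @param peaks data frame with a `pos` summit column.
#' @param annotation list with `exons` and `introns` data frames
#'   (`start`, `end`; 0-based half-open), e.g. from [make_annotation()].
#' @return logical vector per peak.
#' @export
intron_location <- function(peaks, annotation) {
  if (nrow(peaks) == 0) return(logical(0))
  pt <- IRanges::IRanges(start = peaks$pos + 1L, width = 1L)
  as_ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)
  in_intron <- if (nrow(annotation$introns)) {
    IRanges::overlapsAny(pt, as_ir(annotation$introns))
  } else rep(FALSE, nrow(peaks))
  in_exon <- if (nrow(annotation$exons)) {
    IRanges::overlapsAny(pt, as_ir(annotation$exons))
  } else rep(FALSE, nrow(peaks))
  in_intron & !in_exon
}

#' Ranked aggregation matrix around anchors
#'
#' Samples tracks in fixed-width bins around each anchor (e.g. every WT
#' boundary, ranked by insulation defect), producing the per-anchor matrix,
#' a summary row (column means for score tracks, percentages for presence
#' tracks), and the enrichment over the three central columns (+/- one bin
#' around the anchor). Anchors too close to the arm end get `NA` cells that
#' are excluded from summaries.
#'
#' @param anchors data frame with a `pos` column (bp), pre-sorted by the
#'   ranking key of interest.
#' @param tracks named list; each element is a list with `kind`
#'   (`"score"`, `"presence"` or `"occupancy"`) and `values` (per-genome-bin
#'   numeric vector for scores/occupancy) or `positions` (feature bp
#'   positions for presence tracks).
#' @param n_bins number of genome bins on the arm.
#' @param bin_size genome bin width, bp (default 2000).
#' @param half_width half-width of the aggregation window, bp
#'   (default 25000).
#' @return list of class `aggregation_matrix`: `offsets_bp`, and per track
#'   `cells` (anchors x offsets), `summary` (per column), `central`
#'   (enrichment over the three central columns).
#' @export
aggregate_around_anchors <- function(anchors, tracks, n_bins,
                                     bin_size = 2000, half_width = 25000) {
  k <- floor(half_width / bin_size)
  offsets <- -k:k
  anchor_bin <- anchors$pos %/% bin_size + 1L
  res <- lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    kind <- match.arg(tr$kind, c("score", "presence", "occupancy"))
    vals <- if (kind == "presence") {
      as.numeric(tabulate(tr$positions %/% bin_size + 1L, nbins = n_bins) > 0)
    } else {
      stopifnot(length(tr$values) == n_bins)
      tr$values
    }
    cells <- vapply(offsets, function(off) {
      idx <- anchor_bin + off
      out <- rep(NA_real_, length(idx))
      ok <- idx >= 1L & idx <= n_bins
      out[ok] <- vals[idx[ok]]
      out
    }, numeric(length(anchor_bin)))
    cells <- matrix(cells, nrow = length(anchor_bin))
    colnames(cells) <- offsets * bin_size
    central_cols <- which(abs(offsets) <= 1L)
    if (kind == "presence") {
      summary_row <- 100 * colMeans(cells, na.rm = TRUE)
      # per anchor: any feature within +/- one bin, then percentage
      any_central <- apply(cells[, central_cols, drop = FALSE], 1,
                           function(x) if (all(is.na(x))) NA else as.numeric(any(x > 0, na.rm = TRUE)))
      central <- 100 * mean(any_central, na.rm = TRUE)
    } else {
      summary_row <- colMeans(cells, na.rm = TRUE)
      central <- mean(cells[, central_cols], na.rm = TRUE)
    }
    list(kind = kind, cells = cells, summary = summary_row, central = central)
  })
  names(res) <- names(tracks)
  structure(list(offsets_bp = offsets * bin_size, tracks = res),
            class = "aggregation_matrix")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two groups with midranks for ties. The W
#' statistic is reported for the first group (number of (a, b) pairs with
#' `a > b`, counting ties as 1/2). Small untied samples use the exact null
#' distribution; otherwise the two-sided normal approximation with
#' continuity correction and tie-corrected variance is used (the standard
#' large-sample convention). Two groups with all values identical give
#' p = 1 by convention.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @return list with `W` and `p`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (length(unique(c(group_a, group_b))) == 1L) {
    return(list(W = length(group_a) * length(group_b) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Contingency-table enrichment
#'
#' Per-cell `log10(observed / expected)` where the expected count assumes
#' independence of rows and columns:
#' `expected_ij = rowsum_i * colsum_j / total`. Zero observed counts give
#' `-Inf`; cells in all-zero rows or columns are `NA` (flagged undefined).
#'
#' @param table numeric matrix of counts (total > 0).
#' @return matrix of log10 enrichments.
#' @export
contingency_enrichment <- function(table) {
  stopifnot(is.matrix(table), sum(table) > 0, all(table >= 0))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  out <- suppressWarnings(log10(table / expected))
  out[expected == 0] <- NA_real_
  out
}

#' Overlap percentage, rounded half-up
#'
#' @param overlapping,total counts with `0 <= overlapping <= total`,
#'   `total > 0`.
#' @return integer percentage.
#' @export
overlap_fraction_summary <- function(overlapping, total) {
  if (total <= 0) stop_invalid("`total` must be positive")
  if (overlapping < 0 || overlapping > total) {
    stop_invalid("`overlapping` must lie in [0, total]")
  }
  as.integer(floor(100 * overlapping / total + 0.5))
}
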