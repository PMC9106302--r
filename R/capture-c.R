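# Capture-C style viewpoint profiling: informative-pair selection, 1-kb
# restriction-aware binning, differential profiles between genotypes.

#' Restriction fragments from a site table
#'
#' Fragment `i` spans `[site[i-1], site[i])`; the first and last fragments
#' run to the arm ends. Matches the indexing of [fragment_index()].
#'
#' @param sites sorted restriction-site positions (bp).
#' @param arm_length arm length, bp.
#' @return data frame `frag`, `start`, `end` (0-based half-open).
#' @export
fragments_from_sites <- function(sites, arm_length) {
  edges <- c(0L, sites, arm_length)
  data.frame(
    frag = seq_len(length(edges) - 1L),
    start = edges[-length(edges)],
    end = edges[-1]
  )
}

#' Select informative viewpoint pairs
#'
#' Keeps unique read pairs (likely PCR duplicates discarded, same
#' definition as rule iv of [filter_pairs()]) with at least one mate on the
#' viewpoint restriction fragment or one of its two neighboring fragments.
#'
#' @param pairs pair records with `frag1`/`frag2` columns.
#' @param viewpoint_frag viewpoint fragment index.
#' @param fragments a [fragments_from_sites()] table (validates the index).
#' @return data frame of informative pairs.
#' @export
select_viewpoint_pairs <- function(pairs, viewpoint_frag, fragments) {
  if (!viewpoint_frag %in% fragments$frag) {
    stop_invalid("viewpoint fragment %d not in the fragment table", viewpoint_frag)
  }
  key <- paste(
    pmin(pairs$pos1, pairs$pos2),
    pmax(pairs$pos1, pairs$pos2),
    ifelse(pairs$pos1 <= pairs$pos2, pairs$strand1, pairs$strand2),
    ifelse(pairs$pos1 <= pairs$pos2, pairs$strand2, pairs$strand1)
  )
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  vp_set <- intersect(viewpoint_frag + (-1L:1L), fragments$frag)
  keep <- pairs$frag1 %in% vp_set | pairs$frag2 %in% vp_set
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a Capture-C viewpoint profile
#'
#' Bins the non-viewpoint ends of informative pairs into a nominal 1-kb
#' grid whose edges are snapped to the nearest restriction site (degenerate
#' bins merged). Because fragments are delimited by restriction sites, each
#' fragment falls entirely inside one snapped bin. Bins closer than
#' `near` bp to the viewpoint fragment or farther than `far` bp are
#' excluded from the output; their counts are tallied in `excluded_count`
#' so that retained + excluded counts equal the informative pair count.
#'
#' @param pairs informative pairs from [select_viewpoint_pairs()].
#' @param viewpoint_frag viewpoint fragment index.
#' @param sites restriction-site positions (bp).
#' @param arm_length arm length, bp.
#' @param bin nominal bin width, bp (default 1000).
#' @param near,far exclusion-zone limits, bp (default 2 kb and 100 kb).
#' @return list of class `capture_profile`: `viewpoint` (start/end bp),
#'   `bins` (retained bins with `start`, `end`, `count`),
#'   `excluded_count`, `library_size` (informative pair count).
#' @export
build_capture_profile <- function(pairs, viewpoint_frag, sites, arm_length,
                                  bin = 1000, near = 2000, far = 100000) {
  fragments <- fragments_from_sites(sites, arm_length)
  if (!viewpoint_frag %in% fragments$frag) {
    stop_invalid("viewpoint fragment %d not in the fragment table", viewpoint_frag)
  }
  vp <- fragments[fragments$frag == viewpoint_frag, ]
  # snap nominal 1-kb edges to the nearest restriction site; keep arm ends
  nominal <- seq(0L, arm_length, by = bin)
  snap <- vapply(nominal, function(e) {
    if (e == 0L || e == arm_length) return(as.numeric(e))
    sites[which.min(abs(sites - e))]
  }, numeric(1))
  edges <- sort(unique(snap))
  bins <- data.frame(start = edges[-length(edges)], end = edges[-1])

  vp_set <- intersect(viewpoint_frag + (-1L:1L), fragments$frag)
  # non-viewpoint end of each pair (arbitrary mate if both on the viewpoint)
  other_frag <- ifelse(pairs$frag1 %in% vp_set, pairs$frag2, pairs$frag1)
  frag_start <- fragments$start[other_frag]
  bin_idx <- findInterval(frag_start, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin_idx, nbins = nrow(bins))

  gap <- pmax(0, pmax(bins$start - vp$end, vp$start - bins$end))
  retained <- gap >= near & gap <= far
  out_bins <- bins[retained, , drop = FALSE]
  out_bins$count <- counts[retained]
  rownames(out_bins) <- NULL
  structure(
    list(
      viewpoint = c(start = vp$start, end = vp$end),
      bins = out_bins,
      excluded_count = sum(counts[!retained]),
      library_size = nrow(pairs)
    ),
    class = "capture_profile"
  )
}

#' Differential Capture-C profile between conditions
#'
#' Scales each replicate profile to counts per million by its library size,
#' averages replicates within each condition, and returns the per-bin
#' `log2((mean_a + c) / (mean_b + c))` with pseudo-count `c` (in CPM) for
#' stability at zero counts. Swapping the conditions negates the track
#' exactly.
#'
#' @param profiles_a,profiles_b lists of [build_capture_profile()] results
#'   (replicates of each condition) on identical bin grids.
#' @param pseudocount stabilizing constant in CPM units (default 0.5).
#' @return data frame `start`, `end`, `log2fc`.
#' @export
differential_profile <- function(profiles_a, profiles_b, pseudocount = 0.5) {
  grids <- lapply(c(profiles_a, profiles_b), function(p) p$bins[, c("start", "end")])
  for (g in grids[-1]) {
    if (!identical(g, grids[[1]])) stop_invalid("profiles are on different bin grids")
  }
  cpm <- function(p) p$bins$count / p$library_size * 1e6
  mean_a <- rowMeans(vapply(profiles_a, cpm, numeric(nrow(grids[[1]]))))
  mean_b <- rowMeans(vapply(profiles_b, cpm, numeric(nrow(grids[[1]]))))
  # computed as a difference of logs so that swapping the conditions
  # negates the track exactly, bit for bit
  data.frame(
    start = grids[[1]]$start,
    end = grids[[1]]$end,
    log2fc = log2(mean_a + pseudocount) - log2(mean_b + pseudocount)
  )
}
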