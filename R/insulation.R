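# Physical insulation score, multi-scale boundary calling, cross-genotype
# harmonization and mutant boundary classification.

#' Diamond contact signal (binSignal)
#'
#' For each bin `i`, the average normalized contact frequency between the
#' `w` bins upstream of `i` and the `w` bins starting at `i` (a `w x w`
#' diamond straddling the bin edge). Masked cells are excluded from the
#' mean; the signal is undefined (`NA`) within `w` bins of the arm ends or
#' when the whole diamond is masked.
#'
#' @param mat an ICE-normalized [contact_matrix()].
#' @param w window size in bins (`>= 1`).
#' @return numeric vector of per-bin binSignal values.
#' @export
bin_signal <- function(mat, w) {
  M <- norm_matrix(mat)
  n <- nrow(M)
  if (w < 1 || 2 * w > n) stop_invalid("window w = %d does not fit a %d-bin arm", w, n)
  bs <- rep(NA_real_, n)
  for (i in seq.int(w + 1L, n - w + 1L)) {
    block <- M[(i - w):(i - 1L), i:(i + w - 1L)]
    if (all(is.na(block))) next
    bs[i] <- mean(block, na.rm = TRUE)
  }
  bs
}

#' Physical insulation score
#'
#' The log2 ratio of a bin's binSignal to its local average over a window
#' of size `w` (bins `j` with `i - w/2 < j < i + w/2` whose binSignal is
#' defined). Lower scores indicate stronger boundaries; a uniform matrix
#' scores 0 everywhere defined. Undefined where the bin's own binSignal is
#' missing or the local average is empty or non-positive.
#'
#' @param bin_signal per-bin binSignal values from [bin_signal()].
#' @param w window size in bins (same `w` used for the binSignal).
#' @return numeric vector of per-bin scores (log2 units).
#' @export
insulation_score <- function(bin_signal, w) {
  n <- length(bin_signal)
  half <- w / 2
  out <- rep(NA_real_, n)
  defined <- !is.na(bin_signal)
  for (i in which(defined)) {
    lo <- max(1L, as.integer(floor(i - half)) + 1L)
    hi <- min(n, as.integer(ceiling(i + half)) - 1L)
    nb <- bin_signal[lo:hi]
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    la <- mean(nb)
    if (la <= 0 || bin_signal[i] <= 0) next
    out[i] <- log2(bin_signal[i] / la)
  }
  out
}

#' Call candidate boundaries at one window size
#'
#' Candidates are strict local minima of the insulation-score profile
#' (score below both immediately adjacent defined scores; plateaus of equal
#' values resolve to their leftmost bin) passing the score filter
#' `score <= threshold`.
#'
#' @param score per-bin insulation scores.
#' @param threshold maximal score of a reportable boundary (default -0.1;
#'   shallower minima are ignored).
#' @return integer vector of boundary bin indices.
#' @export
call_boundaries <- function(score, threshold = -0.1) {
  r <- rle(score)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  k <- length(v)
  if (k < 3) return(integer(0))
  cand <- integer(0)
  for (j in seq.int(2L, k - 1L)) {
    if (is.na(v[j]) || is.na(v[j - 1L]) || is.na(v[j + 1L])) next
    if (v[j] < v[j - 1L] && v[j] < v[j + 1L] && v[j] <= threshold) {
      cand <- c(cand, starts[j])
    }
  }
  cand
}

#' Multi-scale insulation profiles for one matrix
#'
#' Computes binSignal and insulation score at each window size plus the
#' per-bin mean score across windows (defined windows only).
#'
#' @param mat an ICE-normalized [contact_matrix()].
#' @param windows_bp window sizes in bp (default 20, 40, 80 and 160 kb).
#' @return list of class `insulation_profile`: `windows_bp`, `windows_bins`,
#'   `scores` (bins x windows matrix), `mean_score` (per-bin vector).
#' @export
insulation_profile <- function(mat, windows_bp = c(20e3, 40e3, 80e3, 160e3)) {
  stopifnot(inherits(mat, "contact_matrix"))
  w_bins <- as.integer(windows_bp / mat$bin_size)
  if (any(windows_bp %% mat$bin_size != 0)) {
    stop_invalid("window sizes must be multiples of the bin size")
  }
  scores <- vapply(w_bins, function(w) {
    insulation_score(bin_signal(mat, w), w)
  }, numeric(mat$n_bins))
  colnames(scores) <- paste0("w", windows_bp)
  mean_score <- rowMeans(scores, na.rm = TRUE)
  mean_score[!is.finite(mean_score)] <- NA_real_
  structure(
    list(windows_bp = windows_bp, windows_bins = w_bins,
         scores = scores, mean_score = mean_score),
    class = "insulation_profile"
  )
}

#' Merge boundary candidates across window sizes
#'
#' Pools candidates called at every window size (union by default),
#' collapses candidates within 2 kb of each other to the bin with the
#' lowest mean score, attaches the mean score across window sizes, and
#' removes boundaries whose mean score exceeds the filter. Boundaries are
#' 2-kb bin intervals, so "within 2 kb" is the interval gap: bins at most
#' two indices apart are collapsed.
#'
#' @param profile an [insulation_profile()].
#' @param threshold score filter applied per window and on the mean
#'   (default -0.1).
#' @param mode `"union"` (default) keeps bins called at any window size;
#'   `"intersection"` requires all window sizes to call the same bin.
#' @return data frame of class `boundary_set`: `bin`, `score` (mean across
#'   windows), `n_windows` (window sizes that called the bin or an adjacent
#'   one).
#' @export
merge_windows <- function(profile, threshold = -0.1,
                          mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "insulation_profile"))
  per_window <- lapply(seq_along(profile$windows_bins), function(k) {
    call_boundaries(profile$scores[, k], threshold = threshold)
  })
  bins <- sort(unique(unlist(per_window)))
  if (mode == "intersection" && length(bins)) {
    in_all <- vapply(bins, function(b) {
      all(vapply(per_window, function(cb) b %in% cb, logical(1)))
    }, logical(1))
    bins <- bins[in_all]
  }
  ms <- profile$mean_score
  out <- data.frame(bin = integer(0), score = numeric(0), n_windows = integer(0))
  if (length(bins)) {
    grp <- cumsum(c(1L, as.integer(diff(bins) > 2L)))
    rows <- lapply(split(bins, grp), function(g) {
      sc <- ms[g]
      best <- g[which.min(replace(sc, is.na(sc), Inf))]
      data.frame(
        bin = best,
        score = ms[best],
        n_windows = sum(vapply(per_window, function(cb) any(cb %in% g), logical(1)))
      )
    })
    out <- do.call(rbind, rows)
    out <- out[!is.na(out$score) & out$score <= threshold, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("boundary_set", "data.frame")
  attr(out, "windows_bp") <- profile$windows_bp
  out
}

#' Harmonize boundary positions across genotypes
#'
#' Pools boundaries called in all genotypes, chains groups of boundaries
#' within 2 kb of each other (interval gap between the 2-kb boundary bins,
#' i.e. bins at most two indices apart, transitively), and replaces each
#' group with
#' the single position minimizing the global insulation score — the sum,
#' over genotypes that called a boundary in the group, of that genotype's
#' mean-window score at the candidate position (ties resolve to the
#' leftmost position). Each genotype with a boundary in the group is marked
#' present at the consensus position, with its score re-read there.
#'
#' @param boundary_sets named list of [merge_windows()] results, one per
#'   genotype.
#' @param profiles named list of [insulation_profile()] objects matching
#'   `boundary_sets` (for re-reading scores at consensus positions).
#' @return data frame of class `boundary_consensus`: `bin`, then for each
#'   genotype `<g>.present` (logical) and `<g>.score`.
#' @export
harmonize_genotypes <- function(boundary_sets, profiles) {
  stopifnot(is.list(boundary_sets), is.list(profiles),
            !is.null(names(boundary_sets)),
            all(names(boundary_sets) %in% names(profiles)))
  genotypes <- names(boundary_sets)
  pooled <- sort(unique(unlist(lapply(boundary_sets, function(b) b$bin))))
  cols <- c("bin", as.vector(rbind(paste0(genotypes, ".present"),
                                   paste0(genotypes, ".score"))))
  if (!length(pooled)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
    class(out) <- c("boundary_consensus", "data.frame")
    return(out)
  }
  grp <- cumsum(c(1L, as.integer(diff(pooled) > 2L)))
  rows <- lapply(split(pooled, grp), function(g) {
    present <- vapply(genotypes, function(gt) {
      any(boundary_sets[[gt]]$bin %in% g)
    }, logical(1))
    global <- vapply(g, function(p) {
      sc <- vapply(genotypes[present], function(gt) {
        profiles[[gt]]$mean_score[p]
      }, numeric(1))
      sum(sc, na.rm = TRUE)
    }, numeric(1))
    best <- g[which.min(global)]  # which.min takes the first (leftmost) tie
    row <- data.frame(bin = best)
    for (gt in genotypes) {
      row[[paste0(gt, ".present")]] <- unname(present[gt])
      row[[paste0(gt, ".score")]] <-
        if (present[gt]) profiles[[gt]]$mean_score[best] else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("boundary_consensus", "data.frame")
  out
}

#' Classify mutant boundary defects
#'
#' For every boundary present in the wild type: `lost` if absent in the
#' mutant; otherwise `weaker` when the insulation-score change
#' (mutant minus WT) is at least `delta_threshold`, and `intact` otherwise
#' (including reinforced boundaries with negative change). Boundaries
#' absent in the wild type are excluded and counted in the
#' `excluded_non_wt` attribute.
#'
#' @param consensus a [harmonize_genotypes()] result covering both
#'   genotypes.
#' @param wt,mutant genotype names as used in the consensus columns.
#' @param delta_threshold minimal score increase calling a boundary weaker
#'   (default 0.01 log2 units).
#' @return data frame `bin`, `score_wt`, `score_mut`, `delta`, `label`
#'   (factor with levels lost/weaker/intact).
#' @export
classify_boundaries <- function(consensus, wt, mutant, delta_threshold = 0.01) {
  pw <- consensus[[paste0(wt, ".present")]]
  pm <- consensus[[paste0(mutant, ".present")]]
  if (is.null(pw) || is.null(pm)) {
    stop_invalid("consensus lacks genotype '%s' or '%s'", wt, mutant)
  }
  keep <- which(pw)
  out <- data.frame(
    bin = consensus$bin[keep],
    score_wt = consensus[[paste0(wt, ".score")]][keep],
    score_mut = consensus[[paste0(mutant, ".score")]][keep]
  )
  out$delta <- out$score_mut - out$score_wt
  out$label <- factor(
    ifelse(!pm[keep], "lost",
           ifelse(out$delta >= delta_threshold, "weaker", "intact")),
    levels = c("lost", "weaker", "intact")
  )
  attr(out, "excluded_non_wt") <- sum(!pw)
  out
}

#' Differential insulation track
#'
#' Per-bin mean-window insulation score of the mutant minus the wild type;
#' undefined bins propagate as `NA`.
#'
#' @param wt_profile,mutant_profile [insulation_profile()] objects on the
#'   same arm, bin size and window set.
#' @return numeric per-bin difference vector.
#' @export
delta_insulation <- function(wt_profile, mutant_profile) {
  if (length(wt_profile$mean_score) != length(mutant_profile$mean_score) ||
      !identical(wt_profile$windows_bp, mutant_profile$windows_bp)) {
    stop_invalid("profiles differ in shape or window set")
  }
  mutant_profile$mean_score - wt_profile$mean_score
}

#' Full boundary-calling pipeline for one matrix
#'
#' Convenience wrapper: masking, ICE balancing, multi-scale insulation and
#' window merging in one call.
#'
#' @param mat a raw [contact_matrix()].
#' @param windows_bp window sizes in bp.
#' @param threshold boundary score filter.
#' @return list with `matrix` (masked, normalized), `profile`
#'   ([insulation_profile()]) and `boundaries` ([merge_windows()] result).
#' @export
call_domain_boundaries <- function(mat, windows_bp = c(20e3, 40e3, 80e3, 160e3),
                                   threshold = -0.1) {
  mat <- mask_low_coverage(mat)
  mat <- ice_normalize(mat)
  prof <- insulation_profile(mat, windows_bp)
  list(matrix = mat, profile = prof,
       boundaries = merge_windows(prof, threshold = threshold))
}
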