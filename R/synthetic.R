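#' Configuration for the synthetic Hi-C generator
#'
#' Defines the generative model used throughout the test suite: contacts
#' decay with genomic distance as a power law `d(s) = (s+1)^-alpha` (in
#' bins), every planted boundary multiplies contacts crossing it by a factor
#' `f` in (0, 1] (lower = stronger insulation), and pairs of bins in the same
#' compartment are enriched by `compartment_contrast`. Counts are Poisson
#' around this expectation. The model is deliberately minimal: it is the
#' simplest process under which insulation dips, distance decay and the
#' compartment checkerboard are all well defined and analytically checkable.
#'
#' @param arm_length modeled chromosome-arm length in bp.
#' @param bin_size bin width in bp (default 2000, the working resolution of
#'   the boundary analysis).
#' @param n_boundaries number of planted domain boundaries.
#' @param insulation_factors per-boundary contact multiplier in (0, 1];
#'   recycled to `n_boundaries`.
#' @param decay_exponent power-law exponent alpha of the distance decay.
#' @param compartment_block_size compartment block width in bins; 0 disables
#'   the compartment checkerboard.
#' @param compartment_contrast multiplicative enrichment (>= 1) of
#'   same-compartment contacts.
#' @param sequencing_depth expected total number of cis pairs.
#' @param duplicate_rate probability that a genuine pair gains a PCR
#'   duplicate copy.
#' @param nonunique_rate,mismatch_rate,close_pair_rate contaminant rates,
#'   expressed as a fraction of `sequencing_depth`, for multi-mapping pairs,
#'   reads with >2 mismatches, and opposite-orientation pairs <2 kb apart.
#' @param min_boundary_spacing minimum spacing between planted boundaries,
#'   in bins (default 20).
#' @param boundary_edge_margin minimum distance of a planted boundary from
#'   either arm end, in bins (default 0: uniform placement over the arm
#'   interior). The insulation score is undefined within a window of the
#'   arm ends, so boundaries planted there are undetectable by
#'   construction; set a positive margin to confine truth to the region
#'   the method can see.
#' @param n_peaks number of synthetic ChIP peaks; defaults to
#'   `2 * n_boundaries`.
#' @param peak_fraction_at_boundary fraction of peaks placed within +/-2 kb
#'   of a planted boundary; the rest are decoys placed away from boundaries.
#' @param tss_zero_fraction fraction of synthetic TSSs with RPKM 0
#'   (untranscribed).
#' @param seed integer seed; identical configs with identical seeds give
#'   bit-identical outputs from every generator.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(arm_length,
                             bin_size = 2000,
                             n_boundaries = 0,
                             insulation_factors = 0.5,
                             decay_exponent = 1,
                             compartment_block_size = 0,
                             compartment_contrast = 1,
                             sequencing_depth = 5e5,
                             duplicate_rate = 0,
                             nonunique_rate = 0,
                             mismatch_rate = 0,
                             close_pair_rate = 0,
                             min_boundary_spacing = 20,
                             boundary_edge_margin = 0,
                             n_peaks = NULL,
                             peak_fraction_at_boundary = 0.7,
                             tss_zero_fraction = 0.3,
                             seed = 1) {
  if (!is_count(arm_length)) stop_invalid("`arm_length` must be a positive integer")
  if (!is_count(bin_size)) stop_invalid("`bin_size` must be a positive integer")
  if (arm_length %% bin_size != 0) {
    stop_invalid("`bin_size` (%d) must divide `arm_length` (%d)", bin_size, arm_length)
  }
  if (!is_count(n_boundaries, positive = FALSE)) {
    stop_invalid("`n_boundaries` must be a non-negative integer")
  }
  f <- rep_len(insulation_factors, max(n_boundaries, 1L))[seq_len(n_boundaries)]
  if (n_boundaries > 0 && (any(f <= 0) || any(f > 1))) {
    stop_invalid("`insulation_factors` must lie in (0, 1]")
  }
  if (sequencing_depth < 0) stop_invalid("`sequencing_depth` must be >= 0")
  rates <- c(duplicate_rate, nonunique_rate, mismatch_rate, close_pair_rate)
  if (any(rates < 0 | rates > 1)) stop_invalid("contaminant rates must lie in [0, 1]")
  if (compartment_contrast < 1) stop_invalid("`compartment_contrast` must be >= 1")
  structure(
    list(
      arm_length = as.integer(arm_length),
      bin_size = as.integer(bin_size),
      n_bins = as.integer(arm_length %/% bin_size),
      n_boundaries = as.integer(n_boundaries),
      insulation_factors = f,
      decay_exponent = decay_exponent,
      compartment_block_size = as.integer(compartment_block_size),
      compartment_contrast = compartment_contrast,
      sequencing_depth = sequencing_depth,
      duplicate_rate = duplicate_rate,
      nonunique_rate = nonunique_rate,
      mismatch_rate = mismatch_rate,
      close_pair_rate = close_pair_rate,
      min_boundary_spacing = as.integer(min_boundary_spacing),
      boundary_edge_margin = as.integer(boundary_edge_margin),
      n_peaks = if (is.null(n_peaks)) 2L * as.integer(n_boundaries) else as.integer(n_peaks),
      peak_fraction_at_boundary = peak_fraction_at_boundary,
      tss_zero_fraction = tss_zero_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Mean spacing of the merged restriction landscape of the two 4-cutter
# enzymes, bp. One site every 256 bp on average.
RESTRICTION_MEAN_SPACING <- 256

#' Generate a synthetic genome annotation
#'
#' Emulates the annotation tables the real pipeline consumes: restriction
#' sites (the merged landscape of two 4-cutter enzymes, geometric inter-site
#' gaps with mean 256 bp), TSSs with RPKM expression values (a configurable
#' fraction untranscribed), motif occurrence intervals for three named motif
#' classes, and simple gene models with exons and introns.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `sites` (sorted bp positions), `tss`
#'   (data frame `pos`, `strand`, `rpkm`), `motifs` (data frame `motif`,
#'   `start`, `end`; 0-based half-open), `genes`, `exons`, `introns`
#'   (data frames with `gene`, `start`, `end`).
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$arm_length
  with_seed(config$seed, {
    # restriction sites: geometric gaps, mean RESTRICTION_MEAN_SPACING
    n_guess <- ceiling(L / RESTRICTION_MEAN_SPACING * 1.5) + 50L
    gaps <- stats::rgeom(n_guess, prob = 1 / RESTRICTION_MEAN_SPACING) + 1L
    pos <- cumsum(gaps)
    while (pos[length(pos)] < L) {
      gaps <- stats::rgeom(n_guess, prob = 1 / RESTRICTION_MEAN_SPACING) + 1L
      pos <- c(pos, pos[length(pos)] + cumsum(gaps))
    }
    sites <- pos[pos < L]

    # TSSs: roughly one per 5 kb, a fraction silent (RPKM 0)
    n_tss <- max(1L, round(L / 5000))
    tss_pos <- sort(sample.int(L, n_tss))
    silent <- stats::runif(n_tss) < config$tss_zero_fraction
    tss <- data.frame(
      pos = tss_pos,
      strand = sample(c("+", "-"), n_tss, replace = TRUE),
      rpkm = ifelse(silent, 0, round(stats::rlnorm(n_tss, 1, 1), 3))
    )

    # motif occurrences for three insulator-protein motif classes
    classes <- c("CTCF", "SuHw", "BEAF32")
    motifs <- do.call(rbind, lapply(classes, function(cl) {
      n_m <- max(1L, round(L / 10000))
      s <- sort(sample.int(L - 20L, n_m))
      data.frame(motif = cl, start = s, end = s + sample(8:15, n_m, replace = TRUE))
    }))

    # non-overlapping gene models walked along the arm, 2-4 exons each
    genes <- list(); exons <- list(); introns <- list()
    cursor <- 0L; gid <- 0L
    while (cursor < L - 8000L) {
      cursor <- cursor + sample(500:4000, 1L)
      glen <- sample(3000:6000, 1L)
      if (cursor + glen >= L) break
      gid <- gid + 1L
      gname <- sprintf("gene%03d", gid)
      n_ex <- sample(2:4, 1L)
      # cut the gene into 2*n_ex-1 alternating exon/intron segments
      cuts <- sort(sample.int(glen - 1L, 2L * n_ex - 2L))
      edges <- c(0L, cuts, glen) + cursor
      seg <- data.frame(start = edges[-length(edges)], end = edges[-1])
      is_exon <- seq_len(nrow(seg)) %% 2L == 1L
      genes[[gid]] <- data.frame(gene = gname, start = cursor, end = cursor + glen)
      exons[[gid]] <- cbind(gene = gname, seg[is_exon, ])
      if (any(!is_exon)) introns[[gid]] <- cbind(gene = gname, seg[!is_exon, ])
      cursor <- cursor + glen
    }
    empty <- data.frame(gene = character(), start = integer(), end = integer())
    list(
      sites = sites,
      tss = tss,
      motifs = motifs,
      genes = if (length(genes)) do.call(rbind, genes) else empty,
      exons = if (length(exons)) do.call(rbind, exons) else empty,
      introns = if (length(introns)) do.call(rbind, introns) else empty
    )
  })
}

#' Plant ground truth: boundaries, compartments, ChIP peaks
#'
#' Places `n_boundaries` domain boundaries with a minimum spacing, assigns
#' alternating A/B compartment blocks, and scatters ChIP peaks either at
#' planted boundaries (within +/-2 kb) or as decoys well away from any
#' boundary. A boundary "at bin b" separates bins `< b` from bins `>= b`;
#' its genomic coordinate is the start of bin `b`.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_truth`: list with
#'   `boundary_bins` (1-based bin indices, strictly increasing),
#'   `boundary_factors`, `compartment_labels` (per-bin "A"/"B"),
#'   `peaks` (data frame `pos`, `occupancy`, `at_boundary`),
#'   `mutant_edits` (`NULL` for wild type), `reporter_truth` (`NULL`).
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_bins
  k <- config$n_boundaries
  s <- config$min_boundary_spacing
  with_seed(config$seed + 1L, {
    if (k > 0) {
      # boundaries live on interior bins, kept an edge margin away from the
      # arm ends (the insulation score is undefined there); subtract the
      # spacing budget, sample distinct slots, re-expand so gaps are >= s
      m <- config$boundary_edge_margin
      repeat {
        lo <- max(2L, m + 1L)
        hi <- min(n - 1L, n - m)
        span <- (hi - lo + 1L) - (k - 1L) * (s - 1L)
        if (span >= k || m == 0L) break
        m <- m %/% 2L
      }
      if (span < k) {
        stop_invalid(
          "cannot place %d boundaries with spacing %d on %d bins", k, s, n
        )
      }
      slots <- sort(sample.int(span, k))
      bins <- (lo - 1L) + slots + (seq_len(k) - 1L) * (s - 1L)
    } else {
      bins <- integer(0)
    }
    labels <- if (config$compartment_block_size > 0) {
      rep_len(
        rep(c("A", "B"), each = config$compartment_block_size),
        n
      )
    } else {
      rep("A", n)
    }
    # ChIP peaks: a fraction at boundaries, decoys >= 4 kb from any boundary
    np <- config$n_peaks
    peaks <- data.frame(
      pos = numeric(0), occupancy = numeric(0), at_boundary = logical(0)
    )
    if (np > 0) {
      boundary_bp <- (bins - 1L) * config$bin_size
      n_at <- if (k > 0) round(config$peak_fraction_at_boundary * np) else 0L
      pos_at <- if (n_at > 0) {
        anchors <- boundary_bp[sample.int(k, n_at, replace = n_at > k)]
        pmin(pmax(anchors + sample(-2000:2000, n_at, replace = TRUE), 0L),
             config$arm_length - 1L)
      } else numeric(0)
      n_decoy <- np - n_at
      pos_decoy <- numeric(0)
      while (length(pos_decoy) < n_decoy) {
        cand <- sample.int(config$arm_length, n_decoy * 2L) - 1L
        if (length(boundary_bp)) {
          d <- vapply(cand, function(p) min(abs(p - boundary_bp)), numeric(1))
          cand <- cand[d > 4000]
        }
        pos_decoy <- c(pos_decoy, cand)[seq_len(min(n_decoy, length(pos_decoy) + length(cand)))]
      }
      peaks <- data.frame(
        pos = c(pos_at, pos_decoy),
        occupancy = round(stats::runif(np, 1.2, 6), 3),
        at_boundary = rep(c(TRUE, FALSE), c(n_at, n_decoy))
      )
    }
    structure(
      list(
        boundary_bins = bins,
        boundary_factors = config$insulation_factors,
        compartment_labels = labels,
        peaks = peaks,
        mutant_edits = NULL,
        reporter_truth = NULL
      ),
      class = "synthetic_truth"
    )
  })
}

#' Edit planted truth into a mutant genotype
#'
#' Removes or weakens chosen boundaries, emulating architectural-protein
#' mutants in which some contact-domain boundaries are lost and others are
#' weaker but retained. Removed boundaries stay in the table with factor 1.0
#' (no insulation) so that positions remain comparable between genotypes.
#'
#' @param truth a [plant_truth()] result.
#' @param edits data frame with columns `index` (boundary index into
#'   `truth$boundary_bins`) and `factor` (new insulation factor; `NA` means
#'   remove, i.e. factor 1.0).
#' @return edited `synthetic_truth` with `mutant_edits` recorded.
#' @export
perturb_truth <- function(truth, edits) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(edits) || nrow(edits) == 0) return(truth)
  stopifnot(all(c("index", "factor") %in% names(edits)))
  k <- length(truth$boundary_bins)
  if (any(edits$index < 1 | edits$index > k)) {
    stop_invalid("unknown boundary index in `edits`")
  }
  f <- truth$boundary_factors
  new_f <- ifelse(is.na(edits$factor), 1.0, edits$factor)
  if (any(new_f <= 0 | new_f > 1)) stop_invalid("edited factors must lie in (0, 1]")
  f[edits$index] <- new_f
  truth$boundary_factors <- f
  truth$mutant_edits <- edits
  truth
}

#' Expectation matrix of the generative contact model
#'
#' Returns the noise-free expected contact matrix
#' `e_ij = scale * (|i-j|+1)^-alpha * prod(f_b) * contrast^[same compartment]`
#' where the product runs over planted boundaries crossed by the pair and
#' `scale` is set so that the upper triangle (diagonal included) sums to
#' `sequencing_depth`.
#'
#' @param truth a [plant_truth()] (possibly [perturb_truth()]-edited) result.
#' @param config the matching [synthetic_config()].
#' @return numeric `n_bins x n_bins` symmetric matrix of expectations.
#' @export
expected_matrix <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "synthetic_config"))
  n <- config$n_bins
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  E <- (d + 1)^(-config$decay_exponent)
  for (b_i in seq_along(truth$boundary_bins)) {
    b <- truth$boundary_bins[b_i]
    f <- truth$boundary_factors[b_i]
    if (f == 1) next
    cross <- outer(idx < b, idx >= b, "&")
    cross <- cross | t(cross)
    E[cross] <- E[cross] * f
  }
  if (config$compartment_contrast != 1) {
    same <- outer(truth$compartment_labels, truth$compartment_labels, "==")
    E[same] <- E[same] * config$compartment_contrast
  }
  tot <- sum(E[upper.tri(E, diag = TRUE)])
  E * (config$sequencing_depth / tot)
}

#' Simulate a binned contact matrix from planted truth
#'
#' Draws independent Poisson counts around [expected_matrix()] on the upper
#' triangle and mirrors them (`noise = "poisson"`), or returns the
#' expectation itself (`noise = "none"`, useful for exact model-recovery
#' tests).
#'
#' @inheritParams expected_matrix
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed; defaults to `config$seed + 2`.
#' @return a [contact_matrix()].
#' @export
simulate_matrix <- function(truth, config, noise = c("poisson", "none"),
                            seed = config$seed + 2L) {
  noise <- match.arg(noise)
  E <- expected_matrix(truth, config)
  n <- nrow(E)
  if (noise == "none") {
    counts <- E
  } else {
    counts <- with_seed(seed, {
      up <- upper.tri(E, diag = TRUE)
      C <- matrix(0, n, n)
      C[up] <- stats::rpois(sum(up), E[up])
      C + t(C) - diag(diag(C))
    })
  }
  contact_matrix(counts, config$bin_size, chrom = "armS")
}

#' Simulate Hi-C read pairs from planted truth
#'
#' Samples cis pairs from the expectation matrix, places mates uniformly
#' within their bins, assigns restriction-fragment indices from the
#' annotation, and injects labelled contaminants: PCR duplicates,
#' multi-mapping pairs, reads with >2 mismatches, and opposite-orientation
#' pairs <2 kb apart. Every record carries a `truth` label so that filter
#' tests are exact rather than statistical. Genuine pairs closer than 2 kb
#' are emitted in same-strand orientation (the orientation rejection rule
#' targets undigested fragments, not true ligation products), and genuine
#' pair coordinates are de-collided so that none is an accidental duplicate.
#'
#' @inheritParams expected_matrix
#' @param annotation a [make_annotation()] result (for fragment indices);
#'   generated from `config` if omitted.
#' @param seed RNG seed; defaults to `config$seed + 3`.
#' @return data frame of pair records: `id`, `chrom1`, `pos1`, `strand1`,
#'   `frag1`, `chrom2`, `pos2`, `strand2`, `frag2`, `is_unique`,
#'   `n_mismatch`, `has_indel`, `truth`
#'   (one of `"good"`, `"duplicate"`, `"nonunique"`, `"mismatch"`,
#'   `"close_pair"`).
#' @export
simulate_pairs <- function(truth, config, annotation = NULL,
                           seed = config$seed + 3L) {
  stopifnot(config$sequencing_depth > 0)
  if (is.null(annotation)) annotation <- make_annotation(config)
  E <- expected_matrix(truth, config)
  n <- nrow(E)
  bs <- config$bin_size
  chrom <- "armS"
  with_seed(seed, {
    up <- which(upper.tri(E, diag = TRUE), arr.ind = TRUE)
    p <- E[upper.tri(E, diag = TRUE)]
    counts <- as.vector(stats::rmultinom(1, size = round(config$sequencing_depth), prob = p))
    nz <- counts > 0
    bi <- rep(up[nz, 1L], counts[nz])
    bj <- rep(up[nz, 2L], counts[nz])
    m <- length(bi)
    pos1 <- (bi - 1L) * bs + sample.int(bs, m, replace = TRUE) - 1L
    pos2 <- (bj - 1L) * bs + sample.int(bs, m, replace = TRUE) - 1L
    strand1 <- sample(c("+", "-"), m, replace = TRUE)
    strand2 <- sample(c("+", "-"), m, replace = TRUE)
    close_opp <- abs(pos1 - pos2) < 2000 & strand1 != strand2
    strand2[close_opp] <- strand1[close_opp]
    # de-collide genuine records so rule (iv) never fires on them
    key <- paste(pos1, strand1, pos2, strand2)
    for (attempt in seq_len(20L)) {
      dup <- duplicated(key)
      if (!any(dup)) break
      j <- which(dup)
      pos2[j] <- (bj[j] - 1L) * bs + sample.int(bs, length(j), replace = TRUE) - 1L
      close_opp <- abs(pos1[j] - pos2[j]) < 2000 & strand1[j] != strand2[j]
      strand2[j][close_opp] <- strand1[j][close_opp]
      key <- paste(pos1, strand1, pos2, strand2)
    }
    good <- data.frame(
      chrom1 = chrom, pos1 = pos1, strand1 = strand1,
      chrom2 = chrom, pos2 = pos2, strand2 = strand2,
      is_unique = TRUE,
      n_mismatch = sample(0:2, m, replace = TRUE),
      has_indel = FALSE,
      truth = "good"
    )
    records <- good

    # PCR duplicates: exact copies of genuine records
    dup_sel <- stats::runif(m) < config$duplicate_rate
    if (any(dup_sel)) {
      d <- good[dup_sel, ]
      d$truth <- "duplicate"
      records <- rbind(records, d)
    }
    rand_records <- function(count, label) {
      p1 <- sample.int(config$arm_length, count) - 1L
      p2 <- sample.int(config$arm_length, count) - 1L
      data.frame(
        chrom1 = chrom, pos1 = p1, strand1 = sample(c("+", "-"), count, TRUE),
        chrom2 = chrom, pos2 = p2, strand2 = sample(c("+", "-"), count, TRUE),
        is_unique = TRUE, n_mismatch = 0L, has_indel = FALSE, truth = label
      )
    }
    n_of <- function(rate) stats::rbinom(1L, round(config$sequencing_depth), rate)
    k <- n_of(config$nonunique_rate)
    if (k > 0) {
      r <- rand_records(k, "nonunique"); r$is_unique <- FALSE
      records <- rbind(records, r)
    }
    k <- n_of(config$mismatch_rate)
    if (k > 0) {
      r <- rand_records(k, "mismatch"); r$n_mismatch <- 3L
      records <- rbind(records, r)
    }
    k <- n_of(config$close_pair_rate)
    if (k > 0) {
      r <- rand_records(k, "close_pair")
      r$pos1 <- sample.int(config$arm_length - 2000L, k) - 1L
      r$pos2 <- r$pos1 + sample(100:1900, k, replace = TRUE)
      r$strand1 <- "+"; r$strand2 <- "-"
      records <- rbind(records, r)
    }
    records$frag1 <- fragment_index(records$pos1, annotation$sites)
    records$frag2 <- fragment_index(records$pos2, annotation$sites)
    records$id <- sprintf("r%07d", seq_len(nrow(records)))
    rownames(records) <- NULL
    records[, c("id", "chrom1", "pos1", "strand1", "frag1",
                "chrom2", "pos2", "strand2", "frag2",
                "is_unique", "n_mismatch", "has_indel", "truth")]
  })
}

#' Restriction-fragment index of a position
#'
#' Fragment `i` spans `[site[i-1], site[i])`, with fragment 1 running from
#' the arm start to the first site and fragment `length(sites)+1` from the
#' last site to the arm end.
#'
#' @param pos bp positions (0-based).
#' @param sites sorted restriction-site positions.
#' @return integer fragment indices.
#' @export
fragment_index <- function(pos, sites) {
  findInterval(pos, sites) + 1L
}

#' Simulate reporter-assay cell populations
#'
#' Emulates flow-cytometry measurements of an enhancer-blocking reporter:
#' each transfected cell expresses EGFP (enhancer side, dampened by the
#' tested insulator) and mCherry (reference side), and insulation shifts the
#' per-cell `log2(mCherry/EGFP)` ratio. The planted ratio is
#' `baseline + (true_strength/100) * gypsy_offset` plus Gaussian noise;
#' `true_strength` is expressed as percent of the gypsy insulator (100 =
#' gypsy-level blocking, 0 = neutral spacer).
#'
#' @param true_strength planted insulator strength, percent of gypsy.
#' @param n_cells number of cells.
#' @param noise_sd per-cell Gaussian noise on the log2 ratio.
#' @param seed RNG seed.
#' @param fragment,replicate labels attached to the output.
#' @param baseline spacer-level log2 ratio (default 0).
#' @param gypsy_offset log2-ratio shift of a gypsy-level insulator
#'   (default 2).
#' @return data frame `fragment`, `replicate`, `egfp`, `mcherry`.
#' @export
simulate_reporter_cells <- function(true_strength, n_cells, noise_sd = 0.5,
                                    seed = 1, fragment = "frag",
                                    replicate = 1L,
                                    baseline = 0, gypsy_offset = 2) {
  if (!is_count(n_cells)) stop_invalid("`n_cells` must be >= 1")
  with_seed(seed, {
    ratio <- baseline + (true_strength / 100) * gypsy_offset +
      stats::rnorm(n_cells, 0, noise_sd)
    egfp <- 2^stats::rnorm(n_cells, 10, 0.8)
    data.frame(
      fragment = fragment,
      replicate = replicate,
      egfp = egfp,
      mcherry = egfp * 2^ratio
    )
  })
}
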