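test_that("fusion reads split at junction midpoints and trim to 60 nt", {
  # no junction: one sub-read, trimmed
  long <- paste(rep("ACGT", 20), collapse = "") # 80 nt, no junction motif
  out <- split_fusion_read(long)
  expect_length(out, 1)
  expect_equal(nchar(out), 60)
  # single junction splits between the half-sites
  out2 <- split_fusion_read("AAAAGTATACTTTT")
  expect_equal(out2, c("AAAAGTA", "TACTTTT"))
  # all four patterns split
  for (pat in c("GTATAC", "TTATAA", "GTATAA", "TTATAC")) {
    expect_length(split_fusion_read(paste0("CCCC", pat, "GGGG")), 2)
  }
  expect_equal(split_fusion_read(""), character(0))
  expect_error(split_fusion_read("ACGU"), "non-ACGTN")
})

test_that("planted junction counts match sub-read totals", {
  # oracle: plant k junctions in junction-free backgrounds; the number of
  # sub-reads must be reads + junctions
  set.seed(42)
  bg <- function(n) paste(sample(c("A", "C", "G"), n, replace = TRUE), collapse = "")
  total_sub <- 0L
  n_reads <- 200L
  n_junctions <- 0L
  for (i in seq_len(n_reads)) {
    k <- sample(0:2, 1)
    n_junctions <- n_junctions + k
    parts <- vapply(seq_len(k + 1), function(j) bg(sample(8:20, 1)), character(1))
    junctions <- sample(c("GTATAC", "TTATAA", "GTATAA", "TTATAC"), k, replace = TRUE)
    read <- parts[1]
    for (j in seq_len(k)) read <- paste0(read, junctions[j], parts[j + 1])
    total_sub <- total_sub + length(split_fusion_read(read))
  }
  expect_equal(total_sub, n_reads + n_junctions)
})

test_that("pair filter applies the four rules in order on a hand-built fixture", {
  rec <- function(pos1, pos2, strand1 = "+", strand2 = "+", uniq = TRUE,
                  mm = 0, indel = FALSE) {
    data.frame(chrom1 = "arm", pos1 = pos1, strand1 = strand1,
               chrom2 = "arm", pos2 = pos2, strand2 = strand2,
               is_unique = uniq, n_mismatch = mm, has_indel = indel)
  }
  fixture <- rbind(
    rec(1000, 50000),                       # keep
    rec(2000, 60000, "-", "-"),             # keep
    rec(3000, 70000),                       # keep
    rec(1000, 50000),                       # duplicate of record 1
    rec(4000, 80000, uniq = FALSE),         # non-unique
    rec(5000, 90000, mm = 3),               # too many mismatches
    rec(10000, 11500, "+", "-"),            # opposite strands, 1.5 kb apart
    rec(6000, 95000),                       # keep
    rec(50000, 1000, "+", "+"),             # duplicate of record 1, mates swapped
    rec(7000, 99000),                       # keep
    rec(8000, 99500),                       # keep
    rec(9000, 99900)                        # keep
  )
  out <- filter_pairs(fixture)
  expect_equal(nrow(out$kept), 7)
  tab <- table(out$rejected$reason)
  expect_equal(unname(tab[c("duplicate", "non_unique", "mismatch", "close_pair")]),
               array(c(2L, 1L, 1L, 1L)))
  # completeness: every record lands in exactly one output
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(fixture))
  # rule (iii) boundary: exactly 2 kb apart is kept
  ok <- filter_pairs(rec(10000, 12000, "+", "-"))
  expect_equal(nrow(ok$kept), 1)
  # empty input
  empty <- filter_pairs(fixture[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("binning counts each cis pair once at floor(pos/bin)", {
  p <- data.frame(chrom1 = "arm", pos1 = c(1000, 8500), strand1 = "+",
                  chrom2 = "arm", pos2 = c(5000, 9000), strand2 = "+",
                  is_unique = TRUE, n_mismatch = 0, has_indel = FALSE)
  mat <- bin_pairs(p, 2000, 20000)
  expect_equal(mat$counts[1, 3], 1)
  expect_equal(mat$counts[3, 1], 1)
  expect_equal(mat$counts[5, 5], 1) # both mates in bin 5 (0-based bin 4)
  expect_equal(matrix_total(mat), 2)
  # trans pairs dropped with a counter
  p$chrom2[1] <- "other"
  mat2 <- bin_pairs(p, 2000, 20000, chrom = "arm")
  expect_equal(attr(mat2, "trans_dropped"), 1)
  expect_equal(matrix_total(mat2), 1)
  # out-of-range position errors
  p$chrom2[1] <- "arm"; p$pos2[1] <- 30000
  expect_error(bin_pairs(p, 2000, 20000), "beyond arm")
})

test_that("low-coverage mask follows the zero + smallest-5% rule", {
  # worked example: 20 bins, marginals 0, 1, then 18 bins of 10
  n <- 20
  mat <- contact_matrix(diag(c(0, 1, rep(10, 18))), 2000)
  mat <- mask_low_coverage(mat)
  expect_identical(which(!mat$valid), c(1L, 2L))
  # all-equal marginals: ceil(0.05 n) lowest-index bins masked
  mat2 <- contact_matrix(diag(rep(4, 40)), 2000)
  mat2 <- mask_low_coverage(mat2)
  expect_identical(which(!mat2$valid), 1:2)
  # random matrices against the sort-and-threshold oracle
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    C <- matrix(rpois(n * n, 0.8), n, n)
    C <- C + t(C)
    m <- mask_low_coverage(contact_matrix(C, 2000))
    expect_identical(m$valid, oracle_mask(C))
  }
})

test_that("ICE balancing meets its contract", {
  set.seed(2)
  n <- 50
  A <- matrix(runif(n * n, 1, 5), n, n); A <- A + t(A)
  mat <- contact_matrix(A, 2000)
  mat <- ice_normalize(mat)
  marg <- rowSums(mat$normalized)
  expect_lt(sd(marg) / mean(marg), 1e-6)
  expect_equal(mean(marg), 1, tolerance = 1e-9)
  # scale invariance
  mat7 <- ice_normalize(contact_matrix(7 * A, 2000))
  expect_equal(mat7$normalized, mat$normalized, tolerance = 1e-9)
  # idempotence
  again <- contact_matrix(mat$normalized, 2000)
  again <- ice_normalize(again)
  expect_lt(max(abs(again$normalized - mat$normalized)), 1e-9)
  # doubly-balanced input is a fixed point up to scale
  B <- mat$normalized
  fixed <- ice_normalize(contact_matrix(B * 3, 2000))
  expect_equal(fixed$normalized, B, tolerance = 1e-9)
  # matches the independent Sinkhorn-Knopp oracle when both are run to
  # high precision
  tight <- ice_normalize(contact_matrix(A, 2000), tol = 1e-13, max_iter = 1000)
  expect_lt(max(abs(tight$normalized - oracle_sinkhorn(A))), 1e-8)
  # masked bins stay undefined
  C <- A; C[3, ] <- 0; C[, 3] <- 0
  m2 <- mask_low_coverage(contact_matrix(C, 2000))
  m2 <- ice_normalize(m2)
  expect_true(all(is.na(m2$normalized[3, ])))
  expect_error(ice_normalize(contact_matrix(matrix(1, 1, 1), 2000)), "2 valid bins")
})

test_that("downsampling is exact, deterministic and bounded", {
  p <- data.frame(chrom1 = "arm", pos1 = 1:100 * 10, strand1 = "+",
                  chrom2 = "arm", pos2 = 1:100 * 20, strand2 = "-",
                  is_unique = TRUE, n_mismatch = 0, has_indel = FALSE)
  expect_identical(downsample_pairs(p, 100, seed = 1), p)
  expect_equal(nrow(downsample_pairs(p, 0, seed = 1)), 0)
  expect_identical(downsample_pairs(p, 40, seed = 9), downsample_pairs(p, 40, seed = 9))
  expect_error(downsample_pairs(p, 101, seed = 1), "downsample")
})

test_that("replicate correlation matches a brute-force flatten", {
  cfg <- synthetic_config(4e5, bin_size = 10000, n_boundaries = 0,
                          sequencing_depth = 1e5, seed = 4)
  truth <- plant_truth(cfg)
  m1 <- ice_normalize(mask_low_coverage(simulate_matrix(truth, cfg, seed = 41)))
  m2 <- ice_normalize(mask_low_coverage(simulate_matrix(truth, cfg, seed = 42)))
  r <- replicate_correlation(m1, m2, max_dist = 1e5)
  # brute force
  A <- m1$normalized; B <- m2$normalized
  va <- m1$valid & m2$valid
  xs <- c(); ys <- c()
  n <- nrow(A)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- (j - i) * 10000
      if (d > 0 && d < 1e5 && va[i] && va[j] && !is.na(A[i, j]) && !is.na(B[i, j])) {
        xs <- c(xs, A[i, j]); ys <- c(ys, B[i, j])
      }
    }
  }
  expect_equal(r, cor(xs, ys), tolerance = 1e-12)
  # self-correlation and affine invariance
  expect_equal(replicate_correlation(m1, m1), 1.0, tolerance = 1e-12)
  m3 <- m1; m3$normalized <- 3 * m1$normalized + 5
  expect_equal(replicate_correlation(m1, m3), 1.0, tolerance = 1e-12)
})

test_that("pair and matrix text round-trips preserve content", {
  cfg <- synthetic_config(1e5, n_boundaries = 0, sequencing_depth = 2e3, seed = 6)
  truth <- plant_truth(cfg)
  pairs <- simulate_pairs(truth, cfg)
  f <- tempfile(fileext = ".tsv")
  write_pairs(pairs, f)
  back <- read_pairs(f)
  expect_equal(back$pos1, pairs$pos1)
  expect_equal(back$truth, pairs$truth)
  mat <- bin_pairs(pairs[pairs$truth == "good", ], 2000, 1e5)
  mat <- mask_low_coverage(mat)
  f2 <- tempfile(fileext = ".mtx")
  write_matrix_triplets(mat, f2)
  back2 <- read_matrix_triplets(f2)
  expect_equal(back2$counts, mat$counts)
  expect_identical(back2$valid, mat$valid)
  unlink(c(f, f2, paste0(f2, ".bins")))
})
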