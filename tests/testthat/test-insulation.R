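test_that("binSignal equals the diamond double-loop oracle", {
  set.seed(21)
  for (i in 1:6) {
    cm <- random_norm_matrix(60, masked = sample(60, 2))
    for (w in c(5, 10)) {
      expect_equal(bin_signal(cm, w), oracle_bin_signal(cm$normalized, w),
                   tolerance = 1e-12)
    }
  }
  # uniform matrix: binSignal equals the constant
  cu <- random_norm_matrix(40)
  cu$normalized[] <- 3.7
  bs <- bin_signal(cu, 5)
  expect_true(all(bs[6:36] == 3.7))
  expect_true(all(is.na(bs[c(1:5, 37:40)])))
  # fully masked diamond is undefined
  cm2 <- random_norm_matrix(40, masked = 11:20)
  expect_true(is.na(bin_signal(cm2, 5)[16]))
  expect_error(bin_signal(cu, 30), "does not fit")
})

test_that("insulation score matches the windowed-mean oracle and nulls", {
  set.seed(22)
  for (i in 1:6) {
    bs <- runif(80, 0.5, 2)
    bs[sample(80, 5)] <- NA
    for (w in c(6, 10)) {
      expect_equal(insulation_score(bs, w), oracle_insulation(bs, w),
                   tolerance = 1e-12)
    }
  }
  # uniform profile scores zero
  expect_equal(insulation_score(rep(2, 30), 10), rep(0, 30))
  # a bin at half its neighborhood average scores -1
  bs <- rep(1, 41)
  # solve for the dip value v with v / mean(window) = 1/2: the w = 10
  # window holds 8 ones plus v itself, so 9v/(8+v) = 1/2 => v = 8/17
  w <- 10
  v <- 8 / 17
  bs[21] <- v
  expect_equal(insulation_score(bs, w)[21], -1, tolerance = 1e-12)
})

test_that("boundary calling finds strict minima with plateau and threshold rules", {
  # monotone profile: nothing called
  expect_length(call_boundaries(seq(-1, 0, length.out = 20)), 0)
  # single dip
  s <- rep(0, 21); s[11] <- -0.5
  expect_identical(call_boundaries(s), 11L)
  # shallow dip ignored by the -0.1 filter
  s2 <- rep(0, 21); s2[11] <- -0.05
  expect_length(call_boundaries(s2), 0)
  expect_identical(call_boundaries(s2, threshold = -0.01), 11L)
  # plateau resolves to its leftmost bin
  s3 <- rep(0, 21); s3[10:12] <- -0.3
  expect_identical(call_boundaries(s3), 10L)
  # minima adjacent to undefined bins are not called
  s4 <- rep(0, 21); s4[11] <- -0.5; s4[12] <- NA
  expect_length(call_boundaries(s4), 0)
})

test_that("zero-noise planted boundaries are recovered exactly at every window", {
  # margin keeps planted boundaries inside the region where all four
  # window sizes are defined, so recovery must be exact
  cfg <- synthetic_config(1e6, 2000, n_boundaries = 10, insulation_factors = 0.5,
                          sequencing_depth = 5e5, boundary_edge_margin = 80,
                          seed = 8)
  truth <- plant_truth(cfg)
  mat <- simulate_matrix(truth, cfg, noise = "none")
  mat$valid <- rep(TRUE, mat$n_bins)
  mat <- ice_normalize(mat)
  prof <- insulation_profile(mat)
  for (k in seq_along(prof$windows_bins)) {
    called <- call_boundaries(prof$scores[, k])
    expect_true(all(truth$boundary_bins %in% called),
                info = sprintf("window %d", prof$windows_bp[k]))
  }
  merged <- merge_windows(prof)
  expect_true(all(truth$boundary_bins %in% merged$bin))
})

test_that("translation of a planted boundary translates its call", {
  base <- synthetic_config(6e5, 2000, n_boundaries = 1, insulation_factors = 0.5,
                           sequencing_depth = 1e5, seed = 1)
  truth <- plant_truth(base)
  for (shift in c(-7, 13)) {
    shifted <- truth
    shifted$boundary_bins <- truth$boundary_bins + shift
    m <- simulate_matrix(shifted, base, noise = "none")
    m <- ice_normalize(m)
    called <- merge_windows(insulation_profile(m))$bin
    expect_true((truth$boundary_bins + shift) %in% called)
  }
})

test_that("stronger planted insulation gives lower mean scores", {
  scores <- vapply(c(0.8, 0.6, 0.4, 0.2), function(f) {
    cfg <- synthetic_config(6e5, 2000, n_boundaries = 1, insulation_factors = f,
                            sequencing_depth = 1e5, seed = 3)
    truth <- plant_truth(cfg)
    m <- ice_normalize(simulate_matrix(truth, cfg, noise = "none"))
    insulation_profile(m)$mean_score[truth$boundary_bins]
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("window merging averages scores and applies the mean filter", {
  # same bin called at all windows: score is the window mean
  prof <- structure(list(
    windows_bp = c(20e3, 40e3, 80e3, 160e3), windows_bins = c(10, 20, 40, 80),
    scores = cbind(rep(0, 50), 0, 0, 0), mean_score = rep(0, 50)
  ), class = "insulation_profile")
  prof$scores[25, ] <- c(-0.2, -0.3, -0.4, -0.5)
  for (k in 1:4) { # make bin 25 a strict minimum everywhere
    prof$scores[24, k] <- -0.01; prof$scores[26, k] <- -0.01
  }
  prof$mean_score <- rowMeans(prof$scores)
  out <- merge_windows(prof)
  expect_equal(out$bin, 25)
  expect_equal(out$score, -0.35)
  expect_equal(out$n_windows, 4)
  # mean score above -0.1 is dropped even if windows called it
  prof2 <- prof
  prof2$scores[25, ] <- c(-0.15, -0.05, -0.0, -0.0)
  prof2$mean_score <- rowMeans(prof2$scores)
  expect_equal(nrow(merge_windows(prof2)), 0)
  # nearby candidates collapse to the lowest-mean-score bin
  prof3 <- prof
  prof3$scores[27, ] <- c(-0.6, -0.6, -0.6, -0.6)
  prof3$scores[26, ] <- 0; prof3$scores[28, ] <- -0.01
  prof3$mean_score <- rowMeans(prof3$scores)
  out3 <- merge_windows(prof3)
  expect_equal(out3$bin, 27)
})

test_that("genotype harmonization follows the lowest-global-score rule", {
  mk_prof <- function(values) {
    structure(list(windows_bp = c(20e3, 40e3, 80e3, 160e3),
                   windows_bins = c(10, 20, 40, 80),
                   scores = cbind(values, values, values, values),
                   mean_score = values), class = "insulation_profile")
  }
  mk_set <- function(bins, scores) {
    structure(data.frame(bin = bins, score = scores, n_windows = 4L),
              class = c("boundary_set", "data.frame"))
  }
  # worked example: WT at 100 (-0.30), mutant at 101 (-0.20);
  # WT@101 = -0.28, mut@100 = -0.19
  wt_scores <- rep(0, 200); wt_scores[100] <- -0.30; wt_scores[101] <- -0.28
  mut_scores <- rep(0, 200); mut_scores[100] <- -0.19; mut_scores[101] <- -0.20
  cons <- harmonize_genotypes(
    list(WT = mk_set(100, -0.30), mut = mk_set(101, -0.20)),
    list(WT = mk_prof(wt_scores), mut = mk_prof(mut_scores))
  )
  # global(100) = -0.49 < global(101) = -0.48
  expect_equal(cons$bin, 100)
  expect_true(cons$WT.present & cons$mut.present)
  expect_equal(cons$WT.score, -0.30)
  expect_equal(cons$mut.score, -0.19)
  # isolated boundary in one genotype passes through unchanged
  solo <- harmonize_genotypes(list(WT = mk_set(50, -0.4)),
                              list(WT = mk_prof(replace(rep(0, 200), 50, -0.4))))
  expect_equal(solo$bin, 50)
  expect_true(solo$WT.present)
  # chained group spanning three genotype calls resolves to one consensus
  sc <- rep(0, 200); sc[98:102] <- c(-0.1, -0.2, -0.5, -0.2, -0.1)
  cons3 <- harmonize_genotypes(
    list(a = mk_set(98, -0.1), b = mk_set(100, -0.5), c = mk_set(102, -0.1)),
    list(a = mk_prof(sc), b = mk_prof(sc), c = mk_prof(sc))
  )
  expect_equal(nrow(cons3), 1)
  expect_equal(cons3$bin, 100)
})

test_that("boundary classification applies the lost/weaker/intact rules", {
  cons <- data.frame(
    bin = c(10, 20, 30, 40),
    WT.present = c(TRUE, TRUE, TRUE, FALSE),
    WT.score = c(-0.5, -0.5, -0.5, NA),
    mut.present = c(FALSE, TRUE, TRUE, TRUE),
    mut.score = c(NA, -0.48, -0.55, -0.3)
  )
  cls <- classify_boundaries(cons, "WT", "mut")
  expect_equal(as.character(cls$label), c("lost", "weaker", "intact"))
  expect_equal(cls$delta[2], 0.02)
  expect_equal(cls$delta[3], -0.05)
  expect_equal(attr(cls, "excluded_non_wt"), 1)
  # threshold boundary: delta exactly 0.01 is weaker
  cons$mut.score[2] <- -0.49
  cls2 <- classify_boundaries(cons, "WT", "mut")
  expect_equal(as.character(cls2$label[2]), "weaker")
})

test_that("differential insulation is an element-wise difference", {
  mk <- function(values) {
    structure(list(windows_bp = c(20e3), windows_bins = 10,
                   scores = cbind(values), mean_score = values),
              class = "insulation_profile")
  }
  a <- c(NA, -0.2, 0, 0.1)
  b <- c(NA, -0.1, 0.2, NA)
  expect_equal(delta_insulation(mk(a), mk(b)), b - a)
  expect_equal(delta_insulation(mk(a), mk(a)), c(NA, 0, 0, 0))
  expect_error(delta_insulation(mk(a), mk(c(1, 2))), "shape")
})
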