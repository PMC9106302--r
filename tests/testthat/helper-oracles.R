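# Independent brute-force oracles used to check the implementation.
# These are deliberately written as plain double loops / enumerations,
# sharing no code with the package internals.

# random symmetric positive matrix wrapped as a normalized contact_matrix
random_norm_matrix <- function(n, bin_size = 2000, masked = integer(0)) {
  M <- matrix(stats::runif(n * n, 0.5, 2), n, n)
  M <- (M + t(M)) / 2
  valid <- rep(TRUE, n)
  valid[masked] <- FALSE
  M[!valid, ] <- NA_real_
  M[, !valid] <- NA_real_
  cm <- contact_matrix(matrix(1, n, n), bin_size, valid = valid)
  cm$normalized <- M
  cm
}

# diamond mean by explicit double loop
oracle_bin_signal <- function(M, w) {
  n <- nrow(M)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w - 1 > n) next
    vals <- numeric(w * w)
    k <- 0L
    for (a in (i - w):(i - 1)) {
      for (b in i:(i + w - 1)) {
        k <- k + 1L
        vals[k] <- M[a, b]
      }
    }
    if (all(is.na(vals))) next
    out[i] <- mean(vals, na.rm = TRUE)
  }
  out
}

# windowed local mean by explicit loop
oracle_insulation <- function(bs, w) {
  n <- length(bs)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(bs[i])) next
    nb <- c()
    for (j in seq_len(n)) {
      if (j > i - w / 2 && j < i + w / 2 && !is.na(bs[j])) nb <- c(nb, bs[j])
    }
    if (!length(nb)) next
    m <- mean(nb)
    if (m > 0 && bs[i] > 0) out[i] <- log2(bs[i] / m)
  }
  out
}

# low-coverage mask by sort-and-threshold
oracle_mask <- function(counts, fraction = 0.05) {
  marg <- rowSums(counts)
  valid <- rep(TRUE, length(marg))
  valid[marg == 0] <- FALSE
  nz <- which(marg > 0)
  n_low <- ceiling(fraction * length(nz))
  ord <- nz[order(marg[nz], nz)]
  valid[ord[seq_len(n_low)]] <- FALSE
  valid
}

# Sinkhorn-Knopp balancing: alternate row and column scalings on the full
# matrix, tracked through explicit scaling vectors
oracle_sinkhorn <- function(A, iters = 5000) {
  n <- nrow(A)
  r <- rep(1, n)
  for (k in seq_len(iters)) {
    B <- A * outer(r, r)
    m <- rowSums(B)
    r <- r / sqrt(m / mean(m))
    if (stats::sd(rowSums(A * outer(r, r))) / mean(rowSums(A * outer(r, r))) < 1e-12) break
  }
  B <- A * outer(r, r)
  B / mean(rowSums(B))
}

# per-diagonal expected value by explicit loops
oracle_oe <- function(M) {
  n <- nrow(M)
  OE <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in seq_len(n - d)) vals <- c(vals, M[i, i + d])
    e <- mean(vals, na.rm = TRUE)
    if (!is.finite(e) || e == 0) next
    for (i in seq_len(n - d)) {
      OE[i, i + d] <- M[i, i + d] / e
      OE[i + d, i] <- M[i + d, i] / e
    }
  }
  OE
}

# leading eigenvector by power iteration
oracle_power_iteration <- function(C, iters = 10000, tol = 1e-12) {
  # shift to make the target eigenvalue the largest in magnitude
  shift <- sum(abs(C))
  A <- C + diag(shift, nrow(C))
  v <- rep(1, nrow(C)) / sqrt(nrow(C))
  for (k in seq_len(iters)) {
    v2 <- A %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(abs(v2) - abs(v))) < tol) break
    v <- v2
  }
  as.vector(v2)
}

# exact two-sided Wilcoxon p by enumeration of all group assignments
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force nearest-feature distance
oracle_min_dist <- function(pos, features) {
  vapply(pos, function(p) {
    if (!length(features)) return(Inf)
    min(abs(features - p))
  }, numeric(1))
}

# quadratic interval-overlap oracle on half-open intervals
oracle_overlap <- function(s1, e1, s2, e2) {
  out <- logical(length(s1))
  for (i in seq_along(s1)) {
    hit <- FALSE
    for (j in seq_along(s2)) {
      if (s1[i] < e2[j] && s2[j] < e1[i]) hit <- TRUE
    }
    out[i] <- hit
  }
  out
}
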