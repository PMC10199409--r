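# Independent oracles used across the suite. None of these call the package
# routines they are used to check.

# Naive O(n^3) Ward agglomeration via the Lance-Williams recurrence.
# squared = TRUE reproduces the ward.D2 convention (recurrence on squared
# dissimilarities, heights reported on the original scale).
naive_ward <- function(d, squared = TRUE) {
  n <- nrow(d)
  D <- if (squared) d^2 else d
  sizes <- rep(1, n)
  active <- 1:n
  ids <- -(1:n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in 1:(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) if (ii < jj) {
      a <- active[ii]; b <- active[jj]
      if (D[a, b] < bv) { bv <- D[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- if (squared) sqrt(bv) else bv
    merges[step, ] <- c(ids[a], ids[b])
    for (k in active) if (k != a && k != b) {
      na <- sizes[a]; nb <- sizes[b]; nk <- sizes[k]
      D[a, k] <- D[k, a] <-
        ((na + nk) * D[a, k] + (nb + nk) * D[b, k] - nk * D[a, b]) /
        (na + nb + nk)
    }
    sizes[a] <- sizes[a] + sizes[b]
    ids[a] <- step
    active <- setdiff(active, b)
  }
  list(merges = merges, heights = heights)
}

# Textbook Pearson correlation from raw sums.
pearson_formula <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Brute-force count of 3D lattice points (spacing `step` mm) whose distance
# from `center` is <= radius, enumerating integer offsets exhaustively.
brute_force_sphere_count <- function(center, radius, step = 3) {
  half <- ceiling(radius / step) + 1
  cnt <- 0L
  for (a in -half:half) for (b in -half:half) for (c in -half:half) {
    if (sum((c(a, b, c) * step)^2) <= radius^2) cnt <- cnt + 1L
  }
  cnt
}

# Top-k eigenpairs of a symmetric matrix by power iteration with deflation.
power_iteration_eigen <- function(S, k = 2, iters = 5000) {
  vals <- numeric(k)
  vecs <- matrix(0, nrow(S), k)
  for (j in 1:k) {
    v <- rep(1, nrow(S)) + seq_len(nrow(S)) / nrow(S)
    for (i in 1:iters) {
      v <- S %*% v
      nv <- sqrt(sum(v^2))
      if (nv == 0) break
      v <- v / nv
    }
    lam <- drop(t(v) %*% S %*% v)
    vals[j] <- lam
    vecs[, j] <- v
    S <- S - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

# Exhaustive search over all k-cluster partitions of items, returning the one
# minimising total within-cluster dissimilarity.
best_partition_exhaustive <- function(d, k = 3) {
  n <- nrow(d)
  best <- NULL; bv <- Inf
  # enumerate restricted-growth strings (canonical set partitions)
  assign_next <- function(labels) {
    if (length(labels) == n) {
      if (length(unique(labels)) != k) return()
      w <- 0
      for (g in 1:k) {
        idx <- which(labels == g)
        if (length(idx) > 1) w <- w + sum(d[idx, idx]) / 2
      }
      if (w < bv) { bv <<- w; best <<- labels }
      return()
    }
    for (g in 1:min(k, max(labels) + 1)) assign_next(c(labels, g))
  }
  assign_next(1L)
  structure(best, names = rownames(d))
}

# Monte-Carlo power of a one-sample one-tailed t-test by simulating raw data.
mc_power_one_sample <- function(d, n, alpha = 0.05, reps = 50000) {
  x <- matrix(rnorm(reps * n, mean = d, sd = 1), nrow = reps)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  mean(tstat > qt(1 - alpha, n - 1))
}

# Small random symmetric RDM-like matrix with labels.
random_rdm_matrix <- function(n) {
  m <- matrix(runif(n * n, 0.1, 1.9), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
  m
}

# Compact voxel grid (3 mm) covering all 21 printed peaks.
peaks_grid <- function() {
  affine <- rbind(c(3, 0, 0, -66),
                  c(0, 3, 0, -97),
                  c(0, 0, 3, -46),
                  c(0, 0, 0, 1))
  voxel_grid(c(44L, 55L, 30L), affine)
}
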