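make_resp <- function(nroi = 5, ntask = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nroi * ntask), nroi,
              dimnames = list(paste0("roi", 1:nroi), paste0("task", 1:ntask)))
  m
}

test_that("correlation distances follow the 1 - Pearson definition", {
  m <- make_resp()
  m["roi2", ] <- m["roi1", ]            # identical profiles
  m["roi3", ] <- -m["roi1", ]           # anti-correlated profiles
  d <- correlation_distance_matrix(m, orientation = "rois")
  expect_equal(unname(d["roi1", "roi2"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["roi1", "roi3"]), 2, tolerance = 1e-12)

  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(0, 5, 1))
  colnames(m2) <- paste0("t", 1:3)
  d2 <- correlation_distance_matrix(m2, orientation = "rois")
  expect_equal(unname(d2["a", "b"]),
               1 - pearson_formula(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)

  # orientations: tasks correlates columns, rois correlates rows
  m3 <- make_resp(6, 5, seed = 2)
  dt_ <- correlation_distance_matrix(m3, orientation = "tasks")
  expect_equal(dim(dt_), c(5L, 5L))
  expect_equal(unname(dt_["task1", "task2"]),
               1 - pearson_formula(m3[, "task1"], m3[, "task2"]),
               tolerance = 1e-12)

  m3["roi1", ] <- 7
  expect_error(correlation_distance_matrix(m3, orientation = "rois"), "roi1")
})

test_that("correlation distances are invariant to profile shift and positive scale", {
  m <- make_resp(6, 5, seed = 3)
  d0 <- correlation_distance_matrix(m, orientation = "rois")
  m_shift <- m; m_shift["roi4", ] <- m["roi4", ] + 11
  m_scale <- m; m_scale["roi2", ] <- m["roi2", ] * 4.2
  expect_equal(unclass(correlation_distance_matrix(m_shift, "rois")),
               unclass(d0), tolerance = 1e-10)
  expect_equal(unclass(correlation_distance_matrix(m_scale, "rois")),
               unclass(d0), tolerance = 1e-10)
  # construction always yields symmetric, zero-diagonal, [0, 2] entries
  for (seed in 4:8) {
    d <- correlation_distance_matrix(make_resp(5, 6, seed), "tasks")
    expect_equal(unclass(d), t(unclass(d)))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 2))
  }
})

test_that("group averaging is the entrywise mean with matching labels", {
  rdms <- lapply(1:24, function(s)
    correlation_distance_matrix(make_resp(5, 4, seed = s), "tasks"))
  expect_equal(unclass(average_rdms(rdms[1])), unclass(rdms[[1]]),
               ignore_attr = "level")
  avg <- average_rdms(rdms)
  ref <- Reduce(`+`, lapply(rdms, unclass)) / 24   # direct summation
  expect_equal(unclass(avg), ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(avg, "level"), "group")
  bad <- rdms
  rownames(bad[[2]]) <- colnames(bad[[2]]) <- paste0("z", 1:4)
  expect_error(average_rdms(bad), "mismatch")
})

test_that("Ward linkage matches the naive Lance-Williams oracle", {
  # two leaves: single merge at the input dissimilarity
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- ward_linkage(d2)
  expect_equal(hc2$height, 0.7)

  # 1-D points {0, 1, 10, 11}: pairs merge first, heights match the oracle
  pts <- c(0, 1, 10, 11)
  dd <- as.matrix(dist(pts))
  dimnames(dd) <- list(c("p0", "p1", "p10", "p11"), c("p0", "p1", "p10", "p11"))
  hc <- ward_linkage(dd)
  o <- naive_ward(dd)
  expect_equal(hc$height, o$heights, tolerance = 1e-10)
  expect_equal(unname(cut_tree(hc, 2)), c(1, 1, 2, 2))

  # ward.D convention against the unsquared recurrence
  hcD <- ward_linkage(dd, method = "ward.D")
  oD <- naive_ward(dd, squared = FALSE)
  expect_equal(hcD$height, oD$heights, tolerance = 1e-10)

  # random RDMs of size <= 7: heights agree, and heights are monotone
  set.seed(5)
  for (i in 1:40) {
    m <- random_rdm_matrix(sample(4:7, 1))
    hc <- ward_linkage(m)
    expect_equal(hc$height, naive_ward(m)$heights, tolerance = 1e-8)
    expect_true(all(diff(hc$height) >= -1e-12))
  }

  expect_error(ward_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("a planted 3-block RDM is recovered at k = 3", {
  n <- 9
  blocks <- rep(1:3, each = 3)
  m <- matrix(0.9, n, n)
  m[outer(blocks, blocks, "==")] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
  hc <- ward_linkage(m)
  cut <- cut_tree(hc, 3)
  expect_equal(length(unique(cut)), 3)
  expect_true(all(tapply(cut, blocks, function(v) length(unique(v))) == 1))
  expect_equal(unname(cut_tree(hc, 1)), rep(1, n))
  expect_equal(unname(cut_tree(hc, n)), 1:n)
  expect_error(cut_tree(hc, 0), "between 1")
  expect_error(cut_tree(hc, n + 1), "between 1")
})

test_that("classical MDS reproduces exact configurations and ignores label order", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  e0 <- suppressWarnings(classical_mds(z, dims = 2))  # degenerate: no positive eigenvalues
  expect_true(all(abs(e0$points) < 1e-12))

  # collinear points A-B-C with d(A,B) = d(B,C) = 1, d(A,C) = 2
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  emb <- classical_mds(d3, dims = 1)
  got <- as.matrix(dist(emb$points))
  expect_equal(unname(got), unname(d3), tolerance = 1e-8)

  # oracle: power-iteration eigendecomposition of the double-centred matrix
  D2 <- d3^2
  J <- diag(3) - 1 / 3
  B <- -0.5 * J %*% D2 %*% J
  pe <- power_iteration_eigen(B, k = 1)
  ref_coord <- pe$vectors[, 1] * sqrt(pe$values[1])
  expect_equal(abs(unname(emb$points[, 1])), abs(ref_coord), tolerance = 1e-6)

  # permutation of labels leaves the embedded distances unchanged
  m <- random_rdm_matrix(6)
  p <- c(4, 1, 6, 2, 5, 3)
  e1 <- classical_mds(m, dims = 2)
  e2 <- classical_mds(m[p, p], dims = 2)
  expect_equal(as.matrix(dist(e2$points))[order(p), order(p)],
               unname(as.matrix(dist(e1$points))), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(classical_mds(m, dims = 6), "at most")
  # coordinates are centred
  expect_lt(max(abs(colMeans(e1$points))), 1e-10)
})

test_that("Newick export preserves topology and heights through a round trip", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  nwk <- tree_to_newick(ward_linkage(d2))
  expect_true(nwk %in% c("(A:0.4,B:0.4);", "(B:0.4,A:0.4);"))

  pts <- c(0, 1, 10, 11)
  dd <- as.matrix(dist(pts))
  dimnames(dd) <- list(c("p0", "p1", "p10", "p11"), c("p0", "p1", "p10", "p11"))
  tree <- ward_linkage(dd)
  phy <- ape::read.tree(text = tree_to_newick(tree))
  # topology: {p0, p1} and {p10, p11} are sister pairs
  expect_true(ape::is.monophyletic(phy, c("p0", "p1")))
  expect_true(ape::is.monophyletic(phy, c("p10", "p11")))
  # ultrametric depths recover the merge heights (leaf depth = height / 2)
  depths <- ape::node.depth.edgelength(phy)
  root_depth <- max(depths)
  expect_equal(2 * root_depth, max(tree$height), tolerance = 1e-8)
})
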