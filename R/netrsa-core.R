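# Correlation-distance matrices, Ward linkage, tree cutting, classical MDS.

new_rdm <- function(values, orientation = c("tasks", "rois", "model"),
                    level = c("subject", "group", "model"), tol = 1e-8) {
  orientation <- match.arg(orientation)
  level <- match.arg(level)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    stop("RDM requires labels", call. = FALSE)
  }
  if (max(abs(values - t(values))) > tol) {
    stop("RDM must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(values))) > tol) {
    stop("RDM must have a zero diagonal", call. = FALSE)
  }
  if (min(values) < -tol || max(values) > 2 + tol) {
    stop("RDM entries must lie in [0, 2]", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  values[values < 0] <- 0
  values[values > 2] <- 2
  structure(values, class = c("rdm", class(values)),
            orientation = orientation, level = level)
}

#' @export
print.rdm <- function(x, digits = 3, ...) {
  cat(sprintf("%s-level %s RDM (1 - r), %d items\n", attr(x, "level"),
              attr(x, "orientation"), nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Correlation-distance matrix of an ROI x task response matrix
#'
#' Computes `1 - Pearson r` between all pairs of profiles. With
#' `orientation = "rois"` the profiles are ROI rows (correlated across tasks,
#' the regional-taxonomy orientation); with `orientation = "tasks"` the matrix
#' is transposed first so task columns are correlated across ROIs (the
#' cognitive-taxonomy orientation).
#'
#' @param m Numeric ROI x task matrix with dimnames, at least 3 rows and
#'   3 columns.
#' @param orientation `"tasks"` or `"rois"`.
#' @param level RDM level tag (default `"subject"`).
#' @return An `rdm`: symmetric matrix with zero diagonal, entries in
#'   \[0, 2\].
#' @export
correlation_distance_matrix <- function(m, orientation = c("tasks", "rois"),
                                        level = "subject") {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(m), !anyNA(m))
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop("need at least 3 ROIs and 3 tasks for correlation distances",
         call. = FALSE)
  }
  profiles <- if (orientation == "rois") t(m) else m   # profiles in columns
  sds <- apply(profiles, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ",
         paste(colnames(profiles)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(profiles)
  new_rdm(d, orientation = orientation, level = level)
}

#' Average per-subject RDMs into a group RDM
#'
#' Entrywise arithmetic mean across subjects. Per-subject similarity followed
#' by averaging only at the clustering stage preserves subject-level
#' variability for inference.
#'
#' @param rdms List of `rdm` objects with identical labels and orientation.
#' @return Group-level `rdm`.
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1L, all(vapply(rdms, inherits, TRUE, "rdm")))
  ref <- rdms[[1]]
  for (r in rdms[-1]) {
    if (!identical(rownames(r), rownames(ref)) ||
        !identical(attr(r, "orientation"), attr(ref, "orientation"))) {
      stop("RDM labels/orientation mismatch across subjects", call. = FALSE)
    }
  }
  avg <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  new_rdm(avg, orientation = attr(ref, "orientation"), level = "group")
}

#' Ward agglomerative clustering of an RDM
#'
#' Applies Ward's minimum-variance agglomeration directly to the correlation
#' distances via the Lance-Williams recurrence. The default `"ward.D2"`
#' convention squares the dissimilarities inside the recurrence (treating
#' them as Euclidean distances); `"ward.D"` applies the recurrence to the
#' dissimilarities as given.
#'
#' @param rdm An `rdm` (or symmetric zero-diagonal matrix with labels).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return Object of class `c("linkage_tree", "hclust")`: `n - 1` merges with
#'   non-decreasing heights.
#' @export
ward_linkage <- function(rdm, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  m <- unclass(rdm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("input must be symmetric", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(m), method = method)
  class(hc) <- c("linkage_tree", "hclust")
  hc
}

#' Cut a linkage tree into k clusters
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector: leaf label -> cluster id.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1 || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  stats::cutree(tree, k = k)
}

#' Classical (Torgerson) metric MDS of an RDM
#'
#' Double-centres the squared dissimilarities, eigendecomposes, and returns
#' the top `dims` coordinates scaled by the square root of each eigenvalue.
#' Negative eigenvalues among the requested dimensions are truncated to zero
#' with a warning (the corresponding coordinates are zero).
#'
#' @param rdm An `rdm` or symmetric labelled matrix.
#' @param dims Embedding dimension (default 2); must be `<= n - 1`.
#' @return Object of class `mds_embedding`: list with `points`
#'   (n x dims, centred), `eig` (all eigenvalues, decreasing) and `labels`.
#' @export
classical_mds <- function(rdm, dims = 2) {
  m <- unclass(rdm)
  n <- nrow(m)
  if (dims > n - 1) {
    stop("dims must be at most n - 1 = ", n - 1, call. = FALSE)
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = dims, eig = TRUE)
  pts <- matrix(0, nrow = n, ncol = dims,
                dimnames = list(rownames(m), paste0("dim", seq_len(dims))))
  if (!is.null(fit$points) && ncol(fit$points) > 0L) {
    pts[, seq_len(ncol(fit$points))] <- fit$points
  }
  neg <- sum(fit$eig[seq_len(dims)] < 0)
  if (neg > 0L) {
    warning(neg, " negative eigenvalue(s) among requested dimensions truncated to zero",
            call. = FALSE)
  }
  structure(list(points = pts, eig = sort(fit$eig, decreasing = TRUE),
                 labels = rownames(m)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, digits = 3, ...) {
  cat(sprintf("classical MDS embedding: %d points in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  print(round(x$points, digits))
  invisible(x)
}

#' Export a linkage tree as a Newick string
#'
#' Uses the ultrametric convention of `ape`: each leaf sits at depth
#' `height/2` below the merge that created its cluster, so two leaves merged
#' at height `h` appear as `(A:h/2,B:h/2);`. Round-trips through a Newick
#' parser preserving topology and heights.
#'
#' @param tree A `linkage_tree`.
#' @return Newick string (with trailing semicolon).
#' @export
tree_to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy)
}
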