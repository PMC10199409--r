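# Spherical ROI construction in MNI space and beta extraction.

#' Voxel grid in MNI space
#'
#' A regular 3-D sampling grid defined by its shape and a 4x4 affine mapping
#' 0-based voxel indices to MNI millimetre coordinates of voxel centres.
#'
#' @param shape Integer vector of 3 dimensions.
#' @param affine 4x4 invertible matrix, voxel index (i, j, k, 1) -> mm.
#' @return Object of class `voxel_grid` with fields `shape`, `affine`,
#'   `voxel_size` (mm along each axis).
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible", call. = FALSE)
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel size must be positive", call. = FALSE)
  structure(list(shape = shape, affine = affine, voxel_size = vs),
            class = "voxel_grid")
}

#' Standard 3 mm isotropic MNI grid
#'
#' 61 x 73 x 61 voxels spanning x in \[-90, 90\], y in \[-126, 90\],
#' z in \[-72, 108\] mm, matching the 3 x 3 x 3 mm functional resolution.
#'
#' @return A [voxel_grid()].
#' @export
mni_grid_3mm <- function() {
  affine <- rbind(c(3, 0, 0, -90),
                  c(0, 3, 0, -126),
                  c(0, 0, 3, -72),
                  c(0, 0, 0, 1))
  voxel_grid(c(61L, 73L, 61L), affine)
}

# mm -> nearest 0-based voxel index
mni_to_voxel <- function(grid, mm) {
  v <- solve(grid$affine, c(mm, 1))[1:3]
  round(v)
}

# 0-based (i,j,k) matrix -> mm coordinates of voxel centres
voxel_to_mni <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# mm centre coordinates of every voxel, in R linear-index order (nvox x 3)
voxel_center_coords <- function(grid) {
  g <- expand.grid(i = 0:(grid$shape[1] - 1L),
                   j = 0:(grid$shape[2] - 1L),
                   k = 0:(grid$shape[3] - 1L))
  voxel_to_mni(grid, as.matrix(g))
}

new_roi_mask <- function(indices, grid, provenance, warn_empty = TRUE) {
  if (length(indices) == 0L && warn_empty) {
    warning("empty ROI mask (", provenance, ")", call. = FALSE)
  }
  structure(list(indices = as.integer(sort(indices)), grid = grid,
                 provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d voxels (%s) on %s grid\n", length(x$indices),
              x$provenance, paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Spherical ROI mask
#'
#' Selects exactly the voxels whose centre lies within `radius` mm (inclusive)
#' of the sphere centre, measuring centre-to-centre Euclidean distance in mm.
#' On a 3 mm isotropic grid with the centre on a grid point, the default
#' 7.5 mm radius yields 81 voxels.
#'
#' @param center MNI mm coordinates (length 3), or one row of
#'   [roi_sphere_specs()] (a list with `x`, `y`, `z`).
#' @param grid A [voxel_grid()].
#' @param radius Sphere radius in mm (default 7.5).
#' @return An object of class `roi_mask` holding linear (1-based, R order)
#'   voxel indices into the grid.
#' @examples
#' m <- sphere_mask(c(-33, -88, -10), mni_grid_3mm())
#' length(m$indices)  # 81
#' @export
sphere_mask <- function(center, grid, radius = 7.5) {
  if (is.list(center) || is.data.frame(center)) {
    center <- c(center$x, center$y, center$z)
  }
  stopifnot(length(center) == 3L, radius >= 0)
  ctr_idx <- solve(grid$affine, c(center, 1))[1:3]
  if (any(ctr_idx < -0.5) || any(ctr_idx > grid$shape - 0.5)) {
    stop("sphere centre outside grid: (", paste(center, collapse = ", "), ")",
         call. = FALSE)
  }
  # bounding box in voxel units, then exact mm test
  half <- ceiling(radius / grid$voxel_size)
  lo <- pmax(round(ctr_idx) - half, 0)
  hi <- pmin(round(ctr_idx) + half, grid$shape - 1L)
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- voxel_to_mni(grid, g)
  keep <- rowSums((mm - matrix(center, nrow(mm), 3L, byrow = TRUE))^2) <= radius^2
  idx <- 1L + g[keep, 1L] + grid$shape[1L] * (g[keep, 2L] +
                                                grid$shape[2L] * g[keep, 3L])
  new_roi_mask(idx, grid, provenance = "sphere", warn_empty = FALSE)
}

#' Conjoin an ROI mask with a thresholded statistic map
#'
#' Intersects a sphere mask with the suprathreshold (`map >= threshold`)
#' voxels of a localiser statistic map on the same grid, as used to restrict
#' spheres to functionally selective voxels. An empty conjunction is returned
#' with a warning, never an error, so the condition is recorded.
#'
#' @param mask A `roi_mask`.
#' @param stat_map 3-D array on the same grid.
#' @param threshold Scalar threshold.
#' @return A `roi_mask` with provenance `"conjunction"`.
#' @export
conjoin_mask <- function(mask, stat_map, threshold) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(stat_map), as.integer(mask$grid$shape))) {
    stop("statistic map grid mismatch: map is ",
         paste(dim(stat_map), collapse = "x"), ", mask grid is ",
         paste(mask$grid$shape, collapse = "x"), call. = FALSE)
  }
  keep <- mask$indices[stat_map[mask$indices] >= threshold]
  new_roi_mask(keep, mask$grid, provenance = "conjunction")
}

#' Mean beta within a mask, per condition
#'
#' Arithmetic mean of each condition's beta volume over the mask voxels.
#' Non-finite voxels are excluded with a message reporting the count.
#'
#' @param beta_volumes Named list of 3-D arrays (one per condition) or a
#'   single 3-D array.
#' @param mask A nonempty `roi_mask` on the same grid.
#' @return Named numeric vector of per-condition means.
#' @export
extract_mean_betas <- function(beta_volumes, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (length(mask$indices) == 0L) stop("empty ROI mask", call. = FALSE)
  if (is.array(beta_volumes) && length(dim(beta_volumes)) == 3L) {
    beta_volumes <- list(value = beta_volumes)
  }
  vapply(beta_volumes, function(vol) {
    if (!identical(dim(vol), as.integer(mask$grid$shape))) {
      stop("beta volume grid mismatch", call. = FALSE)
    }
    v <- vol[mask$indices]
    bad <- !is.finite(v)
    if (any(bad)) {
      message(sum(bad), " non-finite voxel(s) excluded from ROI mean")
      v <- v[!bad]
    }
    mean(v)
  }, numeric(1))
}

#' Subtract the control-condition baseline
#'
#' Removes the response common to reading a name without a knowledge demand:
#' `adjusted(roi, task) = beta(roi, task) - beta(roi, control)`. The famous
#' name 1-back condition is the default baseline; all control columns are
#' dropped from the output.
#'
#' @param betas ROI x condition matrix, or a `beta_dataset`
#'   (subject x ROI x condition array), with named columns/slices.
#' @param control Control condition label (default `"name_1back"`).
#' @param drop Conditions to drop from the output in addition to task columns
#'   being kept; defaults to both control conditions present.
#' @return Same shape as the input minus control columns: ROI x task matrix,
#'   or subject x ROI x task array.
#' @export
subtract_control <- function(betas, control = control_conditions()[1],
                             drop = NULL) {
  if (inherits(betas, "beta_dataset")) {
    arr <- betas$betas
    if (!control %in% dimnames(arr)[[3]]) {
      stop("control condition not present: ", control, call. = FALSE)
    }
    keep <- betas$tasks
    adj <- arr[, , keep, drop = FALSE]
    for (tk in keep) adj[, , tk] <- arr[, , tk] - arr[, , control]
    return(adj)
  }
  stopifnot(is.matrix(betas))
  if (!control %in% colnames(betas)) {
    stop("control condition not present: ", control, call. = FALSE)
  }
  if (is.null(drop)) drop <- intersect(colnames(betas), control_conditions())
  keep <- setdiff(colnames(betas), unique(c(control, drop)))
  adj <- betas[, keep, drop = FALSE] - betas[, control]
  adj
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x 3-D array, or a `roi_mask` (written as a 0/1 volume).
#' @param grid The [voxel_grid()] supplying the affine (taken from the mask
#'   when `x` is a `roi_mask`).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, grid = NULL) {
  if (inherits(x, "roi_mask")) {
    grid <- x$grid
    vol <- array(0L, dim = grid$shape)
    vol[x$indices] <- 1L
    x <- vol
  }
  stopifnot(!is.null(grid), inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(x)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
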