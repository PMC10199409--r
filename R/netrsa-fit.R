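#' Fit a network-level RSA to subject-level ROI responses
#'
#' The central fitting function. From per-subject ROI x task response matrices
#' (baseline-subtracted beta estimates) it computes, for every subject, the
#' task-similarity and ROI-similarity structures as correlation distances
#' (1 - Pearson r); averages each orientation across subjects; clusters the
#' group matrices with Ward linkage; and embeds them with classical MDS.
#' Per-subject RDMs are retained for model-comparison inference (see
#' [fit_model_per_subject()]).
#'
#' @param x A `beta_dataset` (control conditions are subtracted first, famous
#'   name 1-back baseline), a subject x ROI x task array, or a list of
#'   ROI x task matrices (one per subject).
#' @param control Baseline condition label used when `x` is a `beta_dataset`.
#' @param method Ward convention passed to [ward_linkage()].
#' @param mds_dims Embedding dimension (default 2).
#' @return Object of class `netrsa`: list with per-subject RDM lists
#'   (`task_rdms`, `roi_rdms`), group RDMs (`group_task_rdm`,
#'   `group_roi_rdm`), linkage trees (`task_tree`, `roi_tree`), MDS embeddings
#'   (`task_mds`, `roi_mds`), `n_subjects`, label vectors and the matched
#'   call.
#' @examples
#' sim <- generate_subject_betas(synthetic_config(n_subjects = 6, seed = 2))
#' fit <- netrsa(sim$betas)
#' fit
#' cut_tree(fit$task_tree, k = 3)
#' @export
netrsa <- function(x, control = control_conditions()[1],
                   method = c("ward.D2", "ward.D"), mds_dims = 2) {
  method <- match.arg(method)
  if (inherits(x, "beta_dataset")) {
    x <- subtract_control(x, control = control)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    subjects <- dimnames(x)[[1]]
    x <- lapply(seq_len(dim(x)[1]),
                function(s) x[s, , , drop = TRUE])
    names(x) <- subjects
  }
  stopifnot(is.list(x), length(x) >= 1L, all(vapply(x, is.matrix, TRUE)))

  task_rdms <- lapply(x, correlation_distance_matrix, orientation = "tasks")
  roi_rdms <- lapply(x, correlation_distance_matrix, orientation = "rois")
  group_task <- average_rdms(task_rdms)
  group_roi <- average_rdms(roi_rdms)

  structure(list(task_rdms = task_rdms,
                 roi_rdms = roi_rdms,
                 group_task_rdm = group_task,
                 group_roi_rdm = group_roi,
                 task_tree = ward_linkage(group_task, method = method),
                 roi_tree = ward_linkage(group_roi, method = method),
                 task_mds = classical_mds(group_task, dims = mds_dims),
                 roi_mds = classical_mds(group_roi, dims = mds_dims),
                 n_subjects = length(x),
                 tasks = rownames(group_task),
                 rois = rownames(group_roi),
                 method = method,
                 call = match.call()),
            class = "netrsa")
}

#' @export
print.netrsa <- function(x, ...) {
  cat("Network-level RSA fit\n")
  cat(sprintf("  %d subjects, %d ROIs, %d tasks; Ward linkage (%s)\n",
              x$n_subjects, length(x$rois), length(x$tasks), x$method))
  cat(sprintf("  group task RDM: mean 1-r = %.3f; group ROI RDM: mean 1-r = %.3f\n",
              mean(x$group_task_rdm[lower.tri(x$group_task_rdm)]),
              mean(x$group_roi_rdm[lower.tri(x$group_roi_rdm)])))
  invisible(x)
}

#' Summarise a NetRSA fit
#'
#' Reports the cluster memberships obtained by cutting each tree at `k`,
#' variance explained by the leading MDS dimensions, and RDM dispersion.
#'
#' @param object A `netrsa` fit.
#' @param k_tasks,k_rois Numbers of clusters for the task and ROI trees
#'   (defaults 3).
#' @param ... Unused.
#' @return Object of class `summary.netrsa`.
#' @export
summary.netrsa <- function(object, k_tasks = 3, k_rois = 3, ...) {
  pos_eig_share <- function(mds) {
    pos <- pmax(mds$eig, 0)
    if (sum(pos) == 0) return(rep(0, ncol(mds$points)))
    pos[seq_len(ncol(mds$points))] / sum(pos)
  }
  structure(list(n_subjects = object$n_subjects,
                 task_clusters = cut_tree(object$task_tree, k_tasks),
                 roi_clusters = cut_tree(object$roi_tree, k_rois),
                 task_mds_var = pos_eig_share(object$task_mds),
                 roi_mds_var = pos_eig_share(object$roi_mds),
                 method = object$method),
            class = "summary.netrsa")
}

#' @export
print.summary.netrsa <- function(x, ...) {
  cat("NetRSA summary (", x$n_subjects, " subjects, Ward ", x$method, ")\n",
      sep = "")
  cat("\nTask clusters:\n")
  print(split(names(x$task_clusters), x$task_clusters))
  cat("ROI clusters:\n")
  print(split(names(x$roi_clusters), x$roi_clusters))
  cat(sprintf("MDS variance shares: tasks %s; ROIs %s\n",
              paste(sprintf("%.0f%%", 100 * x$task_mds_var), collapse = "/"),
              paste(sprintf("%.0f%%", 100 * x$roi_mds_var), collapse = "/")))
  invisible(x)
}

#' Plot a NetRSA fit
#'
#' Draws the task dendrogram, ROI dendrogram and the two MDS configurations.
#'
#' @param x A `netrsa` fit.
#' @param which Subset of `c("task_tree", "roi_tree", "task_mds", "roi_mds")`.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.netrsa <- function(x, which = c("task_tree", "roi_tree",
                                     "task_mds", "roi_mds"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (w in which) {
    if (w %in% c("task_tree", "roi_tree")) {
      plot(stats::as.dendrogram(x[[w]]),
           main = if (w == "task_tree") "Task taxonomy" else "Regional taxonomy",
           ylab = "Ward height", ...)
    } else {
      emb <- x[[w]]
      plot(emb$points, type = "n",
           main = if (w == "task_mds") "Task MDS" else "ROI MDS",
           xlab = "dim 1", ylab = "dim 2", ...)
      graphics::text(emb$points, labels = emb$labels, cex = 0.8)
    }
  }
  invisible(x)
}
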