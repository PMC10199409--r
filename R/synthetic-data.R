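# Seeded synthetic beta generator with planted task / regional structure.
# All user-visible randomness flows from config$seed through fixed stream
# offsets; the latent group-by-macro-domain tuning is drawn once from an
# internal fixed seed so the planted geometry is identical across user seeds.

.LATENT_SEED <- 20230701L

# stream-splitting rule: sub-seed s_k = (seed + 1000003 * k) mod (2^31 - 1)
stream_seed <- function(seed, stream) {
  as.integer((as.double(seed) + 1000003 * stream) %% 2147483647)
}

#' Configuration for the synthetic beta generator
#'
#' Describes a synthetic study: subjects, the ten-task battery with its
#' five-domain pairing and three macro-domains, two 1-back control conditions,
#' the 21-ROI network with a tripartite coordination partition, and the
#' generative scalars.
#'
#' Betas are generated as
#' `beta(s, roi, cond) = baseline_mean + signal_strength * latent(group(roi), cond) + N(0, noise_sd)`
#' for task conditions, and `baseline_mean + N(0, noise_sd)` for control
#' conditions (controls carry no task signal, so baseline subtraction removes
#' them exactly in the noiseless case). `latent` is constant across tasks of a
#' macro-domain up to within-domain jitter: the two tasks of each knowledge
#' domain share a domain-level jitter offset (scale `jitter`) plus a smaller
#' task-level offset (scale `jitter/2`), giving tight task pairs nested inside
#' macro-domain blocks.
#'
#' Subject noise is independent Gaussian across ROIs and conditions; no
#' cross-ROI noise covariance is modelled (configurable data would require a
#' covariance the study design does not constrain).
#'
#' @param n_subjects Number of subjects (default 24).
#' @param signal_strength Nonnegative between-cluster pattern separation
#'   (arbitrary beta units; default 1).
#' @param noise_sd Nonnegative subject-noise standard deviation (default 0.4).
#' @param baseline_mean Control-condition response level (default 0.5).
#' @param jitter Relative within-domain jitter; the effective jitter scale is
#'   `jitter * signal_strength` (default 0.1).
#' @param tasks Data frame as [person_knowledge_tasks()]: columns `task`,
#'   `domain`, `macro_domain`; exactly 10 tasks in 5 domains of 2.
#' @param controls Two control-condition labels; the first is the baseline.
#' @param roi_partition Named character vector ROI -> group with exactly three
#'   nonempty groups (default [default_roi_partition()]).
#' @param seed Integer root seed.
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg$n_subjects
#' @export
synthetic_config <- function(n_subjects = 24,
                             signal_strength = 1,
                             noise_sd = 0.4,
                             baseline_mean = 0.5,
                             jitter = 0.1,
                             tasks = person_knowledge_tasks(),
                             controls = control_conditions(),
                             roi_partition = default_roi_partition(),
                             seed = 1L) {
  stopifnot(is.data.frame(tasks),
            all(c("task", "domain", "macro_domain") %in% names(tasks)))
  if (nrow(tasks) != 10L || length(unique(tasks$domain)) != 5L ||
      any(table(tasks$domain) != 2L)) {
    stop("configuration error: need exactly 10 tasks forming 5 domain pairs",
         call. = FALSE)
  }
  if (length(controls) != 2L || anyDuplicated(controls)) {
    stop("configuration error: need exactly 2 distinct control labels",
         call. = FALSE)
  }
  tp <- table(tasks$macro_domain)
  if (length(tp) != 3L || any(tp == 0L)) {
    stop("configuration error: task partition must have exactly 3 nonempty macro-domains",
         call. = FALSE)
  }
  rp <- table(roi_partition)
  if (length(rp) != 3L || any(rp == 0L)) {
    stop("configuration error: ROI partition must have exactly 3 nonempty groups",
         call. = FALSE)
  }
  if (noise_sd < 0 || signal_strength < 0 || jitter < 0) {
    stop("configuration error: signal_strength, noise_sd and jitter must be nonnegative",
         call. = FALSE)
  }
  if (n_subjects < 1) stop("configuration error: n_subjects must be >= 1",
                           call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 signal_strength = signal_strength,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 jitter = jitter,
                 tasks = tasks,
                 controls = controls,
                 roi_partition = roi_partition,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic NetRSA study configuration\n")
  cat(sprintf("  %d subjects, %d ROIs (%d groups), %d tasks + %d controls\n",
              x$n_subjects, length(x$roi_partition),
              length(unique(x$roi_partition)), nrow(x$tasks),
              length(x$controls)))
  cat(sprintf("  signal %.3g, noise sd %.3g, baseline %.3g, jitter %.3g, seed %d\n",
              x$signal_strength, x$noise_sd, x$baseline_mean, x$jitter, x$seed))
  invisible(x)
}

# latent tuning matrix: ROI-group x condition, task columns only carry signal.
# Base values per (group, macro-domain) from the fixed internal seed; jitter
# offsets (domain-level + task-level) from the user's jitter stream.
latent_tuning_matrix <- function(config) {
  groups <- sort(unique(unname(config$roi_partition)))
  macros <- sort(unique(config$tasks$macro_domain))
  domains <- unique(config$tasks$domain)

  set.seed(.LATENT_SEED)
  base <- matrix(stats::rnorm(length(groups) * length(macros)),
                 nrow = length(groups),
                 dimnames = list(groups, macros))

  set.seed(stream_seed(config$seed, 1L))
  dom_jit <- matrix(stats::rnorm(length(groups) * length(domains)),
                    nrow = length(groups),
                    dimnames = list(groups, domains))
  task_jit <- matrix(stats::rnorm(length(groups) * nrow(config$tasks)),
                     nrow = length(groups),
                     dimnames = list(groups, config$tasks$task))

  latent <- matrix(0, nrow = length(groups), ncol = nrow(config$tasks),
                   dimnames = list(groups, config$tasks$task))
  for (i in seq_len(nrow(config$tasks))) {
    t_ <- config$tasks$task[i]
    latent[, t_] <- base[, config$tasks$macro_domain[i]] +
      config$jitter * (dom_jit[, config$tasks$domain[i]] + 0.5 * task_jit[, t_])
  }
  latent
}

#' Generate subject-level ROI betas with planted structure
#'
#' Simulates per-subject beta estimates for every ROI and condition under the
#' generative model documented in [synthetic_config()], and returns the ground
#' truth needed for recovery tests. Output is deterministic given the config
#' (bit-identical across calls with the same seed).
#'
#' @param config A [synthetic_config()].
#' @return List with elements:
#'   \describe{
#'     \item{betas}{`beta_dataset`: 3-D array `subject x ROI x condition`
#'       (tasks then controls) plus condition roles.}
#'     \item{truth}{`list` with `latent_tuning` (group x task, jitter
#'       included), `task_partition`, `roi_partition`, `seed`.}
#'   }
#' @examples
#' sim <- generate_subject_betas(synthetic_config(n_subjects = 4, seed = 7))
#' dim(sim$betas$betas)
#' @export
generate_subject_betas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  latent <- latent_tuning_matrix(config)
  rois <- names(config$roi_partition)
  conds <- c(config$tasks$task, config$controls)
  n <- config$n_subjects
  subjects <- sprintf("sub%02d", seq_len(n))

  signal <- matrix(0, nrow = length(rois), ncol = length(conds),
                   dimnames = list(rois, conds))
  signal[, config$tasks$task] <-
    config$signal_strength * latent[config$roi_partition[rois], , drop = FALSE]

  set.seed(stream_seed(config$seed, 2L))
  betas <- array(stats::rnorm(n * length(rois) * length(conds),
                              sd = config$noise_sd),
                 dim = c(n, length(rois), length(conds)),
                 dimnames = list(subjects, rois, conds))
  for (s in seq_len(n)) {
    betas[s, , ] <- betas[s, , ] + config$baseline_mean + signal
  }

  ds <- structure(list(betas = betas,
                       tasks = config$tasks$task,
                       controls = config$controls,
                       roi_info = roi_sphere_specs(validate = FALSE)),
                  class = "beta_dataset")
  task_partition <- structure(config$tasks$macro_domain,
                              names = config$tasks$task)
  truth <- list(latent_tuning = latent,
                task_partition = task_partition,
                roi_partition = config$roi_partition,
                seed = config$seed)
  list(betas = ds, truth = truth)
}

#' @export
print.beta_dataset <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf("beta_dataset: %d subjects x %d ROIs x %d conditions (%d tasks, %d controls)\n",
              d[1], d[2], d[3], length(x$tasks), length(x$controls)))
  invisible(x)
}

#' Tidy view of a beta dataset
#'
#' @param x A `beta_dataset`.
#' @param ... Unused.
#' @return Data frame with columns `subject`, `roi`, `hemisphere`, `condition`,
#'   `beta` (the tidy CSV interchange layout).
#' @export
as.data.frame.beta_dataset <- function(x, ...) {
  d <- dimnames(x$betas)
  df <- expand.grid(subject = d[[1]], roi = d[[2]], condition = d[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hemi <- x$roi_info$hemisphere[match(df$roi, x$roi_info$name)]
  df$hemisphere <- hemi
  df$beta <- as.vector(x$betas)
  df[, c("subject", "roi", "hemisphere", "condition", "beta")]
}

#' Read a tidy beta CSV back into a beta_dataset
#'
#' Inverse of `write.csv(as.data.frame(x))` for the tidy interchange layout.
#'
#' @param path CSV with columns `subject`, `roi`, `condition`, `beta`
#'   (hemisphere optional); condition roles are inferred from
#'   [person_knowledge_tasks()] and [control_conditions()] unless given.
#' @param tasks,controls Condition role vectors.
#' @return A `beta_dataset`.
#' @export
read_beta_csv <- function(path, tasks = person_knowledge_tasks()$task,
                          controls = control_conditions()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "roi", "condition", "beta") %in% names(df)))
  subjects <- unique(df$subject); rois <- unique(df$roi)
  conds <- unique(df$condition)
  arr <- array(NA_real_, dim = c(length(subjects), length(rois), length(conds)),
               dimnames = list(subjects, rois, conds))
  arr[cbind(match(df$subject, subjects), match(df$roi, rois),
            match(df$condition, conds))] <- df$beta
  if (anyNA(arr)) stop("incomplete beta table: missing subject/roi/condition cells",
                       call. = FALSE)
  structure(list(betas = arr,
                 tasks = intersect(conds, tasks),
                 controls = intersect(conds, controls),
                 roi_info = roi_sphere_specs(validate = FALSE)),
            class = "beta_dataset")
}

#' Synthetic voxel volumes with Gaussian blobs at the ROI peaks
#'
#' Builds per-condition beta volumes containing a Gaussian blob at each of the
#' 21 MNI peaks (amplitude = that ROI's beta for the condition) plus seeded
#' voxel noise, together with a localiser statistic map that is suprathreshold
#' at and around every peak. These volumes feed the ROI-extraction stage in
#' end-to-end tests.
#'
#' @param config A [synthetic_config()].
#' @param grid A [voxel_grid()] covering all peaks.
#' @param amplitudes ROI x condition amplitude matrix; defaults to the
#'   noiseless beta signal of subject 1 (baseline + planted signal).
#' @param blob_fwhm Blob full width at half maximum in mm (default 12).
#' @param voxel_noise_sd Voxel noise SD (default 0.05).
#' @param localizer_height Peak height of the localiser statistic blobs
#'   (default 10).
#' @return List: `beta_volumes` (named list of 3-D arrays, one per condition),
#'   `localizer` (3-D array), `grid`, `amplitudes`.
#' @export
generate_voxel_volume <- function(config, grid,
                                  amplitudes = NULL,
                                  blob_fwhm = 12,
                                  voxel_noise_sd = 0.05,
                                  localizer_height = 10) {
  stopifnot(inherits(config, "synthetic_config"), inherits(grid, "voxel_grid"))
  specs <- roi_sphere_specs(validate = FALSE)
  rois <- names(config$roi_partition)
  specs <- specs[match(rois, specs$name), , drop = FALSE]
  for (i in seq_len(nrow(specs))) {
    idx <- mni_to_voxel(grid, c(specs$x[i], specs$y[i], specs$z[i]))
    if (any(idx < 0) || any(idx >= grid$shape)) {
      stop("peak outside grid: ", specs$name[i], call. = FALSE)
    }
  }
  if (is.null(amplitudes)) {
    latent <- latent_tuning_matrix(config)
    conds <- c(config$tasks$task, config$controls)
    amplitudes <- matrix(config$baseline_mean, nrow = length(rois),
                         ncol = length(conds), dimnames = list(rois, conds))
    amplitudes[, config$tasks$task] <- amplitudes[, config$tasks$task] +
      config$signal_strength * latent[config$roi_partition[rois], , drop = FALSE]
  }
  stopifnot(identical(rownames(amplitudes), rois))

  sigma <- blob_fwhm / (2 * sqrt(2 * log(2)))
  centers_mm <- as.matrix(specs[, c("x", "y", "z")])
  coords <- voxel_center_coords(grid)              # nvox x 3, mm
  # per-peak Gaussian kernel over all voxels (nvox x npeak)
  kern <- vapply(seq_len(nrow(centers_mm)), function(i) {
    d2 <- rowSums((coords - matrix(centers_mm[i, ], nrow(coords), 3,
                                   byrow = TRUE))^2)
    exp(-d2 / (2 * sigma^2))
  }, numeric(nrow(coords)))

  set.seed(stream_seed(config$seed, 3L))
  conds <- colnames(amplitudes)
  beta_volumes <- lapply(conds, function(cond) {
    v <- kern %*% amplitudes[, cond]
    if (voxel_noise_sd > 0) v <- v + stats::rnorm(length(v), sd = voxel_noise_sd)
    array(v, dim = grid$shape)
  })
  names(beta_volumes) <- conds
  loc <- kern %*% rep(localizer_height, ncol(kern))
  if (voxel_noise_sd > 0) loc <- loc + stats::rnorm(length(loc), sd = voxel_noise_sd)
  list(beta_volumes = beta_volumes,
       localizer = array(loc, dim = grid$shape),
       grid = grid, amplitudes = amplitudes)
}

#' Synthetic per-subject reaction-time similarity matrices
#'
#' For each subject, RT feature vectors per task are built as
#' `rt_effect * scale(neural profile) + N(0, 1)` and pairwise correlated, so
#' `rt_effect = 0` gives RT similarity independent of neural task similarity
#' and large `rt_effect` reproduces the neural similarity structure.
#'
#' @param config A [synthetic_config()].
#' @param rt_effect Nonnegative coupling of RT structure to neural structure.
#' @param betas Optional `beta_dataset` to take neural profiles from; defaults
#'   to regenerating from `config`.
#' @return List of `n_subjects` task x task RT similarity matrices.
#' @export
generate_rt_table <- function(config, rt_effect = 0, betas = NULL) {
  stopifnot(inherits(config, "synthetic_config"), rt_effect >= 0)
  if (is.null(betas)) betas <- generate_subject_betas(config)$betas
  set.seed(stream_seed(config$seed, 4L))
  tasks <- betas$tasks
  lapply(seq_len(dim(betas$betas)[1]), function(s) {
    prof <- betas$betas[s, , tasks, drop = TRUE]         # ROI x task
    feats <- apply(prof, 2L, function(v) {
      z <- if (stats::sd(v) > 0) as.numeric(scale(v)) else v * 0
      rt_effect * z + stats::rnorm(length(v))
    })
    sim <- stats::cor(feats)
    dimnames(sim) <- list(tasks, tasks)
    sim
  })
}
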