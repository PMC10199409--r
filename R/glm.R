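# Minimal block-design GLM: canonical double-gamma HRF, boxcar convolution,
# ordinary least squares. No prewhitening, smoothing or normalisation.

#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical haemodynamic response function modelled as the
#' difference of two gamma densities: a positive response peaking around 5 s
#' and a later undershoot, with a peak:undershoot amplitude ratio.
#'
#' @param peak_delay Delay of response gamma (s, default 6).
#' @param undershoot_delay Delay of undershoot gamma (s, default 16).
#' @param peak_dispersion,undershoot_dispersion Dispersions (s, default 1).
#' @param ratio Peak:undershoot amplitude ratio (default 6).
#' @param length Kernel length (s, default 32).
#' @param dt Sampling step (s, default 0.1).
#' @return Object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     ratio = 6, length = 32, dt = 0.1) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, ratio, length, dt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all HRF parameters must be positive and finite", call. = FALSE)
  }
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, length = length, dt = dt),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities (shape = delay/dispersion,
#' scale = dispersion), undershoot scaled by `1/ratio`, sampled on
#' `seq(0, length, by = dt)` and normalised to unit peak.
#'
#' @param spec An [hrf_spec()].
#' @return Numeric kernel with attribute `times` (s).
#' @examples
#' h <- canonical_hrf(hrf_spec())
#' attr(h, "times")[which.max(h)]  # ~5 s
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$length, by = spec$dt)
  peak <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                        scale = spec$peak_dispersion)
  under <- stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                         scale = spec$undershoot_dispersion)
  h <- peak - under / spec$ratio
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

#' Build a block-design matrix
#'
#' Boxcar regressors per condition are built at the HRF's fine internal step,
#' convolved with the canonical HRF, and sampled at volume acquisition times
#' `(0, TR, 2 TR, ...)` per run. Motion parameters (if given) are appended
#' unconvolved, followed by one intercept column per run.
#'
#' @param events Data frame with columns `condition`, `onset` (s, within-run),
#'   `duration` (s, > 0) and `run` (1-based index).
#' @param TR Repetition time in seconds.
#' @param volumes_per_run Volumes acquired per run.
#' @param n_runs Number of runs; defaults to `max(events$run)`.
#' @param hrf An [hrf_spec()].
#' @param motion Optional per-volume motion table (`n_runs * volumes_per_run`
#'   rows, 6 columns).
#' @return Object of class `design_matrix`: the numeric matrix with labelled
#'   columns, plus attributes `TR`, `conditions`, `n_runs`.
#' @examples
#' ev <- data.frame(condition = "a", onset = 10, duration = 4, run = 1)
#' X <- build_design(ev, TR = 2.5, volumes_per_run = 209)
#' nrow(X)  # 209
#' @export
build_design <- function(events, TR, volumes_per_run, n_runs = NULL,
                         hrf = hrf_spec(), motion = NULL) {
  stopifnot(is.data.frame(events),
            all(c("condition", "onset", "duration", "run") %in% names(events)),
            TR > 0, volumes_per_run >= 1)
  if (any(events$onset < 0) || any(events$duration <= 0)) {
    stop("onsets must be nonnegative and durations positive", call. = FALSE)
  }
  run_length <- volumes_per_run * TR
  if (any(events$onset + events$duration > run_length)) {
    bad <- which(events$onset + events$duration > run_length)[1]
    stop(sprintf("event past run end: condition '%s' at %.1f s (+%.1f s) in run %d (run length %.1f s)",
                 events$condition[bad], events$onset[bad],
                 events$duration[bad], events$run[bad], run_length),
         call. = FALSE)
  }
  if (is.null(n_runs)) n_runs <- max(events$run)
  conds <- unique(events$condition)
  kernel <- canonical_hrf(hrf)
  dt <- hrf$dt
  fine_n <- ceiling(run_length / dt)
  vol_idx <- 1L + round((0:(volumes_per_run - 1L)) * TR / dt)

  task_cols <- matrix(0, nrow = n_runs * volumes_per_run, ncol = length(conds),
                      dimnames = list(NULL, conds))
  for (r in seq_len(n_runs)) {
    rows <- (r - 1L) * volumes_per_run + seq_len(volumes_per_run)
    ev_r <- events[events$run == r, , drop = FALSE]
    for (cond in conds) {
      box <- numeric(fine_n)
      ev_c <- ev_r[ev_r$condition == cond, , drop = FALSE]
      for (i in seq_len(nrow(ev_c))) {
        a <- floor(ev_c$onset[i] / dt) + 1L
        b <- min(ceiling((ev_c$onset[i] + ev_c$duration[i]) / dt), fine_n)
        box[a:b] <- 1
      }
      conv <- stats::convolve(box, rev(kernel), type = "open")[seq_len(fine_n)]
      task_cols[rows, cond] <- conv[vol_idx] * dt
    }
  }

  X <- task_cols
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(X) || ncol(motion) != 6L) {
      stop("motion table must have 6 columns and one row per volume",
           call. = FALSE)
    }
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  run_ic <- matrix(0, nrow = nrow(X), ncol = n_runs,
                   dimnames = list(NULL, paste0("run", seq_len(n_runs))))
  for (r in seq_len(n_runs)) {
    run_ic[(r - 1L) * volumes_per_run + seq_len(volumes_per_run), r] <- 1
  }
  X <- cbind(X, run_ic)
  if (anyDuplicated(colnames(X))) stop("duplicate design column labels",
                                       call. = FALSE)
  structure(X, class = c("design_matrix", class(X)), TR = TR,
            conditions = conds, n_runs = n_runs)
}

#' Ordinary least squares GLM fit
#'
#' Estimates `B` in `Y = X B + E` by OLS via the QR decomposition. Rank
#' deficiency is an error (naming the dependent columns), never a silent
#' drop.
#'
#' @param Y Time x units numeric matrix (or vector).
#' @param X Design matrix with labelled columns.
#' @return Regressor x unit beta matrix with regressor row names.
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  Xm <- unclass(X)
  stopifnot(nrow(Y) == nrow(Xm))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dep <- colnames(Xm)[qrX$pivot[(qrX$rank + 1L):ncol(Xm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  rownames(B) <- colnames(Xm)
  B
}
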