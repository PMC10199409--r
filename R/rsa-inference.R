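# Model-RDM construction, per-subject model fits, t-tests, power and the
# auxiliary univariate / control analyses.

lower_tri <- function(m) m[lower.tri(m)]

#' Partition model RDM
#'
#' Builds the binary model structure implied by a labelled partition:
#' dissimilarity 0 within a group, 1 between groups.
#'
#' @param labels Item labels (order of the model matrix).
#' @param partition Named vector label -> group covering every label.
#' @return An `rdm` (orientation `"model"`).
#' @export
partition_model <- function(labels, partition) {
  missing <- setdiff(labels, names(partition))
  if (length(missing) > 0L) {
    stop("partition does not cover label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- partition[labels]
  m <- outer(g, g, FUN = function(a, b) as.numeric(a != b))
  dimnames(m) <- list(labels, labels)
  new_rdm(m, orientation = "model", level = "model")
}

#' Per-subject fit of an RDM model
#'
#' For every subject, the Pearson correlation between the lower triangles
#' (diagonal excluded) of the observed RDM and the model RDM — one r per
#' subject, the quantity the group-level t-tests operate on. By convention,
#' observed dissimilarities are correlated with model dissimilarities
#' (0 within group, 1 between); correlating similarities instead would only
#' flip the sign of r.
#'
#' @param rdms List of subject-level `rdm` objects (or a single `rdm`).
#' @param model An `rdm`/matrix with the same labels.
#' @param model_id Identifier stored in the result.
#' @return Object of class `rsa_fit`: per-subject `r`, `mean_r`, `model_id`.
#' @export
fit_model_per_subject <- function(rdms, model, model_id = "model") {
  if (inherits(rdms, "rdm") || (is.matrix(rdms) && !is.list(rdms))) {
    rdms <- list(rdms)
  }
  mv <- lower_tri(unclass(model))
  if (stats::sd(mv) == 0) stop("model RDM has zero variance", call. = FALSE)
  r <- vapply(rdms, function(o) {
    if (!identical(rownames(o), rownames(model))) {
      stop("observed and model RDM labels differ", call. = FALSE)
    }
    ov <- lower_tri(unclass(o))
    if (stats::sd(ov) == 0) stop("observed RDM has zero variance",
                                 call. = FALSE)
    stats::cor(ov, mv)
  }, numeric(1))
  if (!is.null(names(rdms))) names(r) <- names(rdms)
  structure(list(r = r, mean_r = mean(r), model_id = model_id,
                 n = length(r)),
            class = "rsa_fit")
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf("RSA model fit '%s': mean r = %.3f over %d subject(s)\n",
              x$model_id, x$mean_r, x$n))
  invisible(x)
}

new_rsa_test <- function(t, df, p, kind, tails, n, estimate) {
  structure(list(statistic = t, df = df, p.value = p, kind = kind,
                 tails = tails, n = n, estimate = estimate),
            class = "rsa_test")
}

#' @export
print.rsa_test <- function(x, ...) {
  cat(sprintf("%s t-test (%s-tailed): t(%d) = %.3f, p = %.4g, mean = %.3f, n = %d\n",
              x$kind, x$tails, x$df, x$statistic, x$p.value, x$estimate, x$n))
  invisible(x)
}

#' One-sample t-test against a constant
#'
#' Standard one-sample t on the mean, `df = n - 1`. A sample with zero
#' variance raises an explicit degenerate-variance error rather than a
#' division by zero.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param mu Null value (default 0).
#' @param tails `"two"` (default) or `"one"` (alternative: mean > mu).
#' @return Object of class `rsa_test` (`statistic`, `df`, `p.value`, `kind`,
#'   `tails`, `n`, `estimate`).
#' @export
one_sample_t <- function(values, mu = 0, tails = c("two", "one")) {
  tails <- match.arg(tails)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate variance: all values identical; t is undefined",
         call. = FALSE)
  }
  alt <- if (tails == "two") "two.sided" else "greater"
  ht <- stats::t.test(values, mu = mu, alternative = alt)
  new_rsa_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
               kind = "one-sample", tails = tails, n = length(values),
               estimate = mean(values))
}

#' Paired t-test between two matched samples
#'
#' Implemented exactly as a one-sample t-test on the differences
#' (`paired_t(a, b)` and `one_sample_t(a - b)` agree to the last bit), with
#' `df = n - 1`.
#'
#' @param a,b Numeric vectors of equal length.
#' @inheritParams one_sample_t
#' @return Object of class `rsa_test` with `kind = "paired"`.
#' @export
paired_t <- function(a, b, tails = c("two", "one")) {
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  out <- one_sample_t(a - b, mu = 0, tails = tails)
  out$kind <- "paired"
  out
}

#' Group-level test of an RSA model fit
#'
#' One-sample t-test of the per-subject fit values against zero, on raw r by
#' default or on Fisher-z transformed values.
#'
#' @param fit An `rsa_fit`.
#' @param tails Passed to [one_sample_t()].
#' @param fisher_z Apply `atanh` before testing (default `FALSE`).
#' @return An `rsa_test`.
#' @export
test_model_fit <- function(fit, tails = c("two", "one"), fisher_z = FALSE) {
  stopifnot(inherits(fit, "rsa_fit"))
  v <- if (fisher_z) atanh(fit$r) else fit$r
  one_sample_t(v, mu = 0, tails = tails)
}

#' Contrast of biographical-knowledge grouping models
#'
#' Tests whether biographical knowledge is represented more like episodic
#' than like nominal knowledge: model A groups the biographical and episodic
#' tasks in one cluster, model B groups the biographical and nominal tasks,
#' all remaining tasks being singletons (between-group dissimilarity 1). Both
#' models are fitted per subject and compared with a paired t-test; a
#' positive t favours the biographical-with-episodic grouping.
#'
#' @param task_rdms List of subject-level task `rdm`s over the ten tasks.
#' @param tasks Task metadata as [person_knowledge_tasks()].
#' @param tails Passed to [paired_t()].
#' @return List: `fit_bio_episodic`, `fit_bio_nominal` (`rsa_fit`) and `test`
#'   (`rsa_test`).
#' @export
grouping_contrast <- function(task_rdms, tasks = person_knowledge_tasks(),
                              tails = c("two", "one")) {
  labels <- rownames(task_rdms[[1]])
  dom <- structure(tasks$domain, names = tasks$task)[labels]
  if (anyNA(dom)) stop("task RDM labels not covered by task metadata",
                       call. = FALSE)
  make_part <- function(paired_domains) {
    p <- ifelse(dom %in% paired_domains, "grouped", labels)
    names(p) <- labels
    p
  }
  model_a <- partition_model(labels, make_part(c("biographical", "episodic")))
  model_b <- partition_model(labels, make_part(c("biographical", "nominal")))
  fit_a <- fit_model_per_subject(task_rdms, model_a, "bio_with_episodic")
  fit_b <- fit_model_per_subject(task_rdms, model_b, "bio_with_nominal")
  list(fit_bio_episodic = fit_a,
       fit_bio_nominal = fit_b,
       test = paired_t(fit_a$r, fit_b$r, tails = tails))
}

#' Cross-modal cognitive-tuning stability
#'
#' Tests whether each region's tuning profile over the ten tasks is preserved
#' across stimulus modalities: for every subject, the Pearson correlation
#' between the (group-mean) face-experiment pattern and that subject's
#' name-experiment pattern is computed per region and averaged over the
#' region set; the per-subject averages are tested against zero.
#'
#' @param face_patterns Region x task matrix of group-mean model patterns.
#' @param name_patterns List of per-subject region x task matrices, or a
#'   subject x region x task array.
#' @param regions Region names to average over (default the extended set).
#' @param tails Passed to [one_sample_t()].
#' @return List: `fit` (`rsa_fit`, one mean r per subject) and `test`
#'   (`rsa_test`).
#' @export
tuning_stability <- function(face_patterns, name_patterns,
                             regions = region_set("extended"),
                             tails = c("two", "one")) {
  if (is.array(name_patterns) && length(dim(name_patterns)) == 3L) {
    name_patterns <- lapply(seq_len(dim(name_patterns)[1]),
                            function(s) name_patterns[s, , , drop = TRUE])
  }
  missing <- setdiff(regions, rownames(face_patterns))
  if (length(missing) > 0L) {
    stop("region(s) missing from face model patterns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(face_patterns), colnames(name_patterns[[1]]))) {
    stop("task labels differ between modalities", call. = FALSE)
  }
  r <- vapply(name_patterns, function(p) {
    miss <- setdiff(regions, rownames(p))
    if (length(miss) > 0L) {
      stop("region(s) missing from name patterns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    mean(vapply(regions, function(reg) {
      stats::cor(face_patterns[reg, ], p[reg, ])
    }, numeric(1)))
  }, numeric(1))
  fit <- structure(list(r = r, mean_r = mean(r),
                        model_id = "cross_modal_tuning", n = length(r)),
                   class = "rsa_fit")
  list(fit = fit, test = one_sample_t(r, tails = tails))
}

#' Reaction-time control analysis
#'
#' Correlates, within each subject, the lower triangles of the reaction-time
#' similarity matrix and the neural task similarity (1 minus the task RDM),
#' then tests the per-subject correlations against zero. Any number of
#' subjects with usable RT data is accepted; the n actually used is recorded
#' in the result.
#'
#' @param rt_similarity List of per-subject task x task RT similarity
#'   matrices.
#' @param task_rdms List of subject-level task `rdm`s (same order/labels).
#' @param tails Passed to [one_sample_t()].
#' @return List: `fit` (`rsa_fit`) and `test` (`rsa_test`).
#' @export
rt_control <- function(rt_similarity, task_rdms, tails = c("two", "one")) {
  stopifnot(length(rt_similarity) == length(task_rdms))
  r <- vapply(seq_along(task_rdms), function(s) {
    if (!identical(rownames(rt_similarity[[s]]), rownames(task_rdms[[s]]))) {
      stop("RT and neural task labels differ", call. = FALSE)
    }
    neural_sim <- 1 - lower_tri(unclass(task_rdms[[s]]))
    rt <- lower_tri(rt_similarity[[s]])
    if (stats::sd(rt) == 0 || stats::sd(neural_sim) == 0) {
      stop("zero variance in similarity vector", call. = FALSE)
    }
    stats::cor(rt, neural_sim)
  }, numeric(1))
  fit <- structure(list(r = r, mean_r = mean(r), model_id = "rt_control",
                        n = length(r)),
                   class = "rsa_fit")
  list(fit = fit, test = one_sample_t(r, tails = tails))
}

#' Regional domain-preference profiles
#'
#' For each ROI, the mean baseline-subtracted response per knowledge domain
#' (two tasks each) and each domain's percentage of the total (summed)
#' response across the five domains. When the summed response is not
#' positive, percentages are withheld (`NA`) and the ROI flagged.
#'
#' @param betas ROI x task matrix of baseline-subtracted responses.
#' @param tasks Task metadata as [person_knowledge_tasks()]; every task
#'   column must be mapped to a domain.
#' @return Data frame with columns `roi`, `domain`, `mean_response`,
#'   `percent`, `flagged`.
#' @export
domain_profile <- function(betas, tasks = person_knowledge_tasks()) {
  stopifnot(is.matrix(betas))
  unmapped <- setdiff(colnames(betas), tasks$task)
  if (length(unmapped) > 0L) {
    stop("task(s) not mapped to a domain: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  domains <- unique(tasks$domain)
  out <- do.call(rbind, lapply(rownames(betas), function(roi) {
    means <- vapply(domains, function(d) {
      mean(betas[roi, tasks$task[tasks$domain == d]])
    }, numeric(1))
    total <- sum(means)
    flagged <- !(total > 0)
    data.frame(roi = roi, domain = domains, mean_response = unname(means),
               percent = if (flagged) NA_real_ else unname(100 * means / total),
               flagged = flagged, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-ROI univariate response tests
#'
#' For each ROI, the subject-wise mean baseline-subtracted response averaged
#' over all tasks is tested against zero with a one-sample t-test; flags mark
#' ROIs significant at the Bonferroni-corrected threshold `alpha / m`.
#'
#' @param betas Subject x ROI x task array of baseline-subtracted responses.
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons for the correction; defaults to the number
#'   of ROIs tested.
#' @param tails Passed to [one_sample_t()].
#' @return Data frame: `roi`, `mean_response`, `t`, `df`, `p`, `significant`;
#'   the corrected threshold is attached as attribute `"threshold"`.
#' @export
roi_univariate_tests <- function(betas, alpha = 0.05, m = NULL,
                                 tails = c("two", "one")) {
  stopifnot(is.array(betas), length(dim(betas)) == 3L, dim(betas)[1] >= 2L)
  rois <- dimnames(betas)[[2]]
  if (is.null(m)) m <- length(rois)
  thr <- bonferroni_alpha(alpha, m)
  rows <- lapply(rois, function(roi) {
    v <- apply(betas[, roi, , drop = FALSE], 1L, mean)
    tt <- one_sample_t(v, tails = tails)
    data.frame(roi = roi, mean_response = tt$estimate, t = tt$statistic,
               df = tt$df, p = tt$p.value, significant = tt$p.value < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of comparisons, `m >= 1`.
#' @return `alpha / m` (e.g. 0.05 / 15 = 0.00333...).
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Minimal detectable effect size of a one-sample t-test
#'
#' Root-finds the smallest Cohen's d such that a one-sample t-test with `n`
#' subjects at level `alpha` reaches the target power, using the noncentral t
#' distribution (df `n - 1`, noncentrality `d * sqrt(n)`). `d_2dp` quotes the
#' result conservatively at two decimals: the smallest two-decimal effect
#' size whose power meets the target (rounding the root down would claim
#' sensitivity the design does not have).
#'
#' @param n Number of subjects.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails `"one"` (default; the convention under which a 24-subject
#'   design detects d of about half a standard deviation) or `"two"`.
#' @return Object of class `power_mde`: list with the exact root `d`, the
#'   conservative quote `d_2dp`, and the spec (`n`, `alpha`, `power`,
#'   `tails`).
#' @examples
#' power_mde(n = 24)$d_2dp  # 0.53
#' @export
power_mde <- function(n, alpha = 0.05, power = 0.80,
                      tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  df <- n - 1
  pw <- function(d) {
    ncp <- d * sqrt(n)
    if (tails == "one") {
      tc <- stats::qt(1 - alpha, df)
      1 - stats::pt(tc, df, ncp = ncp)
    } else {
      tc <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
    }
  }
  upper <- 10
  if (pw(upper) < power) stop("target power unattainable for d <= 10",
                              call. = FALSE)
  d <- stats::uniroot(function(x) pw(x) - power, c(1e-8, upper),
                      tol = 1e-10)$root
  d_2dp <- ceiling(d * 100 - 1e-9) / 100
  structure(list(d = d, d_2dp = d_2dp, n = n, alpha = alpha, power = power,
                 tails = tails),
            class = "power_mde")
}

#' @export
print.power_mde <- function(x, ...) {
  cat(sprintf("minimal detectable Cohen's d: %.4f (quoted %.2f) for n = %d, alpha = %g %s-tailed, power = %g\n",
              x$d, x$d_2dp, x$n, x$alpha, x$tails, x$power))
  invisible(x)
}

#' Spearman rank correlation between two mean-response vectors
#'
#' Standard rank correlation with midrank ties, used to check consistency of
#' average responses across matched items (e.g. across experiments).
#'
#' @param a,b Numeric vectors of matched items, length >= 3.
#' @return Spearman's rho.
#' @export
spearman_consistency <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must be matched", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 items", call. = FALSE)
  stats::cor(a, b, method = "spearman")
}
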