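tasks_meta <- person_knowledge_tasks()
macro_part <- structure(tasks_meta$macro_domain, names = tasks_meta$task)

test_that("partition models are binary with the expected block structure", {
  m <- partition_model(tasks_meta$task, macro_part)
  expect_equal(dim(m), c(10L, 10L))
  expect_true(all(m %in% c(0, 1)))
  # three diagonal blocks: within macro-domain 0, between 1
  for (i in tasks_meta$task) for (j in tasks_meta$task) {
    same <- macro_part[i] == macro_part[j]
    expect_equal(unname(m[i, j]), as.numeric(!same))
  }
  one <- partition_model(letters[1:4], structure(rep("g", 4), names = letters[1:4]))
  expect_true(all(one == 0))
  singles <- partition_model(letters[1:4], structure(letters[1:4], names = letters[1:4]))
  expect_true(all(singles[lower.tri(singles)] == 1))
  expect_error(partition_model(letters[1:5], structure(letters[1:4],
                                                       names = letters[1:4])),
               "does not cover")
})

test_that("per-subject model fits are lower-triangle Pearson correlations", {
  model <- partition_model(letters[1:6],
                           structure(rep(c("p", "q"), each = 3),
                                     names = letters[1:6]))
  obs_eq <- unclass(model)
  f1 <- fit_model_per_subject(list(obs_eq, obs_eq), model)
  expect_equal(unname(f1$r), c(1, 1))

  obs_neg <- 1.5 - 0.5 * unclass(model)
  dimnames(obs_neg) <- dimnames(model); diag(obs_neg) <- 0
  f2 <- fit_model_per_subject(obs_neg, model)
  expect_equal(unname(f2$r), -1)

  set.seed(6)
  obs <- random_rdm_matrix(6)
  dimnames(obs) <- dimnames(model)
  mod <- random_rdm_matrix(6)
  dimnames(mod) <- dimnames(model)
  f3 <- fit_model_per_subject(obs, mod)
  expect_equal(unname(f3$r),
               pearson_formula(obs[lower.tri(obs)], mod[lower.tri(mod)]),
               tolerance = 1e-12)

  # affine positive rescaling of the observed RDM leaves r unchanged
  f4 <- fit_model_per_subject(0.3 + 0.5 * obs, mod)
  expect_equal(f4$r, f3$r, tolerance = 1e-12)

  expect_error(fit_model_per_subject(obs, matrix(0, 6, 6,
                                                 dimnames = dimnames(mod))),
               "zero variance")
})

test_that("t-tests follow the textbook formulas with explicit degenerate errors", {
  expect_equal(one_sample_t(c(-1, 1))$statistic, 0)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "degenerate variance")
  expect_error(one_sample_t(c(2, 2, 2)), "degenerate variance")
  expect_error(one_sample_t(1), "at least 2")

  v <- c(0.5, 0.5, 0.7, 0.3)
  tt <- one_sample_t(v)
  t_ref <- mean(v) / (sd(v) / sqrt(4))          # textbook formula
  expect_equal(tt$statistic, t_ref, tolerance = 1e-12)
  expect_equal(tt$df, 3)
  expect_equal(tt$p.value, 2 * pt(-abs(t_ref), 3), tolerance = 1e-12)
  expect_equal(one_sample_t(v, tails = "one")$p.value, 1 - pt(t_ref, 3),
               tolerance = 1e-12)

  # paired test is exactly the one-sample test on differences
  set.seed(8)
  a <- rnorm(24); b <- rnorm(24)
  pa <- paired_t(a, b)
  os <- one_sample_t(a - b)
  expect_identical(pa$statistic, os$statistic)
  expect_identical(pa$p.value, os$p.value)
  expect_equal(pa$df, 23)
  expect_error(paired_t(1:3, 1:5), "equal length")
})

test_that("the biographical grouping contrast recovers planted directions", {
  make_rdms <- function(coupled_with, n = 16, noise = 0.08, seed = 1) {
    set.seed(seed)
    base <- partition_model(tasks_meta$task,
                            structure(ifelse(tasks_meta$domain %in%
                                               c("biographical", coupled_with),
                                             "grp", tasks_meta$task),
                                      names = tasks_meta$task))
    lapply(1:n, function(s) {
      e <- matrix(rnorm(100, sd = noise), 10)
      e <- (e + t(e)) / 2; diag(e) <- 0
      m <- pmin(pmax(unclass(base) * 0.8 + 0.6 + e, 0), 2)
      diag(m) <- 0
      dimnames(m) <- dimnames(base)
      netrsa:::new_rdm(m, orientation = "tasks", level = "subject")
    })
  }
  ge <- grouping_contrast(make_rdms("episodic"))
  expect_gt(ge$fit_bio_episodic$mean_r, ge$fit_bio_nominal$mean_r)
  expect_gt(ge$test$statistic, 0)

  gn <- grouping_contrast(make_rdms("nominal"))
  expect_lt(gn$test$statistic, 0)

  # null data: paired t centred on zero across simulations
  set.seed(9)
  ts <- replicate(60, {
    rdms <- lapply(1:8, function(s) {
      m <- random_rdm_matrix(10)
      dimnames(m) <- list(tasks_meta$task, tasks_meta$task)
      m
    })
    grouping_contrast(rdms)$test$statistic
  })
  expect_lt(abs(mean(ts)), 0.6)

  # recovery probability grows with SNR
  hit <- vapply(c(0.45, 0.2, 0.05), function(noise) {
    mean(vapply(1:20, function(s) {
      g <- grouping_contrast(make_rdms("episodic", n = 8, noise = noise,
                                       seed = s))
      g$test$statistic > 0
    }, TRUE))
  }, numeric(1))
  expect_true(all(diff(hit) >= 0))
  expect_equal(hit[3], 1)
})

test_that("cross-modal tuning stability behaves at its fixed points and under shared signal", {
  rois <- names(default_roi_partition())
  tasks <- tasks_meta$task
  set.seed(10)
  face <- matrix(rnorm(21 * 10), 21, dimnames = list(rois, tasks))

  # identical patterns: every per-region r is 1, so the t-test degenerates
  same <- lapply(1:5, function(s) face)
  expect_error(tuning_stability(face, same), "degenerate variance")

  # independent patterns: mean r near zero
  indep <- lapply(1:200, function(s)
    matrix(rnorm(21 * 10), 21, dimnames = list(rois, tasks)))
  st0 <- tuning_stability(face, indep)
  expect_lt(abs(st0$fit$mean_r), 0.03)

  # shared signal at a set SNR: mean r matches a Monte-Carlo oracle
  lambda <- 0.8
  gen_subject <- function() {
    p <- lambda * face + matrix(rnorm(21 * 10), 21)
    dimnames(p) <- dimnames(face)
    p
  }
  set.seed(11)
  shared <- lapply(1:300, function(s) gen_subject())
  st1 <- tuning_stability(face, shared)
  # oracle: direct Monte-Carlo of the per-region correlation
  set.seed(12)
  ref <- mean(replicate(300, {
    p <- gen_subject()
    mean(vapply(region_set("extended"), function(rg) cor(face[rg, ], p[rg, ]),
                numeric(1)))
  }))
  expect_equal(st1$fit$mean_r, ref, tolerance = 0.03)
  expect_gt(st1$test$statistic, 10)

  # core set uses only the six perceptual ROIs
  stc <- tuning_stability(face, shared, regions = region_set("core"))
  expect_equal(stc$fit$n, 300)
  expect_error(tuning_stability(face[1:5, ], shared), "missing")
})

test_that("domain profiles convert responses to percentages of the summed response", {
  rois <- c("r1", "r2")
  betas <- matrix(1, 2, 10, dimnames = list(rois, tasks_meta$task))
  dp <- domain_profile(betas)
  expect_true(all(abs(dp$percent - 20) < 1e-12))
  expect_equal(sum(dp$percent[dp$roi == "r1"]), 100)

  betas2 <- betas
  betas2["r1", tasks_meta$task[tasks_meta$domain == "nominal"]] <- 4
  dp2 <- domain_profile(betas2)
  nom <- dp2$percent[dp2$roi == "r1" & dp2$domain == "nominal"]
  expect_equal(nom, 50)
  expect_true(all(abs(dp2$percent[dp2$roi == "r1" & dp2$domain != "nominal"] -
                        12.5) < 1e-12))

  set.seed(13)
  betas3 <- matrix(runif(20, 0.2, 2), 2, 10,
                   dimnames = list(rois, tasks_meta$task))
  dp3 <- domain_profile(betas3)
  for (d in unique(tasks_meta$domain)) {
    ref_mean <- mean(betas3["r2", tasks_meta$task[tasks_meta$domain == d]])
    row <- dp3[dp3$roi == "r2" & dp3$domain == d, ]
    expect_equal(row$mean_response, ref_mean, tolerance = 1e-12)
  }
  expect_equal(tapply(dp3$percent, dp3$roi, sum), c(r1 = 100, r2 = 100),
               tolerance = 1e-9, ignore_attr = TRUE)

  # nonpositive summed response: percentages withheld and flagged
  betas4 <- betas; betas4["r1", ] <- -1
  dp4 <- domain_profile(betas4)
  expect_true(all(is.na(dp4$percent[dp4$roi == "r1"])))
  expect_true(all(dp4$flagged[dp4$roi == "r1"]))
  expect_error(domain_profile(cbind(betas, extra = 1)), "not mapped")
})

test_that("univariate ROI tests flag planted effects at the Bonferroni threshold", {
  expect_equal(bonferroni_alpha(0.05, 15), 0.05 / 15)
  expect_equal(round(bonferroni_alpha(0.05, 15), 4), 0.0033)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")

  set.seed(14)
  n <- 24; rois <- paste0("roi", 1:6)
  arr <- array(rnorm(n * 6 * 10, sd = 0.3),
               dim = c(n, 6, 10),
               dimnames = list(NULL, rois, tasks_meta$task))
  arr[, "roi3", ] <- arr[, "roi3", ] + 1      # strong planted effect
  res <- roi_univariate_tests(arr, m = 15)
  expect_equal(attr(res, "threshold"), 0.05 / 15)
  expect_identical(res$roi[res$significant], "roi3")
  expect_equal(res$df, rep(23, 6))
})

test_that("minimal detectable effect size is monotone and matches printed sensitivity", {
  p <- power_mde(24)
  expect_equal(p$d, 0.5232, tolerance = 1e-3)
  expect_equal(p$d_2dp, 0.53)
  # d strictly decreasing in n
  ds <- vapply(5:100, function(n) power_mde(n)$d, numeric(1))
  expect_true(all(diff(ds) < 0))
  # two-tailed convention requires a larger effect
  expect_gt(power_mde(24, tails = "two")$d, p$d)
  expect_error(power_mde(3, alpha = 1e-12, power = 0.999999), "unattainable")
})

test_that("Spearman consistency is rank-then-Pearson with midrank ties", {
  expect_equal(spearman_consistency(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_consistency(1:5, rev(1:5)), -1)
  set.seed(15)
  a <- c(3, 1, 4, 1, 5, 9, 2, 6)   # ties present
  b <- rnorm(8)
  expect_equal(spearman_consistency(a, b),
               pearson_formula(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(spearman_consistency(1:2, 1:2), "at least 3")
})
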