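# End-to-end orchestration: simulate -> adjust -> RDMs -> clustering ->
# inference -> serialized artefacts -> report. Each stage only consumes the
# previous stage's artefacts held in the bundle, and every output file is
# stamped with the config hash and seed.

# small FNV-1a hash over the serialized config; stable for identical configs
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' before any stage runs. May be given as an R list or a YAML file path with
#' the same keys.
#'
#' @param synthetic List of arguments for [synthetic_config()] (the `seed`
#'   there is overridden by the pipeline `seed`).
#' @param seed Root seed controlling all randomness.
#' @param tails Tail convention for reported tests (`"two"` default).
#' @param correction_m Bonferroni comparison count for the univariate tests
#'   (default 15, the extended-system ROI count).
#' @param fisher_z Test model fits on Fisher-z values (default `FALSE`).
#' @param k_tasks,k_rois Cluster counts for reporting (default 3).
#' @param rt_effect RT-neural coupling for the simulated RT control; `NULL`
#'   skips the RT section.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), seed = 1L, tails = "two",
                            correction_m = 15, fisher_z = FALSE,
                            k_tasks = 3, k_rois = 3, rt_effect = 0) {
  cfg <- list(synthetic = synthetic, seed = as.integer(seed), tails = tails,
              fisher_z = isTRUE(fisher_z), correction_m = correction_m,
              k_tasks = k_tasks, k_rois = k_rois, rt_effect = rt_effect)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  allowed <- c("synthetic", "seed", "tails", "correction_m", "fisher_z",
               "k_tasks", "k_rois", "rt_effect")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  syn_allowed <- setdiff(names(formals(synthetic_config)), "")
  unknown_syn <- setdiff(names(cfg$synthetic), syn_allowed)
  if (length(unknown_syn) > 0L) {
    stop("unknown synthetic configuration key(s): ",
         paste(unknown_syn, collapse = ", "), call. = FALSE)
  }
  if (!cfg$tails %in% c("two", "one")) {
    stop("tails must be 'two' or 'one'", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [pipeline_config()] keys.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  validate_pipeline_config(utils::modifyList(unclass(defaults), cfg))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full NetRSA pipeline on a synthetic study
#'
#' Simulates a study, subtracts the control baseline, fits the NetRSA
#' ([netrsa()]), runs the inferential analyses (macro-domain model,
#' biographical grouping contrast, tripartite regional model, cross-modal
#' tuning stability for extended and core sets, per-ROI univariate tests,
#' domain preferences, RT control, design power) and, if `out_dir` is given,
#' serializes every artefact (tidy betas, RDMs, Newick trees, MDS
#' coordinates, test table, JSON results, report).
#'
#' The "face experiment" patterns used as empirical cross-modal model are an
#' independent synthetic replicate (same planted structure, shifted seed)
#' averaged across its subjects, mirroring how an empirical model from a
#' separate cohort enters the analysis.
#'
#' @param config A [pipeline_config()], a list of its keys, or a YAML path.
#' @param out_dir Optional output directory (created if missing).
#' @return Object of class `netrsa_bundle` (invisibly when writing): all
#'   stage results plus `hash` and `seed` stamps.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(
      utils::modifyList(unclass(pipeline_config()), config))
  }
  hash <- config_hash(config)

  syn_args <- utils::modifyList(config$synthetic, list(seed = config$seed))
  scfg <- run_stage("simulate", do.call(synthetic_config, syn_args))
  sim <- run_stage("simulate", generate_subject_betas(scfg))

  adjusted <- run_stage("adjust", subtract_control(sim$betas))
  fit <- run_stage("rdm", netrsa(sim$betas))

  # independent replicate standing in for the face-experiment group means
  face_cfg <- run_stage("infer", do.call(
    synthetic_config, utils::modifyList(syn_args,
                                        list(seed = stream_seed(config$seed, 11L),
                                             n_subjects = 20L))))
  face_sim <- run_stage("infer", generate_subject_betas(face_cfg))
  face_adj <- run_stage("infer", subtract_control(face_sim$betas))
  face_mean <- run_stage("infer", apply(face_adj, c(2L, 3L), mean))

  tasks_meta <- scfg$tasks
  macro_model <- partition_model(fit$tasks,
                                 structure(tasks_meta$macro_domain,
                                           names = tasks_meta$task))
  macro_fit <- run_stage("infer",
                         fit_model_per_subject(fit$task_rdms, macro_model,
                                               "macro_domain"))
  macro_test <- test_model_fit(macro_fit, tails = config$tails,
                               fisher_z = config$fisher_z)

  contrast <- run_stage("infer", grouping_contrast(fit$task_rdms, tasks_meta,
                                                   tails = config$tails))

  extended <- region_set("extended")
  ext_rdms <- run_stage("infer", lapply(
    seq_len(dim(adjusted)[1]),
    function(s) correlation_distance_matrix(adjusted[s, extended, ],
                                            orientation = "rois")))
  iec_model <- partition_model(extended, iec_partition())
  iec_fit <- run_stage("infer",
                       fit_model_per_subject(ext_rdms, iec_model, "iec"))
  iec_test <- test_model_fit(iec_fit, tails = config$tails,
                             fisher_z = config$fisher_z)
  face_roi_rdm <- run_stage("infer",
                            correlation_distance_matrix(face_mean[extended, ],
                                                        orientation = "rois"))
  face_roi_fit <- run_stage("infer",
                            fit_model_per_subject(ext_rdms, face_roi_rdm,
                                                  "empirical_face"))
  iec_vs_empirical <- paired_t(face_roi_fit$r, iec_fit$r,
                               tails = config$tails)

  name_patterns <- lapply(seq_len(dim(adjusted)[1]),
                          function(s) adjusted[s, , , drop = TRUE])
  stab_ext <- run_stage("infer", tuning_stability(face_mean, name_patterns,
                                                  regions = region_set("extended"),
                                                  tails = config$tails))
  stab_core <- run_stage("infer", tuning_stability(face_mean, name_patterns,
                                                   regions = region_set("core"),
                                                   tails = config$tails))

  uni <- run_stage("infer", roi_univariate_tests(adjusted,
                                                 m = config$correction_m,
                                                 tails = config$tails))
  profiles <- run_stage("infer",
                        domain_profile(apply(adjusted, c(2L, 3L), mean),
                                       tasks_meta))

  rt <- NULL
  if (!is.null(config$rt_effect)) {
    rt_sims <- run_stage("infer", generate_rt_table(scfg, config$rt_effect,
                                                    betas = sim$betas))
    rt <- run_stage("infer", rt_control(rt_sims, fit$task_rdms,
                                        tails = config$tails))
  }

  power <- power_mde(n = scfg$n_subjects)

  bundle <- structure(list(config = config, seed = config$seed, hash = hash,
                           synthetic = scfg, truth = sim$truth,
                           betas = sim$betas, adjusted = adjusted, fit = fit,
                           tests = list(macro_domain = list(fit = macro_fit,
                                                            test = macro_test),
                                        grouping = contrast,
                                        iec = list(fit = iec_fit,
                                                   test = iec_test),
                                        empirical_face = list(fit = face_roi_fit,
                                                              test = iec_vs_empirical),
                                        tuning_extended = stab_ext,
                                        tuning_core = stab_core,
                                        rt_control = rt),
                           univariate = uni, profiles = profiles,
                           power = power),
                      class = "netrsa_bundle")
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    write_report(bundle, file.path(out_dir, "report.md"))
  }
  bundle
}

#' @export
print.netrsa_bundle <- function(x, ...) {
  cat(sprintf("NetRSA pipeline bundle (seed %d, config %s)\n", x$seed, x$hash))
  print(x$fit)
  invisible(x)
}

write_rdm_csv <- function(rdm, path) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
}

#' Serialize a pipeline bundle's artefacts
#'
#' Writes tidy betas, group RDMs (CSV), Newick trees, MDS coordinates, the
#' univariate and domain-preference tables, and a JSON summary of all
#' inferential tests. File contents depend only on the bundle, so reruns
#' with the same seed are byte-identical.
#'
#' @param bundle A `netrsa_bundle`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(config_hash = bundle$hash, seed = bundle$seed)
  utils::write.csv(as.data.frame(bundle$betas),
                   file.path(out_dir, "betas.csv"), row.names = FALSE)
  write_rdm_csv(bundle$fit$group_task_rdm,
                file.path(out_dir, "group_task_rdm.csv"))
  write_rdm_csv(bundle$fit$group_roi_rdm,
                file.path(out_dir, "group_roi_rdm.csv"))
  writeLines(tree_to_newick(bundle$fit$task_tree),
             file.path(out_dir, "task_tree.nwk"))
  writeLines(tree_to_newick(bundle$fit$roi_tree),
             file.path(out_dir, "roi_tree.nwk"))
  utils::write.csv(data.frame(label = bundle$fit$task_mds$labels,
                              bundle$fit$task_mds$points),
                   file.path(out_dir, "task_mds.csv"), row.names = FALSE)
  utils::write.csv(data.frame(label = bundle$fit$roi_mds$labels,
                              bundle$fit$roi_mds$points),
                   file.path(out_dir, "roi_mds.csv"), row.names = FALSE)
  utils::write.csv(bundle$univariate,
                   file.path(out_dir, "roi_univariate.csv"), row.names = FALSE)
  utils::write.csv(bundle$profiles,
                   file.path(out_dir, "domain_profiles.csv"), row.names = FALSE)

  test_json <- lapply(collect_tests(bundle), function(x) {
    list(model = x$model, r_per_subject = x$r, mean_r = x$mean_r,
         t = x$t, df = x$df, p = x$p)
  })
  jsonlite::write_json(list(stamp = as.list(stamp), tests = test_json),
                       file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(tests_table(bundle), file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  for (w in c("task_tree", "roi_tree", "task_mds", "roi_mds")) {
    grDevices::png(file.path(out_dir, paste0(w, ".png")),
                   width = 900, height = 700, res = 120)
    plot(bundle$fit, which = w)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

collect_tests <- function(bundle) {
  tl <- bundle$tests
  out <- list()
  add <- function(name, fit, test) {
    out[[name]] <<- list(model = name,
                         r = if (is.null(fit)) NULL else unname(fit$r),
                         mean_r = if (is.null(fit)) NA_real_ else fit$mean_r,
                         t = test$statistic, df = test$df, p = test$p.value)
  }
  add("macro_domain", tl$macro_domain$fit, tl$macro_domain$test)
  add("bio_episodic_vs_bio_nominal", tl$grouping$fit_bio_episodic,
      tl$grouping$test)
  add("iec_regional", tl$iec$fit, tl$iec$test)
  add("empirical_vs_iec", tl$empirical_face$fit, tl$empirical_face$test)
  add("tuning_extended", tl$tuning_extended$fit, tl$tuning_extended$test)
  add("tuning_core", tl$tuning_core$fit, tl$tuning_core$test)
  if (!is.null(tl$rt_control)) {
    add("rt_control", tl$rt_control$fit, tl$rt_control$test)
  }
  out
}

tests_table <- function(bundle) {
  rows <- lapply(collect_tests(bundle), function(x) {
    data.frame(model = x$model, mean_r = x$mean_r, t = x$t, df = x$df,
               p = x$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a Markdown report from a pipeline bundle
#'
#' The report is regenerated from the numbers stored in the bundle only (no
#' recomputation) and contains the config stamp, the univariate ROI table,
#' domain preferences, both taxonomies (cluster memberships and Newick
#' strings), the MDS coordinates and all model-comparison tests; the RT
#' section is omitted when absent. Identical bundles render identical
#' reports.
#'
#' @param bundle A `netrsa_bundle`.
#' @param path Output `.md` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  fmt_test <- function(name, x) {
    sprintf("- %s: mean r = %.3f, t(%d) = %.2f, p = %.4g", name,
            x$mean_r, x$df, x$t, x$p)
  }
  tl <- collect_tests(bundle)
  smry <- summary(bundle$fit, k_tasks = bundle$config$k_tasks,
                  k_rois = bundle$config$k_rois)
  lines <- c(
    "# NetRSA pipeline report",
    "",
    sprintf("Config hash: `%s`; seed: %d; subjects: %d.",
            bundle$hash, bundle$seed, bundle$fit$n_subjects),
    "",
    "## Design power",
    "",
    sprintf("Minimal detectable Cohen's d (n = %d, alpha = %g, %s-tailed, power = %g): %.2f.",
            bundle$power$n, bundle$power$alpha, bundle$power$tails,
            bundle$power$power, bundle$power$d_2dp),
    "",
    "## Univariate ROI responses (vs control baseline)",
    "",
    sprintf("Bonferroni-corrected threshold: p < %.4g.",
            attr(bundle$univariate, "threshold")),
    "",
    paste(utils::capture.output(print(bundle$univariate, digits = 3)),
          collapse = "\n"),
    "",
    "## Domain preferences",
    "",
    paste(utils::capture.output(print(head(bundle$profiles, 15), digits = 3)),
          collapse = "\n"),
    "",
    "## Cognitive taxonomy (task dendrogram)",
    "",
    sprintf("Clusters at k = %d: %s", bundle$config$k_tasks,
            paste(vapply(split(names(smry$task_clusters), smry$task_clusters),
                         paste, "", collapse = ", "), collapse = " | ")),
    "",
    sprintf("Newick: `%s`", tree_to_newick(bundle$fit$task_tree)),
    "",
    "### Task MDS (2-D)",
    "",
    paste(utils::capture.output(print(round(bundle$fit$task_mds$points, 3))),
          collapse = "\n"),
    "",
    "## Regional taxonomy (ROI dendrogram)",
    "",
    sprintf("Clusters at k = %d: %s", bundle$config$k_rois,
            paste(vapply(split(names(smry$roi_clusters), smry$roi_clusters),
                         paste, "", collapse = ", "), collapse = " | ")),
    "",
    sprintf("Newick: `%s`", tree_to_newick(bundle$fit$roi_tree)),
    "",
    "### ROI MDS (2-D)",
    "",
    paste(utils::capture.output(print(round(bundle$fit$roi_mds$points, 3))),
          collapse = "\n"),
    "",
    "## Model comparisons",
    "",
    vapply(names(tl), function(nm) fmt_test(nm, tl[[nm]]), "")
  )
  writeLines(lines, path)
  invisible(path)
}
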