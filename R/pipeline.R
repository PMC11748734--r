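#' Pipeline configuration with defaults
#'
#' Defaults reproduce the analysis settings used throughout the package:
#' 256 density sample points, sparsity range 0.08-0.40 in steps of 0.02
#' (17 thresholds), 100 rewired nulls, 1000 shuffles for the
#' variance-component null, 10000 for location tests, FDR level q = 0.05.
#' Unknown keys in a config file are rejected rather than silently
#' ignored.
#'
#' @param path optional YAML file whose keys override the defaults; nested
#'   keys under `simulation` override [simulation_config()] arguments.
#' @param overrides optional named list applied on top of the file.
#' @return A `morph_pipeline_config` list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  defaults <- list(
    stages = list(topology = TRUE, reliability = TRUE, association = TRUE,
                  group_comparison = TRUE),
    atlas = list(n_gyral_per_hemi = 29, n_sulcal_per_hemi = 31,
                 n_ambiguous_per_hemi = 14),
    simulation = as.list(unclass(simulation_config())),
    n_points = 256,
    sparsity_min = 0.08, sparsity_max = 0.40, sparsity_step = 0.02,
    n_null = 100,
    n_perm_location = 10000,
    n_perm_variance = 1000,
    n_behavior_items = 6,
    V_true = 0.3,
    q = 0.05,
    seed = 1L
  )
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  if (!is.null(overrides)) user <- utils::modifyList(user, overrides)
  merge_checked <- function(base, new, prefix = "") {
    unknown <- setdiff(names(new), names(base))
    if (length(unknown) > 0) {
      stop("unknown config key: ", prefix, unknown[1])
    }
    for (k in names(new)) {
      if (is.list(base[[k]]) && is.list(new[[k]])) {
        base[[k]] <- merge_checked(base[[k]], new[[k]],
                                   prefix = paste0(prefix, k, "."))
      } else {
        if (is.list(new[[k]]) != is.list(base[[k]])) {
          stop("type mismatch for config key: ", prefix, k)
        }
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  cfg <- merge_checked(defaults, user)
  cfg$sparsities <- seq(cfg$sparsity_min, cfg$sparsity_max,
                        by = cfg$sparsity_step)
  class(cfg) <- "morph_pipeline_config"
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> build networks -> subcomponent contrasts ->
#' small-world topology -> test-retest reliability (when sessions >= 2) ->
#' behavioural variance component -> group comparison (when patients are
#' present), writing stage outputs as TSV and a reproducibility manifest
#' as YAML. One master seed deterministically spawns per-stage seeds, so a
#' stage can be reproduced in isolation.
#'
#' @param config a `morph_pipeline_config` from [load_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stage results and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("morphnet_run_")) {
  stopifnot(inherits(config, "morph_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 9)
  names(seeds) <- c("simulate", "topology", "topology_ss", "contrast2",
                    "contrast3", "reliability", "behavior", "association",
                    "group")
  log_stage <- function(...) message(sprintf("[morphnet] %s", sprintf(...)))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)

  log_stage("simulate: %d subjects x %d sessions",
            config$simulation$n_subjects, config$simulation$n_sessions)
  atlas <- make_default_atlas(config$atlas$n_gyral_per_hemi,
                              config$atlas$n_sulcal_per_hemi,
                              config$atlas$n_ambiguous_per_hemi)
  sim_cfg <- do.call(simulation_config,
                     utils::modifyList(config$simulation,
                                       list(seed = seeds[["simulate"]])))
  cohort <- simulate_cohort(sim_cfg, atlas)

  log_stage("build networks (%d density points)", config$n_points)
  networks <- build_cohort_networks(cohort, n_points = config$n_points)
  session1 <- lapply(networks, `[[`, 1)

  results <- list(cohort = cohort, networks = networks)

  # per-subject subcomponent means + paired contrasts
  block_means <- t(vapply(session1, function(net) {
    sub <- extract_subcomponents(net)
    c(gg = mean_similarity(sub$gg), ss = mean_similarity(sub$ss),
      gs = mean_similarity(sub$gs, square = FALSE))
  }, numeric(3)))
  utils::write.table(data.frame(subject = rownames(block_means), block_means),
                     file.path(out_dir, "subcomponent_means.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  contrasts <- list(
    gg_vs_ss = paired_subcomponent_test(block_means[, "gg"], block_means[, "ss"],
                                        n_perm = config$n_perm_location,
                                        seed = seeds[["topology"]]),
    gg_vs_gs = paired_subcomponent_test(block_means[, "gg"], block_means[, "gs"],
                                        n_perm = config$n_perm_location,
                                        seed = seeds[["contrast2"]]),
    ss_vs_gs = paired_subcomponent_test(block_means[, "ss"], block_means[, "gs"],
                                        n_perm = config$n_perm_location,
                                        seed = seeds[["contrast3"]])
  )
  results$subcomponents <- list(means = block_means, tests = contrasts)

  if (isTRUE(config$stages$topology)) {
    log_stage("topology: sparsity sweep on cohort-mean G-G and S-S networks")
    mean_w <- function(block) {
      mats <- lapply(session1, function(net) extract_subcomponents(net)[[block]])
      Reduce(`+`, mats) / length(mats)
    }
    results$topology <- list(
      gg = sparsity_sweep(mean_w("gg"), config$sparsities,
                          n_null = config$n_null, seed = seeds[["topology"]]),
      ss = sparsity_sweep(mean_w("ss"), config$sparsities,
                          n_null = config$n_null, seed = seeds[["topology_ss"]])
    )
    for (b in c("gg", "ss")) {
      utils::write.table(results$topology[[b]]$curves,
                         file.path(out_dir, sprintf("smallworld_%s.tsv", b)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (any(results$topology[[b]]$curves$disconnected)) {
        note(sprintf("disconnected graphs at some sparsities (%s block)", b))
      }
    }
  }

  if (isTRUE(config$stages$reliability) && config$simulation$n_sessions >= 2) {
    log_stage("reliability: edgewise ICC (sessions 1-2)")
    results$reliability <- list(
      gg = edgewise_icc(networks, "gg", sessions = 1:2),
      ss = edgewise_icc(networks, "ss", sessions = 1:2)
    )
    results$reliability$comparison <- compare_reliability(
      results$reliability$gg$icc, results$reliability$ss$icc,
      n_perm = config$n_perm_location, seed = seeds[["reliability"]])
    icc_tab <- rbind(
      data.frame(block = "gg", icc = results$reliability$gg$icc,
                 bin = results$reliability$gg$bin),
      data.frame(block = "ss", icc = results$reliability$ss$icc,
                 bin = results$reliability$ss$bin))
    utils::write.table(icc_tab, file.path(out_dir, "edgewise_icc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (isTRUE(config$stages$association)) {
    log_stage("association: variance component model (%d shuffles)",
              config$n_perm_variance)
    M <- subject_similarity_matrix(session1, block = "gsgs")
    Y <- simulate_behavior(M, config$n_behavior_items, config$V_true,
                           seed = seeds[["behavior"]])
    results$association <- permutation_pvalue_V(
      Y, M, n_perm = config$n_perm_variance, seed = seeds[["association"]])
    if (results$association$estimate$n_clamped > 0) {
      note(sprintf("%d variance component(s) clamped at zero",
                   results$association$estimate$n_clamped))
    }
    utils::write.table(
      data.frame(V = results$association$V, p = results$association$p),
      file.path(out_dir, "variance_explained.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (isTRUE(config$stages$group_comparison) &&
      config$simulation$n_patients > 0) {
    log_stage("group comparison: S-S mean similarity, age/sex adjusted")
    results$group <- permutation_group_test(
      block_means[, "ss"],
      factor(cohort$subjects$group, levels = c("patient", "control")),
      covariates = cohort$subjects[, c("age", "sex")],
      n_perm = config$n_perm_location, seed = seeds[["group"]])
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("morphnet")),
    master_seed = config$seed,
    stage_seeds = as.list(seeds),
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("sparsities"))],
    outputs = as.list(tools::md5sum(outputs)),
    warnings = warnings_log
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  results$out_dir <- out_dir
  log_stage("done: %d output files in %s", length(outputs) + 1L, out_dir)
  invisible(results)
}
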