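#' Default end-to-end pipeline configuration
#'
#' All analysis defaults follow the study conditions: functional density
#' 0.20, NBS thresholds 2.0-4.0 (step 0.1) with 5000 permutations and
#' intensity sizing, 1000 bootstrap replications, ball-and-stick
#' diffusivities 1.7e-3 / 3.0e-3 mm^2/s.
#'
#' @param seed integer master seed; every stage derives its seed from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(),                       # synth_config() overrides
    commit = list(grid_shape = c(4L, 4L, 2L), n_streamlines = 30L),
    functional = list(density = 0.20),
    nbs = list(thresholds = seq(2.0, 4.0, by = 0.1), n_perm = 5000L,
               size_measure = "intensity", alpha = 0.05,
               contrast = "patient<control", component_threshold = 3.0),
    stats = list(n_boot = 1000L)
  )
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains the stages end to end: (1) simulate a cohort; (2) demonstrate
#' streamline-weight fitting on a toy tractogram and assemble its
#' structural connectome; (3) prevalence-filter structural matrices and
#' absolutise/density-threshold functional ones; (4) compute the five
#' global graph metrics per subject and modality; (5) run network-based
#' statistics on the structural matrices; (6) group statistics: robust
#' ANCOVA with BH correction over the global metrics, subnetwork
#' disruption/deviation indices with Cohen's d, and the moderation model
#' of cognition on the scored patients. Outputs are written under
#' `out_dir` together with a JSON run manifest (config, seeds, file
#' hashes).
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   a path to a YAML file with the same structure.
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when not `NULL`.
#' @return The run manifest, invisibly; stage results in attribute
#'   `results`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("quantconn_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  t0 <- Sys.time()

  run_stage <- function(name, fun) {
    message("[", name, "] ...")
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed after stages: ",
           paste(stages, collapse = ", "), " -- ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  # 1. simulate
  cohort <- run_stage("simulate", function() {
    cfg <- do.call(synth_config, c(list(seed = config$seed),
                                   config$cohort))
    ch <- gen_cohort(cfg)
    write_cohort(ch, file.path(out_dir, "cohort"))
    ch
  })
  hc <- which(cohort$covariates$group == "control")

  # 2. toy streamline-weight fit
  commit_res <- run_stage("fit-commit", function() {
    gs <- config$commit$grid_shape
    node_map <- integer(prod(gs))
    node_map[voxel_index(cbind(1, seq_len(gs[2]), 1), gs)] <- 1L
    node_map[voxel_index(cbind(gs[1], seq_len(gs[2]), 1), gs)] <- 2L
    node_map[voxel_index(cbind(1, seq_len(gs[2]), gs[3]), gs)] <- 3L
    node_map[voxel_index(cbind(gs[1], seq_len(gs[2]), gs[3]), gs)] <- 4L
    toy <- gen_toy_tractogram(gs, config$commit$n_streamlines, node_map,
                              seed = config$seed + 10L)
    grads <- default_gradients()
    sig <- gen_dwi_signal(toy$tractogram, toy$truth, grads)
    op <- build_operator(toy$tractogram, grads)
    w <- fit_commit(op, sig)
    nodes <- data.frame(node_id = 1:4, name = sprintf("roi_%d", 1:4))
    sc <- assemble_structural(toy$tractogram, w, nodes)
    utils::write.table(
      data.frame(streamline_id = seq_along(w$x), weight = w$x,
                 truth = toy$truth$streamline_weights),
      file.path(out_dir, "toy_streamline_weights.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    list(weights = w, truth = toy$truth, connectome = sc,
         rmse = sqrt(mean((w$x - toy$truth$streamline_weights)^2)))
  })

  # 3. connectome thresholding
  conn <- run_stage("build-connectome", function() {
    pf <- prevalence_filter(cohort$struct, hc)
    func_thr <- lapply(cohort$func, absolutize_and_threshold,
                       density = config$functional$density)
    list(struct = pf$matrices, mask = pf$mask,
         n_removed = pf$n_removed, func = func_thr)
  })

  # 4. global graph metrics
  metrics <- run_stage("metrics", function() {
    per_subject <- function(mats, modality) do.call(rbind, lapply(
      seq_along(mats), function(s) {
        gm <- graph_metrics(mats[[s]])
        data.frame(subject_id = cohort$covariates$subject_id[s],
                   modality = modality,
                   metric = c("density", "mean_strength",
                              "global_efficiency",
                              "clustering_coefficient", "modularity"),
                   value = c(gm$density, gm$mean_strength,
                             gm$global_efficiency,
                             gm$clustering_coefficient, gm$modularity))
      }))
    out <- rbind(per_subject(conn$struct, "structural"),
                 per_subject(conn$func, "functional"))
    utils::write.csv(out, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    out
  })

  # 5. network-based statistics (structural, patient < control)
  nbs_res <- run_stage("nbs", function() {
    cfg <- nbs_config(thresholds = config$nbs$thresholds,
                      n_perm = config$nbs$n_perm,
                      size_measure = config$nbs$size_measure,
                      alpha = config$nbs$alpha, seed = config$seed + 20L,
                      contrast = config$nbs$contrast)
    design <- cohort$covariates[c("group", "age", "sex")]
    res <- nbs_test(conn$struct, design, cfg, mask = conn$mask)
    sig <- lapply(res$components, function(cl)
      Filter(function(cc) isTRUE(cc$significant), cl))
    jsonlite::write_json(
      lapply(seq_along(res$thresholds), function(ti) list(
        threshold = res$thresholds[ti],
        components = lapply(res$components[[ti]], function(cc)
          list(nodes = cc$nodes, extent = cc$extent,
               intensity = cc$intensity, p_fwer = cc$p_fwer)))),
      file.path(out_dir, "nbs.json"), auto_unbox = TRUE, digits = NA)
    list(result = res, significant = sig)
  })

  # 6. cohort statistics
  stats_res <- run_stage("stats", function() {
    cv <- cohort$covariates
    ancova <- do.call(rbind, lapply(split(metrics, list(metrics$modality,
                                                        metrics$metric)),
      function(d) {
        vals <- d$value[match(cv$subject_id, d$subject_id)]
        covs <- if (d$modality[1] == "functional")
          cv[c("age", "sex", "motion")] else cv[c("age", "sex")]
        if (stats::sd(vals) == 0) return(NULL)
        ra <- robust_ancova(vals, cv$group, covs)
        data.frame(modality = d$modality[1], metric = d$metric[1],
                   estimate = ra$estimate, t = ra$statistic,
                   p = ra$p_value)
      }))
    fdr <- bh_fdr(ancova$p, config$nbs$alpha)
    ancova$p_fdr <- fdr$p_adjusted
    ancova$significant <- fdr$reject
    utils::write.csv(ancova, file.path(out_dir, "group_stats.csv"),
                     row.names = FALSE)

    # subnetwork of interest: significant NBS component at the chosen
    # threshold, else the planted ground truth
    ti <- which.min(abs(nbs_res$result$thresholds -
                          config$nbs$component_threshold))
    sig_comps <- nbs_res$significant[[ti]]
    subnet_edges <- if (length(sig_comps) > 0) sig_comps[[1]]$edges else
      cohort$ground_truth$subnet_edges
    disr <- disruption_index(conn$struct, subnet_edges, cv, hc,
                             "structural")
    devi <- disruption_index(cohort$func, subnet_edges, cv, hc,
                             "functional")
    pat <- which(cv$group == "patient")
    d_str <- cohens_d(length(pat), mean(disr[pat]), stats::sd(disr[pat]),
                      length(hc), mean(disr[hc]), stats::sd(disr[hc]))
    d_fun <- cohens_d(length(pat), mean(devi[pat]), stats::sd(devi[pat]),
                      length(hc), mean(devi[hc]), stats::sd(devi[hc]))
    scored <- which(!is.na(cv$score))
    mod <- moderation_fit(cv$score[scored], disr[scored], devi[scored],
                          cv$age[scored], cv$sex[scored])
    slopes <- simple_slopes(mod)
    report <- list(
      disruption_cohens_d = d_str, deviation_cohens_d = d_fun,
      moderation = list(coefficients = as.list(mod$coefficients),
                        r_squared = mod$r_squared, model_p = mod$model_p),
      simple_slopes = slopes)
    jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    list(ancova = ancova, disruption = disr, deviation = devi,
         cohens_d = c(structural = d_str, functional = d_fun),
         moderation = mod, slopes = slopes)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("quantconn")),
    seed = config$seed, config = config, stages = stages,
    started = format(t0), finished = format(Sys.time()),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- structure(manifest, results = list(
    cohort = cohort, commit = commit_res, connectomes = conn,
    metrics = metrics, nbs = nbs_res, stats = stats_res))
  invisible(res)
}
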