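#' Run the full assembly-analysis pipeline
#'
#' Orchestrates data ingestion (or simulation), generalist/specialist
#' classification, pairwise assembly-process partitioning (overall and per
#' salinity level), the Sloan neutral-model fit, per-level co-occurrence
#' networks with stability and cohesion reports, and the Mantel/PERMANOVA
#' tests, writing result tables and a run manifest to an output directory.
#'
#' The configuration is a YAML file or an equivalent nested list. A minimal
#' simulation-driven config:
#' ```yaml
#' output_dir: results/run1
#' seed: 11
#' input: {scenario: neutral}
#' ```
#' (further [scenario_config()] arguments may be given alongside `scenario`),
#' or file-driven:
#' ```yaml
#' input:
#'   otu_table: otu_table.tsv
#'   orientation: samples_as_rows
#'   tree: tree.nwk
#'   metadata: metadata.tsv
#' ```
#' Optional blocks `salinity_bins`, `niche`, `assembly`, `ncm`, `network`,
#' `stats` override the defaults recorded in the manifest. Every randomized
#' stage derives its seed from the top-level `seed`, so a rerun with the same
#' config is byte-identical. On a stage failure, partial outputs are retained
#' next to a `FAILED` marker naming the stage.
#'
#' @param config path to a YAML config, or a list.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  yaml::write_yaml(config, file.path(out, "config.yaml"))

  manifest <- list(package_version = as.character(utils::packageVersion("amfassembly")),
                   seed = cfg$seed, parameters = cfg, stages = list())
  stage <- function(name, fun) {
    message(sprintf("[%s] running", name))
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop_value("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- res
    res
  }

  dat <- stage("ingest", function() {
    if (!is.null(cfg$input$scenario)) {
      extra <- cfg$input[setdiff(names(cfg$input),
                                 c("scenario", "otu_table", "orientation",
                                   "tree", "metadata"))]
      sim <- simulate_scenario(do.call(scenario_config,
                                       c(list(cfg$input$scenario, seed = cfg$seed),
                                         extra)))
      write_simulation(sim, file.path(out, "simulated_input"))
      list(source = paste0("simulated:", cfg$input$scenario),
           n_samples = nrow(sim$table), n_otus = ncol(sim$table),
           .data = sim)
    } else {
      tab <- read_community_table(cfg$input$otu_table,
                                  orientation = cfg$input$orientation %||% "samples_as_rows")
      meta <- align_metadata(tab, read_sample_metadata(cfg$input$metadata))
      dm <- read_phylogeny(cfg$input$tree, colnames(tab))
      list(source = cfg$input$otu_table,
           n_samples = nrow(tab), n_otus = ncol(tab),
           .data = list(table = tab, metadata = meta, distances = dm))
    }
  })
  sim <- dat$.data
  manifest$stages$ingest$.data <- NULL
  table <- sim$table
  meta <- align_metadata(table, sim$metadata)
  dists <- sim$distances
  binning <- salinity_binning(cfg$salinity_bins)
  levels_map <- assign_salinity_levels(meta, binning)

  niche_res <- stage("niche", function() {
    cls <- classify_generalists_specialists(table,
                                            n_permutations = cfg$niche$n_permutations,
                                            seed = cfg$seed + 1L)
    write.table(cls, file.path(out, "niche_classification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    c(as.list(table(cls$label)), list(n_otus = nrow(cls)))
  })

  stage("assembly", function() {
    pairs <- t(combn(rownames(table), 2L))
    if (nrow(pairs) > cfg$assembly$max_pairs) {
      keep <- with_seed(cfg$seed + 2L, sample.int(nrow(pairs), cfg$assembly$max_pairs))
      pairs <- pairs[sort(keep), , drop = FALSE]
    }
    pa <- assembly_pairs(table, dists, n_null = cfg$assembly$n_null,
                         seed = cfg$seed + 3L, pairs = pairs,
                         groups = levels_map)
    pa$salinity_level <- pa$group
    write.table(pa[, c("sample_a", "sample_b", "bmntd_obs", "bnti", "rc_bray",
                       "process", "salinity_level")],
                file.path(out, "assembly_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    overall <- summarize_assembly(pa)
    per_level <- lapply(split(pa, pa$group), function(df) {
      if (sum(!is.na(df$process)) > 0) summarize_assembly(df) else NULL
    })
    summ <- rbind(
      data.frame(group = "all", process = names(overall$fractions),
                 fraction = unname(overall$fractions)),
      do.call(rbind, lapply(names(per_level), function(g) {
        if (is.null(per_level[[g]])) return(NULL)
        data.frame(group = g, process = names(per_level[[g]]$fractions),
                   fraction = unname(per_level[[g]]$fractions))
      })))
    write.table(summ, file.path(out, "assembly_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_pairs = overall$n_pairs, n_flagged = overall$n_excluded,
         stochastic_fraction = overall$stochastic_fraction)
  })

  stage("neutral_model", function() {
    fit <- fit_ncm(table, detection_limit = cfg$ncm$detection_limit)
    write.table(fit$otu, file.path(out, "ncm_otu.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summ <- list(m = fit$m, Nm = fit$Nm, R2 = fit$r_squared,
                 detection_limit = fit$detection_limit)
    jsonlite::write_json(summ, file.path(out, "ncm_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    summ
  })

  stage("networks", function() {
    res <- list()
    for (lv in binning$bin_labels) {
      rows <- names(levels_map)[levels_map == lv]
      if (length(rows) < 5L) next
      sub <- community_table(count_matrix(table)[rows, , drop = FALSE])
      rep <- tryCatch(
        network_stability_report(sub, seed = cfg$seed + 4L,
                                 min_mean_relative_abundance = cfg$network$min_mean_relative_abundance,
                                 rho_threshold = cfg$network$rho_threshold,
                                 alpha = cfg$network$alpha,
                                 removal_fraction = cfg$network$removal_fraction,
                                 n_repetitions = cfg$network$n_repetitions,
                                 n_null = cfg$network$cohesion_null),
        error = function(e) NULL)
      if (is.null(rep)) next
      safe <- gsub("[^0-9A-Za-z._-]", "_", lv)
      export_network(rep$network,
                     edge_list_path = file.path(out, sprintf("network_%s_edges.tsv", safe)),
                     graphml_path = file.path(out, sprintf("network_%s.graphml", safe)))
      res[[lv]] <- data.frame(
        salinity_level = lv,
        n_nodes = rep$topology$n_nodes, n_edges = rep$topology$n_edges,
        robustness_mean = rep$robustness$robustness_mean %||% NA_real_,
        robustness_sd = rep$robustness$robustness_sd %||% NA_real_,
        vulnerability = rep$vulnerability,
        positive_cohesion = rep$cohesion$positive,
        negative_cohesion = rep$cohesion$negative,
        complexity = rep$cohesion$complexity)
    }
    if (length(res)) {
      write.table(do.call(rbind, res), file.path(out, "network_stability.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(levels_built = names(res))
  })

  stage("stats", function() {
    dcom <- bray_curtis_distance(table)
    denv <- environment_distance(meta, cfg$stats$mantel_covariates)
    mt <- mantel_test(dcom, denv, n_permutations = cfg$stats$n_permutations,
                      seed = cfg$seed + 5L)
    pm <- tryCatch(
      permanova(dcom, levels_map, n_permutations = cfg$stats$n_permutations,
                seed = cfg$seed + 6L),
      error = function(e) list(error = conditionMessage(e)))
    res <- list(mantel = mt, permanova = pm)
    jsonlite::write_json(res, file.path(out, "stats.json"), auto_unbox = TRUE,
                         digits = NA)
    res
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

pipeline_defaults <- function(config) {
  if (is.null(config$seed)) stop_value("config must set a top-level `seed`")
  if (is.null(config$input) ||
      (is.null(config$input$scenario) &&
       (is.null(config$input$otu_table) || is.null(config$input$tree) ||
        is.null(config$input$metadata)))) {
    stop_value("config `input` must give a scenario or otu_table+tree+metadata paths")
  }
  merge_defaults <- function(user, def) {
    for (k in names(def)) user[[k]] <- user[[k]] %||% def[[k]]
    user
  }
  cfg <- config
  cfg$output_dir <- cfg$output_dir %||% "amfassembly_results"
  cfg$seed <- as.integer(cfg$seed)
  cfg$salinity_bins <- cfg$salinity_bins %||% c(0, 1, 2, 4, 7, 11)
  cfg$niche <- merge_defaults(cfg$niche %||% list(), list(n_permutations = 1000L))
  cfg$assembly <- merge_defaults(cfg$assembly %||% list(),
                                 list(n_null = 999L, max_pairs = 300L))
  cfg$ncm <- merge_defaults(cfg$ncm %||% list(), list(detection_limit = "auto"))
  cfg$network <- merge_defaults(cfg$network %||% list(),
                                list(rho_threshold = 0.6, alpha = 0.05,
                                     min_mean_relative_abundance = 0.001,
                                     removal_fraction = 0.5,
                                     n_repetitions = 100L, cohesion_null = 200L))
  cfg$stats <- merge_defaults(cfg$stats %||% list(),
                              list(mantel_covariates = "salinity",
                                   n_permutations = 999L))
  cfg
}
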