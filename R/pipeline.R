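#' Default end-to-end pipeline configuration
#'
#' All stages enabled on synthetic inputs, with the analysis defaults: QC
#' 600/6000 genes and 10/20 percent organelle caps, 3% cell-cycle variance
#' threshold, alpha 0.05, 10-spot cluster omission floor, 5-nucleus sepal
#' floor.
#'
#' @param out_dir output directory.
#' @param seed integer seed threaded through every stage.
#' @param stages character vector of stages to run (subset of simulate, qc,
#'   cellcycle, score, spatial, reporter, growth).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("sepalsig_run_"), seed = 1,
                       stages = c("simulate", "qc", "cellcycle", "score",
                                  "spatial", "reporter", "growth")) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 qc = qc_thresholds(), cc_threshold = 0.03, alpha = 0.05,
                 min_spots = 10, min_nuclei = 5),
            class = "run_config")
}

#' Run the pipeline end to end
#'
#' Executes simulate -> qc -> cellcycle -> score -> spatial -> reporter ->
#' growth in order, skipping disabled stages, writing every stage's table
#' as a stamped CSV under `config$out_dir` and returning a run report
#' (stages completed, row counts, warnings). Any stage error halts the run
#' with the stage name.
#'
#' @param config a [run_config()].
#' @return list with `stages` (completed), `outputs` (named file paths),
#'   `rows` (row counts), `warnings`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  env <- environment()
  report <- list(stages = character(0), outputs = character(0),
                 rows = integer(0), warnings = character(0))
  note <- function(stage, name, df, params = list()) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    write_csv_stamped(df, path, seed = seed, params = params)
    report$stages <<- union(report$stages, stage)
    report$outputs[name] <<- path
    report$rows[name] <<- nrow(df)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        env$report$warnings <- c(env$report$warnings,
                                 sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  sim <- NULL
  run_stage("simulate", function() {
    lm <- matrix(0, 2, 3, dimnames = list(c("WT", "mutant"),
                                          c("c0", "c1", "c2")))
    lm["mutant", "c1"] <- 1
    cfg <- sc_sim_config(
      seed = seed,
      beta = c(auxin = 0, cytokinin = 0, brassinosteroid = 0.2,
               abscisic_acid = 0, gibberellin = 0, ethylene = 0),
      latent_mean = lm)
    s <- simulate_sc(cfg)
    s$cfg <- cfg
    env$sim <- s
    note("simulate", "sim_truth", s$truth,
         list(beta_brassinosteroid = 0.2, planted_cluster = "c1"))
  })
  if (is.null(sim)) stop("run_pipeline requires the simulate stage")

  sce <- sim$sce
  run_stage("qc", function() {
    qc <- filter_cells(sim$sce, config$qc)
    env$sce <- qc$sce
    note("qc", "qc_summary", qc$qc,
         list(min_genes = config$qc$min_genes, max_genes = config$qc$max_genes))
  })

  run_stage("cellcycle", function() {
    cc <- score_cell_cycle(sce, sim_cc_genes(sim$cfg), seed = seed)
    reduced <- remove_cc_genes(sce, cc$phase, config$cc_threshold)
    env$sce <- reduced$sce
    note("cellcycle", "phase_scores", cc, list(threshold = config$cc_threshold))
    note("cellcycle", "variance_report", reduced$report,
         list(threshold = config$cc_threshold))
  })

  run_stage("score", function() {
    scores <- score_cells(sce, sim_gene_sets(sim$cfg))
    meta <- SummarizedExperiment::colData(sce)
    contrasts <- contrast_clusters(scores, meta$cluster, meta$genotype,
                                   alpha = config$alpha)
    calls <- infer_directions(contrasts)
    note("score", "contrasts", as.data.frame(contrasts),
         list(alpha = config$alpha,
              bonferroni = attr(contrasts, "bonferroni_threshold")))
    note("score", "direction_calls", calls)
  })

  run_stage("spatial", function() {
    sp <- simulate_spots(sim$cfg)
    labels <- best_cluster(sp$scores)
    meta <- SummarizedExperiment::colData(sp$sce)
    props <- cluster_spot_proportions(labels, meta$genotype, config$min_spots)
    qc_areas <- spot_qc(sp$sce)
    keep <- meta$capture_area %in% qc_areas$capture_area[!qc_areas$flagged]
    sc <- score_spots(sp$sce[, keep], sim_gene_sets(sim$cfg),
                      labels[keep], meta$genotype[keep], alpha = config$alpha)
    note("spatial", "spot_labels",
         data.frame(spot = names(labels), best_cluster = labels,
                    genotype = meta$genotype))
    note("spatial", "spot_proportions", props, list(min_spots = config$min_spots))
    note("spatial", "spot_area_qc", qc_areas)
    note("spatial", "spot_contrasts", as.data.frame(sc$contrasts))
  })

  run_stage("reporter", function() {
    nuc <- simulate_nuclei(seed = seed)
    summ <- sepal_summary(nuc$nuclei, config$min_nuclei)
    cmp <- group_compare(summ, by = "position")
    note("reporter", "sepal_summaries", summ, list(min_nuclei = config$min_nuclei))
    note("reporter", "reporter_comparisons", cmp)
  })

  run_stage("growth", function() {
    gr <- simulate_growth(noise_sd = 0.02, seed = seed)
    rec <- growth_records(gr$series)
    note("growth", "growth_contributions", rec$contributions)
    note("growth", "area_ratios", rec$ratios)
  })

  report
}
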