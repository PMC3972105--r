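#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis. Inputs
#' are either pre-existing files (`paths`) or a simulation request
#' (`simulate`, arguments for [sim_config]); exactly one must be given.
#'
#' @param paths named list of input files (`expression`, `samples`,
#'   `tf_table`, `target_table`, `known`, `annotations`), or `NULL`.
#' @param simulate named list of [sim_config] arguments, or `NULL`.
#' @param out_dir output directory for all stage artifacts.
#' @param sam list of [sam_params] arguments.
#' @param background overlap background size; `NULL` uses the number
#'   of probes assayed.
#' @param min_score,consensus,top_k target-filter parameters.
#' @param alpha,top_n enrichment parameters.
#' @param ir_threshold inclusive IR hub threshold.
#' @param r_min,hub_fraction co-expression parameters.
#' @param k number of hierarchical clusters.
#' @param seed seed applied to simulation and SAM permutations.
#' @return list of class `run_config`.
#' @export
run_config <- function(paths = NULL, simulate = NULL, out_dir = tempfile("hubmir_"),
                       sam = list(), background = NULL,
                       min_score = 20, consensus = 3, top_k = 10,
                       alpha = 0.05, top_n = 20, ir_threshold = 70,
                       r_min = 0.9, hub_fraction = 0.8, k = 6, seed = 1) {
  if (is.null(paths) == is.null(simulate))
    stop_config("paths/simulate", "exactly one of them must be given")
  if (!is.null(paths)) {
    need <- c("expression", "samples", "tf_table", "target_table",
              "known", "annotations")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stop_config("paths", paste("missing:", paste(missing, collapse = ", ")))
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent))
      stop_config("paths", paste("file(s) not found:",
                                 paste(absent, collapse = ", ")))
  }
  structure(list(paths = paths, simulate = simulate, out_dir = out_dir,
                 sam = sam, background = background, min_score = min_score,
                 consensus = consensus, top_k = top_k, alpha = alpha,
                 top_n = top_n, ir_threshold = ir_threshold, r_min = r_min,
                 hub_fraction = hub_fraction, k = k, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Novel and shared hub miRs
#'
#' Combines the hub calls of the regulatory (IR) and co-expression
#' analyses: `novel` are hubs absent from the curated known list,
#' `common` are miRs that are hubs in both network types.
#'
#' @param ir_hubs,coexpr_hubs,known character vectors of miR names.
#' @return list with sorted character vectors `novel` and `common`.
#' @export
common_hubs <- function(ir_hubs, coexpr_hubs, known) {
  ir_hubs <- unique(canonicalize_mir(ir_hubs))
  coexpr_hubs <- unique(canonicalize_mir(coexpr_hubs))
  known <- unique(canonicalize_mir(known))
  list(novel = sort(setdiff(union(ir_hubs, coexpr_hubs), known)),
       common = sort(intersect(ir_hubs, coexpr_hubs)))
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full hub-miR analysis
#'
#' Executes the whole workflow: simulate-or-load inputs, SAM
#' differential expression, overlap with the known list and Group 1/2
#' partition, consensus + score + top-k target filtering, enrichment
#' per group, tripartite regulatory network and IR hubs per group,
#' co-expression network with topological hubs, hierarchical
#' clustering, and the cross-network novel-hub summary. Every stage
#' writes its artifact under `config$out_dir` before the next starts;
#' a fixed seed yields an identical report.
#'
#' @param config a [run_config].
#' @param verbose emit one progress line per stage.
#' @return the run report (list), invisibly written as
#'   `report.json` in `out_dir`.
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  paths <- run_stage("inputs", function() {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      sim <- simulate_inputs(do.call(sim_config, args),
                             file.path(out, "inputs"))
      sim$paths
    } else config$paths
  })
  dataset <- read_expression(paths$expression, paths$samples)
  tf_table <- read_tf_table(paths$tf_table)
  target_table <- read_target_table(paths$target_table)
  known <- read_mir_list(paths$known)
  sets <- read_gmt(paths$annotations)
  stage_log(verbose, "inputs", "%d probes, %d samples, %d known miRs",
            nrow(dataset$values), ncol(dataset$values), length(known))

  # --- differential expression ---------------------------------------
  sam <- run_stage("de", function() {
    args <- config$sam
    args$seed <- args$seed %||% config$seed
    sam_fdr(dataset, do.call(sam_params, args))
  })
  de <- select_de(sam)
  utils::write.table(sam$table, file.path(out, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(s0 = sam$s0, delta = sam$delta,
                            n_called = sam$n_called),
                       file.path(out, "de_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log(verbose, "de", "s0 = %.3g, %d DE miRs", sam$s0, length(de))

  # --- overlap / partition -------------------------------------------
  background <- config$background %||% nrow(dataset$values)
  overlap <- run_stage("overlap", function()
    overlap_significance(de, known, background))
  write_mir_list(overlap$group1, file.path(out, "group1.txt"))
  write_mir_list(overlap$group2, file.path(out, "group2.txt"))
  jsonlite::write_json(overlap[c("n_de", "n_known", "n_overlap",
                                 "background", "p_value")],
                       file.path(out, "overlap.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_log(verbose, "overlap", "%d/%d known, p = %.3g", overlap$n_overlap,
            overlap$n_de, overlap$p_value)

  # --- target filtering ----------------------------------------------
  filtered <- run_stage("targets", function() {
    cons <- consensus_targets(target_table,
                              required_predictors = config$consensus)
    top_k_targets(filter_by_score(cons, config$min_score), config$top_k)
  })
  write_edge_table(filtered, file.path(out, "filtered_targets.tsv"))

  # --- per-group enrichment + regulatory network ---------------------
  gmt_genes <- unique(unlist(lapply(sets, `[[`, "genes")))
  gene_background <- union(gmt_genes, unique(target_table$gene))
  groups <- list(group1 = overlap$group1, group2 = overlap$group2)
  regnet <- lapply(names(groups), function(gname) {
    mirs <- groups[[gname]]
    sub_targets <- filtered[filtered$miR %in% mirs, , drop = FALSE]
    query <- unique_target_genes(mirs, sub_targets)
    if (!length(query)) {
      jsonlite::write_json(list(), file.path(out, paste0("enrich_", gname, ".json")))
      return(list(hubs = data.frame(miR = character(), m = integer(),
                                    n = integer(), ir = integer()),
                  n_mirs = 0L))
    }
    rows <- enrich(query, sets, gene_background)
    utils::write.table(rows, file.path(out, paste0("enrich_", gname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    subset <- mirs_for_top_terms(rows, sets, sub_targets, config$top_n)
    net <- build_tripartite(tf_table, sub_targets, subset)
    report <- select_ir_hubs(net, config$ir_threshold)
    utils::write.table(report$hubs,
                       file.path(out, paste0("ir_hubs_", gname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(net$mirs))
      write_network(net, file.path(out, paste0("regnet_", gname, ".sif")),
                    "SIF")
    stage_log(verbose, "regnet", "%s: %d miRs in network, %d IR hubs",
              gname, length(net$mirs), nrow(report$hubs))
    list(hubs = report$hubs, n_mirs = length(net$mirs))
  })
  names(regnet) <- names(groups)

  # --- co-expression network -----------------------------------------
  coexpr <- run_stage("coexpr", function() {
    if (length(de) < 2) return(NULL)
    graph <- threshold_edges(pearson_matrix(dataset, de), config$r_min)
    if (igraph::vcount(graph$graph) == 0) return(NULL)
    metrics <- node_metrics(graph)
    utils::write.table(metrics, file.path(out, "coexpr_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- summarize_nodes(metrics)
    utils::write.table(cbind(metric = rownames(summary), summary),
                       file.path(out, "coexpr_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network(graph, file.path(out, "coexpr.graphml"), "GraphML")
    hubs <- select_degree_hubs(metrics, config$hub_fraction)
    utils::write.table(hubs$hubs, file.path(out, "coexpr_hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(graph = graph, metrics = metrics, hubs = hubs)
  })
  stage_log(verbose, "coexpr", "%d nodes, %d edges, %d hubs",
            if (is.null(coexpr)) 0 else igraph::vcount(coexpr$graph$graph),
            if (is.null(coexpr)) 0 else igraph::ecount(coexpr$graph$graph),
            if (is.null(coexpr)) 0 else nrow(coexpr$hubs$hubs))

  # --- hierarchical clustering ---------------------------------------
  clusters <- run_stage("cluster", function() {
    if (length(de) < 2) return(NULL)
    dend <- average_linkage(correlation_dist_matrix(dataset, de))
    assign <- cut_clusters(dend, min(config$k, length(de)))
    utils::write.table(data.frame(miR = names(assign), cluster = assign),
                       file.path(out, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    assign
  })

  # --- cross-network summary -----------------------------------------
  ir_hub_mirs <- unique(c(regnet$group1$hubs$miR, regnet$group2$hubs$miR))
  coexpr_hub_mirs <- if (is.null(coexpr)) character() else coexpr$hubs$hubs$miR
  hubs <- common_hubs(ir_hub_mirs, coexpr_hub_mirs, known)

  report <- list(
    parameters = list(background = background, min_score = config$min_score,
                      consensus = config$consensus, top_k = config$top_k,
                      alpha = config$alpha, top_n = config$top_n,
                      ir_threshold = config$ir_threshold,
                      r_min = config$r_min,
                      hub_fraction = config$hub_fraction, k = config$k,
                      seed = config$seed),
    sam = list(s0 = sam$s0, delta = sam$delta, n_de = length(de)),
    overlap = list(n_overlap = overlap$n_overlap, p_value = overlap$p_value,
                   n_group1 = length(overlap$group1),
                   n_group2 = length(overlap$group2)),
    targets = list(n_filtered_records = nrow(filtered)),
    regnet = list(n_ir_hubs_group1 = nrow(regnet$group1$hubs),
                  n_ir_hubs_group2 = nrow(regnet$group2$hubs)),
    coexpr = list(
      n_nodes = if (is.null(coexpr)) 0L else igraph::vcount(coexpr$graph$graph),
      n_edges = if (is.null(coexpr)) 0L else igraph::ecount(coexpr$graph$graph),
      n_hubs = if (is.null(coexpr)) 0L else nrow(coexpr$hubs$hubs)),
    clusters = list(sizes = if (is.null(clusters)) integer()
                    else as.integer(attr(clusters, "sizes"))),
    hubs = list(ir = sort(ir_hub_mirs), coexpr = sort(coexpr_hub_mirs),
                novel = hubs$novel, common = hubs$common,
                n_novel = length(hubs$novel)))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
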