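#' Configuration for the synthetic-data generator
#'
#' Defines the statistical structure of a simulated two-channel miR
#' microarray study and its companion knowledge tables. Defaults mirror
#' the study design the pipeline is built for: 19 disease vs 13 control
#' samples of log2(Hy3/Hy5) ratios, a planted subset of upregulated
#' miRs (additive shift on the log2 scale, disease side only), planted
#' high-correlation miR blocks driven by a shared latent factor, a
#' TF->miR table, a three-predictor miR->gene target table with
#' miTG-like scores, a known disease-miR list overlapping the planted
#' DE set, and GMT annotation sets with planted enriched terms.
#'
#' @param n_probes number of miR probes on the array.
#' @param n_disease,n_control per-group sample counts (defaults 19/13).
#' @param n_de number of planted upregulated miRs.
#' @param de_effect mean disease-minus-control shift of planted miRs,
#'   in log2 units.
#' @param noise_sd per-observation Gaussian standard deviation.
#' @param block_sizes sizes of planted correlation blocks (disjoint
#'   from the DE set and from each other).
#' @param block_rho target within-block pairwise correlation in
#'   \[0, 1).
#' @param n_tfs number of transcription factors available.
#' @param tf_per_mir_range integer range (min, max) of TFs drawn per
#'   miR.
#' @param n_genes size of the gene pool for targets.
#' @param targets_per_mir consensus targets planted per miR.
#' @param n_predictors number of target predictors (default 3).
#' @param score_range (min, max) of the uniform miTG-like score.
#' @param decoy_fraction decoy targets per miR, as a fraction of
#'   `targets_per_mir`; decoys appear under fewer than `n_predictors`
#'   predictors and exercise the consensus filter.
#' @param known_list_overlap fraction of planted DE miRs included in
#'   the known list.
#' @param n_known total length of the known disease-miR list (padded
#'   with non-DE fillers; default 73).
#' @param n_terms number of annotation terms, of which `n_enriched`
#'   are planted with DE-target genes.
#' @param n_enriched number of planted enriched terms.
#' @param term_size genes per annotation term.
#' @param seed global seed; independent per-generator streams are
#'   derived from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 300, n_disease = 19, n_control = 13,
                       n_de = 30, de_effect = 2.0, noise_sd = 1.0,
                       block_sizes = c(20), block_rho = 0.95,
                       n_tfs = 40, tf_per_mir_range = c(0, 14),
                       n_genes = 500, targets_per_mir = 12,
                       n_predictors = 3, score_range = c(10, 40),
                       decoy_fraction = 0.3,
                       known_list_overlap = 0.5, n_known = 73,
                       n_terms = 25, n_enriched = 2, term_size = 40,
                       seed = 1) {
  cfg <- list(n_probes = n_probes, n_disease = n_disease,
              n_control = n_control, n_de = n_de, de_effect = de_effect,
              noise_sd = noise_sd, block_sizes = block_sizes,
              block_rho = block_rho, n_tfs = n_tfs,
              tf_per_mir_range = tf_per_mir_range, n_genes = n_genes,
              targets_per_mir = targets_per_mir,
              n_predictors = n_predictors, score_range = score_range,
              decoy_fraction = decoy_fraction,
              known_list_overlap = known_list_overlap, n_known = n_known,
              n_terms = n_terms, n_enriched = n_enriched,
              term_size = term_size, seed = seed)
  counts <- c("n_probes", "n_disease", "n_control", "n_de", "n_tfs",
              "n_genes", "targets_per_mir", "n_predictors", "n_known",
              "n_terms", "n_enriched", "term_size")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop_config(f, "must be a single non-negative count")
  if (cfg$n_de > cfg$n_probes) stop_config("n_de", "exceeds n_probes")
  if (sum(cfg$block_sizes) > cfg$n_probes)
    stop_config("block_sizes", "sum exceeds n_probes")
  if (!(cfg$block_rho >= 0 && cfg$block_rho < 1))
    stop_config("block_rho", "must lie in [0, 1)")
  if (cfg$noise_sd < 0) stop_config("noise_sd", "must be non-negative")
  if (!(cfg$known_list_overlap >= 0 && cfg$known_list_overlap <= 1))
    stop_config("known_list_overlap", "must lie in [0, 1]")
  if (length(cfg$tf_per_mir_range) != 2 ||
      cfg$tf_per_mir_range[1] > cfg$tf_per_mir_range[2] ||
      cfg$tf_per_mir_range[1] < 0)
    stop_config("tf_per_mir_range", "must be a non-decreasing pair >= 0")
  if (cfg$tf_per_mir_range[2] > cfg$n_tfs)
    stop_config("tf_per_mir_range", "maximum exceeds n_tfs")
  if (length(cfg$score_range) != 2 || cfg$score_range[1] > cfg$score_range[2])
    stop_config("score_range", "must be a non-decreasing pair")
  if (cfg$decoy_fraction < 0) stop_config("decoy_fraction", "must be >= 0")
  structure(cfg, class = "sim_config")
}

# sample without the scalar-x trap of base::sample
sample_from <- function(x, size) x[sample.int(length(x), size)]

sim_probe_names <- function(n) {
  # deliberately mixed-case to exercise name canonicalization downstream
  sprintf("hsa-miR-SIM%04d", seq_len(n))
}

#' Simulate the expression matrix
#'
#' Probes are Gaussian log2-ratio noise around zero; the planted DE
#' subset receives an additive `de_effect` in the disease samples only
#' (all planted miRs upregulated); each correlation block shares a
#' per-sample latent factor, `x = sqrt(rho) f + sqrt(1 - rho) eps`, so
#' the expected pairwise within-block correlation is `rho`. Bit
#' identical under a fixed seed.
#'
#' @param config a [sim_config].
#' @return list with `dataset` (a [mir_expression]) and `truth` (list
#'   with `de_mirs`, `block_assignments`, `mirs`, `enriched_terms`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  probes <- sim_probe_names(config$n_probes)
  canon <- canonicalize_mir(probes)
  n <- config$n_disease + config$n_control
  groups <- rep(c("disease", "control"), c(config$n_disease, config$n_control))
  out <- withr::with_seed(derive_seed(config$seed, "expression"), {
    values <- matrix(stats::rnorm(config$n_probes * n, sd = config$noise_sd),
                     config$n_probes, n)
    de_idx <- if (config$n_de > 0)
      sort(sample.int(config$n_probes, config$n_de)) else integer()
    # co-expression blocks are drawn preferentially from the DE rows,
    # emulating disease-responsive miR modules; overflow spills into the
    # remaining probes, and blocks stay disjoint from each other
    pool_de <- de_idx
    pool_other <- setdiff(seq_len(config$n_probes), de_idx)
    block_assignments <- integer()
    for (b in seq_along(config$block_sizes)) {
      size <- config$block_sizes[b]
      take_de <- sort(sample_from(pool_de, min(size, length(pool_de))))
      extra <- size - length(take_de)
      take_other <- if (extra > 0) sort(sample_from(pool_other, extra))
                    else integer()
      members <- sort(c(take_de, take_other))
      pool_de <- setdiff(pool_de, members)
      pool_other <- setdiff(pool_other, members)
      f <- stats::rnorm(n)
      values[members, ] <- config$noise_sd *
        (sqrt(config$block_rho) * matrix(f, size, n, byrow = TRUE) +
           sqrt(1 - config$block_rho) *
             matrix(stats::rnorm(size * n), size, n))
      block_assignments[canon[members]] <- b
    }
    if (length(de_idx))
      values[de_idx, groups == "disease"] <-
        values[de_idx, groups == "disease"] + config$de_effect
    list(values = values, de_idx = de_idx,
         block_assignments = block_assignments)
  })
  dimnames(out$values) <- list(probes,
                               sprintf("S%02d_%s", seq_len(n),
                                       ifelse(groups == "disease", "PD", "CT")))
  dataset <- mir_expression(out$values, groups)
  truth <- list(de_mirs = canon[out$de_idx],
                block_assignments = out$block_assignments,
                mirs = canon, enriched_terms = character())
  list(dataset = dataset, truth = truth)
}

#' Simulate TF and target tables
#'
#' Each miR receives a TF count drawn uniformly in `tf_per_mir_range`;
#' each miR gets `targets_per_mir` consensus target genes listed under
#' all `n_predictors` predictors with a shared per-pair miTG-like score
#' drawn uniformly in `score_range`, plus decoy records listed under
#' fewer than `n_predictors` predictors to exercise consensus
#' filtering.
#'
#' @param config a [sim_config].
#' @param truth ground truth from [generate_expression] (same config).
#' @return list with `tf_table` (columns `TF`, `miR`, `effect`) and
#'   `target_table` (columns `miR`, `gene`, `predictor`, `score`).
#' @export
generate_regulation_tables <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  mirs <- truth$mirs
  tfs <- sprintf("TF%03d", seq_len(config$n_tfs))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  predictors <- c("diana", "miranda", "targetscan",
                  sprintf("predictor%d", seq_len(max(0, config$n_predictors - 3)) + 3))
  predictors <- predictors[seq_len(config$n_predictors)]
  withr::with_seed(derive_seed(config$seed, "regulation"), {
    rng <- config$tf_per_mir_range
    tf_rows <- lapply(mirs, function(mir) {
      k <- if (rng[1] == rng[2]) rng[1] else
        rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
      if (k == 0) return(NULL)
      data.frame(TF = sample(tfs, k), miR = mir,
                 effect = sample(c("activation", "repression", "regulation"),
                                 k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    tf_table <- do.call(rbind, tf_rows)
    if (is.null(tf_table))
      tf_table <- data.frame(TF = character(), miR = character(),
                             effect = character())
    n_decoy <- round(config$decoy_fraction * config$targets_per_mir)
    target_rows <- lapply(mirs, function(mir) {
      gs <- sample(genes, min(config$targets_per_mir + n_decoy,
                              config$n_genes))
      consensus <- gs[seq_len(min(config$targets_per_mir, length(gs)))]
      decoys <- setdiff(gs, consensus)
      score <- stats::runif(length(gs), config$score_range[1],
                            config$score_range[2])
      names(score) <- gs
      rows <- list()
      if (length(consensus))
        rows$consensus <- data.frame(
          miR = mir, gene = rep(consensus, each = length(predictors)),
          predictor = rep(predictors, length(consensus)),
          score = rep(score[consensus], each = length(predictors)),
          stringsAsFactors = FALSE)
      if (length(decoys)) {
        n_pred <- sample(seq_len(max(1, config$n_predictors - 1)),
                         length(decoys), replace = TRUE)
        rows$decoys <- do.call(rbind, lapply(seq_along(decoys), function(i)
          data.frame(miR = mir, gene = decoys[i],
                     predictor = sample(predictors, n_pred[i]),
                     score = unname(score[decoys[i]]),
                     stringsAsFactors = FALSE)))
      }
      do.call(rbind, rows)
    })
    target_table <- do.call(rbind, target_rows)
    rownames(target_table) <- NULL
    list(tf_table = tf_table, target_table = target_table)
  })
}

#' Simulate the known disease-miR list
#'
#' The list contains `round(known_list_overlap * n_de)` planted DE
#' names plus non-DE fillers (non-DE probes first, then off-array
#' names) up to `n_known` entries, without duplicates.
#'
#' @inheritParams generate_regulation_tables
#' @return character vector of canonical miR names.
#' @export
generate_known_list <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "known"), {
    n_planted <- round(config$known_list_overlap * length(truth$de_mirs))
    planted <- if (n_planted > 0) sample(truth$de_mirs, n_planted)
               else character()
    n_fill <- max(0, config$n_known - n_planted)
    pool <- setdiff(truth$mirs, truth$de_mirs)
    fillers <- sample(pool, min(n_fill, length(pool)))
    extra <- if (n_fill > length(pool))
      canonicalize_mir(sprintf("hsa-miR-EXT%04d", seq_len(n_fill - length(pool))))
    else character()
    sample(c(planted, fillers, extra))
  })
}

#' Simulate GMT annotation sets
#'
#' Plants `n_enriched` terms whose member genes are drawn preferentially
#' from the consensus targets of the planted DE miRs (so downstream
#' enrichment recovers them) and `n_terms - n_enriched` background
#' terms with random membership. Empty sets are never emitted.
#'
#' @inheritParams generate_regulation_tables
#' @param target_table the table from [generate_regulation_tables].
#' @return annotation sets in [read_gmt] form, with attribute
#'   `enriched_terms` naming the planted terms.
#' @export
generate_annotations <- function(config, truth, target_table) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  de_targets <- unique(target_table$gene[
    canonicalize_mir(target_table$miR) %in% truth$de_mirs])
  withr::with_seed(derive_seed(config$seed, "annotation"), {
    sets <- list()
    planted_ids <- character()
    # with nothing planted the "enriched" terms degrade to background sets
    source_pool <- if (length(de_targets)) de_targets else genes
    for (i in seq_len(config$n_enriched)) {
      size <- min(config$term_size, length(source_pool))
      members <- sample(source_pool, size)
      id <- sprintf("TERM%04d_planted", i)
      planted_ids <- c(planted_ids, id)
      sets[[id]] <- list(description = "planted DE-target process",
                         genes = members)
    }
    for (i in seq_len(max(0, config$n_terms - config$n_enriched))) {
      members <- sample(genes, min(config$term_size, config$n_genes))
      sets[[sprintf("TERM%04d", config$n_enriched + i)]] <-
        list(description = "background process", genes = members)
    }
    sets <- Filter(function(s) length(s$genes) > 0, sets)
    attr(sets, "enriched_terms") <- planted_ids
    sets
  })
}

#' Write a complete simulated input directory
#'
#' Generates all five inputs of the pipeline and writes them in the
#' standard formats: `expression.tsv` + `samples.tsv`,
#' `tf_table.tsv`, `target_table.tsv`, `known_mirs.txt`,
#' `annotations.gmt`, plus `ground_truth.json` recording the planted
#' structure.
#'
#' @param config a [sim_config].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the `truth`.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- generate_expression(config)
  reg <- generate_regulation_tables(config, expr$truth)
  known <- generate_known_list(config, expr$truth)
  sets <- generate_annotations(config, expr$truth, reg$target_table)
  truth <- expr$truth
  truth$enriched_terms <- attr(sets, "enriched_terms")
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    tf_table = file.path(dir, "tf_table.tsv"),
    target_table = file.path(dir, "target_table.tsv"),
    known = file.path(dir, "known_mirs.txt"),
    annotations = file.path(dir, "annotations.gmt"),
    truth = file.path(dir, "ground_truth.json"))
  write_expression(expr$dataset, paths$expression, paths$samples)
  write_edge_table(reg$tf_table, paths$tf_table)
  write_edge_table(reg$target_table, paths$target_table)
  write_mir_list(known, paths$known)
  write_gmt(sets, paths$annotations)
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE)
  invisible(list(paths = paths, truth = truth))
}
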