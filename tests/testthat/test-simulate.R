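test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_probes = 80, n_de = 8, seed = 42)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  ra <- generate_regulation_tables(cfg, a$truth)
  rb <- generate_regulation_tables(cfg, b$truth)
  expect_identical(ra, rb)
  expect_identical(generate_known_list(cfg, a$truth),
                   generate_known_list(cfg, b$truth))
  expect_identical(generate_annotations(cfg, a$truth, ra$target_table),
                   generate_annotations(cfg, b$truth, rb$target_table))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_de = 50, n_probes = 20), "n_de")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(known_list_overlap = 1.2), "known_list_overlap")
  expect_error(sim_config(block_sizes = c(200, 200), n_probes = 300),
               "block_sizes")
  expect_error(sim_config(tf_per_mir_range = c(5, 2)), "tf_per_mir_range")
})

test_that("null config plants nothing and group means differ only by noise", {
  sim <- generate_expression(sim_config(n_probes = 200, n_de = 0,
                                        block_sizes = integer(), seed = 5))
  expect_length(sim$truth$de_mirs, 0)
  g <- sim$dataset$groups
  contrast <- rowMeans(sim$dataset$values[, g == "disease"]) -
    rowMeans(sim$dataset$values[, g == "control"])
  se <- sqrt(1 / 19 + 1 / 13)  # noise_sd = 1
  expect_lt(max(abs(contrast)), 5 * se)
  expect_lt(abs(mean(contrast)), 4 * se / sqrt(200))
})

test_that("planted DE rows carry the configured effect size", {
  cfg <- sim_config(n_probes = 300, n_de = 30, de_effect = 2.0,
                    noise_sd = 1.0, block_sizes = integer(), seed = 1)
  sim <- generate_expression(cfg)
  g <- sim$dataset$groups
  de <- sim$truth$de_mirs
  expect_length(de, 30)
  contrast <- rowMeans(sim$dataset$values[de, g == "disease"]) -
    rowMeans(sim$dataset$values[de, g == "control"])
  # mean of 30 normal contrasts, each with se sqrt(1/19 + 1/13)
  se_mean <- sqrt(1 / 19 + 1 / 13) / sqrt(30)
  expect_lt(abs(mean(contrast) - 2.0), 3 * se_mean)
})

test_that("correlation blocks reach the target within-block correlation", {
  within_frac <- between_med <- numeric(10)
  for (s in 1:10) {
    sim <- generate_expression(sim_config(n_de = 0, block_sizes = 20,
                                          block_rho = 0.95, seed = s))
    blk <- names(sim$truth$block_assignments)
    expect_length(blk, 20)
    r <- pearson_matrix(sim$dataset)
    within <- r[blk, blk][upper.tri(diag(20))]
    within_frac[s] <- mean(within > 0.9)
    between_med[s] <- median(abs(r[blk, setdiff(rownames(r), blk)]))
  }
  expect_gte(mean(within_frac), 0.9)
  expect_lt(max(between_med), 0.3)
})

test_that("regulation tables respect TF ranges, consensus votes and top-k counts", {
  cfg <- sim_config(n_probes = 40, n_de = 6, targets_per_mir = 12,
                    tf_per_mir_range = c(2, 5), seed = 9)
  sim <- generate_expression(cfg)
  reg <- generate_regulation_tables(cfg, sim$truth)
  per_mir_tfs <- tapply(reg$tf_table$TF, reg$tf_table$miR,
                        function(x) length(unique(x)))
  expect_true(all(per_mir_tfs >= 2 & per_mir_tfs <= 5))
  # consensus + score + top-k keeps exactly 10 per miR out of 12 planted
  cons <- consensus_targets(reg$target_table, 3)
  top <- top_k_targets(filter_by_score(cons, min_score = 0), k = 10)
  expect_true(all(table(top$miR) == 10))

  # a zero-TF range forces m = 0 in any regulatory network
  cfg0 <- sim_config(n_probes = 20, n_de = 3, tf_per_mir_range = c(0, 0),
                     seed = 2)
  sim0 <- generate_expression(cfg0)
  reg0 <- generate_regulation_tables(cfg0, sim0$truth)
  expect_equal(nrow(reg0$tf_table), 0)
  net <- build_tripartite(reg0$tf_table,
                          consensus_targets(reg0$target_table, 3),
                          sim0$truth$mirs[1:3])
  expect_true(all(net$mir_stats$m == 0))
  expect_true(all(net$mir_stats$ir == 0))
})

test_that("decoy-free tables pass the consensus filter untouched", {
  cfg <- sim_config(n_probes = 15, n_de = 2, decoy_fraction = 0,
                    targets_per_mir = 4, block_sizes = integer(), seed = 3)
  sim <- generate_expression(cfg)
  reg <- generate_regulation_tables(cfg, sim$truth)
  cons <- consensus_targets(reg$target_table, 3)
  expect_equal(nrow(cons), length(unique(paste(reg$target_table$miR,
                                               reg$target_table$gene))))
})

test_that("known list contains the configured planted fraction", {
  cfg <- sim_config(n_probes = 300, n_de = 30, known_list_overlap = 0.5,
                    seed = 4)
  sim <- generate_expression(cfg)
  known <- generate_known_list(cfg, sim$truth)
  expect_equal(sum(known %in% sim$truth$de_mirs), 15)
  expect_false(anyDuplicated(known) > 0)
  expect_length(known, 73)

  cfg0 <- sim_config(n_probes = 300, n_de = 30, known_list_overlap = 0,
                     seed = 4)
  expect_length(intersect(generate_known_list(cfg0, sim$truth),
                          sim$truth$de_mirs), 0)
  cfg1 <- sim_config(n_probes = 300, n_de = 30, known_list_overlap = 1,
                     seed = 4)
  expect_true(all(sim$truth$de_mirs %in% generate_known_list(cfg1, sim$truth)))
})

test_that("planted annotation terms are recovered as most enriched", {
  cfg <- sim_config(n_probes = 60, n_de = 10, seed = 6)
  sim <- generate_expression(cfg)
  reg <- generate_regulation_tables(cfg, sim$truth)
  sets <- generate_annotations(cfg, sim$truth, reg$target_table)
  expect_true(all(vapply(sets, function(s) length(s$genes) > 0, logical(1))))
  planted <- attr(sets, "enriched_terms")
  query <- unique_target_genes(sim$truth$de_mirs,
                               consensus_targets(reg$target_table, 3))
  background <- union(unique(unlist(lapply(sets, `[[`, "genes"))),
                      unique(reg$target_table$gene))
  rows <- enrich(query, sets, background)
  expect_equal(rows$term[1], planted[1])
  expect_true(all(rows$p_value[rows$term %in% planted] <=
                    min(rows$p_value[!(rows$term %in% planted)])))
})
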