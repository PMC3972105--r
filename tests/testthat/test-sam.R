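test_that("sam_statistic matches the pooled-SE hand computation", {
  ds <- tiny_dataset(rbind(c(3, 4, 5, 1, 2, 3)), 3, 3)
  st <- sam_statistic(ds, s0 = 0)
  expect_equal(st$r, 2)
  expect_equal(st$s, sqrt((1 / 3 + 1 / 3) * (2 + 2) / 4))
  expect_equal(st$d, 2 / sqrt(2 / 3))
})

test_that("the d identity d = r / (s + s0) holds on every row", {
  sim <- generate_expression(sim_config(n_probes = 50, n_de = 5, seed = 8))
  st <- sam_statistic(sim$dataset, s0 = 0.3)
  expect_equal(st$d, st$r / (st$s + 0.3))
})

test_that("equal groups give d = 0 and scaling leaves d unchanged at s0 = 0", {
  ds <- tiny_dataset(rbind(c(1, 2, 3, 1, 2, 3)), 3, 3)
  expect_equal(sam_statistic(ds, 0)$d, 0)
  sim <- generate_expression(sim_config(n_probes = 30, n_de = 3, seed = 2))
  st1 <- sam_statistic(sim$dataset, 0)
  ds10 <- sim$dataset
  ds10$values <- ds10$values * 10
  st10 <- sam_statistic(ds10, 0)
  expect_equal(st10$r, 10 * st1$r)
  expect_equal(st10$s, 10 * st1$s)
  expect_equal(st10$d, st1$d)
})

test_that("miRs with under two usable values per group are excluded", {
  m <- rbind(c(1, NA, NA, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  rownames(m) <- c("hsa-mir-bad", "hsa-mir-good")
  ds <- tiny_dataset(m, 3, 3)
  st <- sam_statistic(ds)
  expect_false(st$usable[st$miR == "hsa-mir-bad"])
  expect_true(st$usable[st$miR == "hsa-mir-good"])
})

test_that("choose_s0 scales with the data and detects heteroskedasticity", {
  sim <- generate_expression(sim_config(n_probes = 200, n_de = 0, seed = 3))
  s0 <- choose_s0(sim$dataset)
  ds2 <- sim$dataset
  ds2$values <- ds2$values * 2
  expect_equal(choose_s0(ds2), 2 * s0)

  # inflate r exactly where s is small: s0 = 0 then maximizes the CV of d
  withr::with_seed(7, {
    n <- 32
    low_s <- matrix(rnorm(100 * n, sd = 0.05), 100, n)
    low_s[, 1:19] <- low_s[, 1:19] + rnorm(100, sd = 2)  # inflated r, tiny s
    high_s <- matrix(rnorm(100 * n, sd = 3), 100, n)
    m <- rbind(low_s, high_s)
    dimnames(m) <- list(paste0("hsa-mir-h", 1:200), paste0("s", 1:n))
  })
  ds <- mir_expression(m, rep(c("disease", "control"), c(19, 13)))
  expect_gt(choose_s0(ds), 0)
})

test_that("exhaustive permutation mode matches brute-force label enumeration", {
  ds <- tiny_dataset(rbind(c(5, 6, 1, 2), c(2, 1, 2, 1), c(0, 4, 2, 3)), 2, 2)
  run <- function(seed) suppressWarnings(suppressMessages(
    sam_fdr(ds, sam_params(n_permutations = 1000, seed = seed,
                           fdr_target = 0.5))))
  res1 <- run(1)
  res2 <- run(999)
  expect_true(res1$exhaustive)
  expect_equal(res1$n_permutations, choose(4, 2))
  expect_identical(res1$table, res2$table)  # seed-independent when exhaustive

  # the permuted d statistics agree with an independent enumeration that
  # recomputes the pooled-SE statistic per label assignment from scratch
  vals <- ds$values
  brute <- sapply(combn(4, 2, simplify = FALSE), function(idx) {
    apply(vals, 1, function(x) {
      a <- x[idx]; b <- x[-idx]
      r <- mean(a) - mean(b)
      s <- sqrt((1 / 2 + 1 / 2) *
                  (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 2)
      d <- r / s
      if (r == 0) 0 else d
    })
  })
  plan <- hubmir:::permutation_plan(4, 2, 1000, 1)
  ours <- sapply(plan, function(idx) hubmir:::sam_d_permuted(vals, idx, 0))
  expect_equal(ours, brute, ignore_attr = TRUE)
})

test_that("null data yield almost no calls at a 0.3% FDR target", {
  fracs <- vapply(1:20, function(s) {
    sim <- generate_expression(sim_config(n_probes = 300, n_de = 0, seed = s))
    res <- suppressMessages(
      sam_fdr(sim$dataset, sam_params(n_permutations = 100, seed = s)))
    res$n_called / 300
  }, numeric(1))
  expect_lte(mean(fracs), 0.01)
})

test_that("planted upregulated miRs are recovered with high sensitivity", {
  sens <- fdp <- up <- numeric(10)
  for (s in 1:10) {
    sim <- generate_expression(sim_config(n_probes = 300, n_de = 30,
                                          de_effect = 2.0, noise_sd = 1.0,
                                          seed = s))
    res <- suppressMessages(
      sam_fdr(sim$dataset, sam_params(n_permutations = 100, seed = s)))
    de <- select_de(res)
    sens[s] <- mean(sim$truth$de_mirs %in% de)
    fdp[s] <- if (length(de)) mean(!(de %in% sim$truth$de_mirs)) else 0
    dirs <- res$table$direction[res$table$called]
    up[s] <- if (length(dirs)) mean(dirs == "up") else 1
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdp), 0.1)
  expect_gte(mean(up == 1), 0.95)  # every call upregulated in >= 95% of seeds
})

test_that("lowering the FDR target never enlarges the call set", {
  sim <- generate_expression(sim_config(n_probes = 200, n_de = 15,
                                        de_effect = 1.2, seed = 12))
  called_at <- function(t) suppressMessages(
    sam_fdr(sim$dataset, sam_params(fdr_target = t, n_permutations = 100,
                                    seed = 1)))$n_called
  counts <- vapply(c(0.3, 0.1, 0.03, 0.003), called_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("select_de orders by |d| and handles empty call sets", {
  sim <- generate_expression(sim_config(n_probes = 60, n_de = 6,
                                        de_effect = 3, seed = 4))
  res <- suppressMessages(sam_fdr(sim$dataset,
                                  sam_params(n_permutations = 50, seed = 4)))
  de <- select_de(res)
  expect_length(de, res$n_called)
  d_of <- abs(res$table$d[match(de, res$table$miR)])
  expect_true(all(diff(d_of) <= 1e-12))
  empty <- res
  empty$table$called <- FALSE
  expect_length(select_de(empty), 0)
})
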