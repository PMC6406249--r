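test_that("generators are pure functions of their seed", {
  a <- gen_cell_line_dataset(n_genes = 40, seed = 12)
  b <- gen_cell_line_dataset(n_genes = 40, seed = 12)
  expect_identical(a, b)
  fit <- chemopanel(a$expression, a$response, panel_size = 5,
                    alpha = 0.05, seed = 3)
  c1 <- gen_cohort(fit, n_patients = 50, seed = 7)
  c2 <- gen_cohort(fit, n_patients = 50, seed = 7)
  expect_identical(c1, c2)
})

test_that("null expression matches the KW screen's true false-positive rate", {
  n_genes <- 400
  hits <- 0L
  for (s in 1:20) {
    sim <- gen_cell_line_dataset(n_cell_lines = 25, n_genes = n_genes,
                                 n_signal_genes = 0, effect_size = 0,
                                 seed = s)
    res <- kruskal_wallis_filter(zscore_genes(sim$expression), sim$groups,
                                 alpha = 0.01)
    hits <- hits + sum(res$selected)
  }
  total <- 20L * n_genes

  # The chi-square approximation to Kruskal-Wallis is conservative at
  # N = 25 (true level ~0.6%, not the nominal 1%), so calibrate against a
  # rank-permutation oracle at the same 9/8/8 group sizes.
  set.seed(1234)
  n <- 25
  sizes <- c(9, 8, 8)
  idx <- rep(1:3, sizes)
  reps <- 40000
  null_hit <- vapply(seq_len(reps), function(r) {
    rk <- sample.int(n)
    rb <- tapply(rk, idx, mean)
    h <- 12 / (n * (n + 1)) * sum(sizes * (rb - (n + 1) / 2)^2)
    pchisq(h, 2, lower.tail = FALSE) < 0.01
  }, logical(1))
  rate <- mean(null_hit)
  se <- sqrt(rate * (1 - rate) / reps)
  expect_lt(rate, 0.01) # the approximation really is conservative here
  bounds <- c(qbinom(0.005, total, max(rate - 3 * se, 1e-4)),
              qbinom(0.995, total, rate + 3 * se))
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("a 3-sd planted shift is detected in nearly every dataset", {
  ok <- vapply(1:20, function(s) {
    sim <- gen_cell_line_dataset(n_cell_lines = 25, n_genes = 100,
                                 n_signal_genes = 10, effect_size = 3,
                                 seed = s)
    res <- kruskal_wallis_filter(zscore_genes(sim$expression), sim$groups,
                                 alpha = 0.01)
    all(sim$signal_genes %in% res$gene[res$selected])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("planted group means differ by the specified shift", {
  sim <- gen_cell_line_dataset(n_cell_lines = 3000, n_genes = 12,
                               n_signal_genes = 4, effect_size = 2,
                               noise_sd = 1.5, seed = 9)
  g <- sim$groups
  for (gene in sim$signal_genes) {
    lo <- mean(sim$expression[gene, g == "low"])
    hi <- mean(sim$expression[gene, g == "high"])
    expect_equal(hi - lo, 2 * 2 * 1.5, tolerance = 0.15) # 2e*noise_sd, MC
  }
  null_gene <- setdiff(rownames(sim$expression), sim$signal_genes)[1]
  expect_equal(mean(sim$expression[null_gene, g == "high"]) -
                 mean(sim$expression[null_gene, g == "low"]),
               0, tolerance = 0.2)
})

test_that("cohort censoring and hazards follow the simulation spec", {
  sim <- separable_fixture(seed = 7)
  fit <- chemopanel(sim$expression, sim$response, seed = 11)

  none <- gen_cohort(fit, n_patients = 150, censoring_rate = 0, seed = 2)
  expect_true(all(none$clinical$event == 1))

  some <- gen_cohort(fit, n_patients = 2000, censoring_rate = 0.4, seed = 3)
  expect_equal(mean(some$clinical$event == 0), 0.4, tolerance = 0.05)

  expect_error(gen_cohort(fit, hazard_ratios = c(medium = 0.7, high = 0)),
               "positive")
})

test_that("equal group hazards give a uniform log-rank null", {
  sim <- separable_fixture(seed = 7)
  fit <- chemopanel(sim$expression, sim$response, seed = 11)
  set.seed(55)
  pvals <- vapply(1:200, function(r) {
    coh <- gen_cohort(fit, n_patients = 120,
                      hazard_ratios = c(medium = 1, high = 1),
                      group_probs = c(low = 1, medium = 1, high = 1) / 3,
                      seed = 1000 + r)
    lab <- panel_term(classify_cohort(fit, coh), "high_vs_low")
    keep <- !is.na(lab)
    logrank_test(coh$clinical$time[keep], coh$clinical$event[keep],
                 lab[keep])$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate() draws cohorts from the fitted model", {
  sim <- separable_fixture(seed = 7)
  fit <- chemopanel(sim$expression, sim$response, seed = 11)
  one <- simulate(fit, nsim = 1, seed = 5, n_patients = 40)
  expect_s3_class(one, "panel_cohort")
  two <- simulate(fit, nsim = 2, seed = 5, n_patients = 40)
  expect_length(two, 2)
  expect_identical(two[[1]], one)
})
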