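# Synthetic-data generator: proteomes, designs, planted effects and MNAR
# censoring.

test_that("proteome generation respects bounds, uniqueness and seeding", {
  expect_equal(nrow(generate_proteome(0)), 0)
  p <- generate_proteome(100, min_len = 50, max_len = 400, seed = 3)
  expect_equal(nrow(p), 100)
  expect_false(anyDuplicated(p$id) > 0)
  expect_true(all(nchar(p$sequence) >= 50 & nchar(p$sequence) <= 400))
  expect_true(all(strsplit(paste(p$sequence, collapse = ""), "")[[1]] %in%
                    exocargo:::AA_ALPHABET))
  expect_error(generate_proteome(5, min_len = 10, max_len = 5), "min_len")
  # byte-identical FASTA for identical seeds
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_proteome_fasta(generate_proteome(5, seed = 1), f1)
  write_proteome_fasta(generate_proteome(5, seed = 1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the 2x2 design is balanced and partitions the samples", {
  d <- generate_design(3)
  expect_equal(nrow(d), 12)
  expect_equal(unname(table(d$treatment, d$knockdown)), matrix(3L, 2, 2))
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_equal(nrow(generate_design(1)), 4)
  expect_error(generate_design(0), "n_reps")
})

test_that("the noise-free limit recovers planted fold changes exactly", {
  tp <- truth_params(rep_sigma = 0, censor_mid = -Inf, seed = 5)
  sim <- simulate_cargo_experiment(80, 3, tp)
  ib <- suppressWarnings(compute_ibaq(sim$peptides, sim$proteome))
  lmat <- log2_transform(ib)
  cs <- design_contrasts(sim$design)
  fc <- contrast_fold_change(lmat, cs$ctrl)
  planted <- sim$truth$fc_ctrl[match(fc$protein, sim$truth$id)]
  expect_equal(fc$fc, planted, tolerance = 1e-12)
})

test_that("planted class labels are consistent with planted fold changes", {
  tp <- truth_params(seed = 9)
  sim <- simulate_cargo_experiment(400, 3, tp)
  tr <- sim$truth
  d <- tr$fc_kd - tr$fc_ctrl
  expect_true(all(tr$fc_ctrl[tr$class == "ATE1_loaded"] > 1 &
                    d[tr$class == "ATE1_loaded"] < -0.3))
  expect_true(all(tr$fc_ctrl[tr$class == "ATE1_excluded"] < 1 &
                    d[tr$class == "ATE1_excluded"] > 0.3))
  expect_true(all(d[tr$class == "ATE1_independent"] == 0))
  expect_true(all(tr$fc_ctrl[tr$class == "unregulated"] == 1 &
                    tr$fc_kd[tr$class == "unregulated"] == 1))
})

test_that("simulation is deterministic given the seed", {
  tp <- truth_params(seed = 21)
  s1 <- simulate_cargo_experiment(40, 2, tp)
  s2 <- simulate_cargo_experiment(40, 2, tp)
  expect_identical(s1, s2)
})

test_that("logistic censoring at the median removes about half the measurements", {
  # same seed without censoring exposes the underlying intensities, because
  # censoring draws happen after all intensity draws
  tp0 <- truth_params(rep_sigma = 0.3, censor_mid = -Inf, seed = 13,
                      frac_ate1_dependent = 0, frac_independent = 0)
  sim0 <- simulate_cargo_experiment(150, 3, tp0)
  x <- log2(as.matrix(sim0$peptides[sim0$design$sample_id]))
  m <- stats::median(x)
  tp1 <- tp0; tp1$censor_mid <- m; tp1$censor_tau <- 1
  sim1 <- simulate_cargo_experiment(150, 3, tp1)
  y <- as.matrix(sim1$peptides[sim1$design$sample_id])
  # collapse of duplicate fragments can merge rows; require a large count
  n <- length(y)
  expect_gt(n, 1e4)
  p_model <- stats::plogis((m - x) / 1)
  expected <- mean(p_model)
  se <- sqrt(sum(p_model * (1 - p_model))) / n
  miss_rate <- mean(is.na(y))
  expect_lt(abs(miss_rate - expected), 3 * se + 0.01)
  expect_lt(abs(miss_rate - 0.5), 0.05)
})

test_that("missingness increases as underlying intensity decreases", {
  tp <- truth_params(censor_mid = 20, censor_tau = 1, rep_sigma = 0.3, seed = 17)
  tp0 <- tp; tp0$censor_mid <- -Inf
  sim0 <- simulate_cargo_experiment(100, 3, tp0)
  sim1 <- simulate_cargo_experiment(100, 3, tp)
  x <- log2(as.matrix(sim0$peptides[sim0$design$sample_id]))
  y <- as.matrix(sim1$peptides[sim1$design$sample_id])
  terc <- cut(x, stats::quantile(x, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
              labels = c("low", "mid", "high"))
  rates <- tapply(is.na(y), terc, mean)
  expect_gt(rates["low"], rates["mid"])
  expect_gt(rates["mid"], rates["high"])
})

test_that("a fully censored table is flagged", {
  tp <- truth_params(censor_mid = 1e6, censor_tau = 1e-9, seed = 1)
  expect_warning(simulate_experiment(generate_proteome(5, seed = 1),
                                     generate_design(1), tp),
                 "fully missing")
})
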