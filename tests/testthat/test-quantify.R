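# In-silico digestion, observable-peptide counting, and iBAQ roll-up.

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_identical(digest_tryptic("AKRPGKTR"), c("AK", "RPGK", "TR"))
  expect_identical(digest_tryptic("KK"), c("K", "K"))
  expect_identical(digest_tryptic("MALWMNV"), "MALWMNV")  # no K/R
  expect_error(digest_tryptic("AKZ"), "illegal residue")
  expect_error(digest_tryptic(""), "non-empty")
})

test_that("fully cleaved peptides concatenate to the input, matching the regex oracle", {
  set.seed(41)
  for (i in 1:50) {
    s <- random_aa_seq(sample(5:120, 1))
    frags <- digest_tryptic(s)
    expect_identical(paste(frags, collapse = ""), s)
    expect_identical(frags, digest_oracle(s))
  }
})

test_that("missed cleavages add every run of adjacent fragments", {
  frags <- digest_tryptic("AKRPGKTR", 1)
  expect_setequal(frags, c("AK", "RPGK", "TR", "AKRPGK", "RPGKTR"))
  frags2 <- digest_tryptic("AKRPGKTR", 2)
  expect_setequal(frags2, c(frags, "AKRPGKTR"))
  # requesting more missed cleavages than sites is harmless
  expect_setequal(digest_tryptic("AKRPGKTR", 10), frags2)
})

test_that("observable-peptide counts match exhaustive enumeration on the window", {
  expect_equal(count_observable("AKRPGKTR", 7, 30), 0)
  expect_equal(count_observable("AKRPGKTR", 2, 4), 3)
  expect_equal(count_observable("MALWM", 7, 30), 0)  # shorter than window
  expect_error(count_observable("AK", 5, 3), "min_len")
  set.seed(42)
  for (i in 1:40) {
    s <- random_aa_seq(sample(3:60, 1))
    lo <- sample(1:5, 1); hi <- lo + sample(0:20, 1)
    lens <- nchar(digest_oracle(s))
    expect_equal(count_observable(s, lo, hi), sum(lens >= lo & lens <= hi))
  }
})

test_that("iBAQ divides summed peptide intensity by the observable count", {
  proteome <- data.frame(id = "P1",
                         sequence = paste0("AAAGGGK", "CCCDDDR", "EEEFFFK", "MW"))
  # three fully cleaved peptides of length 7 plus a terminal dipeptide: N_obs = 3
  peptides <- data.frame(
    sequence = c("AAAGGGK", "CCCDDDR", "EEEFFFK"),
    protein = "P1",
    s1 = c(1e9, 1e9, 1e9),
    s2 = c(2e9, NA, NA),
    s3 = c(NA_real_, NA_real_, NA_real_))
  ib <- compute_ibaq(peptides, proteome)
  expect_equal(unname(ib$n_obs["P1"]), 3)
  expect_equal(ib$ibaq["P1", "s1"], 1e9)
  expect_equal(ib$ibaq["P1", "s2"], 2e9 / 3)
  expect_true(is.na(ib$ibaq["P1", "s3"]))  # no peptide observed
})

test_that("iBAQ is homogeneous of degree 1 and fold changes survive rescaling", {
  sim <- simulate_cargo_experiment(30, 2, truth_params(seed = 11))
  ib1 <- suppressWarnings(compute_ibaq(sim$peptides, sim$proteome))
  doubled <- sim$peptides
  sc <- sim$design$sample_id
  doubled[sc] <- doubled[sc] * 2
  ib2 <- suppressWarnings(compute_ibaq(doubled, sim$proteome))
  expect_equal(ib2$ibaq, ib1$ibaq * 2)
  # global rescaling cancels in ratios
  r1 <- ib1$ibaq[, 1] / ib1$ibaq[, 2]
  r2 <- ib2$ibaq[, 1] / ib2$ibaq[, 2]
  expect_equal(r1, r2)
})

test_that("shared peptides are dropped with a warning and orphan proteins rejected", {
  proteome <- data.frame(id = c("P1", "P2"),
                         sequence = c("AAAGGGKCCCDDDR", "AAAGGGKEEEFFFR"))
  peptides <- data.frame(sequence = c("AAAGGGK", "AAAGGGK", "CCCDDDR"),
                         protein = c("P1", "P2", "P1"),
                         s1 = c(1e9, 1e9, 4e9), s2 = c(1e9, 1e9, 6e9))
  expect_warning(ib <- compute_ibaq(peptides, proteome), "shared")
  expect_equal(rownames(ib$ibaq), "P1")
  expect_equal(ib$ibaq["P1", "s1"], 4e9 / 2)  # N_obs("P1") = 2
  bad <- data.frame(sequence = "CCCDDDR", protein = "P9", s1 = 1e9)
  expect_error(compute_ibaq(bad, proteome), "not in proteome")
})

test_that("proteins with zero observable peptides are excluded and reported", {
  proteome <- data.frame(id = c("P1", "P2"),
                         sequence = c("AKAKAKAK", "AAAGGGKCCCDDDR"))
  peptides <- data.frame(sequence = c("AK", "AAAGGGK"),
                         protein = c("P1", "P2"),
                         s1 = c(1e9, 2e9), s2 = c(1e9, 2e9))
  expect_warning(ib <- compute_ibaq(peptides, proteome), "zero observable")
  expect_identical(ib$excluded, "P1")
  expect_identical(rownames(ib$ibaq), "P2")
  expect_error(suppressWarnings(compute_ibaq(peptides[1, ], proteome[1, ])),
               "no quantifiable proteins")
})
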