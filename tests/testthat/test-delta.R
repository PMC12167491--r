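# The delta fold change and the classification / candidate cascade.

make_diff_tab <- function(protein, fc, p) {
  data.frame(protein = protein, fc = fc, log2fc = log2(fc), t = 0, p = p,
             q = p, significant = p < 0.05, degenerate = FALSE)
}

test_that("delta is the difference of linear fold changes", {
  expect_equal(delta_fold_change(2.1, 0.6), -1.5)
  expect_equal(delta_fold_change(1.7, 1.7), 0)
  expect_equal(delta_fold_change(1.0, 1.8), 0.8)
  expect_error(delta_fold_change(0, 1), "strictly positive")
  expect_error(delta_fold_change(2, -1), "strictly positive")
  expect_error(delta_fold_change(2, Inf), "strictly positive")
})

test_that("the cascade classifies the reference cases", {
  ctrl <- make_diff_tab(c("ANXA1", "BOUND", "FLAT", "NOSIG"),
                        fc = c(2.1, 1.2, 1.0, 3.0),
                        p = c(0.01, 0.01, 0.01, 0.2))
  kd <- make_diff_tab(c("ANXA1", "BOUND", "FLAT", "NOSIG"),
                      fc = c(0.6, 0.9, 1.0, 3.0),
                      p = rep(0.5, 4))
  d <- classify_cargo(ctrl, kd)
  r <- function(p) d[d$protein == p, ]
  # up-regulated, delta = -1.5: loading requires the transferase; candidate
  expect_equal(r("ANXA1")$delta, -1.5)
  expect_equal(r("ANXA1")$direction, "up")
  expect_equal(r("ANXA1")$ate1_class, "ATE1_loaded")
  expect_true(r("ANXA1")$candidate)
  # delta exactly at the band edge is independent (strict inequalities)
  expect_equal(r("BOUND")$delta, -0.3)
  expect_equal(r("BOUND")$ate1_class, "ATE1_independent")
  # FC = 1 and non-significant rows are unregulated with no class
  expect_equal(r("FLAT")$direction, "unregulated")
  expect_true(is.na(r("FLAT")$ate1_class))
  expect_equal(r("NOSIG")$direction, "unregulated")
})

test_that("down-regulated proteins mirror the classification", {
  ctrl <- make_diff_tab(c("EXCL", "DEEP", "IND"),
                        fc = c(0.5, 0.5, 0.5), p = rep(0.01, 3))
  kd <- make_diff_tab(c("EXCL", "DEEP", "IND"),
                      fc = c(1.4, 0.1, 0.6), p = rep(0.5, 3))
  d <- classify_cargo(ctrl, kd)
  expect_equal(d$direction, rep("down", 3))
  expect_equal(d$ate1_class[d$protein == "EXCL"], "ATE1_excluded")
  expect_equal(d$ate1_class[d$protein == "DEEP"], "ATE1_loaded")
  expect_equal(d$ate1_class[d$protein == "IND"], "ATE1_independent")
  expect_false(any(d$candidate))
})

test_that("classes partition regulated proteins and candidates nest in the up set", {
  set.seed(43)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  ctrl <- make_diff_tab(ids, fc = 2^rnorm(n, 0, 1), p = runif(n))
  kd <- make_diff_tab(ids, fc = 2^rnorm(n, 0, 1), p = runif(n))
  d <- classify_cargo(ctrl, kd)
  reg <- d$direction != "unregulated"
  expect_true(all(!is.na(d$ate1_class[reg])))
  expect_true(all(is.na(d$ate1_class[!reg])))
  cands <- select_candidates(d)
  loaded_up <- d$protein[reg & d$direction == "up" &
                           d$ate1_class == "ATE1_loaded"]
  expect_true(all(cands$protein %in% loaded_up))
  expect_true(all(loaded_up %in% d$protein[d$direction == "up"]))
  expect_identical(cands$candidate, rep(TRUE, nrow(cands)))
  expect_error(classify_cargo(ctrl[0, ], kd), "no proteins")
})

test_that("raising FC_kd never moves a loaded protein toward candidacy", {
  fc_kd_seq <- seq(0.2, 3, by = 0.1)
  cand <- vapply(fc_kd_seq, function(f) {
    d <- classify_cargo(make_diff_tab("P", 2.5, 0.01),
                        make_diff_tab("P", f, 0.5))
    d$candidate
  }, logical(1))
  expect_true(all(diff(as.integer(cand)) <= 0))  # TRUE...TRUE FALSE...FALSE
})

test_that("candidate selection applies strict gates and deterministic ordering", {
  ctrl <- make_diff_tab(c("A", "B", "C", "D", "E"),
                        fc = c(2.1, 1.9, 2.5, 4.0, 4.0),
                        p = c(0.01, 0.01, 0.01, 0.01, 0.01))
  kd <- make_diff_tab(c("A", "B", "C", "D", "E"),
                      fc = c(0.6, 0.4, 1.6, 2.5, 2.5),
                      p = rep(0.5, 5))
  d <- classify_cargo(ctrl, kd)
  cands <- select_candidates(d)
  # B fails the FC gate, C fails the delta gate (-0.9); D/E tie on delta
  expect_identical(cands$protein, c("A", "D", "E"))
  expect_equal(cands$delta, c(-1.5, -1.5, -1.5))
})

test_that("delta summaries report means per direction and absent sets as NA", {
  ctrl <- make_diff_tab(c("A", "B", "C"), fc = c(2, 3, 2.5),
                        p = rep(0.01, 3))
  kd <- make_diff_tab(c("A", "B", "C"), fc = c(0.5, 2.5, 2.8),
                      p = rep(0.5, 3))
  d <- classify_cargo(ctrl, kd)
  s <- summarize_delta(d)
  expect_equal(s$n_up, 3)
  expect_equal(s$mean_delta_up, mean(c(0.5 - 2, 2.5 - 3, 2.8 - 2.5)))
  expect_true(is.na(s$mean_delta_down))
  expect_equal(s$n_down, 0)
  expect_equal(s$n_loaded_in_up, 2)      # deltas -1.5 and -0.5 fall below -0.3
  expect_equal(s$n_abs_delta_gt_sig, 2)  # |-1.5| and |-0.5| exceed 0.3; |0.3| does not
})

test_that("a log2-scale delta mode is available but non-default", {
  ctrl <- make_diff_tab("P", 2.1, 0.01)
  kd <- make_diff_tab("P", 0.6, 0.5)
  d_lin <- classify_cargo(ctrl, kd)
  d_log <- classify_cargo(ctrl, kd, delta_scale = "log2")
  expect_equal(d_lin$delta, -1.5)
  expect_equal(d_log$delta, log2(0.6) - log2(2.1))
})
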