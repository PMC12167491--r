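# The central statistic: the delta fold change (difference between a
# protein's oxidant-response fold change in the knockdown arm and in the
# control arm) and the classification / candidate cascade built on it.

#' Thresholds of the cargo classification cascade
#'
#' All comparisons against these thresholds are strict.
#'
#' @param delta_sig Significance band half-width on the delta fold change
#'   (default 0.3: deltas greater than +0.3 or less than -0.3 count as
#'   knockdown-dependent).
#' @param fc_candidate Minimum control-arm linear fold change for the
#'   candidate filter (default 2).
#' @param delta_candidate Maximum delta for the candidate filter
#'   (default -1).
#' @param alpha Significance level on the raw t-test p-value (default 0.05).
#' @return A list of class `cargo_thresholds`.
#' @export
cargo_thresholds <- function(delta_sig = 0.3, fc_candidate = 2,
                             delta_candidate = -1, alpha = 0.05) {
  stopifnot(delta_sig > 0, fc_candidate > 1, delta_candidate < 0,
            alpha > 0, alpha < 1)
  structure(list(delta_sig = delta_sig, fc_candidate = fc_candidate,
                 delta_candidate = delta_candidate, alpha = alpha),
            class = "cargo_thresholds")
}

#' Delta fold change
#'
#' The difference of two linear fold changes: the knockdown-arm FC minus
#' the control-arm FC. A negative delta means the protein's
#' oxidant-induced loading is lost when the transferase is silenced.
#'
#' @param fc_ctrl,fc_kd Linear fold changes (vectors of equal length; all
#'   values finite and strictly positive).
#' @return `fc_kd - fc_ctrl` (vectorized).
#' @examples
#' delta_fold_change(2.1, 0.6)  # -1.5
#' @export
delta_fold_change <- function(fc_ctrl, fc_kd) {
  if (length(fc_ctrl) != length(fc_kd)) {
    stop("`fc_ctrl` and `fc_kd` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(fc_ctrl)) || any(!is.finite(fc_kd)) ||
      any(fc_ctrl <= 0) || any(fc_kd <= 0)) {
    stop("fold changes must be finite and strictly positive", call. = FALSE)
  }
  fc_kd - fc_ctrl
}

#' Classify proteins by knockdown dependence of their exosomal loading
#'
#' Direction is taken from the control-arm contrast: `up` requires
#' significance (p < alpha) and FC_ctrl > 1, `down` significance and
#' FC_ctrl < 1, everything else is `unregulated`. Within the up set, a
#' delta below `-delta_sig` marks `ATE1_loaded` cargo (loading requires
#' the transferase), above `+delta_sig` marks `ATE1_excluded`, otherwise
#' `ATE1_independent`. The down set mirrors this: a delta above
#' `+delta_sig` (depletion lost on knockdown) is `ATE1_excluded`, below
#' `-delta_sig` is `ATE1_loaded`, otherwise `ATE1_independent`.
#'
#' @param ctrl,kd Differential tables from [differential_table()] for the
#'   control-arm and knockdown-arm contrasts; only their shared protein
#'   set is classified.
#' @param thr A [cargo_thresholds()].
#' @param delta_scale `"linear"` (default; deltas of linear FCs) or
#'   `"log2"` (deltas of log2 FCs, non-default alternative).
#' @return Delta table: data frame with `protein`, `fc_ctrl`, `p_ctrl`,
#'   `sig_ctrl`, `fc_kd`, `p_kd`, `delta`, `direction`, `ate1_class`
#'   (`NA` for unregulated proteins), `candidate`.
#' @export
classify_cargo <- function(ctrl, kd, thr = cargo_thresholds(),
                           delta_scale = c("linear", "log2")) {
  delta_scale <- match.arg(delta_scale)
  stopifnot(inherits(thr, "cargo_thresholds"))
  shared <- intersect(ctrl$protein, kd$protein)
  if (!length(shared)) {
    stop("the two contrasts share no proteins", call. = FALSE)
  }
  ctrl <- ctrl[match(shared, ctrl$protein), ]
  kd <- kd[match(shared, kd$protein), ]
  delta <- if (delta_scale == "linear") {
    delta_fold_change(ctrl$fc, kd$fc)
  } else {
    kd$log2fc - ctrl$log2fc
  }
  direction <- ifelse(!ctrl$significant | ctrl$fc == 1, "unregulated",
                      ifelse(ctrl$fc > 1, "up", "down"))
  ate1_class <- rep(NA_character_, length(shared))
  reg <- direction != "unregulated"
  ate1_class[reg & delta < -thr$delta_sig] <- "ATE1_loaded"
  ate1_class[reg & delta > thr$delta_sig] <- "ATE1_excluded"
  ate1_class[reg & abs(delta) <= thr$delta_sig] <- "ATE1_independent"
  out <- data.frame(protein = shared,
                    fc_ctrl = ctrl$fc, p_ctrl = ctrl$p,
                    sig_ctrl = ctrl$significant,
                    fc_kd = kd$fc, p_kd = kd$p,
                    delta = delta, direction = direction,
                    ate1_class = ate1_class, row.names = NULL)
  out$candidate <- out$direction == "up" & out$sig_ctrl &
    out$fc_ctrl > thr$fc_candidate & out$delta < thr$delta_candidate
  attr(out, "thresholds") <- thr
  attr(out, "delta_scale") <- delta_scale
  out
}

#' Select candidate cargo proteins
#'
#' Candidates are significantly up-regulated proteins whose control-arm
#' fold change exceeds `fc_candidate` and whose delta falls below
#' `delta_candidate` (both strict), sorted by ascending delta with ties
#' broken lexicographically by protein id.
#'
#' @param delta A delta table from [classify_cargo()].
#' @param thr A [cargo_thresholds()].
#' @return The candidate rows of `delta`, sorted.
#' @export
select_candidates <- function(delta, thr = cargo_thresholds()) {
  sel <- delta$direction == "up" & delta$sig_ctrl &
    delta$fc_ctrl > thr$fc_candidate & delta$delta < thr$delta_candidate
  out <- delta[sel, , drop = FALSE]
  out[order(out$delta, out$protein), , drop = FALSE]
}

#' Summary statistics of a delta table
#'
#' Mean delta over the up- and down-regulated sets, class counts, and the
#' two alternative knockdown-dependence tallies (delta < -delta_sig within
#' the up set vs |delta| > delta_sig overall) which need not agree and are
#' both reported.
#'
#' @param delta A delta table from [classify_cargo()].
#' @param thr A [cargo_thresholds()].
#' @return List with `n_up`, `n_down`, `n_unregulated`, `mean_delta_up`,
#'   `mean_delta_down` (`NA` marks an absent/empty set, never reported as
#'   zero), `class_counts`, `n_loaded_in_up`, `n_abs_delta_gt_sig`,
#'   `n_candidates`.
#' @export
summarize_delta <- function(delta, thr = cargo_thresholds()) {
  up <- delta$delta[delta$direction == "up"]
  down <- delta$delta[delta$direction == "down"]
  list(
    n_up = length(up),
    n_down = length(down),
    n_unregulated = sum(delta$direction == "unregulated"),
    mean_delta_up = if (length(up)) mean(up) else NA_real_,
    mean_delta_down = if (length(down)) mean(down) else NA_real_,
    class_counts = table(factor(delta$ate1_class,
                                levels = c("ATE1_loaded", "ATE1_excluded",
                                           "ATE1_independent"))),
    n_loaded_in_up = sum(delta$direction == "up" &
                           delta$delta < -thr$delta_sig),
    n_abs_delta_gt_sig = sum(delta$direction != "unregulated" &
                               abs(delta$delta) > thr$delta_sig),
    n_candidates = sum(delta$candidate)
  )
}
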