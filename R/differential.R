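# Per-contrast differential statistics: fold changes and row-wise
# two-sample t-tests on the imputed log2 matrix.

#' Define a contrast between two sample groups
#'
#' @param name Contrast label.
#' @param numerator,denominator Disjoint, non-empty character vectors of
#'   sample ids; the fold change is numerator over denominator.
#' @return A list of class `contrast`.
#' @export
contrast <- function(name, numerator, denominator) {
  if (!length(numerator) || !length(denominator)) {
    stop("contrast groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(numerator, denominator))) {
    stop("contrast groups must be disjoint", call. = FALSE)
  }
  structure(list(name = name, numerator = as.character(numerator),
                 denominator = as.character(denominator)),
            class = "contrast")
}

#' The two oxidant-vs-vehicle contrasts of the 2x2 design
#'
#' One contrast per knockdown arm: oxidant over vehicle within siCtrl
#' (`ctrl`) and within siATE1 (`kd`).
#'
#' @param design A design table from [generate_design()] or
#'   [read_design()].
#' @return Named list of two [contrast()] objects (`ctrl`, `kd`).
#' @export
design_contrasts <- function(design) {
  pick <- function(tr, kd) design$sample_id[design$treatment == tr &
                                              design$knockdown == kd]
  list(
    ctrl = contrast("oxidant_vs_vehicle.siCtrl",
                    pick("oxidant", "siCtrl"), pick("vehicle", "siCtrl")),
    kd = contrast("oxidant_vs_vehicle.siATE1",
                  pick("oxidant", "siATE1"), pick("vehicle", "siATE1"))
  )
}

#' Per-protein fold change for a contrast
#'
#' On the default geometric scale, `log2FC` is the difference of group
#' means of log2 values and the linear FC is `2^log2FC` (a geometric-mean
#' ratio). The `arithmetic` scale instead ratios the arithmetic means of
#' the linear intensities.
#'
#' @param matrix A complete (imputed) `log_matrix`.
#' @param contrast A [contrast()].
#' @param fc_scale `"geometric"` (default) or `"arithmetic"`.
#' @return Data frame with `protein`, `fc`, `log2fc`.
#' @export
contrast_fold_change <- function(matrix, contrast,
                                 fc_scale = c("geometric", "arithmetic")) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(inherits(matrix, "log_matrix"), inherits(contrast, "contrast"))
  vals <- matrix$values
  if (anyNA(vals)) stop("fold changes require a complete (imputed) matrix",
                        call. = FALSE)
  num <- vals[, contrast$numerator, drop = FALSE]
  den <- vals[, contrast$denominator, drop = FALSE]
  if (fc_scale == "geometric") {
    log2fc <- rowMeans(num) - rowMeans(den)
    fc <- 2^log2fc
  } else {
    fc <- rowMeans(2^num) / rowMeans(2^den)
    log2fc <- log2(fc)
  }
  data.frame(protein = rownames(vals), fc = fc, log2fc = log2fc,
             row.names = NULL)
}

#' Row-wise two-sample t-tests
#'
#' Student's pooled-variance test by default (the Perseus two-sample
#' default); Welch's unequal-variance variant optionally. Degenerate rows
#' with zero variance in both groups give t = 0, p = 1 when the means are
#' equal and p = 0 flagged `degenerate` when they differ.
#'
#' @param matrix A complete `log_matrix`.
#' @param contrast A [contrast()] with at least two samples per group.
#' @param variant `"student"` (default) or `"welch"`.
#' @return Data frame with `protein`, `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_t <- function(matrix, contrast, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(matrix, "log_matrix"), inherits(contrast, "contrast"))
  vals <- matrix$values
  if (anyNA(vals)) stop("t-tests require a complete (imputed) matrix",
                        call. = FALSE)
  x <- vals[, contrast$numerator, drop = FALSE]
  y <- vals[, contrast$denominator, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) {
    stop("each contrast group needs at least 2 samples", call. = FALSE)
  }
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  if (variant == "student") {
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2L, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  }
  delta <- mx - my
  tstat <- delta / se
  degenerate <- se == 0 & delta != 0
  tstat[se == 0 & delta == 0] <- 0
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0 & delta == 0] <- 1
  p[degenerate] <- 0
  df[se == 0] <- nx + ny - 2L
  data.frame(protein = rownames(vals), t = tstat, df = df, p = p,
             degenerate = degenerate, row.names = NULL)
}

#' Differential table for one contrast
#'
#' Joins fold changes and t-test results; a protein is `significant` iff
#' its raw p-value is strictly below `alpha` (no multiple-testing
#' correction in the headline call, matching the Perseus-style workflow);
#' BH q-values are reported alongside for transparency.
#'
#' @param matrix A complete `log_matrix` (filtered and imputed for this
#'   contrast's samples).
#' @param design Design table used to resolve `contrast` when given by
#'   name.
#' @param contrast A [contrast()] object, or one of `"ctrl"`/`"kd"`
#'   resolved via [design_contrasts()].
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param variant,fc_scale Passed to [two_sample_t()] and
#'   [contrast_fold_change()].
#' @return Data frame with columns `protein`, `fc`, `log2fc`, `t`, `p`,
#'   `q`, `significant`, `n_obs_num`, `n_obs_den` (observed counts before
#'   imputation).
#' @export
differential_table <- function(matrix, design = NULL, contrast = "ctrl",
                               alpha = 0.05, variant = "student",
                               fc_scale = "geometric") {
  if (is.character(contrast)) {
    if (is.null(design)) {
      stop("`design` is required to resolve a contrast by name", call. = FALSE)
    }
    cs <- design_contrasts(design)
    if (!contrast %in% names(cs)) {
      stop(sprintf("unknown contrast name '%s' (expected one of: %s)",
                   contrast, paste(names(cs), collapse = ", ")), call. = FALSE)
    }
    contrast <- cs[[contrast]]
  }
  stopifnot(inherits(contrast, "contrast"))
  fc <- contrast_fold_change(matrix, contrast, fc_scale = fc_scale)
  tt <- two_sample_t(matrix, contrast, variant = variant)
  out <- merge(fc, tt[c("protein", "t", "p", "degenerate")], by = "protein",
               sort = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out$n_obs_num <- rowSums(matrix$observed[out$protein, contrast$numerator,
                                           drop = FALSE])
  out$n_obs_den <- rowSums(matrix$observed[out$protein, contrast$denominator,
                                           drop = FALSE])
  attr(out, "contrast") <- contrast$name
  out
}

#' Filter, impute and test one contrast of the full matrix
#'
#' The valid-value filter is applied per contrast using that contrast's two
#' groups (the "2/3 valid values in each group" rule), then missing values
#' are imputed column-wise and the differential table computed.
#'
#' @param matrix Full `log_matrix` over all samples.
#' @param contrast A [contrast()].
#' @param cfg A [preprocess_config()].
#' @param ... Passed to [differential_table()] (`alpha`, `variant`,
#'   `fc_scale`).
#' @return A differential table (see [differential_table()]).
#' @export
analyze_contrast <- function(matrix, contrast, cfg = preprocess_config(), ...) {
  stopifnot(inherits(contrast, "contrast"))
  groups <- list(numerator = contrast$numerator,
                 denominator = contrast$denominator)
  filtered <- filter_valid(matrix, groups, cfg)
  imputed <- impute_downshift(filtered, cfg)
  out <- differential_table(imputed, contrast = contrast, ...)
  attr(out, "n_filtered_out") <- attr(filtered, "n_removed")
  attr(out, "n_imputed") <- attr(imputed, "n_imputed")
  out
}
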