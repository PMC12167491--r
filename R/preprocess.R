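# Perseus-style preprocessing: log2 transform, valid-value filtering, and
# seeded down-shifted-normal imputation of left-censored missing values.

#' Preprocessing configuration
#'
#' @param min_valid_frac Minimum fraction of observed values required in
#'   every group for a protein to be retained (default 2/3, i.e. at least 2
#'   of 3 replicates; applied with a ceiling).
#' @param impute_width Width of the imputation distribution as a multiple
#'   of the column SD (default 0.3).
#' @param impute_downshift Down-shift of the imputation distribution mean
#'   as a multiple of the column SD (default 1.8).
#' @param seed RNG seed for imputation draws.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_valid_frac = 2 / 3, impute_width = 0.3,
                              impute_downshift = 1.8, seed = 1L) {
  assert_fraction(min_valid_frac, "min_valid_frac")
  if (!is.numeric(impute_width) || impute_width < 0) {
    stop("`impute_width` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(impute_downshift) || impute_downshift < 0) {
    stop("`impute_downshift` must be >= 0", call. = FALSE)
  }
  structure(list(min_valid_frac = min_valid_frac, impute_width = impute_width,
                 impute_downshift = impute_downshift, seed = as.integer(seed)),
            class = "preprocess_config")
}

as_log_matrix <- function(values, observed) {
  stopifnot(is.matrix(values), is.matrix(observed),
            identical(dim(values), dim(observed)))
  structure(list(values = values, observed = observed), class = "log_matrix")
}

#' @export
print.log_matrix <- function(x, ...) {
  cat(sprintf("log_matrix: %d proteins x %d samples, %d/%d observed\n",
              nrow(x$values), ncol(x$values), sum(x$observed),
              length(x$observed)))
  invisible(x)
}

#' Log2-transform an iBAQ matrix
#'
#' @param ibaq An `ibaq_matrix` from [compute_ibaq()] or a plain protein x
#'   sample numeric matrix with `NA` for missing.
#' @return A `log_matrix`: list with `values` (log2 scale, `NA` = missing)
#'   and `observed` (logical mask of originally observed entries).
#' @export
log2_transform <- function(ibaq) {
  mat <- if (inherits(ibaq, "ibaq_matrix")) ibaq$ibaq else ibaq
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`ibaq` must be an ibaq_matrix or a numeric matrix", call. = FALSE)
  }
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive intensity for protein '%s' in sample '%s'",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]),
         call. = FALSE)
  }
  as_log_matrix(log2(mat), !is.na(mat))
}

#' Valid-value filtering
#'
#' Retains a protein iff in every supplied group the number of originally
#' observed values is at least `ceiling(min_valid_frac * group size)` —
#' with the defaults, at least 2 of 3 replicates per group.
#'
#' @param matrix A `log_matrix`.
#' @param groups Named list of character vectors of sample ids (one vector
#'   per group; typically the two sides of a contrast).
#' @param cfg A [preprocess_config()].
#' @return The filtered `log_matrix`, columns restricted to the group
#'   samples (attribute `n_removed` records the number of dropped proteins).
#' @export
filter_valid <- function(matrix, groups, cfg = preprocess_config()) {
  stopifnot(inherits(matrix, "log_matrix"), is.list(groups))
  if (!length(groups) || any(!lengths(groups))) {
    stop("every group must contain at least one sample", call. = FALSE)
  }
  samples <- unlist(groups, use.names = FALSE)
  missing_cols <- setdiff(samples, colnames(matrix$values))
  if (length(missing_cols)) {
    stop(sprintf("group sample(s) absent from matrix: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(matrix$values))
  for (g in groups) {
    need <- ceiling(cfg$min_valid_frac * length(g))
    keep <- keep & rowSums(matrix$observed[, g, drop = FALSE]) >= need
  }
  out <- as_log_matrix(matrix$values[keep, samples, drop = FALSE],
                       matrix$observed[keep, samples, drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Down-shifted normal imputation
#'
#' Replaces every missing entry of column `c` with an independent draw from
#' `Normal(mu_c - downshift * sigma_c, (width * sigma_c)^2)`, where `mu_c`
#' and `sigma_c` are the mean and SD of the column's observed values —
#' the Perseus "replace missing values from normal distribution" recipe for
#' left-censored label-free data. Observed entries are never altered; draws
#' are assigned to missing cells in row-major order, so results are
#' reproducible given `cfg$seed`.
#'
#' @param matrix A `log_matrix`.
#' @param cfg A [preprocess_config()]; every column must hold at least two
#'   observed values.
#' @return A complete `log_matrix` (no `NA` left); attribute `n_imputed`
#'   gives the per-column count of imputed entries.
#' @export
impute_downshift <- function(matrix, cfg = preprocess_config()) {
  stopifnot(inherits(matrix, "log_matrix"))
  vals <- matrix$values
  obs <- matrix$observed
  n_obs_col <- colSums(obs)
  if (any(n_obs_col < 2L)) {
    stop(sprintf("column(s) with fewer than 2 observed values: %s",
                 paste(colnames(vals)[n_obs_col < 2L], collapse = ", ")),
         call. = FALSE)
  }
  per_col <- colSums(!obs)
  names(per_col) <- colnames(vals)
  if (!any(!obs)) {
    out <- matrix
    attr(out, "n_imputed") <- per_col
    return(out)
  }
  mu <- vapply(seq_len(ncol(vals)), function(j) mean(vals[obs[, j], j]),
               numeric(1L))
  sg <- vapply(seq_len(ncol(vals)), function(j) sd(vals[obs[, j], j]),
               numeric(1L))
  # row-major traversal of missing cells
  miss_t <- which(t(!obs))  # index into transposed matrix = row-major order
  cols <- (miss_t - 1L) %% ncol(vals) + 1L
  draws <- with_preserved_seed(cfg$seed, rnorm(length(miss_t)))
  imputed <- (mu[cols] - cfg$impute_downshift * sg[cols]) +
    cfg$impute_width * sg[cols] * draws
  tv <- t(vals)
  tv[miss_t] <- imputed
  out <- as_log_matrix(t(tv), obs)
  attr(out, "n_imputed") <- per_col
  out
}
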