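# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures.

# a log_matrix built directly from a values matrix (NA = missing)
make_log_matrix <- function(values) {
  exocargo:::as_log_matrix(values, !is.na(values))
}

# small complete matrix over a 2-group, n-per-group layout
make_two_group_matrix <- function(a, b, proteins = NULL) {
  # a, b: matrices (proteins x reps) of log2 values
  stopifnot(nrow(a) == nrow(b))
  vals <- cbind(a, b)
  colnames(vals) <- c(paste0("A", seq_len(ncol(a))), paste0("B", seq_len(ncol(b))))
  rownames(vals) <- if (is.null(proteins)) sprintf("P%02d", seq_len(nrow(vals))) else proteins
  make_log_matrix(vals)
}

two_group_contrast <- function(na = 3, nb = 3) {
  contrast("AvsB", paste0("A", seq_len(na)), paste0("B", seq_len(nb)))
}

# strip '#' provenance headers so runs into different directories can be
# compared byte-for-byte on their numeric content
read_data_lines <- function(path) {
  grep("^#", readLines(path), value = TRUE, invert = TRUE)
}

# independent regex-based digestion oracle: cleavage sites after K/R not
# followed by P, located with a lookbehind/lookahead pattern
digest_oracle <- function(sequence) {
  cuts <- gregexpr("(?<=[KR])(?!P)", sequence, perl = TRUE)[[1L]]
  cuts <- cuts[cuts > 0L]
  n <- nchar(sequence)
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  keep <- starts <= ends
  substring(sequence, starts[keep], ends[keep])
}

# brute-force upper-tail hypergeometric p via binomial coefficients
hyper_oracle <- function(k, K, N, n) {
  js <- max(0L, n + K - N):min(n, K)
  sum(choose(K, js[js >= k]) * choose(N - K, n - js[js >= k])) / choose(N, n)
}

# BH step-up oracle: q_i = min_{j >= i} p_(j) * m / j, mapped back
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

random_aa_seq <- function(len) {
  paste(sample(exocargo:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}
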