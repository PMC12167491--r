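# iBAQ quantification: in-silico tryptic digestion, observable-peptide
# counting, and peptide-to-protein intensity roll-up.

validate_aa_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) < 1L) {
    stop("`sequence` must be a single non-empty amino-acid string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("illegal residue(s) %s in sequence; only the 20 standard residues are allowed",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  chars
}

#' In-silico tryptic digestion
#'
#' Cleaves an amino-acid sequence after every lysine (K) or arginine (R)
#' unless the following residue is proline (P), the standard trypsin rule.
#' With `missed_cleavages = m > 0` the fully cleaved fragments are returned
#' together with every run of up to `m + 1` consecutive fragments.
#'
#' @param sequence Single amino-acid string over the 20 standard residues.
#' @param missed_cleavages Maximum number of missed cleavage sites
#'   (non-negative integer; default 0, i.e. fully cleaved peptides only).
#' @return Character vector of peptides, ordered by missed-cleavage count
#'   and then by position. With `missed_cleavages = 0` the peptides
#'   concatenate exactly to the input sequence.
#' @examples
#' digest_tryptic("AKRPGKTR")          # "AK" "RPGK" "TR"
#' digest_tryptic("AKRPGKTR", 1)
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 0L) {
  chars <- validate_aa_sequence(sequence)
  missed_cleavages <- assert_count(missed_cleavages, "missed_cleavages")
  n <- length(chars)
  # cleavage after position i: residue i is K/R and residue i+1 is not P
  after <- chars %in% c("K", "R") & c(chars[-1L], "") != "P"
  ends <- unique(c(which(after), n))
  starts <- c(1L, head(ends, -1L) + 1L)
  frags <- substring(sequence, starts, ends)
  if (missed_cleavages == 0L) return(frags)
  k <- length(frags)
  out <- frags
  for (m in seq_len(min(missed_cleavages, k - 1L))) {
    runs <- vapply(seq_len(k - m), function(i) {
      paste(frags[i:(i + m)], collapse = "")
    }, character(1L))
    out <- c(out, runs)
  }
  out
}

#' Count theoretically observable tryptic peptides
#'
#' The iBAQ denominator: the number of fully cleaved tryptic peptides of a
#' protein whose length falls within the observable window (default 7-30
#' residues, the common convention for Orbitrap label-free workflows).
#'
#' @param sequence Single amino-acid string.
#' @param min_len,max_len Inclusive bounds of the observable length window.
#' @return Non-negative integer count.
#' @examples
#' count_observable("AKRPGKTR", 2, 4)  # 3
#' count_observable("AKRPGKTR")        # 0: all fragments shorter than 7
#' @export
count_observable <- function(sequence, min_len = 7L, max_len = 30L) {
  min_len <- assert_count(min_len, "min_len", min = 1L)
  max_len <- assert_count(max_len, "max_len", min = 1L)
  if (min_len > max_len) {
    stop("`min_len` must not exceed `max_len`", call. = FALSE)
  }
  len <- nchar(digest_tryptic(sequence, 0L))
  sum(len >= min_len & len <= max_len)
}

#' iBAQ protein quantification from peptide intensities
#'
#' For every protein and sample, iBAQ is the sum of the present peptide
#' intensities divided by the protein's count of theoretically observable
#' tryptic peptides. A cell is missing when no peptide of the protein was
#' observed in that sample. Peptide sequences assigned to more than one
#' protein are dropped with a warning (razor assignment is out of scope);
#' proteins with zero observable peptides are excluded and reported in the
#' `excluded` field rather than silently quantified as zero.
#'
#' @param peptides Peptide intensity table: data frame with columns
#'   `sequence`, `protein`, and one strictly positive numeric column per
#'   sample (`NA` = not observed).
#' @param proteome Data frame with columns `id` and `sequence` covering
#'   every parent protein referenced by `peptides`.
#' @param min_len,max_len Observable-peptide window passed to
#'   [count_observable()].
#' @return An object of class `ibaq_matrix`: a list with `ibaq` (protein x
#'   sample numeric matrix, `NA` = missing), `n_obs` (named observable
#'   peptide counts), `excluded` (ids with zero observable peptides) and
#'   `n_shared_dropped`.
#' @export
compute_ibaq <- function(peptides, proteome, min_len = 7L, max_len = 30L) {
  stopifnot(is.data.frame(peptides), is.data.frame(proteome))
  if (!all(c("sequence", "protein") %in% names(peptides))) {
    stop("`peptides` must have columns `sequence` and `protein`", call. = FALSE)
  }
  if (!all(c("id", "sequence") %in% names(proteome))) {
    stop("`proteome` must have columns `id` and `sequence`", call. = FALSE)
  }
  sample_cols <- setdiff(names(peptides), c("sequence", "protein"))
  if (!length(sample_cols)) {
    stop("`peptides` has no sample intensity columns", call. = FALSE)
  }
  intens <- as.matrix(peptides[sample_cols])
  storage.mode(intens) <- "double"
  if (any(intens[!is.na(intens)] <= 0)) {
    stop("peptide intensities must be strictly positive where present", call. = FALSE)
  }
  unresolved <- setdiff(unique(peptides$protein), proteome$id)
  if (length(unresolved)) {
    stop(sprintf("peptide parent protein(s) not in proteome: %s",
                 paste(head(unresolved, 5L), collapse = ", ")), call. = FALSE)
  }

  # drop peptide sequences claimed by more than one protein
  owners <- tapply(peptides$protein, peptides$sequence,
                   function(p) length(unique(p)))
  shared_seqs <- names(owners)[owners > 1L]
  n_shared <- 0L
  if (length(shared_seqs)) {
    keep <- !(peptides$sequence %in% shared_seqs)
    n_shared <- sum(!keep)
    warning(sprintf("dropped %d peptide row(s) shared between proteins", n_shared),
            call. = FALSE)
    peptides <- peptides[keep, , drop = FALSE]
    intens <- intens[keep, , drop = FALSE]
  }
  if (!nrow(peptides)) stop("no peptides left to quantify", call. = FALSE)

  prot_ids <- sort(unique(peptides$protein))
  seqs <- setNames(proteome$sequence, proteome$id)[prot_ids]
  n_obs <- vapply(seqs, count_observable, integer(1L),
                  min_len = min_len, max_len = max_len)
  names(n_obs) <- prot_ids
  excluded <- prot_ids[n_obs == 0L]
  if (length(excluded)) {
    warning(sprintf("excluded %d protein(s) with zero observable peptides: %s",
                    length(excluded), paste(head(excluded, 5L), collapse = ", ")),
            call. = FALSE)
    keep <- !(peptides$protein %in% excluded)
    peptides <- peptides[keep, , drop = FALSE]
    intens <- intens[keep, , drop = FALSE]
    prot_ids <- setdiff(prot_ids, excluded)
    n_obs <- n_obs[prot_ids]
  }
  if (!nrow(peptides)) stop("no quantifiable proteins remain", call. = FALSE)

  grp <- factor(peptides$protein, levels = prot_ids)
  sums <- rowsum(ifelse(is.na(intens), 0, intens), grp)
  counts <- rowsum((!is.na(intens)) * 1L, grp)
  ibaq <- sums / n_obs[rownames(sums)]
  ibaq[counts == 0L] <- NA_real_
  colnames(ibaq) <- sample_cols

  structure(list(ibaq = ibaq, n_obs = n_obs, excluded = excluded,
                 n_shared_dropped = n_shared),
            class = "ibaq_matrix")
}

#' @export
print.ibaq_matrix <- function(x, ...) {
  cat(sprintf("ibaq_matrix: %d proteins x %d samples (%d excluded, %d shared peptide rows dropped)\n",
              nrow(x$ibaq), ncol(x$ibaq), length(x$excluded), x$n_shared_dropped))
  invisible(x)
}
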