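# File-format adapters: FASTA proteomes, MaxQuant-style peptide and
# proteinGroups tables, design tables, annotation maps, and stage outputs.
# All tabular files are UTF-8 tab-delimited with "NA" for missing values
# and '#'-prefixed provenance header lines.

#' Write a proteome to FASTA
#'
#' @param proteome Data frame with columns `id`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$id))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a proteome from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame with columns `id` (first whitespace-delimited token
#'   of the header) and `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicate protein ids in FASTA", call. = FALSE)
  data.frame(id = ids, sequence = as.character(aa), row.names = NULL)
}

#' Write a peptide intensity table
#'
#' Tab-delimited with columns `Sequence`, `Proteins`, and one
#' `Intensity.<sample_id>` column per sample; empty cells mark missing
#' measurements.
#'
#' @param peptides Peptide table as produced by [simulate_experiment()].
#' @param path Output file.
#' @param header Optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path, header = character()) {
  sample_cols <- setdiff(names(peptides), c("sequence", "protein"))
  out <- data.frame(Sequence = peptides$sequence, Proteins = peptides$protein,
                    check.names = FALSE)
  for (s in sample_cols) {
    v <- peptides[[s]]
    out[[paste0("Intensity.", s)]] <- ifelse(is.na(v), "", format(v, digits = 15L,
                                                                  trim = TRUE,
                                                                  scientific = FALSE))
  }
  write_stage_tsv(out, path, header)
}

#' Read a peptide intensity table
#'
#' @param path Tab-delimited file in the dialect of
#'   [write_peptide_table()].
#' @param design Optional design table; when supplied, the file's sample
#'   columns must exactly cover the design's sample ids.
#' @return Peptide table (`sequence`, `protein`, one numeric column per
#'   sample, `NA` = missing).
#' @export
read_peptide_table <- function(path, design = NULL) {
  raw <- read_stage_tsv(path, colClasses = "character")
  need <- c("Sequence", "Proteins")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("file '%s': missing required column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  int_cols <- grep("^Intensity\\.", names(raw), value = TRUE)
  if (!length(int_cols)) {
    stop(sprintf("file '%s': no Intensity.<sample> columns", path), call. = FALSE)
  }
  samples <- sub("^Intensity\\.", "", int_cols)
  if (anyDuplicated(samples)) {
    stop(sprintf("file '%s': duplicate sample column(s)", path), call. = FALSE)
  }
  if (!is.null(design)) {
    extra <- setdiff(samples, design$sample_id)
    if (length(extra)) {
      stop(sprintf("file '%s': sample column(s) absent from design: %s", path,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  out <- data.frame(sequence = raw$Sequence, protein = raw$Proteins)
  for (i in seq_along(int_cols)) {
    v <- raw[[int_cols[i]]]
    v[v == "" | is.na(v)] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop(sprintf("file '%s', line %d, column '%s': unparseable number '%s'",
                   path, bad[1L] + 1L, int_cols[i], v[bad[1L]]), call. = FALSE)
    }
    if (any(!is.na(num) & num <= 0)) {
      bad <- which(!is.na(num) & num <= 0)[1L]
      stop(sprintf("file '%s', line %d, column '%s': intensities must be strictly positive",
                   path, bad + 1L, int_cols[i]), call. = FALSE)
    }
    out[[samples[i]]] <- num
  }
  out
}

#' Read a proteinGroups-style table of precomputed iBAQ values
#'
#' Protein-level input mode bypassing peptide quantification: reads a
#' MaxQuant proteinGroups.txt-like tab-delimited file using its
#' `iBAQ <sample>` (or `iBAQ.<sample>`) columns. Zero iBAQ entries are
#' treated as missing, matching MaxQuant's output convention.
#'
#' @param path Tab-delimited file with a protein id column (one of
#'   `Protein IDs`, `Majority protein IDs`, `protein`) and per-sample iBAQ
#'   columns.
#' @return An `ibaq_matrix` (with `n_obs` unavailable, set to `NA`).
#' @export
read_protein_groups <- function(path) {
  raw <- read_stage_tsv(path)
  id_col <- intersect(c("Protein IDs", "Majority protein IDs", "protein"),
                      names(raw))[1L]
  if (is.na(id_col)) {
    stop(sprintf("file '%s': no protein id column found", path), call. = FALSE)
  }
  ib_cols <- grep("^iBAQ[. ]", names(raw), value = TRUE)
  if (!length(ib_cols)) {
    stop(sprintf("file '%s': no 'iBAQ <sample>' columns", path), call. = FALSE)
  }
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    stop(sprintf("file '%s': duplicate protein ids", path), call. = FALSE)
  }
  mat <- as.matrix(raw[ib_cols])
  storage.mode(mat) <- "double"
  mat[mat == 0] <- NA_real_
  rownames(mat) <- ids
  colnames(mat) <- sub("^iBAQ[. ]", "", ib_cols)
  structure(list(ibaq = mat,
                 n_obs = setNames(rep(NA_integer_, length(ids)), ids),
                 excluded = character(), n_shared_dropped = 0L),
            class = "ibaq_matrix")
}

#' Read a design table
#'
#' @param path Tab-delimited file with columns `sample_id`, `treatment`
#'   (`vehicle`/`oxidant`), `knockdown` (`siCtrl`/`siATE1`), `replicate`.
#' @return Validated design data frame.
#' @export
read_design <- function(path) {
  d <- read_stage_tsv(path)
  need <- c("sample_id", "treatment", "knockdown", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("file '%s': missing design column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(d$sample_id)) {
    stop(sprintf("file '%s': duplicate sample_id", path), call. = FALSE)
  }
  if (!all(d$treatment %in% c("vehicle", "oxidant")) ||
      !all(d$knockdown %in% c("siCtrl", "siATE1"))) {
    stop(sprintf("file '%s': treatment must be vehicle/oxidant and knockdown siCtrl/siATE1",
                 path), call. = FALSE)
  }
  d
}

#' Read a protein-to-term annotation map
#'
#' Two tab-delimited columns `protein` and `term`, optional third column
#' `label`. GAF files are deliberately not parsed.
#'
#' @param path Annotation file.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  a <- read_stage_tsv(path)
  if (!all(c("protein", "term") %in% names(a))) {
    stop(sprintf("file '%s': annotation needs columns `protein` and `term`",
                 path), call. = FALSE)
  }
  a
}

#' Write a wide protein x sample matrix
#'
#' @param mat Numeric matrix (or `ibaq_matrix`/`log_matrix`) with protein
#'   row names; `NA` written as "NA".
#' @param path Output file.
#' @param header Optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, header = character()) {
  if (inherits(mat, "ibaq_matrix")) mat <- mat$ibaq
  if (inherits(mat, "log_matrix")) mat <- mat$values
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  write_stage_tsv(df, path, header)
}

#' Read a wide protein x sample matrix
#'
#' @param path File written by [write_matrix_tsv()].
#' @return Numeric matrix with protein row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_stage_tsv(path)
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1L]]
  mat
}

#' Per-protein z-score matrix for relative-scale heatmap export
#'
#' Standardizes each protein's log2 values across all samples,
#' `(x - mean) / sd`, ignoring missing entries; proteins observed fewer
#' than twice, or with zero spread, give `NA` rows.
#'
#' @param matrix A `log_matrix` (complete or not).
#' @return Numeric matrix of z-scores, same dimensions.
#' @export
zscore_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "log_matrix"))
  vals <- matrix$values
  mu <- rowMeans(vals, na.rm = TRUE)
  sg <- apply(vals, 1L, sd, na.rm = TRUE)
  z <- (vals - mu) / sg
  z[!is.finite(z)] <- NA_real_
  z
}
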