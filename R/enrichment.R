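# Term enrichment of protein sets: one-sided hypergeometric tests with
# Benjamini-Hochberg correction across terms.

# Upper-tail hypergeometric probability P(X >= k) for an urn with
# `term_size` annotated among `universe_size` proteins, drawing
# `selected_size`.
hypergeom_tail <- function(overlap, term_size, universe_size, selected_size) {
  phyper(overlap - 1L, term_size, universe_size - term_size, selected_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values with enforced monotonicity (a validated wrapper
#' over [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric term enrichment of a protein set
#'
#' For every term with at least one annotated protein in the universe, the
#' one-sided upper-tail hypergeometric p-value of the observed overlap with
#' the selected set, BH-corrected across terms. The universe should be the
#' set of quantified proteins surviving the valid-value filter, so that
#' detection bias does not masquerade as enrichment.
#'
#' @param selected Character vector of selected protein ids (non-empty,
#'   subset of `universe`).
#' @param universe Character vector of background protein ids.
#' @param annotation Data frame with columns `protein`, `term` and
#'   optionally `label`.
#' @return Data frame sorted by `q` then `p`: `term`, `label`, `overlap`,
#'   `selected_size`, `term_size`, `universe_size`, `p`, `q`.
#' @export
fisher_enrichment <- function(selected, universe, annotation) {
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("`universe` must be non-empty", call. = FALSE)
  if (!length(selected)) stop("`selected` must be non-empty", call. = FALSE)
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop(sprintf("selected protein(s) outside the universe: %s",
                 paste(head(extra, 5L), collapse = ", ")), call. = FALSE)
  }
  if (!all(c("protein", "term") %in% names(annotation))) {
    stop("`annotation` must have columns `protein` and `term`", call. = FALSE)
  }
  ann <- annotation[annotation$protein %in% universe, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("protein", "term")]), , drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(term = character(), label = character(),
                      overlap = integer(), selected_size = integer(),
                      term_size = integer(), universe_size = integer(),
                      p = numeric(), q = numeric()))
  }
  members <- split(ann$protein, ann$term)
  labels <- if ("label" %in% names(ann)) {
    vapply(split(as.character(ann$label), ann$term), function(x) x[1L],
           character(1L))
  } else setNames(names(members), names(members))
  term_size <- lengths(members)
  overlap <- vapply(members, function(m) length(intersect(m, selected)),
                    integer(1L))
  N <- length(universe)
  n_sel <- length(selected)
  p <- hypergeom_tail(overlap, term_size, N, n_sel)
  out <- data.frame(term = names(members), label = unname(labels[names(members)]),
                    overlap = unname(overlap), selected_size = n_sel,
                    term_size = unname(term_size), universe_size = N,
                    p = unname(p), row.names = NULL)
  out$q <- bh_fdr(out$p)
  out[order(out$q, out$p, out$term), , drop = FALSE]
}

#' Synthetic annotation map with optional planted enrichment
#'
#' Assigns random terms to proteins; terms listed in `enrich_terms` are
#' additionally planted into the proteins of `enrich_in` at rate
#' `enrich_rate`, so enrichment calls can be validated against a known
#' signal without external ontologies.
#'
#' @param proteins Character vector of protein ids.
#' @param n_terms Number of terms.
#' @param mean_terms_per_protein Expected number of random term
#'   assignments per protein.
#' @param enrich_terms Character vector of term ids to enrich (subset of
#'   the generated `TERM...` ids), or `NULL`.
#' @param enrich_in Protein ids receiving the planted terms.
#' @param enrich_rate Probability that an `enrich_in` protein carries each
#'   planted term.
#' @param seed RNG seed.
#' @return Annotation data frame (`protein`, `term`, `label`).
#' @export
simulate_annotation <- function(proteins, n_terms = 20L,
                                mean_terms_per_protein = 2,
                                enrich_terms = NULL, enrich_in = character(),
                                enrich_rate = 0.8, seed = 1L) {
  n_terms <- assert_count(n_terms, "n_terms", min = 1L)
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  with_preserved_seed(seed, {
    p_assign <- min(1, mean_terms_per_protein / n_terms)
    hit <- matrix(runif(length(proteins) * n_terms) < p_assign,
                  nrow = length(proteins))
    idx <- which(hit, arr.ind = TRUE)
    ann <- data.frame(protein = proteins[idx[, 1L]], term = terms[idx[, 2L]])
    if (!is.null(enrich_terms) && length(enrich_in)) {
      for (tm in enrich_terms) {
        take <- enrich_in[runif(length(enrich_in)) < enrich_rate]
        if (length(take)) {
          ann <- rbind(ann, data.frame(protein = take, term = tm))
        }
      }
    }
    ann <- ann[!duplicated(ann[c("protein", "term")]), , drop = FALSE]
    ann$label <- paste("synthetic term", ann$term)
    rownames(ann) <- NULL
    ann
  })
}
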