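# Synthetic-data generator: proteomes, 2x2 designs, and peptide-level
# intensity tables with planted knockdown-dependent cargo effects and
# intensity-dependent (left-censored) missingness, plus the ground truth
# needed for parameter-recovery tests.

#' Generate a synthetic proteome
#'
#' Random amino-acid sequences with residue composition uniform over the 20
#' standard residues, with an optional enrichment knob for K/R that controls
#' tryptic cleavage density and hence observable-peptide counts.
#'
#' @param n Number of proteins.
#' @param min_len,max_len Sequence length bounds (residues).
#' @param seed RNG seed.
#' @param kr_weight Relative sampling weight of K and R versus the other 18
#'   residues (1 = uniform composition).
#' @return Data frame with columns `id` (unique accessions `SYNP0001`, ...)
#'   and `sequence`.
#' @export
generate_proteome <- function(n, min_len = 50L, max_len = 400L, seed = 1L,
                              kr_weight = 1) {
  n <- assert_count(n, "n")
  min_len <- assert_count(min_len, "min_len", min = 1L)
  max_len <- assert_count(max_len, "max_len", min = 1L)
  if (min_len > max_len) stop("`min_len` must not exceed `max_len`", call. = FALSE)
  if (!is.numeric(kr_weight) || kr_weight <= 0) {
    stop("`kr_weight` must be positive", call. = FALSE)
  }
  ids <- sprintf("SYNP%04d", seq_len(n))
  if (n == 0L) return(data.frame(id = character(), sequence = character()))
  w <- rep(1, 20)
  w[AA_ALPHABET %in% c("K", "R")] <- kr_weight
  with_preserved_seed(seed, {
    lens <- sample(min_len:max_len, n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = w), collapse = "")
    }, character(1L))
    data.frame(id = ids, sequence = seqs)
  })
}

#' Generate the 2x2 factorial design
#'
#' Treatment (vehicle vs oxidant) crossed with knockdown (siCtrl vs siATE1),
#' `n_reps` replicates per cell; the default of 3 replicates matches typical
#' label-free exosome proteomics designs.
#'
#' @param n_reps Replicates per (treatment x knockdown) cell.
#' @return Data frame with columns `sample_id`, `treatment`, `knockdown`,
#'   `replicate` (4 * `n_reps` rows).
#' @export
generate_design <- function(n_reps = 3L) {
  n_reps <- assert_count(n_reps, "n_reps", min = 1L)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      treatment = c("vehicle", "oxidant"),
                      knockdown = c("siCtrl", "siATE1"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$treatment, grid$knockdown, grid$replicate),
    treatment = grid$treatment,
    knockdown = grid$knockdown,
    replicate = grid$replicate
  )
}

#' Parameters of the synthetic experiment generator
#'
#' @param frac_ate1_dependent Fraction of proteins with knockdown-dependent
#'   loading (split evenly between loaded and excluded cargoes).
#' @param frac_independent Fraction of proteins regulated by oxidant
#'   treatment identically in both knockdown arms.
#' @param base_mu,base_sigma Location/scale of per-protein base log2 iBAQ
#'   abundance.
#' @param fc_ctrl_range,fc_kd_range Linear fold-change intervals for planted
#'   effects: loaded cargoes draw FC_ctrl from `fc_ctrl_range` and FC_kd
#'   from `fc_kd_range`; excluded cargoes mirror the two.
#' @param rep_sigma Replicate noise SD (log2 units).
#' @param censor_mid Log2 peptide intensity at which a measurement is
#'   missing with probability 1/2 (`-Inf` disables censoring).
#' @param censor_tau Slope of the logistic missingness curve (log2 units).
#' @param peptide_efficiency_sigma Lognormal sdlog of per-peptide response
#'   factors (fixed per peptide across samples).
#' @param seed RNG seed.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(frac_ate1_dependent = 0.05,
                         frac_independent = 0.10,
                         base_mu = 25, base_sigma = 2,
                         fc_ctrl_range = c(2.2, 3.5),
                         fc_kd_range = c(0.4, 0.8),
                         rep_sigma = 0.3,
                         censor_mid = 17, censor_tau = 1,
                         peptide_efficiency_sigma = 1,
                         seed = 1L) {
  assert_fraction(frac_ate1_dependent, "frac_ate1_dependent")
  assert_fraction(frac_independent, "frac_independent")
  if (frac_ate1_dependent + frac_independent > 1) {
    stop("planted fractions must sum to at most 1", call. = FALSE)
  }
  stopifnot(base_sigma >= 0, rep_sigma >= 0, censor_tau >= 0,
            peptide_efficiency_sigma >= 0)
  for (r in list(fc_ctrl_range, fc_kd_range)) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop("fold-change ranges must be positive intervals c(lo, hi)", call. = FALSE)
    }
  }
  structure(list(frac_ate1_dependent = frac_ate1_dependent,
                 frac_independent = frac_independent,
                 base_mu = base_mu, base_sigma = base_sigma,
                 fc_ctrl_range = fc_ctrl_range, fc_kd_range = fc_kd_range,
                 rep_sigma = rep_sigma,
                 censor_mid = censor_mid, censor_tau = censor_tau,
                 peptide_efficiency_sigma = peptide_efficiency_sigma,
                 seed = as.integer(seed)),
            class = "truth_params")
}

runif_range <- function(n, range) runif(n, range[1], range[2])

#' Simulate a peptide-level label-free experiment with planted effects
#'
#' Generative model, in order: (i) per-protein base log2 abundance ~
#' Normal(base_mu, base_sigma^2); (ii) planted condition effects — log2
#' FC_ctrl added to oxidant samples of the siCtrl arm and log2 FC_kd to
#' oxidant samples of the siATE1 arm; (iii) replicate noise ~ Normal(0,
#' rep_sigma^2) per protein x sample; (iv) each protein's linear intensity
#' multiplied onto its observable tryptic peptides through per-peptide
#' lognormal efficiency factors fixed across samples (so within-protein
#' ratios, and hence iBAQ fold changes, are preserved); (v) MNAR censoring —
#' each peptide x sample measurement is missing with probability
#' `plogis((censor_mid - x) / censor_tau)` where `x` is its log2 intensity.
#'
#' Planted classes: `ATE1_loaded` (up under oxidant in the control arm,
#' effect lost on knockdown), `ATE1_excluded` (the mirror image),
#' `ATE1_independent` (equal regulation in both arms) and `unregulated`.
#'
#' @param proteome Data frame from [generate_proteome()].
#' @param design Data frame from [generate_design()].
#' @param truth A [truth_params()] object.
#' @param min_len,max_len Observable-peptide window used to decide which
#'   tryptic fragments carry signal (matching the quantification default).
#' @return List with `peptides` (data frame: `sequence`, `protein`, one
#'   intensity column per sample, `NA` = censored) and `truth` (data frame:
#'   `id`, `base_log2`, `fc_ctrl`, `fc_kd`, `class`).
#' @export
simulate_experiment <- function(proteome, design, truth = truth_params(),
                                min_len = 7L, max_len = 30L) {
  if (!is.data.frame(proteome) || !nrow(proteome)) {
    stop("`proteome` must be a non-empty data frame", call. = FALSE)
  }
  if (!is.data.frame(design) || !nrow(design) ||
      !all(c("sample_id", "treatment", "knockdown") %in% names(design))) {
    stop("`design` must be a design table with sample_id/treatment/knockdown",
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design", call. = FALSE)
  }
  stopifnot(inherits(truth, "truth_params"))
  n <- nrow(proteome)
  ns <- nrow(design)

  with_preserved_seed(truth$seed, {
    # planted class assignment and fold changes
    n_dep <- round(n * truth$frac_ate1_dependent)
    n_loaded <- floor(n_dep / 2); n_excluded <- n_dep - n_loaded
    n_indep <- round(n * truth$frac_independent)
    classes <- rep("unregulated", n)
    idx <- sample.int(n, n_loaded + n_excluded + n_indep)
    classes[idx[seq_len(n_loaded)]] <- "ATE1_loaded"
    if (n_excluded) classes[idx[n_loaded + seq_len(n_excluded)]] <- "ATE1_excluded"
    if (n_indep) classes[idx[n_loaded + n_excluded + seq_len(n_indep)]] <- "ATE1_independent"

    fc_ctrl <- rep(1, n); fc_kd <- rep(1, n)
    is_l <- classes == "ATE1_loaded"
    fc_ctrl[is_l] <- runif_range(sum(is_l), truth$fc_ctrl_range)
    fc_kd[is_l] <- runif_range(sum(is_l), truth$fc_kd_range)
    is_e <- classes == "ATE1_excluded"
    fc_ctrl[is_e] <- runif_range(sum(is_e), truth$fc_kd_range)
    fc_kd[is_e] <- runif_range(sum(is_e), truth$fc_ctrl_range)
    is_i <- classes == "ATE1_independent"
    if (any(is_i)) {
      up <- runif(sum(is_i)) < 0.5
      f <- ifelse(up, runif_range(sum(is_i), truth$fc_ctrl_range),
                  1 / runif_range(sum(is_i), truth$fc_ctrl_range))
      fc_ctrl[is_i] <- f; fc_kd[is_i] <- f
    }

    base <- rnorm(n, truth$base_mu, truth$base_sigma)
    oxidant <- design$treatment == "oxidant"
    arm_kd <- design$knockdown == "siATE1"
    effect <- outer(log2(fc_ctrl), oxidant & !arm_kd) +
      outer(log2(fc_kd), oxidant & arm_kd)
    noise <- if (truth$rep_sigma > 0) {
      matrix(rnorm(n * ns, 0, truth$rep_sigma), n, ns)
    } else matrix(0, n, ns)
    prot_log2 <- base + effect + noise  # protein x sample log2 intensity

    # distribute each protein over its observable tryptic peptides
    frag_list <- lapply(proteome$sequence, digest_tryptic, missed_cleavages = 0L)
    obs_list <- lapply(frag_list, function(f) {
      len <- nchar(f)
      f[len >= min_len & len <= max_len]
    })
    n_pep <- lengths(obs_list)
    keep <- n_pep > 0L
    pep_protein <- rep(proteome$id[keep], n_pep[keep])
    pep_seq <- unlist(obs_list[keep], use.names = FALSE)
    eff <- rlnorm(length(pep_seq), meanlog = 0,
                  sdlog = truth$peptide_efficiency_sigma)
    prot_row <- rep(which(keep), n_pep[keep])
    pep_log2 <- prot_log2[prot_row, , drop = FALSE] + log2(eff)

    # MNAR left-censoring, logistic in log2 intensity
    if (is.finite(truth$censor_mid)) {
      p_miss <- plogis((truth$censor_mid - pep_log2) / truth$censor_tau)
      miss <- matrix(runif(length(p_miss)) < p_miss, nrow = nrow(pep_log2))
      pep_log2[miss] <- NA_real_
    }
    intens <- 2^pep_log2
    colnames(intens) <- design$sample_id

    peptides <- data.frame(sequence = pep_seq, protein = pep_protein)
    peptides <- cbind(peptides, as.data.frame(intens))
    # collapse duplicate (sequence, protein) fragments: summed ion current
    key <- paste(peptides$sequence, peptides$protein, sep = "\r")
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      agg <- rowsum(ifelse(is.na(intens), 0, intens), key)
      cnt <- rowsum((!is.na(intens)) * 1L, key)
      agg[cnt == 0L] <- NA_real_
      ord <- key[first]
      peptides <- data.frame(sequence = peptides$sequence[first],
                             protein = peptides$protein[first])
      peptides <- cbind(peptides, as.data.frame(agg[ord, , drop = FALSE]))
      rownames(peptides) <- NULL
    }
    if (all(is.na(as.matrix(peptides[design$sample_id])))) {
      warning("simulated table is fully missing (censoring removed every measurement)",
              call. = FALSE)
    }

    truth_tab <- data.frame(id = proteome$id, base_log2 = base,
                            fc_ctrl = fc_ctrl, fc_kd = fc_kd, class = classes)
    list(peptides = peptides, truth = truth_tab)
  })
}

#' One-call synthetic cargo experiment
#'
#' Convenience wrapper: generates a proteome and design, then simulates the
#' peptide table, all from a single seed.
#'
#' @param n_proteins Number of proteins.
#' @param n_reps Replicates per design cell.
#' @param truth A [truth_params()] object; its `seed` drives all stages.
#' @param min_len,max_len Observable-peptide window.
#' @return List with `proteome`, `design`, `peptides`, `truth`.
#' @export
simulate_cargo_experiment <- function(n_proteins = 500L, n_reps = 3L,
                                      truth = truth_params(),
                                      min_len = 7L, max_len = 30L) {
  proteome <- generate_proteome(n_proteins, seed = truth$seed)
  design <- generate_design(n_reps)
  sim <- simulate_experiment(proteome, design, truth,
                             min_len = min_len, max_len = max_len)
  c(list(proteome = proteome, design = design), sim)
}
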