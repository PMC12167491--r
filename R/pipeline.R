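# End-to-end pipeline: quantify -> preprocess -> differential (both
# contrasts) -> delta classification -> enrichment, with all stage tables
# written to disk alongside a run manifest.

#' Assemble a pipeline configuration
#'
#' @param peptides Path to a peptide intensity table (mutually exclusive
#'   with `protein_groups`).
#' @param proteome Path to the proteome FASTA (required with `peptides`).
#' @param protein_groups Path to a proteinGroups-style table with
#'   precomputed iBAQ columns (bypasses peptide-level quantification).
#' @param design Path to the design table, or an in-memory design data
#'   frame.
#' @param annotation Optional path to a protein-to-term annotation map.
#' @param output_dir Directory for stage outputs (created if absent).
#' @param min_len,max_len Observable-peptide window.
#' @param preprocess A [preprocess_config()].
#' @param thresholds A [cargo_thresholds()].
#' @param fc_scale `"geometric"` or `"arithmetic"`.
#' @param t_variant `"student"` or `"welch"`.
#' @param seed Master seed; recorded in every output header and used for
#'   imputation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(peptides = NULL, proteome = NULL,
                            protein_groups = NULL, design, annotation = NULL,
                            output_dir = "exocargo_out",
                            min_len = 7L, max_len = 30L,
                            preprocess = preprocess_config(),
                            thresholds = cargo_thresholds(),
                            fc_scale = "geometric", t_variant = "student",
                            seed = 1L) {
  if (is.null(peptides) == is.null(protein_groups)) {
    stop("supply exactly one of `peptides` or `protein_groups`", call. = FALSE)
  }
  if (!is.null(peptides) && is.null(proteome)) {
    stop("`proteome` is required for peptide-level input", call. = FALSE)
  }
  preprocess$seed <- as.integer(seed)
  structure(list(peptides = peptides, proteome = proteome,
                 protein_groups = protein_groups, design = design,
                 annotation = annotation, output_dir = output_dir,
                 min_len = min_len, max_len = max_len,
                 preprocess = preprocess, thresholds = thresholds,
                 fc_scale = fc_scale, t_variant = t_variant,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; nested `preprocess`
#' and `thresholds` mappings override the corresponding defaults. Relative
#' paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  pp <- do.call(preprocess_config, c(y$preprocess, list()))
  thr <- do.call(cargo_thresholds, c(y$thresholds, list()))
  pipeline_config(
    peptides = resolve(y$peptides), proteome = resolve(y$proteome),
    protein_groups = resolve(y$protein_groups),
    design = resolve(y$design), annotation = resolve(y$annotation),
    output_dir = if (is.null(y$output_dir)) "exocargo_out" else y$output_dir,
    min_len = if (is.null(y$min_len)) 7L else y$min_len,
    max_len = if (is.null(y$max_len)) 30L else y$max_len,
    preprocess = pp, thresholds = thr,
    fc_scale = if (is.null(y$fc_scale)) "geometric" else y$fc_scale,
    t_variant = if (is.null(y$t_variant)) "student" else y$t_variant,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

#' Run the full differential cargo pipeline
#'
#' Executes quantification (or the proteinGroups bypass), per-contrast
#' preprocessing and differential statistics, the delta classification and
#' candidate cascade, optional term enrichment of the up/down/candidate
#' sets, and the relative-scale (per-protein z-score) heatmap export.
#' Every output table carries the seed and a config hash in its header;
#' two runs with the same inputs and seed produce byte-identical outputs.
#'
#' @param config A `pipeline_config` or the path to a YAML config file.
#' @return Invisibly, a list with the in-memory stage objects (`ibaq`,
#'   `log2`, `ctrl`, `kd`, `delta`, `candidates`, `summary`, `enrichment`,
#'   `zscore`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  design <- if (is.data.frame(config$design)) config$design else
    read_design(config$design)

  # provenance header shared by all outputs
  echo_path <- file.path(config$output_dir, "config_echo.yaml")
  echo <- config
  echo$design <- if (is.data.frame(config$design)) "<inline>" else config$design
  echo$preprocess <- unclass(echo$preprocess)
  echo$thresholds <- unclass(echo$thresholds)
  yaml::write_yaml(unclass(echo), echo_path)
  cfg_hash <- unname(tools::md5sum(echo_path))
  hdr <- sprintf("exocargo %s | seed=%d | config_md5=%s",
                 as.character(packageVersion("exocargo")), config$seed, cfg_hash)

  files <- c(config_echo = echo_path)
  step <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE)
    })
  }

  ibaq <- step("quantify", {
    if (!is.null(config$protein_groups)) {
      read_protein_groups(config$protein_groups)
    } else {
      proteome <- read_proteome_fasta(config$proteome)
      peptides <- read_peptide_table(config$peptides, design)
      compute_ibaq(peptides, proteome, config$min_len, config$max_len)
    }
  })
  files["ibaq"] <- file.path(config$output_dir, "ibaq_matrix.tsv")
  write_matrix_tsv(ibaq, files["ibaq"], hdr)

  lmat <- step("preprocess", log2_transform(ibaq))

  contrasts <- design_contrasts(design)
  pp <- config$preprocess
  tabs <- list()
  for (i in seq_along(contrasts)) {
    nm <- names(contrasts)[i]
    cfg_i <- pp
    cfg_i$seed <- pp$seed + i - 1L  # distinct imputation stream per arm
    tabs[[nm]] <- step(paste0("differential.", nm),
                       analyze_contrast(lmat, contrasts[[i]], cfg_i,
                                        alpha = config$thresholds$alpha,
                                        variant = config$t_variant,
                                        fc_scale = config$fc_scale))
    f <- file.path(config$output_dir, sprintf("contrast_%s.tsv", nm))
    write_stage_tsv(format_differential(tabs[[nm]]), f,
                    c(hdr, sprintf("contrast=%s | filtered_out=%d",
                                   attr(tabs[[nm]], "contrast"),
                                   attr(tabs[[nm]], "n_filtered_out"))))
    files[paste0("contrast_", nm)] <- f
  }

  delta <- step("delta_cargo",
                classify_cargo(tabs$ctrl, tabs$kd, config$thresholds))
  candidates <- select_candidates(delta, config$thresholds)
  summ <- summarize_delta(delta, config$thresholds)
  files["delta"] <- file.path(config$output_dir, "delta_table.tsv")
  write_stage_tsv(delta, files["delta"], hdr)
  files["candidates"] <- file.path(config$output_dir, "candidates.tsv")
  write_stage_tsv(candidates, files["candidates"], hdr)
  files["summary"] <- file.path(config$output_dir, "summary.json")
  jsonlite::write_json(
    c(summ[setdiff(names(summ), "class_counts")],
      list(class_counts = as.list(summ$class_counts))),
    files["summary"], auto_unbox = TRUE, digits = NA, na = "null")

  enrich <- NULL
  if (!is.null(config$annotation)) {
    ann <- step("enrichment", read_annotation(config$annotation))
    universe <- delta$protein
    sets <- list(up = delta$protein[delta$direction == "up"],
                 down = delta$protein[delta$direction == "down"],
                 candidates = candidates$protein)
    enrich <- lapply(sets, function(s) {
      if (!length(s)) return(NULL)
      step("enrichment", fisher_enrichment(s, universe, ann))
    })
    for (nm in names(enrich)) {
      if (is.null(enrich[[nm]])) next
      f <- file.path(config$output_dir, sprintf("enrichment_%s.tsv", nm))
      write_stage_tsv(enrich[[nm]], f, hdr)
      files[paste0("enrichment_", nm)] <- f
    }
  }

  z <- step("heatmap_export", zscore_matrix(lmat))
  z <- z[rowSums(is.finite(z)) > 0L, , drop = FALSE]
  files["zscore"] <- file.path(config$output_dir, "zscore_matrix.tsv")
  df <- data.frame(protein = rownames(z), z, check.names = FALSE,
                   row.names = NULL)
  write_stage_tsv(df, files["zscore"], hdr)

  manifest <- list(
    package = "exocargo",
    version = as.character(packageVersion("exocargo")),
    r_version = as.character(getRversion()),
    seed = config$seed, config_md5 = unname(cfg_hash),
    stage_rows = c(list(ibaq = nrow(ibaq$ibaq)),
                   lapply(tabs, nrow),
                   list(delta = nrow(delta), candidates = nrow(candidates))),
    files = as.list(files)
  )
  files["manifest"] <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA)

  invisible(list(ibaq = ibaq, log2 = lmat, ctrl = tabs$ctrl, kd = tabs$kd,
                 delta = delta, candidates = candidates, summary = summ,
                 enrichment = enrich, zscore = z, files = files))
}

# full-precision numeric columns plus a rounded display column for fc
format_differential <- function(tab) {
  out <- tab
  out$fc_display <- round(out$fc, 2L)
  out
}
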