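#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. With no
#' input paths the pipeline runs fully synthetic: factorial mouse counts
#' with planted hyperoxia effects, a healthy reference cohort, a clinical
#' BPD cohort with a planted severity shift on the knockout-female
#' signature, an ortholog map and a gene-set collection are all generated
#' from `seed`. Any element can instead be loaded from the standard text
#' formats by giving its path.
#'
#' @param seed Integer seed driving every stochastic stage (required).
#' @param out_dir Output directory for all artifacts.
#' @param ... Overrides of the defaults listed below.
#' @return A validated `pipeline_config` list.
#' @section Defaults:
#' `n_genes = 1000`, `n_per_group = 5`, `fdr_max = 0.05`, `min_fold = 1.5`,
#' `gsea_fdr_max = 0.25`, `n_perm = 1000`, `min_set_size = 5`,
#' `max_set_size = 500`, `reference_n = 200`,
#' `severity_counts = c(43, 40, 13, 15)`, `clinical_delta = 0.5`,
#' `discordance_pair = c("F_KO", "F_WT")`, and `NULL` input paths
#' (`counts_path`, `metadata_path`, `reference_path`,
#' `clinical_expression_path`, `clinical_path`, `ortholog_path`,
#' `gmt_path`).
#' @export
pipeline_config <- function(seed, out_dir = "oxisig_run", ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    n_genes = 1000, n_per_group = 5,
    fdr_max = 0.05, min_fold = 1.5,
    gsea_fdr_max = 0.25, n_perm = 1000,
    min_set_size = 5, max_set_size = 500,
    reference_n = 200,
    severity_counts = c(43, 40, 13, 15), clinical_delta = 0.5,
    discordance_pair = c("F_KO", "F_WT"),
    counts_path = NULL, metadata_path = NULL,
    reference_path = NULL, clinical_expression_path = NULL,
    clinical_path = NULL, ortholog_path = NULL, gmt_path = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(cfg, over)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) abort("a seed is required")
  for (th in c("fdr_max", "min_fold", "gsea_fdr_max", "n_perm")) {
    if (cfg[[th]] <= 0) abort(paste0("threshold ", th, " must be positive"))
  }
  ext <- !is.null(cfg$reference_path) || !is.null(cfg$clinical_expression_path)
  if (ext && is.null(cfg$ortholog_path)) {
    abort("an ortholog map path is required when human expression is loaded from file")
  }
  for (pth in c("counts_path", "metadata_path", "reference_path",
                "clinical_expression_path", "clinical_path", "ortholog_path",
                "gmt_path")) {
    if (!is.null(cfg[[pth]]) && !file.exists(cfg[[pth]])) {
      abort(paste0(pth, " does not exist: ", cfg[[pth]]))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with `seed`, `out_dir` and any other
#'   [pipeline_config()] field.
#' @param ... Command-line style overrides applied on top of the file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw <- modifyList(raw, over)
  if (is.null(raw$seed)) abort("config must set a seed")
  do.call(pipeline_config,
          c(list(seed = raw$seed, out_dir = raw$out_dir %||% "oxisig_run"),
            raw[setdiff(names(raw), c("seed", "out_dir"))]))
}

# deterministic default planted effects: blocks of up/down genes per
# contrast, with deliberate shared and opposite-direction genes so the
# overlap and discordance stages have structure to find
default_planted_effects <- function(n_genes) {
  g <- simulated_genes(n_genes)
  blk <- function(contrast, up_idx, down_idx) {
    tibble(contrast = contrast, gene = g[c(up_idx, down_idx)],
           log2_fc = rep(c(2, -2), c(length(up_idx), length(down_idx))))
  }
  planted_effects(bind_rows(
    blk("F_KO", 1:60, 61:120),
    blk("F_WT", 41:70, 121:150),   # shares up genes with F_KO and opposes its down set
    blk("M_KO", 151:190, 191:220),
    blk("M_WT", 161:180, 221:240)
  ))
}

default_gene_sets <- function(n_genes, seed) {
  g <- simulated_genes(n_genes)
  planted <- list(planted_F_KO_up = g[1:60], planted_F_KO_down = g[61:120],
                  planted_M_KO_up = g[151:190], discordant_F = g[61:70])
  rand <- simulate_gene_sets(g, n_sets = 20, set_size = 20, seed = seed)
  sets <- c(planted, rand)
  attr(sets, "description") <- setNames(
    c(rep("synthetic planted set", 4), rep("synthetic random set", 20)),
    names(sets))
  sets
}

write_matrix_tsv <- function(m, path, first_col) {
  tb <- bind_cols(tibble(!!first_col := rownames(m)),
                  as_tibble(as.data.frame(m)))
  readr::write_tsv(tb, path, progress = FALSE)
}

#' Run the signature pipeline end-to-end
#'
#' Executes the full analysis in the order differential expression ->
#' signature extraction -> ortholog translation -> summed z-score
#' projection -> correlation (reference cohort and clinical cohort) ->
#' preranked enrichment -> cross-contrast discordance, writing every table
#' plus a run manifest to `config$out_dir`. Re-running with the same
#' configuration reproduces every numeric output bit-exactly. Any stage
#' failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with the in-memory results (DEG tables,
#'   signatures, score tibbles, correlation objects, enrichment results,
#'   discordance table, and output paths).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(unclass(config))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  ## mouse counts
  sim <- stage("counts", {
    if (!is.null(cfg$counts_path)) {
      list(counts = read_expression(cfg$counts_path, counts = TRUE),
           metadata = read_sample_metadata(cfg$metadata_path))
    } else {
      simulate_mouse_counts(mouse_design(cfg$n_per_group, cfg$n_genes),
                            default_planted_effects(cfg$n_genes),
                            seed = cfg$seed)
    }
  })
  write_expression(sim$counts, out("counts.tsv"))
  readr::write_csv(sim$metadata[c("sample_id", "sex", "genotype", "treatment")],
                   out("sample_metadata.csv"), progress = FALSE)

  ## normalization + differential expression + signatures
  expr <- stage("normalize", cpm_normalize(sim$counts))
  write_expression(expr, out("log2cpm.tsv"))
  degs <- stage("differential_expression", hyperoxia_contrasts(expr, sim$metadata))
  sigs <- list()
  for (ct in names(degs)) {
    readr::write_tsv(degs[[ct]], out(paste0("deg_", ct, ".tsv")), progress = FALSE)
    sigs[[ct]] <- stage("signatures",
                        extract_signature(degs[[ct]], cfg$fdr_max, cfg$min_fold,
                                          name = ct))
    write_signature(sigs[[ct]], out(paste0("signature_", ct, ".txt")))
  }
  overlaps <- stage("overlaps", signature_overlaps(sigs))
  readr::write_tsv(select(overlaps, -"genes"), out("signature_overlaps.tsv"),
                   progress = FALSE)

  ## ortholog map; human-side cohorts arrive in human symbols and are
  ## translated back into mouse symbol space before scoring
  map_m2h <- stage("ortholog_map", {
    if (!is.null(cfg$ortholog_path)) {
      invert_ortholog_map(read_ortholog_map(cfg$ortholog_path))
    } else {
      simulate_ortholog_map(simulated_genes(cfg$n_genes), seed = cfg$seed + 1)
    }
  })
  map_h2m <- invert_ortholog_map(map_m2h)
  write_ortholog_map(map_h2m, out("ortholog_map_human_to_mouse.tsv"))

  ## reference cohort scoring + inter-signature correlation
  ref_human <- stage("reference_cohort", {
    if (!is.null(cfg$reference_path)) {
      read_expression(cfg$reference_path)
    } else {
      ref <- simulate_reference_cohort(cfg$reference_n, cfg$n_genes,
                                       seed = cfg$seed + 2)
      translate_matrix(ref, map_m2h)$expression
    }
  })
  ref_mouse <- stage("translate", translate_matrix(ref_human, map_h2m)$expression)
  ref_scores <- stage("score_reference", score_signatures(ref_mouse, sigs))
  readr::write_tsv(as_tibble(ref_scores), out("reference_scores.tsv"),
                   progress = FALSE)
  sig_cor <- stage("correlate", inter_signature_correlation(ref_scores))
  write_matrix_tsv(sig_cor$r, out("signature_correlation_r.tsv"), "signature")
  write_matrix_tsv(sig_cor$p_value, out("signature_correlation_p.tsv"), "signature")
  tree <- stage("cluster", cluster_signatures(sig_cor))
  readr::write_lines(tree$labels[tree$order], out("signature_cluster_order.txt"))

  ## clinical cohort scoring + clinical correlations
  clin <- stage("clinical_cohort", {
    if (!is.null(cfg$clinical_expression_path)) {
      list(expression = read_expression(cfg$clinical_expression_path),
           clinical = read_clinical(cfg$clinical_path))
    } else {
      cs <- simulate_clinical_cohort(cfg$severity_counts, cfg$clinical_delta,
                                     signature = sigs[["F_KO"]],
                                     n_genes = cfg$n_genes,
                                     seed = cfg$seed + 3)
      cs$expression <- translate_matrix(cs$expression, map_m2h)$expression
      cs
    }
  })
  write_clinical(clin$clinical, out("clinical.csv"))
  clin_mouse <- stage("translate", translate_matrix(clin$expression, map_h2m)$expression)
  clin_scores <- stage("score_clinical", score_signatures(clin_mouse, sigs))
  readr::write_tsv(as_tibble(clin_scores), out("clinical_scores.tsv"),
                   progress = FALSE)
  clin_cor <- stage("clinical_correlation",
                    clinical_correlation(clin_scores, clin$clinical))
  readr::write_tsv(clin_cor, out("clinical_correlation.tsv"), progress = FALSE)

  ## enrichment + discordance
  sets <- stage("gene_sets", {
    if (!is.null(cfg$gmt_path)) read_gmt(cfg$gmt_path)
    else default_gene_sets(cfg$n_genes, seed = cfg$seed + 4)
  })
  write_gmt(sets, out("gene_sets.gmt"))
  gsea <- list()
  for (ct in names(degs)) {
    gsea[[ct]] <- stage("gsea", {
      gsea_preranked(rank_genes(degs[[ct]]), sets, n_perm = cfg$n_perm,
                     seed = cfg$seed + 5, min_size = cfg$min_set_size,
                     max_size = cfg$max_set_size)
    })
    readr::write_tsv(gsea[[ct]], out(paste0("gsea_", ct, ".tsv")),
                     progress = FALSE)
  }
  nes <- stage("nes_matrix", nes_matrix(gsea, fdr_max = cfg$gsea_fdr_max))
  write_matrix_tsv(nes, out("nes_matrix.tsv"), "pathway")
  disc <- stage("discordance", {
    pr <- cfg$discordance_pair
    if (all(pr %in% colnames(nes))) discordant_pathways(nes, pr[1], pr[2])
    else tibble(pathway = character(), nes_a = numeric(), nes_b = numeric(),
                nes_gap = numeric())
  })
  readr::write_tsv(disc, out("discordant_pathways.tsv"), progress = FALSE)

  ## manifest: config echo + derived seeds + version (no timestamps, so
  ## reruns are byte-identical)
  manifest <- c(
    paste0("oxisig_version\t", as.character(packageVersion("oxisig"))),
    paste0("seed\t", cfg$seed),
    paste0("derived_seeds\t", paste(cfg$seed + 1:5, collapse = ",")),
    vapply(setdiff(names(cfg), c("seed")), function(k) {
      v <- cfg[[k]]
      paste0(k, "\t", if (is.null(v)) "NULL" else paste(v, collapse = ","))
    }, character(1)))
  readr::write_lines(manifest, out("manifest.txt"))

  invisible(list(counts = sim$counts, metadata = sim$metadata, deg = degs,
                 signatures = sigs, overlaps = overlaps,
                 reference_scores = ref_scores, signature_correlation = sig_cor,
                 cluster = tree, clinical = clin$clinical,
                 clinical_scores = clin_scores,
                 clinical_correlation = clin_cor, gsea = gsea, nes = nes,
                 discordant = disc, out_dir = cfg$out_dir))
}
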