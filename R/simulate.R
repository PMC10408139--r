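#' Factorial mouse RNA-seq design
#'
#' Describes the 2 x 2 x 2 neonatal-lung design the count simulator draws
#' from: sex (F/M) x genotype (WT/KO) x treatment (room air / hyperoxia),
#' with `n_per_group` replicates in each of the 8 cells. Hyperoxia contrasts
#' are taken within each sex-by-genotype cell, labelled `F_WT`, `F_KO`,
#' `M_WT`, `M_KO`.
#'
#' @param n_per_group Replicates per design cell (>= 2).
#' @param n_genes Number of genes in the simulated transcriptome (>= 10).
#' @return A `mouse_design` object whose `$samples` tibble has columns
#'   `sample_id`, `sex`, `genotype`, `treatment`, `contrast`.
#' @examples
#' mouse_design(n_per_group = 3, n_genes = 100)
#' @export
mouse_design <- function(n_per_group = 5, n_genes = 2000) {
  if (n_per_group < 2) abort("n_per_group must be >= 2")
  if (n_genes < 10) abort("n_genes must be >= 10")
  cells <- tidyr::expand_grid(sex = c("F", "M"), genotype = c("WT", "KO"),
                              treatment = c("room_air", "hyperoxia"))
  samples <- tidyr::uncount(cells, n_per_group, .id = "rep") |>
    mutate(contrast = paste(.data$sex, .data$genotype, sep = "_"),
           sample_id = paste(.data$contrast, .data$treatment, .data$rep, sep = "_")) |>
    select("sample_id", "sex", "genotype", "treatment", "contrast")
  structure(list(n_per_group = n_per_group, n_genes = n_genes,
                 samples = samples),
            class = "mouse_design")
}

#' @export
print.mouse_design <- function(x, ...) {
  cat("<mouse_design> 2x2x2 factorial,", x$n_per_group, "per cell,",
      x$n_genes, "genes\n")
  invisible(x)
}

#' Gene symbols used by the simulators
#'
#' Mouse-convention (capitalized) placeholder symbols `Gene0001`, ...
#'
#' @param n_genes Number of symbols.
#' @return Character vector of length `n_genes`.
#' @export
simulated_genes <- function(n_genes) {
  sprintf("Gene%04d", seq_len(n_genes))
}

#' Planted differential-expression effects
#'
#' Specifies, per hyperoxia contrast, which genes respond to hyperoxia and
#' by how much, plus the negative-binomial noise model: per-gene baseline
#' log2 means are drawn uniformly over `log2_mean_range` and counts use a
#' constant NB dispersion (variance = mu + dispersion * mu^2).
#'
#' @param table Tibble with columns `contrast` (e.g. `"F_KO"`), `gene`, and
#'   nonzero `log2_fc` (positive = up in hyperoxia). Empty by default
#'   (a null simulation).
#' @param log2_mean_range Range of baseline log2 mean counts.
#' @param dispersion NB dispersion (default 0.05, typical of inbred mouse
#'   RNA-seq).
#' @return A `planted_effects` object.
#' @export
planted_effects <- function(table = tibble(contrast = character(),
                                           gene = character(),
                                           log2_fc = numeric()),
                            log2_mean_range = c(2, 12),
                            dispersion = 0.05) {
  table <- as_tibble(table)
  need <- c("contrast", "gene", "log2_fc")
  miss <- setdiff(need, names(table))
  if (length(miss)) abort(paste0("effects table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(table$log2_fc == 0)) abort("planted log2_fc must be nonzero")
  if (anyDuplicated(table[c("contrast", "gene")])) {
    abort("a gene may be planted at most once per contrast (up and down sets must be disjoint)")
  }
  if (dispersion <= 0) abort("dispersion must be > 0")
  structure(list(table = table, log2_mean_range = log2_mean_range,
                 dispersion = dispersion),
            class = "planted_effects")
}

#' Simulate factorial mouse lung counts with planted hyperoxia effects
#'
#' Draws negative-binomial counts for every gene and sample of a
#' [mouse_design()]. Each gene receives one baseline log2 mean; a planted
#' gene's mean is shifted by its log2 fold change in the hyperoxia samples
#' of its targeted sex-by-genotype cell only. The same seed reproduces the
#' counts bit-exactly.
#'
#' @param design A [mouse_design()].
#' @param effects A [planted_effects()]; genes must exist in the design's
#'   transcriptome.
#' @param seed Integer seed.
#' @return A list with `counts` (gene-by-sample tibble), `metadata` (the
#'   design's sample tibble) and `truth` (a `simulation_truth` recording the
#'   effects and seed).
#' @export
simulate_mouse_counts <- function(design, effects = planted_effects(), seed) {
  stopifnot(inherits(design, "mouse_design"), inherits(effects, "planted_effects"))
  genes <- simulated_genes(design$n_genes)
  bad <- setdiff(effects$table$gene, genes)
  if (length(bad)) {
    abort(paste0("planted genes not in the simulated transcriptome: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad_ct <- setdiff(effects$table$contrast, unique(design$samples$contrast))
  if (length(bad_ct)) abort(paste0("unknown contrast(s): ", paste(bad_ct, collapse = ", ")))

  meta <- design$samples
  n_g <- design$n_genes
  n_s <- nrow(meta)
  counts <- withr::with_seed(seed, {
    mu0 <- runif(n_g, effects$log2_mean_range[1], effects$log2_mean_range[2])
    lmu <- matrix(mu0, nrow = n_g, ncol = n_s)
    if (nrow(effects$table)) {
      gi <- match(effects$table$gene, genes)
      for (k in seq_len(nrow(effects$table))) {
        cols <- which(meta$contrast == effects$table$contrast[k] &
                        meta$treatment == "hyperoxia")
        lmu[gi[k], cols] <- lmu[gi[k], cols] + effects$table$log2_fc[k]
      }
    }
    m <- matrix(rnbinom(n_g * n_s, mu = 2^lmu, size = 1 / effects$dispersion),
                nrow = n_g, dimnames = list(genes, meta$sample_id))
    m
  })
  truth <- structure(list(effects = effects, seed = seed,
                          n_per_group = design$n_per_group,
                          n_genes = design$n_genes),
                     class = "simulation_truth")
  list(counts = expr_tbl(counts), metadata = meta, truth = truth)
}

#' Simulate a healthy reference expression cohort
#'
#' Emulates a large compendium of normal lung transcriptomes (the role the
#' GTEx lung cohort, n = 578, plays in signature co-variation analysis):
#' log-scale expression with heterogeneous per-gene means and variances
#' plus a low-rank shared component, so scores of distinct gene sets can be
#' correlated across individuals.
#'
#' @param n_samples Number of individuals (>= 3; default 578).
#' @param n_genes Number of genes (default 2000).
#' @param seed Integer seed.
#' @param n_factors Rank of the shared-covariance component (default 3).
#' @return A gene-by-sample tibble of log-scale expression.
#' @export
simulate_reference_cohort <- function(n_samples = 578, n_genes = 2000, seed,
                                      n_factors = 3) {
  if (n_samples < 3) abort("n_samples must be >= 3")
  genes <- simulated_genes(n_genes)
  m <- withr::with_seed(seed, {
    mu <- runif(n_genes, 2, 12)
    sd_g <- exp(rnorm(n_genes, mean = log(0.6), sd = 0.4))
    load <- matrix(rnorm(n_genes * n_factors, sd = 0.4), n_genes)
    fac <- matrix(rnorm(n_factors * n_samples), n_factors)
    mu + load %*% fac +
      matrix(rnorm(n_genes * n_samples, sd = sd_g), n_genes, n_samples)
  })
  rownames(m) <- genes
  colnames(m) <- sprintf("ref_%04d", seq_len(n_samples))
  expr_tbl(m)
}

#' Simulate a clinical BPD cohort with a planted severity effect
#'
#' Builds a normalized log-scale expression cohort with an ordinal
#' bronchopulmonary-dysplasia severity grade (0 none / 1 mild / 2 moderate /
#' 3 severe) and the clinical covariates used in signature-correlation
#' analyses. The signature's up genes are shifted by `+delta * severity`
#' per-gene standard deviations, down genes by `-delta * severity`.
#' Gestational age and birth weight are drawn negatively correlated with
#' severity (r of about -0.5 by default), oxygen requirement at 28 days
#' increases with severity, and sexes alternate within each severity
#' stratum.
#'
#' @param severity_counts Integer vector of cohort composition at severity
#'   0..3; the default `c(43, 40, 13, 15)` gives the 111-subject cohort.
#' @param delta Planted per-severity-level shift in per-gene SD units; 0
#'   gives a null cohort.
#' @param signature A [gene_signature()] whose genes lie in the simulated
#'   gene universe.
#' @param n_genes Size of the gene universe.
#' @param seed Integer seed.
#' @param severity_slope Per-severity decrease used for gestational age
#'   (weeks) and, scaled, birth weight (g); the default targets r of about
#'   -0.5 for both.
#' @return A list with `expression`, `clinical` (see [read_clinical()]) and
#'   `truth`.
#' @export
simulate_clinical_cohort <- function(severity_counts = c(43, 40, 13, 15),
                                     delta = 0.5, signature, n_genes = 2000,
                                     seed, severity_slope = 1) {
  if (length(severity_counts) != 4L || any(severity_counts < 0)) {
    abort("severity_counts must be 4 nonnegative integers (severity 0..3)")
  }
  if (sum(severity_counts) < 4) abort("cohort must have at least 4 subjects")
  stopifnot(inherits(signature, "gene_signature"))
  genes <- simulated_genes(n_genes)
  bad <- setdiff(c(signature$up, signature$down), genes)
  if (length(bad)) {
    abort(paste0("signature genes outside the gene universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  n <- sum(severity_counts)
  severity <- rep(0:3, severity_counts)
  sex <- unlist(lapply(severity_counts,
                       function(k) rep_len(c("F", "M"), k)), use.names = FALSE)
  dir <- numeric(n_genes)
  dir[match(signature$up, genes)] <- 1
  dir[match(signature$down, genes)] <- -1

  out <- withr::with_seed(seed, {
    mu <- runif(n_genes, 2, 12)
    sd_g <- runif(n_genes, 0.5, 1.5)
    shift <- outer(dir, severity) * delta          # in per-gene SD units
    x <- mu + sd_g * (shift + matrix(rnorm(n_genes * n), n_genes, n))
    # noise SD chosen so cor(covariate, severity) ~ -0.5 at the default slope
    ga <- 29 - severity_slope * severity + rnorm(n, sd = severity_slope * 1.77)
    bw <- 1250 - 120 * severity_slope * severity +
      rnorm(n, sd = 120 * severity_slope * 1.77)
    o2 <- rbinom(n, 1, c(0.1, 0.3, 0.7, 0.9)[severity + 1])
    list(x = x, ga = pmax(ga, 22), bw = pmax(bw, 400), o2 = o2)
  })
  rownames(out$x) <- genes
  colnames(out$x) <- sprintf("pt_%03d", seq_len(n))
  clinical <- tibble(sample_id = colnames(out$x), sex = sex,
                     gestational_age_weeks = out$ga, birth_weight_g = out$bw,
                     bpd_severity = severity, oxygen_28d = out$o2)
  truth <- structure(list(delta = delta, signature = signature, seed = seed,
                          severity_counts = severity_counts),
                     class = "simulation_truth")
  list(expression = expr_tbl(out$x), clinical = clinical, truth = truth)
}

#' Simulate a gene-set collection
#'
#' Random same-size gene sets drawn from a gene universe, for exercising
#' preranked enrichment without bundling curated collections.
#'
#' @param genes Gene universe.
#' @param n_sets Number of sets.
#' @param set_size Genes per set.
#' @param seed Integer seed.
#' @param prefix Set-name prefix.
#' @return A named list of character vectors (GMT-compatible).
#' @export
simulate_gene_sets <- function(genes, n_sets = 20, set_size = 20, seed,
                               prefix = "random_set") {
  if (set_size > length(genes)) abort("set_size exceeds the gene universe")
  sets <- withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  })
  names(sets) <- sprintf("%s_%03d", prefix, seq_len(n_sets))
  attr(sets, "description") <- setNames(rep("synthetic random set", n_sets),
                                        names(sets))
  sets
}

#' Simulate an ortholog symbol map
#'
#' Produces a Biomart-style two-column correspondence from mouse-convention
#' symbols to human-convention (upper-case) symbols, with a requested
#' mixture of one-to-one pairs, one-to-many expansions (two human symbols
#' per mouse symbol) and unmapped symbols. Fractions may sum to less than
#' one; the remainder is mapped one-to-one.
#'
#' @param symbols Source (mouse) symbols.
#' @param frac_one_to_one,frac_one_to_many,frac_missing Expected category
#'   fractions; nonnegative, summing to at most 1.
#' @param seed Integer seed.
#' @return An ortholog-map tibble (`source_symbol`, `target_symbol`) with a
#'   `dropped` attribute listing unmapped source symbols and a `direction`
#'   attribute `"mouse_to_human"`.
#' @export
simulate_ortholog_map <- function(symbols, frac_one_to_one = 0.8,
                                  frac_one_to_many = 0.1,
                                  frac_missing = 0.1, seed) {
  fr <- c(frac_one_to_one, frac_one_to_many, frac_missing)
  if (any(fr < 0)) abort("fractions must be nonnegative")
  if (sum(fr) > 1 + 1e-12) abort("fractions must sum to at most 1")
  cls <- withr::with_seed(seed, {
    sample(c("one", "many", "miss", "one"), length(symbols), replace = TRUE,
           prob = c(fr, max(0, 1 - sum(fr))))
  })
  one <- symbols[cls == "one"]
  many <- symbols[cls == "many"]
  many_targets <- if (length(many)) {
    as.vector(rbind(toupper(many), paste0(toupper(many), "2")))
  } else {
    character(0)
  }
  map <- tibble(
    source_symbol = c(one, rep(many, each = 2L)),
    target_symbol = c(toupper(one), many_targets)
  )
  structure(map, dropped = symbols[cls == "miss"], direction = "mouse_to_human")
}
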