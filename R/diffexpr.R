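#' Log2 counts-per-million normalization
#'
#' Converts raw counts to `log2((count + 0.5) / (library_size + 1) * 1e6)`,
#' where the library size is the sample's column sum of raw counts. The
#' fixed pseudocounts (0.5 on the count, 1 on the library size) avoid
#' log(0) and make the output bit-reproducible.
#'
#' @param counts A gene-by-sample tibble of nonnegative integer counts.
#' @return A gene-by-sample tibble of log2-CPM expression.
#' @examples
#' counts <- tibble::tibble(gene = "Gene0001", s1 = 0L)
#' # with a forced library size this reduces to log2(0.5/(L+1) * 1e6)
#' @export
cpm_normalize <- function(counts) {
  m <- as_expr_matrix(counts)
  validate_expression(counts, counts = TRUE)
  lib <- colSums(m)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    abort(paste0("all-zero sample column(s): ", paste(zero, collapse = ", ")))
  }
  out <- log2(sweep(m + 0.5, 2, lib + 1, "/") * 1e6)
  expr_tbl(out)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1 and returned in the
#' original order. This is the rule behind the study's "FDR < 0.05"
#' (differential expression) and "FDR < 0.25" (enrichment) thresholds.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-group differential expression on log2 expression
#'
#' Per-gene Welch's t-test between two groups of samples on (typically
#' log2-CPM) expression, with `log2_fc = mean(group2) - mean(group1)` and
#' BH-adjusted q-values. Genes with zero variance in both groups get p = 1
#' when the means are equal; when the means differ, the separation is exact
#' and p is set to 0 with `degenerate = TRUE` so such genes stay auditable.
#'
#' @param expr A gene-by-sample expression tibble (log2 scale).
#' @param groups Two-level factor/character vector aligned with the sample
#'   columns, or a named vector of sample ids; the first level (sorted, or
#'   factor order) is the baseline.
#' @param contrast Optional label stored on the result (attribute
#'   `contrast`).
#' @return A tibble with columns `gene`, `log2_fc`, `p_value`, `q_value`,
#'   `degenerate`, `contrast`.
#' @export
differential_expression <- function(expr, groups, contrast = NULL) {
  m <- as_expr_matrix(expr)
  if (length(groups) != ncol(m)) abort("groups must match the sample columns")
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(m), names(groups))
    if (length(miss)) abort(paste0("groups missing sample(s): ", paste(head(miss, 5), collapse = ", ")))
    groups <- groups[colnames(m)]
  }
  f <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(f) != 2L) abort("groups must have exactly 2 levels")
  if (any(table(f) < 2L)) abort("each group needs at least 2 samples")
  i1 <- which(f == levels(f)[1])
  i2 <- which(f == levels(f)[2])
  n1 <- length(i1); n2 <- length(i2)

  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- rowSums((m[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((m[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)

  both_const <- v1 == 0 & v2 == 0
  degen <- both_const & lfc != 0
  p[both_const & lfc == 0] <- 1
  p[degen] <- 0

  if (is.null(contrast)) contrast <- "group2_vs_group1"
  out <- tibble(gene = rownames(m), log2_fc = unname(lfc),
                p_value = unname(p), q_value = bh_adjust(unname(p)),
                degenerate = unname(degen), contrast = contrast)
  attr(out, "contrast") <- contrast
  out
}

#' Per-contrast hyperoxia differential expression
#'
#' Convenience wrapper running [differential_expression()] (hyperoxia vs
#' room air) within every sex-by-genotype cell of a factorial cohort.
#'
#' @param expr Log2 expression tibble covering all samples.
#' @param metadata Sample metadata tibble (`sample_id`, `sex`, `genotype`,
#'   `treatment`).
#' @return A named list of DEG tibbles, one per contrast (`F_WT`, ...).
#' @export
hyperoxia_contrasts <- function(expr, metadata) {
  need <- c("sample_id", "sex", "genotype", "treatment")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  cells <- distinct(metadata, .data$sex, .data$genotype)
  res <- list()
  for (k in seq_len(nrow(cells))) {
    sub <- filter(metadata, .data$sex == cells$sex[k],
                  .data$genotype == cells$genotype[k])
    label <- paste(cells$sex[k], cells$genotype[k], sep = "_")
    cols <- c("gene", sub$sample_id)
    grp <- factor(sub$treatment, levels = c("room_air", "hyperoxia"))
    names(grp) <- sub$sample_id
    res[[label]] <- differential_expression(expr[cols], grp, contrast = label)
  }
  res
}

#' Import an externally produced DEG table
#'
#' Accepts a delimited file with (header-mapped) columns for the gene, the
#' log2 fold change, the p-value and optionally the q-value, so tables
#' produced by other differential-expression engines (e.g. NB-GLM fits) can
#' feed the signature pipeline directly.
#'
#' @param path File path (tab- or comma-delimited, with header).
#' @param recompute_q Recompute q from p with [bh_adjust()]; forced when the
#'   q column is absent.
#' @return A DEG tibble as from [differential_expression()].
#' @export
import_deg_table <- function(path, recompute_q = FALSE) {
  x <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(x) <- tolower(names(x))
  alias <- list(gene = c("gene", "symbol", "gene_symbol"),
                log2_fc = c("log2_fc", "log2fc", "logfc", "log2foldchange"),
                p_value = c("p_value", "p", "pvalue", "p.value"),
                q_value = c("q_value", "q", "qvalue", "fdr", "padj"))
  pick <- function(keys) {
    hit <- intersect(keys, names(x))
    if (length(hit)) x[[hit[1]]] else NULL
  }
  gene <- pick(alias$gene); lfc <- pick(alias$log2_fc); p <- pick(alias$p_value)
  if (is.null(gene)) abort("missing required column: gene")
  if (is.null(lfc)) abort("missing required column: log2_fc")
  if (is.null(p)) abort("missing required column: p_value")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p_value outside [0, 1]")
  q <- pick(alias$q_value)
  if (is.null(q) || recompute_q) q <- bh_adjust(p)
  out <- tibble(gene = as.character(gene), log2_fc = as.numeric(lfc),
                p_value = as.numeric(p), q_value = as.numeric(q),
                degenerate = FALSE, contrast = "imported")
  attr(out, "contrast") <- "imported"
  out
}
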