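#' Read or write GMT gene-set collections
#'
#' Tab-delimited MSigDB format: one set per line, fields are the set name,
#' a description, then the member symbols. Duplicate members within a set
#' are dropped silently.
#'
#' @param path File path.
#' @return A named list of character vectors with a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) abort(paste0("malformed GMT line ", bad[1], ": need name, description, >= 1 member"))
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) abort("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, character(1), 2), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Rank genes for preranked enrichment
#'
#' Orders a DEG table by the ranking metric, descending. The default metric
#' `sign(log2FC) * (-log10 p)` combines effect direction with evidence;
#' `"log2_fc"` ranks by fold change alone. P-values are floored at 1e-300
#' before the log. Ties are broken by gene symbol (lexicographic) and
#' recorded.
#'
#' @param deg A DEG tibble (`gene`, `log2_fc`, `p_value`).
#' @param metric `"signed_logp"` (default) or `"log2_fc"`.
#' @return A `ranked_genes` tibble (`gene`, `score`), sorted descending,
#'   with attribute `ties` listing tied symbols.
#' @export
rank_genes <- function(deg, metric = c("signed_logp", "log2_fc")) {
  metric <- match.arg(metric)
  if (anyDuplicated(deg$gene)) abort("duplicate gene symbols in DEG table")
  score <- switch(metric,
    signed_logp = sign(deg$log2_fc) * -log10(pmax(deg$p_value, 1e-300)),
    log2_fc = deg$log2_fc)
  ord <- order(-score, deg$gene, method = "radix")
  out <- tibble(gene = deg$gene[ord], score = score[ord])
  tied <- out$gene[duplicated(out$score) | duplicated(out$score, fromLast = TRUE)]
  attr(out, "ties") <- tied
  attr(out, "metric") <- metric
  class(out) <- c("ranked_genes", class(out))
  out
}

# ES from sorted hit positions; O(k). w = |score|^exponent at those
# positions, W = sum(w). Returns ES and the hit index of the extremum.
es_from_positions <- function(pos, w, n_total) {
  k <- length(pos)
  W <- sum(w)
  hit_inc <- if (W > 0) w / W else rep(1 / k, k)
  miss_dec <- 1 / (n_total - k)
  cumw <- cumsum(hit_inc)
  after <- cumw - (pos - seq_len(k)) * miss_dec          # just after each hit
  before <- c(0, cumw[-k]) - (pos - seq_len(k)) * miss_dec # just before each hit
  cand <- c(after, before)
  i <- which.max(abs(cand))
  es <- cand[i]
  lead_hit <- if (es >= 0) ((i - 1L) %% k) + 1L else ((i - 1L) %% k) + 1L
  list(es = es, extremum_hit = lead_hit)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The running-sum statistic of preranked gene-set enrichment: walking down
#' the ranked list, the sum rises by `|score|^weight_exponent`, normalized
#' by the total over the set's hits, at each set member and falls by
#' `1 / (N - N_hits)` at each non-member; the enrichment score is the
#' running-sum value of largest magnitude, sign preserved. With
#' `weight_exponent = 0` this is the classical two-sample KS statistic on
#' ranks.
#'
#' @param ranked A `ranked_genes` tibble from [rank_genes()].
#' @param gene_set Character vector of member symbols.
#' @param weight_exponent Weighting of ranking scores (default 1).
#' @return A list with `es` and `running_sum`, a tibble with one row per
#'   list position (`position`, `gene`, `hit`, `running_sum`).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  k <- sum(hit)
  if (k == 0L) abort("gene set has no member in the ranked list")
  if (k == n) abort("gene set covers the entire ranked list")
  w <- abs(ranked$score)^weight_exponent
  W <- sum(w[hit])
  inc <- if (W > 0) w / W else rep(1 / k, n)
  step <- ifelse(hit, inc, -1 / (n - k))
  rs <- cumsum(step)
  es <- rs[which.max(abs(rs))]
  list(es = es,
       running_sum = tibble(position = seq_len(n), gene = ranked$gene,
                            hit = hit, running_sum = rs))
}

#' Preranked gene-set enrichment with permutation significance
#'
#' For each gene set (after size filtering against the ranked list), the
#' weighted-KS enrichment score is compared with a null distribution of
#' scores from `n_perm` random same-size gene draws. NES divides ES by the
#' mean magnitude of same-sign null scores; the permutation p-value is the
#' fraction of null scores whose magnitude reaches the observed magnitude,
#' with a +1 pseudo-count (exactly calibrated under the null, with a floor
#' of `1 / (n_perm + 1)`); FDR q follows the
#' standard signed NES-pool procedure (null and observed NES pooled across
#' sets, compared within sign). Deterministic given the seed.
#'
#' @param ranked A `ranked_genes` tibble.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (required).
#' @param min_size,max_size Set-size bounds applied after intersection with
#'   the ranked list.
#' @param weight_exponent Passed to the enrichment score (default 1).
#' @return A `gsea_result` tibble: `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr_q`, `leading_edge_size`, sorted by `p_value`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed,
                           min_size = 5, max_size = 500,
                           weight_exponent = 1) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  n <- nrow(ranked)
  w_all <- abs(ranked$score)^weight_exponent
  hits <- lapply(sets, function(s) which(ranked$gene %in% s))
  keep <- vapply(hits, function(h) length(h) >= min_size &&
                   length(h) <= max_size && length(h) < n, logical(1))
  if (!any(keep)) abort("no gene set survives the size filter")
  hits <- hits[keep]

  res <- withr::with_seed(seed, {
    lapply(names(hits), function(nm) {
      pos <- sort(hits[[nm]])
      k <- length(pos)
      obs <- es_from_positions(pos, w_all[pos], n)
      null_es <- vapply(seq_len(n_perm), function(b) {
        rp <- sort(sample.int(n, k))
        es_from_positions(rp, w_all[rp], n)$es
      }, numeric(1))
      list(set = nm, size = k, es = obs$es, extremum_hit = obs$extremum_hit,
           null_es = null_es)
    })
  })

  norm_one <- function(es, null_es) {
    pos_m <- mean(null_es[null_es > 0])
    neg_m <- mean(abs(null_es[null_es < 0]))
    nes <- function(e) {
      if (e > 0 && is.finite(pos_m)) e / pos_m
      else if (e < 0 && is.finite(neg_m)) e / neg_m
      else if (e == 0) 0
      else e / mean(abs(null_es))
    }
    list(nes = nes(es), null_nes = vapply(null_es, nes, numeric(1)))
  }

  rows <- list(); null_pool <- list()
  for (r in res) {
    p <- (1 + sum(abs(r$null_es) >= abs(r$es))) / (1 + n_perm)
    nn <- norm_one(r$es, r$null_es)
    lead <- if (r$es >= 0) r$extremum_hit else r$size - r$extremum_hit + 1L
    rows[[r$set]] <- tibble(set = r$set, size = r$size, es = r$es,
                            nes = nn$nes, p_value = p,
                            leading_edge_size = lead)
    null_pool[[r$set]] <- nn$null_nes
  }
  out <- bind_rows(rows)
  pool <- unlist(null_pool, use.names = FALSE)
  out$fdr_q <- vapply(out$nes, function(ns) {
    if (ns == 0) return(1)
    same_null <- if (ns > 0) pool[pool >= 0] else pool[pool < 0]
    same_obs <- if (ns > 0) out$nes[out$nes >= 0] else out$nes[out$nes < 0]
    num <- if (length(same_null)) mean(abs(same_null) >= abs(ns)) else 0
    den <- mean(abs(same_obs) >= abs(ns))
    min(1, num / den)
  }, numeric(1))
  out <- arrange(out, .data$p_value, .data$set)[, c("set", "size", "es", "nes",
                                                    "p_value", "fdr_q",
                                                    "leading_edge_size")]
  class(out) <- c("gsea_result", class(out))
  out
}

#' NES matrix across contrasts
#'
#' Collects per-contrast enrichment results into a pathways-by-contrasts
#' matrix of normalized enrichment scores, keeping NES only where the FDR
#' q-value passes `fdr_max` (default 0.25, the conventional enrichment
#' significance rule); non-significant cells are NA and pathways with no
#' significant cell are dropped.
#'
#' @param results_by_contrast Named list of `gsea_result` tibbles.
#' @param fdr_max Significance threshold on `fdr_q`.
#' @return A numeric matrix, pathways in rows, contrasts in columns.
#' @export
nes_matrix <- function(results_by_contrast, fdr_max = 0.25) {
  if (length(results_by_contrast) < 2L) abort("need at least 2 contrasts")
  nm <- names(results_by_contrast)
  if (is.null(nm) || anyDuplicated(nm)) abort("contrast names must be unique")
  paths <- sort(unique(unlist(lapply(results_by_contrast, `[[`, "set"))))
  m <- matrix(NA_real_, length(paths), length(nm), dimnames = list(paths, nm))
  for (ct in nm) {
    r <- results_by_contrast[[ct]]
    sig <- r[r$fdr_q < fdr_max, , drop = FALSE]
    m[sig$set, ct] <- sig$nes
  }
  keep <- rowSums(!is.na(m)) > 0
  if (!any(keep)) warn("no pathway significant in any contrast")
  m[keep, , drop = FALSE]
}

#' Pathways enriched in opposite directions in two contrasts
#'
#' Lists gene sets that are significantly enriched (present in the NES
#' matrix) with opposite NES sign in the two contrasts — e.g. induced in
#' the knockout female hyperoxia response but suppressed in the wild-type
#' female response — sorted by the NES gap.
#'
#' @param nes An NES matrix from [nes_matrix()].
#' @param contrast_a,contrast_b Column names to compare.
#' @return A tibble `pathway`, `nes_a`, `nes_b`, `nes_gap`, sorted by
#'   `nes_gap` descending.
#' @export
discordant_pathways <- function(nes, contrast_a, contrast_b) {
  miss <- setdiff(c(contrast_a, contrast_b), colnames(nes))
  if (length(miss)) abort(paste0("unknown contrast(s): ", paste(miss, collapse = ", ")))
  a <- nes[, contrast_a]; b <- nes[, contrast_b]
  sel <- !is.na(a) & !is.na(b) & sign(a) * sign(b) < 0
  out <- tibble(pathway = rownames(nes)[sel], nes_a = unname(a[sel]),
                nes_b = unname(b[sel]), nes_gap = unname(abs(a[sel] - b[sel])))
  arrange(out, dplyr::desc(.data$nes_gap), .data$pathway)
}
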