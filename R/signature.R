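#' Gene signatures
#'
#' A gene signature is a named pair of disjoint gene-symbol sets: genes
#' up-regulated and genes down-regulated in a contrast (here, hyperoxia
#' over room air in one sex-by-genotype group), together with the
#' thresholds that produced it.
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene symbols; must be disjoint.
#' @param provenance Optional named list recording how the sets were derived
#'   (e.g. the FDR and fold-change thresholds).
#' @return An object of class `gene_signature`.
#' @examples
#' sig <- gene_signature("demo", up = c("Sox2", "Tbp"), down = "Vcl")
#' tidy(sig)
#' @export
gene_signature <- function(name, up = character(), down = character(),
                           provenance = list()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both)) {
    abort(paste0("up and down sets must be disjoint; shared: ",
                 paste(head(both, 5), collapse = ", ")))
  }
  structure(list(name = as.character(name), up = up, down = down,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' @export
tidy.gene_signature <- function(x, ...) {
  tibble(signature = x$name,
         gene = c(x$up, x$down),
         direction = rep(c("up", "down"), c(length(x$up), length(x$down))))
}

#' Swap the up and down sets of a signature
#'
#' Useful for sign checks: summed z-scores of the flipped signature are the
#' exact negation of the original scores.
#'
#' @param sig A [gene_signature()].
#' @return A `gene_signature` with up and down exchanged.
#' @export
flip_signature <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  gene_signature(paste0(sig$name, "_flipped"), up = sig$down, down = sig$up,
                 provenance = sig$provenance)
}

#' Threshold a differential-expression table into a signature
#'
#' Applies the study's significance rule: a gene enters the signature when
#' its BH-adjusted q-value is at most `fdr_max` and its fold change is at
#' least `min_fold` (i.e. |log2FC| >= log2(min_fold)); both bounds are
#' inclusive. Genes passing with positive log2FC go to `up`, negative to
#' `down`.
#'
#' @param deg A DEG tibble from [differential_expression()] (columns `gene`,
#'   `log2_fc`, `p_value`, `q_value`).
#' @param fdr_max Maximum BH q-value (default 0.05).
#' @param min_fold Minimum linear fold change (default 1.5; must be > 1).
#' @param name Signature name; defaults to the table's contrast label.
#' @return A [gene_signature()] with the thresholds in `provenance`.
#' @export
extract_signature <- function(deg, fdr_max = 0.05, min_fold = 1.5,
                              name = NULL) {
  if (fdr_max <= 0 || min_fold <= 1) {
    abort("fdr_max must be > 0 and min_fold must be > 1")
  }
  need <- c("gene", "log2_fc", "q_value")
  miss <- setdiff(need, names(deg))
  if (length(miss)) abort(paste0("DEG table missing column(s): ", paste(miss, collapse = ", ")))
  if (is.null(name)) {
    name <- attr(deg, "contrast") %||% "signature"
  }
  lfc_min <- log2(min_fold)
  hit <- deg$q_value <= fdr_max
  gene_signature(
    name,
    up = deg$gene[hit & deg$log2_fc >= lfc_min],
    down = deg$gene[hit & deg$log2_fc <= -lfc_min],
    provenance = list(fdr_max = fdr_max, min_fold = min_fold)
  )
}

#' Count shared and discordant genes across signatures
#'
#' For every subset of two or more signatures, counts the genes up-regulated
#' in all of them and the genes down-regulated in all of them (the
#' intersections displayed in an upset plot); for every ordered pair, counts
#' genes moving in opposite directions (up in the first, down in the
#' second).
#'
#' @param signatures A list of [gene_signature()] objects with unique names.
#' @return A tibble with columns `signatures` (names joined by `&`),
#'   `direction` (`"up"`, `"down"`, or `"opposite"`; for `"opposite"` the
#'   first named signature carries the up genes), `n_genes`, and a `genes`
#'   list-column.
#' @export
signature_overlaps <- function(signatures) {
  stopifnot(is.list(signatures), all(vapply(signatures, inherits, TRUE, "gene_signature")))
  if (length(signatures) < 2L) abort("need at least 2 signatures")
  nm <- vapply(signatures, function(s) s$name, character(1))
  if (anyDuplicated(nm)) abort("duplicate signature names")
  names(signatures) <- nm

  rows <- list()
  for (k in 2:length(nm)) {
    for (idx in utils::combn(length(nm), k, simplify = FALSE)) {
      sub <- signatures[idx]
      for (dir in c("up", "down")) {
        shared <- Reduce(intersect, lapply(sub, `[[`, dir))
        rows[[length(rows) + 1L]] <- tibble(
          signatures = paste(nm[idx], collapse = " & "),
          direction = dir, n_genes = length(shared), genes = list(sort(shared)))
      }
    }
  }
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i == j) next
      opp <- intersect(signatures[[i]]$up, signatures[[j]]$down)
      rows[[length(rows) + 1L]] <- tibble(
        signatures = paste(nm[i], nm[j], sep = " & "),
        direction = "opposite", n_genes = length(opp), genes = list(sort(opp)))
    }
  }
  bind_rows(rows)
}

#' Read or write a signature file
#'
#' Two-column tab-delimited text: `direction<TAB>gene`, with `direction` in
#' `up`/`down`; comment lines beginning `#` carry the name and provenance.
#'
#' @param path File path.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  name <- sub("^# *signature: *", "", meta[grepl("^# *signature:", meta)])
  if (!length(name)) name <- "signature"
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) abort(paste0("malformed signature line ", bad[1]))
  dir <- vapply(parts, `[[`, character(1), 1)
  gene <- vapply(parts, `[[`, character(1), 2)
  gene_signature(name[1], up = gene[dir == "up"], down = gene[dir == "down"])
}

#' @rdname read_signature
#' @param sig A [gene_signature()].
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  hdr <- paste0("# signature: ", sig$name)
  if (length(sig$provenance)) {
    hdr <- c(hdr, paste0("# ", names(sig$provenance), ": ",
                         vapply(sig$provenance, format, character(1))))
  }
  body <- c(paste0("up\t", sig$up), paste0("down\t", sig$down))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
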