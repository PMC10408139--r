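#' Read a Biomart-style ortholog map
#'
#' Two-column tab-delimited text, `source_symbol<TAB>target_symbol`, with an
#' optional header line. Duplicate pairs are collapsed with a message.
#' Symbol matching throughout is case-sensitive: mouse (`Sox2`) and human
#' (`SOX2`) conventions differ by case, and silent case-folding would mask
#' map-direction errors.
#'
#' @param path File path.
#' @return A tibble with columns `source_symbol`, `target_symbol`.
#' @export
read_ortholog_map <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(paste0("malformed ortholog line ", bad[1], ": expected 2 tab-separated fields"))
  }
  map <- tibble(source_symbol = vapply(parts, `[[`, character(1), 1),
                target_symbol = vapply(parts, `[[`, character(1), 2))
  if (identical(tolower(unlist(map[1, ])), c("source_symbol", "target_symbol"))) {
    map <- map[-1, ]
  }
  n0 <- nrow(map)
  map <- distinct(map)
  if (nrow(map) < n0) {
    inform(paste0("dropped ", n0 - nrow(map), " duplicate ortholog pair(s)"))
  }
  if (any(!nzchar(map$source_symbol) | !nzchar(map$target_symbol))) {
    abort("empty symbol in ortholog map")
  }
  map
}

#' @rdname read_ortholog_map
#' @param map An ortholog-map tibble.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(map[c("source_symbol", "target_symbol")], path,
                   progress = FALSE)
  invisible(path)
}

#' Reverse the direction of an ortholog map
#'
#' @param map An ortholog-map tibble.
#' @return The map with source and target exchanged.
#' @export
invert_ortholog_map <- function(map) {
  distinct(tibble(source_symbol = map$target_symbol,
                  target_symbol = map$source_symbol))
}

new_translation_report <- function(translated, dropped, collapsed, expanded,
                                   conflicts = character()) {
  structure(list(n_translated = length(translated),
                 n_dropped_unmapped = length(dropped),
                 n_collapsed_many_to_one = length(collapsed),
                 n_expanded_one_to_many = length(expanded),
                 translated = translated, dropped = dropped,
                 collapsed = collapsed, expanded = expanded,
                 conflicts = conflicts),
            class = "translation_report")
}

#' @export
print.translation_report <- function(x, ...) {
  cat("<translation_report> translated:", x$n_translated,
      "| dropped:", x$n_dropped_unmapped,
      "| many-to-one targets:", x$n_collapsed_many_to_one,
      "| one-to-many sources:", x$n_expanded_one_to_many, "\n")
  if (length(x$conflicts)) cat("  direction conflicts:", length(x$conflicts), "\n")
  invisible(x)
}

#' @export
tidy.translation_report <- function(x, ...) {
  tibble(category = c("translated", "dropped_unmapped",
                      "collapsed_many_to_one", "expanded_one_to_many",
                      "conflict"),
         n = c(x$n_translated, x$n_dropped_unmapped,
               x$n_collapsed_many_to_one, x$n_expanded_one_to_many,
               length(x$conflicts)),
         symbols = list(x$translated, x$dropped, x$collapsed, x$expanded,
                        x$conflicts))
}

#' Translate an expression matrix into another species' symbol space
#'
#' Rows whose symbol has no ortholog are dropped; several source rows
#' mapping to one target symbol are collapsed by their arithmetic mean on
#' the log scale; a source row mapping to several targets is duplicated
#' under each target. The default pipeline orientation follows the stated
#' procedure of converting human symbols to mouse symbols, so the human
#' matrix is translated and the mouse signatures stay untouched.
#'
#' @param expr A gene-by-sample expression tibble.
#' @param map Ortholog map whose `source_symbol` space matches the matrix.
#' @return A list with `expression` (translated tibble, rows sorted by
#'   target symbol) and `report` (a `translation_report`).
#' @export
translate_matrix <- function(expr, map) {
  m <- as_expr_matrix(expr)
  hit <- map[map$source_symbol %in% rownames(m), , drop = FALSE]
  if (!nrow(hit)) {
    abort("no matrix symbol appears in the map's source column; wrong direction or species?")
  }
  dropped <- setdiff(rownames(m), hit$source_symbol)
  src_rows <- m[hit$source_symbol, , drop = FALSE]
  tgt <- hit$target_symbol
  # many-to-one collapse: mean of source rows per target
  out <- rowsum(src_rows, group = tgt, reorder = TRUE)
  cnt <- as.vector(table(tgt)[rownames(out)])
  out <- out / cnt
  collapsed <- rownames(out)[cnt > 1]
  expanded <- unique(hit$source_symbol[duplicated(hit$source_symbol)])
  report <- new_translation_report(translated = unique(hit$source_symbol),
                                   dropped = dropped, collapsed = collapsed,
                                   expanded = expanded)
  list(expression = expr_tbl(out), report = report)
}

#' Translate a gene signature into another species' symbol space
#'
#' Alternative orientation to [translate_matrix()]: the signature's up and
#' down sets are mapped. A target symbol landing in both sets after
#' one-to-many expansion is removed from both and reported as a conflict.
#'
#' @param sig A [gene_signature()].
#' @param map Ortholog map whose `source_symbol` space matches the
#'   signature.
#' @return A list with `signature` and `report`.
#' @export
translate_signature <- function(sig, map) {
  stopifnot(inherits(sig, "gene_signature"))
  genes <- c(sig$up, sig$down)
  hit <- map[map$source_symbol %in% genes, , drop = FALSE]
  if (!nrow(hit)) {
    abort("no signature symbol appears in the map's source column; wrong direction or species?")
  }
  up_t <- unique(hit$target_symbol[hit$source_symbol %in% sig$up])
  down_t <- unique(hit$target_symbol[hit$source_symbol %in% sig$down])
  conflict <- intersect(up_t, down_t)
  dropped <- setdiff(genes, hit$source_symbol)
  expanded <- unique(hit$source_symbol[duplicated(hit$source_symbol)])
  collapsed <- unique(hit$target_symbol[duplicated(hit$target_symbol)])
  out <- gene_signature(sig$name, up = setdiff(up_t, conflict),
                        down = setdiff(down_t, conflict),
                        provenance = c(sig$provenance, list(translated = TRUE)))
  report <- new_translation_report(translated = unique(hit$source_symbol),
                                   dropped = dropped, collapsed = collapsed,
                                   expanded = expanded, conflicts = conflict)
  list(signature = out, report = report)
}
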