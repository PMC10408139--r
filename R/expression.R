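#' Expression and count tables
#'
#' Throughout oxisig a gene-by-sample data set is an ordinary tibble whose
#' first column, `gene`, holds unique gene symbols and whose remaining
#' columns are one numeric column per sample. Counts are nonnegative
#' integers; expression values are on the log2 scale unless a function
#' documents otherwise.
#'
#' @param x A gene-by-sample tibble.
#' @param counts Logical; additionally require nonnegative integer values.
#' @return `x`, invisibly, after validation.
#' @examples
#' expr <- tibble::tibble(gene = c("Sox2", "Tbp"), s1 = c(1, 2), s2 = c(3, 4))
#' validate_expression(expr)
#' @export
validate_expression <- function(x, counts = FALSE) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort("expected a data frame with a `gene` column plus >= 1 sample column")
  }
  if (names(x)[1] != "gene") {
    abort("first column must be named `gene`")
  }
  genes <- x$gene
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("duplicate gene symbols: ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (anyNA(vals)) abort("missing values are not allowed")
  if (counts) {
    if (any(vals < 0)) abort("counts must be nonnegative")
    if (any(vals != floor(vals))) abort("counts must be integers")
  }
  invisible(x)
}

# tibble (gene + samples) -> named numeric matrix
as_expr_matrix <- function(x) {
  validate_expression(x)
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene
  m
}

# named matrix -> canonical tibble
expr_tbl <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

#' Read or write a gene-by-sample table
#'
#' Tab-delimited text with the gene symbol in the first column and one
#' column per sample, the layout used for both raw counts and normalized
#' expression.
#'
#' @param path File path.
#' @param counts Logical; validate values as nonnegative integer counts.
#' @return A gene-by-sample tibble (see [validate_expression()]).
#' @export
read_expression <- function(path, counts = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  validate_expression(x, counts = counts)
  x
}

#' @rdname read_expression
#' @param x A gene-by-sample tibble.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read factorial sample metadata
#'
#' CSV with header `sample_id,sex,genotype,treatment`: sex in `F`/`M`,
#' genotype in `WT`/`KO`, treatment in `room_air`/`hyperoxia`.
#'
#' @param path File path.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "sex", "genotype", "treatment")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("metadata missing column(s): ", paste(miss, collapse = ", ")))
  x
}

#' Read a clinical covariate table
#'
#' CSV with header
#' `sample_id,sex,gestational_age_weeks,birth_weight_g,bpd_severity,oxygen_28d`.
#' BPD severity is the ordinal grade 0 (none), 1 (mild), 2 (moderate),
#' 3 (severe); `oxygen_28d` is 0/1 oxygen requirement at 28 days.
#'
#' @param path File path.
#' @return A tibble with one row per subject.
#' @export
read_clinical <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical(x)
  x
}

validate_clinical <- function(x) {
  need <- c("sample_id", "sex", "gestational_age_weeks", "birth_weight_g",
            "bpd_severity", "oxygen_28d")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("clinical table missing column(s): ", paste(miss, collapse = ", ")))
  if (!all(x$bpd_severity %in% 0:3)) abort("bpd_severity must be in 0..3")
  if (any(x$gestational_age_weeks <= 0)) abort("gestational_age_weeks must be > 0")
  if (any(x$birth_weight_g <= 0)) abort("birth_weight_g must be > 0")
  invisible(x)
}

#' @rdname read_clinical
#' @param x A clinical tibble.
#' @export
write_clinical <- function(x, path) {
  validate_clinical(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
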