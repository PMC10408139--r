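#' Per-gene z-scoring across samples
#'
#' Standardizes every gene row across samples: `z = (x - mean) / sd`, with
#' the sample standard deviation (n - 1 denominator). Zero-variance genes
#' cannot be standardized; their rows are set to zero and flagged (zero is
#' the only value that keeps summed scores antisymmetric under up/down
#' exchange).
#'
#' @param expr A gene-by-sample expression tibble with >= 2 samples.
#' @return A gene-by-sample tibble of z-scores with attribute
#'   `zero_variance` (character vector of flagged genes).
#' @examples
#' z <- zscore_matrix(tibble::tibble(gene = "g1", a = 1, b = 2, c = 3))
#' unlist(z[1, -1])  # -1, 0, 1
#' @export
zscore_matrix <- function(expr) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 2L) abort("z-scoring needs at least 2 samples")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  flat <- s == 0
  s[flat] <- 1
  z <- (m - mu) / s
  z[flat, ] <- 0
  out <- expr_tbl(z)
  attr(out, "zero_variance") <- rownames(m)[flat]
  out
}

#' Summed z-score of one signature
#'
#' The per-sample signature score: the sum of the sample's z-scores over
#' the signature's up genes minus the sum over its down genes. Signature
#' genes absent from the matrix are skipped and reported in the coverage
#' attribute; the score is a plain sum, not rescaled by signature size
#' (downstream Pearson correlations are unaffected by scale).
#'
#' @param z A z-scored tibble from [zscore_matrix()].
#' @param sig A [gene_signature()].
#' @return A tibble with columns `sample_id`, `score` and attribute
#'   `coverage` (list with counts of genes used and missing).
#' @export
summed_zscore <- function(z, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  m <- as_expr_matrix(z)
  up <- intersect(sig$up, rownames(m))
  down <- intersect(sig$down, rownames(m))
  if (length(up) + length(down) == 0L) {
    abort(paste0("no gene of signature '", sig$name,
                 "' is present in the matrix; score undefined"))
  }
  score <- colSums(m[up, , drop = FALSE]) - colSums(m[down, , drop = FALSE])
  missing <- setdiff(c(sig$up, sig$down), rownames(m))
  out <- tibble(sample_id = colnames(m), score = unname(score))
  attr(out, "coverage") <- list(
    n_up_used = length(up), n_down_used = length(down),
    n_missing = length(missing), missing = missing,
    fraction = (length(up) + length(down)) /
      max(1L, length(sig$up) + length(sig$down)))
  out
}

#' Score several signatures on one expression cohort
#'
#' Z-scores the matrix once and computes every signature's summed z-score
#' on it. A signature with no gene in the matrix is dropped with a warning
#' rather than failing the batch; per-signature coverage is attached.
#'
#' @param expr A gene-by-sample expression tibble.
#' @param signatures A list of [gene_signature()] objects.
#' @return A `sig_scores` tibble with columns `signature`, `sample_id`,
#'   `score`, and attribute `coverage` (tibble of per-signature gene
#'   coverage).
#' @export
score_signatures <- function(expr, signatures) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  stopifnot(length(signatures) >= 1L,
            all(vapply(signatures, inherits, TRUE, "gene_signature")))
  z <- zscore_matrix(expr)
  rows <- list(); cov <- list()
  for (sig in signatures) {
    res <- tryCatch(summed_zscore(z, sig), error = function(e) NULL)
    if (is.null(res)) {
      warn(paste0("signature '", sig$name,
                  "' has no gene in the matrix; dropped"))
      next
    }
    cv <- attr(res, "coverage")
    rows[[sig$name]] <- mutate(res, signature = sig$name, .before = 1)
    cov[[sig$name]] <- tibble(signature = sig$name,
                              n_up_used = cv$n_up_used,
                              n_down_used = cv$n_down_used,
                              n_missing = cv$n_missing,
                              coverage = cv$fraction)
  }
  if (!length(rows)) abort("no signature had any gene in the matrix")
  out <- bind_rows(rows)
  attr(out, "coverage") <- bind_rows(cov)
  class(out) <- c("sig_scores", class(out))
  out
}

#' Widen signature scores to a signature-by-sample matrix
#'
#' @param scores A `sig_scores` tibble from [score_signatures()].
#' @return A numeric matrix, signatures in rows, samples in columns.
#' @export
scores_as_matrix <- function(scores) {
  need <- c("signature", "sample_id", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) abort(paste0("scores missing column(s): ", paste(miss, collapse = ", ")))
  wide <- tidyr::pivot_wider(as_tibble(scores)[need],
                             names_from = "sample_id", values_from = "score")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$signature
  m
}

#' @rdname score_signatures
#' @param x A `sig_scores` tibble.
#' @param ... Unused.
#' @export
glance.sig_scores <- function(x, ...) {
  cov <- attr(x, "coverage")
  smry <- summarise(group_by(as_tibble(x), .data$signature),
                    n_samples = n(), mean_score = mean(.data$score),
                    sd_score = sd(.data$score), .groups = "drop")
  if (!is.null(cov)) smry <- left_join(smry, cov, by = "signature")
  smry
}
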