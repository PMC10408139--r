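#' Pearson correlation with exact t-based p-value
#'
#' Standard Pearson r with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (the
#' scientific-library default). A constant input makes the correlation
#' undefined; the result is flagged not-computable rather than reported as
#' r = 0.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return A one-row tibble with columns `r`, `p_value`, `n`, `computable`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = n, computable = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  tibble(r = r, p_value = p, n = n, computable = TRUE)
}

#' Pairwise correlation of signature scores over a cohort
#'
#' All pairwise Pearson correlations between signature score vectors across
#' the samples of a cohort (the statistic behind co-variation heatmaps over
#' a large reference cohort). Symmetry and a unit diagonal are exact;
#' constant score rows yield not-computable (NA) entries.
#'
#' @param scores A `sig_scores` tibble from [score_signatures()] or a
#'   signature-by-sample matrix.
#' @return A `sig_cor` object: list with matrices `r` and `p_value`, and
#'   `n` (samples used).
#' @export
inter_signature_correlation <- function(scores) {
  m <- if (is.matrix(scores)) scores else scores_as_matrix(scores)
  if (nrow(m) < 2L) abort("need at least 2 signatures")
  if (ncol(m) < 3L) abort("need at least 3 samples")
  k <- nrow(m)
  r <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(rownames(m), rownames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- pearson(m[i, ], m[j, ])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p_value
    }
  }
  const <- apply(m, 1, sd) == 0
  diag(r)[const] <- NA_real_
  structure(list(r = r, p_value = p, n = ncol(m)), class = "sig_cor")
}

#' @export
print.sig_cor <- function(x, digits = 3, ...) {
  cat("<sig_cor> Pearson correlation of", nrow(x$r), "signatures over",
      x$n, "samples\n")
  print(round(x$r, digits))
  invisible(x)
}

#' @export
tidy.sig_cor <- function(x, ...) {
  nm <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(signature_a = nm[idx[, 1]], signature_b = nm[idx[, 2]],
         r = x$r[idx], p_value = x$p_value[idx], n = x$n)
}

#' Hierarchical clustering of signatures or pathways
#'
#' Agglomerative clustering with correlation distance `d = 1 - r` and
#' average linkage, as used for signature-correlation and NES heatmaps.
#' Rows are sorted lexicographically by label before clustering so tied
#' merge heights resolve deterministically.
#'
#' @param x A `sig_cor` object, a symmetric correlation matrix, or a
#'   numeric matrix of profiles (e.g. pathways-by-contrasts NES) whose row
#'   correlations are clustered.
#' @return An [stats::hclust] tree.
#' @export
cluster_signatures <- function(x) {
  r <- if (inherits(x, "sig_cor")) {
    x$r
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             isTRUE(all.equal(unname(x), unname(t(x)))) &&
             all(abs(diag(x) - 1) < 1e-8, na.rm = TRUE)) {
    x
  } else if (is.matrix(x)) {
    if (anyNA(x)) abort("profile matrix contains NA; drop incomplete rows first")
    suppressWarnings(cor(t(x)))
  } else {
    abort("x must be a sig_cor object or a numeric matrix")
  }
  if (anyNA(r)) {
    abort("correlation matrix has not-computable entries; drop the offending rows first")
  }
  if (nrow(r) == 1L) {
    return(structure(list(merge = matrix(numeric(0), 0, 2), height = numeric(0),
                          order = 1L, labels = rownames(r),
                          method = "average", dist.method = "1 - r"),
                     class = "hclust"))
  }
  ord <- order(rownames(r))
  r <- r[ord, ord]
  hclust(as.dist(1 - r), method = "average")
}

#' Correlate signature scores with clinical variables, by stratum
#'
#' For each signature, clinical variable and stratum, the Pearson
#' correlation between the per-subject signature score and the variable.
#' Default variables are the four used in the BPD analysis (gestational
#' age, birth weight, BPD severity, oxygen at 28 days); ordinal BPD
#' severity is used on its 0-3 scale (a binary any-BPD encoding is
#' available via `bpd_binary`). Default strata are the whole cohort and
#' each sex. Strata with fewer than 3 subjects are reported as
#' not-computable rather than dropped.
#'
#' @param scores A `sig_scores` tibble whose `sample_id`s match the
#'   clinical table.
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @param variables Clinical columns to correlate.
#' @param stratify_by `"all"`, `"sex"`, or both (default).
#' @param bpd_binary Recode `bpd_severity` as 0 (none) vs 1 (any BPD).
#' @return A tibble with columns `signature`, `variable`, `stratum`, `r`,
#'   `p_value`, `n`, `computable`.
#' @export
clinical_correlation <- function(scores, clinical,
                                 variables = c("gestational_age_weeks",
                                               "birth_weight_g",
                                               "bpd_severity", "oxygen_28d"),
                                 stratify_by = c("all", "sex"),
                                 bpd_binary = FALSE) {
  sc <- as_tibble(scores)
  miss_var <- setdiff(variables, names(clinical))
  if (length(miss_var)) abort(paste0("clinical table missing variable(s): ", paste(miss_var, collapse = ", ")))
  mism <- setdiff(unique(sc$sample_id), clinical$sample_id)
  if (length(mism)) {
    abort(paste0("score sample ids absent from clinical table: ",
                 paste(head(mism, 5), collapse = ", ")))
  }
  if (bpd_binary && "bpd_severity" %in% names(clinical)) {
    clinical$bpd_severity <- as.integer(clinical$bpd_severity > 0)
  }
  dat <- left_join(sc, clinical, by = "sample_id")
  strata <- list()
  if ("all" %in% stratify_by) strata[["all"]] <- rep(TRUE, nrow(dat))
  if ("sex" %in% stratify_by) {
    for (s in sort(unique(clinical$sex))) {
      strata[[paste0("sex=", s)]] <- dat$sex == s
    }
  }
  if (!length(strata)) abort("stratify_by must include 'all' and/or 'sex'")

  out <- list()
  for (st in names(strata)) {
    sub <- dat[strata[[st]], , drop = FALSE]
    for (sig in unique(sc$signature)) {
      ss <- sub[sub$signature == sig, , drop = FALSE]
      for (v in variables) {
        res <- if (nrow(ss) < 3) {
          tibble(r = NA_real_, p_value = NA_real_, n = nrow(ss),
                 computable = FALSE)
        } else {
          pearson(ss$score, as.numeric(ss[[v]]))
        }
        out[[length(out) + 1L]] <- bind_cols(
          tibble(signature = sig, variable = v, stratum = st), res)
      }
    }
  }
  bind_rows(out)
}
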