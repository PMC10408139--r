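#' qRT-PCR fold change by the 2^-ddCt method
#'
#' Relative expression with multi-housekeeping normalization and
#' sex-specific baselining. Per sample, the target Ct is normalized by the
#' arithmetic mean of that sample's housekeeping Cts (equivalently, the
#' geometric mean of their expression levels):
#' `dCt = Ct_target - mean(Ct_housekeeping)`. The reference baseline is the
#' mean dCt over the reference-group samples of the same sex, and the fold
#' change is `2^-(dCt - baseline)`.
#'
#' @param ct Long tibble with columns `sample_id`, `sex`, `group`, `gene`,
#'   `ct` (cycles, > 0); one row per gene measurement.
#' @param target Target gene symbol.
#' @param housekeeping Character vector of housekeeping gene symbols (every
#'   sample needs at least one measured).
#' @param reference_group Group label used as baseline (e.g. `"room_air"`);
#'   must be non-empty within every sex stratum present.
#' @return A tibble with one row per sample: `sample_id`, `sex`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("a", "b"), each = 2), sex = "F",
#'   group = rep(c("room_air", "hyperoxia"), each = 2),
#'   gene = rep(c("Tgt", "Tbp"), 2), ct = c(25, 20, 24, 20))
#' ddct_fold_change(ct, "Tgt", "Tbp", "room_air")  # fold 2 in hyperoxia
#' @export
ddct_fold_change <- function(ct, target, housekeeping, reference_group) {
  need <- c("sample_id", "sex", "group", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) abort(paste0("Ct table missing column(s): ", paste(miss, collapse = ", ")))
  if (any(ct$ct <= 0)) abort("Ct values must be > 0")

  hk <- filter(ct, .data$gene %in% housekeeping) |>
    group_by(.data$sample_id) |>
    summarise(hk_ct = mean(.data$ct), .groups = "drop")
  tg <- filter(ct, .data$gene == target) |>
    select("sample_id", "sex", "group", "ct")
  if (!nrow(tg)) abort(paste0("no Ct rows for target gene ", target))
  no_hk <- setdiff(tg$sample_id, hk$sample_id)
  if (length(no_hk)) {
    abort(paste0("sample(s) without housekeeping Cts: ", paste(head(no_hk, 5), collapse = ", ")))
  }
  d <- left_join(tg, hk, by = "sample_id") |>
    mutate(delta_ct = .data$ct - .data$hk_ct)

  base <- filter(d, .data$group == reference_group) |>
    group_by(.data$sex) |>
    summarise(base_dct = mean(.data$delta_ct), .groups = "drop")
  missing_sex <- setdiff(unique(d$sex), base$sex)
  if (length(missing_sex)) {
    abort(paste0("reference group '", reference_group,
                 "' empty for sex stratum: ", paste(missing_sex, collapse = ", ")))
  }
  left_join(d, base, by = "sex") |>
    mutate(delta_delta_ct = .data$delta_ct - .data$base_dct,
           fold_change = 2^(-.data$delta_delta_ct)) |>
    select("sample_id", "sex", "group", "delta_ct", "delta_delta_ct",
           "fold_change")
}

#' Per-group geometric-mean fold changes
#'
#' @param folds Output of [ddct_fold_change()].
#' @return A tibble with per sex-and-group geometric mean fold change and n.
#' @export
group_fold_changes <- function(folds) {
  group_by(folds, .data$sex, .data$group) |>
    summarise(geom_mean_fold = exp(mean(log(.data$fold_change))),
              n = n(), .groups = "drop")
}
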