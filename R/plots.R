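#' Plot methods
#'
#' ggplot2 visualizations of the main result types: a correlation heatmap
#' for `sig_cor`, score distributions for `sig_scores`, an NES bar chart
#' for `gsea_result`, plus score-vs-severity panels and an NES heatmap.
#'
#' @param object,x The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name oxisig-plots
NULL

#' @rdname oxisig-plots
#' @export
autoplot.sig_cor <- function(object, ...) {
  d <- tidyr::expand_grid(signature_a = rownames(object$r),
                          signature_b = colnames(object$r)) |>
    mutate(r = as.vector(t(object$r)))
  ggplot2::ggplot(d, ggplot2::aes(.data$signature_b, .data$signature_a,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Inter-signature correlation") +
    ggplot2::theme_minimal()
}

#' @rdname oxisig-plots
#' @export
autoplot.sig_scores <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$signature, .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "summed z-score") +
    ggplot2::theme_minimal()
}

#' @rdname oxisig-plots
#' @export
autoplot.gsea_result <- function(object, ...) {
  d <- mutate(as_tibble(object), significant = .data$fdr_q < 0.25)
  ggplot2::ggplot(d, ggplot2::aes(.data$nes,
                                  stats::reorder(.data$set, .data$nes),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "NES", y = NULL, fill = "FDR q < 0.25") +
    ggplot2::theme_minimal()
}

#' @rdname oxisig-plots
#' @param scores A `sig_scores` tibble over a clinical cohort.
#' @param clinical The matching clinical table.
#' @export
plot_score_severity <- function(scores, clinical) {
  d <- left_join(as_tibble(scores), clinical, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$bpd_severity), .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~signature, scales = "free_y") +
    ggplot2::labs(x = "BPD severity (0 none - 3 severe)",
                  y = "summed z-score") +
    ggplot2::theme_minimal()
}

#' @rdname oxisig-plots
#' @param nes An NES matrix from [nes_matrix()].
#' @export
plot_nes_heatmap <- function(nes) {
  d <- as_tibble(as.data.frame(nes), rownames = "pathway") |>
    tidyr::pivot_longer(-"pathway", names_to = "contrast", values_to = "nes")
  ggplot2::ggplot(d, ggplot2::aes(.data$contrast, .data$pathway,
                                  fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "NES") +
    ggplot2::theme_minimal()
}
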