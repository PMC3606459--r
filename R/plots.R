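# ggplot2 views of the main result types.

#' Plot per-sample QC statistics
#'
#' Scatter of raw call count against LRR standard deviation with the two QC
#' thresholds drawn as dashed lines; excluded samples are coloured by reason.
#'
#' @param samples Output of [apply_qc()].
#' @param max_num_cnv,max_lrr_sd The thresholds to draw (defaults match
#'   [apply_qc()]).
#' @return A ggplot object.
#' @export
plot_qc <- function(samples, max_num_cnv = 30, max_lrr_sd = 0.24) {
  if (!"qc_pass" %in% names(samples)) abort("run apply_qc() first")
  samples %>%
    mutate(qc = if_else(.data$qc_pass, "pass", .data$qc_reason)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$num_cnv, y = .data$lrr_sd,
                                 colour = .data$qc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = max_num_cnv, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = max_lrr_sd, linetype = "dashed") +
    ggplot2::labs(x = "raw CNV calls per sample", y = "LRR SD",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the CNV size distribution by state
#'
#' Histogram of log10 call size, faceted by deletion/duplication, with the
#' size-bin boundaries marked.
#'
#' @param calls CNV call tibble.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(calls) {
  calls %>%
    mutate(size = cnv_size(calls)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$size, fill = .data$state)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = c(1e4, 1e5, 5e5), linetype = "dotted") +
    ggplot2::labs(x = "CNV size (bp)", y = "calls", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a burden table
#'
#' Side-by-side per-individual CNV frequencies for cases and controls across
#' the four size bins.
#'
#' @param object A `cnv_burden` table from [build_burden_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_burden
#' @export
autoplot.cnv_burden <- function(object, ...) {
  as_tibble(object) %>%
    filter(.data$size_bin != "Total") %>%
    tidyr::pivot_longer(c("freq_case", "freq_control"),
                        names_to = "group", values_to = "freq",
                        names_prefix = "freq_") %>%
    mutate(size_bin = factor(.data$size_bin, levels = size_bins())) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$size_bin, y = .data$freq,
                                 fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CNV size", y = "CNVs per individual", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot MLPA probe ratios for one sample
#'
#' Probe-level normalized ratios in assay order with the deletion and
#' duplication calling thresholds.
#'
#' @param mlpa MLPA tibble for one sample.
#' @param del_threshold,dup_threshold Thresholds to draw (defaults match
#'   [call_mlpa_cnv()]).
#' @return A ggplot object.
#' @export
plot_mlpa_ratios <- function(mlpa, del_threshold = 0.75,
                             dup_threshold = 1.30) {
  if (n_distinct(mlpa$sample_id) != 1) {
    abort("supply measurements for exactly one sample")
  }
  mlpa %>%
    arrange(.data$gene, .data$position) %>%
    mutate(probe = factor(.data$probe_id, levels = unique(.data$probe_id))) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$probe, y = .data$normalized_ratio,
                                 colour = .data$gene)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(del_threshold, 1, dup_threshold),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = NULL, y = "normalized ratio", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
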