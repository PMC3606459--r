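# Per-sample QC gate, run on RAW calls before any merging or filtering:
# the call-count threshold indexes array noise and must see the unfiltered
# call count.

#' Count raw CNV calls per sample
#'
#' Adds (or overwrites) the `num_cnv` column of the sample table with the raw
#' per-sample call count. Samples absent from the call table get 0. Counting
#' happens before merging and filtering, since the QC thresholds were defined
#' on raw caller output.
#'
#' @param samples Sample tibble (see [read_sample_table()]).
#' @param calls Raw CNV call tibble.
#' @return `samples` with an integer `num_cnv` column.
#' @export
compute_num_cnv <- function(samples, calls) {
  unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("calls reference unknown sample ids: ",
                 paste(unknown, collapse = ", ")))
  }
  counts <- count(calls, .data$sample_id, name = "num_cnv")
  samples$num_cnv <- NULL
  samples %>%
    left_join(counts, by = "sample_id") %>%
    mutate(num_cnv = if_else(is.na(.data$num_cnv), 0L, as.integer(.data$num_cnv)))
}

#' Apply the sample QC gate
#'
#' Excludes outlier samples: more than `max_num_cnv` raw calls or a LogR-ratio
#' standard deviation above `max_lrr_sd`. Both thresholds are strict, so
#' boundary values (exactly 30 calls, exactly 0.24) pass. Exclusion reasons
#' are recorded per sample as `"NUM_CNV"`, `"LRR_SD"`, or
#' `"NUM_CNV,LRR_SD"`.
#'
#' @param samples Sample tibble with populated `num_cnv` and `lrr_sd`.
#' @param max_num_cnv Maximum acceptable raw call count (default 30).
#' @param max_lrr_sd Maximum acceptable LRR standard deviation (default 0.24).
#' @return `samples` with logical `qc_pass` and character `qc_reason`
#'   (`NA` for passing samples) columns. The passing and excluded rows
#'   partition the input.
#' @examples
#' s <- tibble::tibble(sample_id = c("a", "b"), cohort = "Antioquia",
#'                     status = "case", batch = "b1",
#'                     lrr_sd = c(0.10, 0.30), num_cnv = c(31L, 40L))
#' apply_qc(s)
#' @export
apply_qc <- function(samples, max_num_cnv = 30, max_lrr_sd = 0.24) {
  if (max_num_cnv <= 0 || max_lrr_sd <= 0) abort("QC thresholds must be positive")
  if (!"num_cnv" %in% names(samples)) {
    abort("num_cnv not populated; run compute_num_cnv() first")
  }
  if (!"lrr_sd" %in% names(samples) || any(is.na(samples$lrr_sd))) {
    abort("lrr_sd missing for one or more samples")
  }
  if (any(is.na(samples$num_cnv))) abort("num_cnv missing for one or more samples")
  samples %>%
    mutate(
      fail_num = .data$num_cnv > max_num_cnv,
      fail_lrr = .data$lrr_sd > max_lrr_sd,
      qc_pass = !.data$fail_num & !.data$fail_lrr,
      qc_reason = case_when(
        .data$fail_num & .data$fail_lrr ~ "NUM_CNV,LRR_SD",
        .data$fail_num ~ "NUM_CNV",
        .data$fail_lrr ~ "LRR_SD",
        TRUE ~ NA_character_
      )
    ) %>%
    select(-"fail_num", -"fail_lrr")
}

#' Keep QC-passing samples
#'
#' @param samples Output of [apply_qc()].
#' @return Rows with `qc_pass == TRUE`.
#' @export
qc_passing <- function(samples) {
  if (!"qc_pass" %in% names(samples)) abort("run apply_qc() first")
  filter(samples, .data$qc_pass)
}

#' Keep QC-excluded samples
#'
#' @param samples Output of [apply_qc()].
#' @return Rows with `qc_pass == FALSE`, with their `qc_reason`.
#' @export
qc_excluded <- function(samples) {
  if (!"qc_pass" %in% names(samples)) abort("run apply_qc() first")
  filter(samples, !.data$qc_pass)
}
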