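# Case-only recurrent gene regions: genes whose exons are hit by CNVs in at
# least `min_cases` distinct cases and in zero controls, stratified into
# large (>500 kb) and small (<=500 kb) size classes.

#' Case calls in regions free of control CNVs
#'
#' Returns the case calls in the given size bin that are overlapped by no
#' control call of any size or state (>= 1 bp, 1-based inclusive overlap).
#'
#' @param calls Final processed call tibble with `size_bin`.
#' @param samples Sample tibble with `status` for every calling sample.
#' @param bin One of [size_bins()], the size class of the case calls
#'   (control calls are not size-restricted).
#' @return The case-only subset of `calls`, input order preserved.
#' @export
case_only_calls <- function(calls, samples, bin = ">500 kb") {
  bin <- match.arg(bin, size_bins())
  if (!"size_bin" %in% names(calls)) {
    calls <- mutate(calls, size_bin = assign_size_bin(cnv_size(calls)))
  }
  status <- setNames(samples$status, samples$sample_id)
  if (any(!calls$sample_id %in% names(status))) {
    abort("calls present for samples absent from the sample table")
  }
  is_case <- status[calls$sample_id] == "case"
  case_bin <- calls[is_case & calls$size_bin == bin, ]
  controls <- calls[!is_case, ]
  if (nrow(case_bin) == 0 || nrow(controls) == 0) return(case_bin)
  case_bin[!overlaps_any(case_bin, controls), ]
}

#' Map CNV calls onto gene exons
#'
#' A call hits a gene iff it overlaps at least one exon base; intron-only
#' overlap does not count.
#'
#' @param calls CNV call tibble.
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @return A tibble with one row per (gene, call) hit: `gene`, `sample_id`,
#'   `chrom`, `start`, `end`, `state`, and the call's other columns.
#' @export
gene_exon_hits <- function(calls, genes) {
  if (nrow(calls) == 0 || nrow(genes) == 0) {
    return(mutate(calls[0, ], gene = character()))
  }
  hits <- purrr::map(unique(genes$gene), function(g) {
    ex <- genes[genes$gene == g, ]
    hit <- overlaps_any(calls, ex)
    if (!any(hit)) return(NULL)
    mutate(calls[hit, ], gene = g)
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(mutate(calls[0, ], gene = character()))
  select(out, "gene", dplyr::everything())
}

#' Genes recurrently rearranged in cases but never in controls
#'
#' Identifies genes whose exons are hit by CNVs of the given size class in at
#' least `min_cases` distinct cases while no control call of any size
#' overlaps their exons. A sample hitting one gene with two calls counts
#' once. Case hits are not required to share deletion/duplication state; the
#' state composition is reported instead.
#'
#' @param calls Final processed call tibble with `size_bin`.
#' @param samples Sample tibble with `status`.
#' @param genes Gene model tibble.
#' @param size_class `"large"` (>500 kb) or `"small"` (all other bins).
#' @param min_cases Minimum number of distinct cases hit (default 2).
#' @return A tibble with one row per reported gene: `gene`, `size_class`,
#'   `n_cases_hit`, `n_control_hits` (always 0), `n_del`, `n_dup`, and a
#'   list-column `case_calls` of the supporting call rows.
#' @export
recurrent_genes <- function(calls, samples, genes,
                            size_class = c("large", "small"),
                            min_cases = 2) {
  size_class <- match.arg(size_class)
  if (!"size_bin" %in% names(calls)) {
    calls <- mutate(calls, size_bin = assign_size_bin(cnv_size(calls)))
  }
  status <- setNames(samples$status, samples$sample_id)
  calls <- mutate(calls, status = unname(status[.data$sample_id]))
  in_class <- if (size_class == "large") {
    calls$size_bin == ">500 kb"
  } else {
    calls$size_bin != ">500 kb"
  }
  case_calls <- calls[calls$status == "case" & in_class, ]
  control_calls <- calls[calls$status == "control", ]
  case_hits <- gene_exon_hits(case_calls, genes)
  if (nrow(case_hits) == 0) return(empty_recurrent())
  control_hits <- gene_exon_hits(control_calls, genes)
  case_hits %>%
    group_by(.data$gene) %>%
    summarise(
      n_cases_hit = n_distinct(.data$sample_id),
      n_del = sum(.data$state == "DEL"),
      n_dup = sum(.data$state == "DUP"),
      case_calls = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) %>%
    mutate(
      n_control_hits = purrr::map_int(
        .data$gene, ~ sum(control_hits$gene == .x)),
      size_class = size_class
    ) %>%
    filter(.data$n_cases_hit >= min_cases, .data$n_control_hits == 0) %>%
    select("gene", "size_class", "n_cases_hit", "n_control_hits",
           "n_del", "n_dup", "case_calls") %>%
    arrange(dplyr::desc(.data$n_cases_hit), .data$gene)
}

empty_recurrent <- function() {
  tibble(gene = character(), size_class = character(),
         n_cases_hit = integer(), n_control_hits = integer(),
         n_del = integer(), n_dup = integer(), case_calls = list())
}

#' Calls overlapping no annotated exon
#'
#' Companion report to [recurrent_genes()]: the calls (typically large,
#' case-only ones) that do not include exons of any annotated gene.
#'
#' @param calls CNV call tibble.
#' @param genes Gene model tibble.
#' @return The subset of `calls` with zero exon overlap.
#' @export
calls_without_exon_overlap <- function(calls, genes) {
  if (nrow(calls) == 0) return(calls)
  if (nrow(genes) == 0) return(calls)
  calls[!overlaps_any(calls, genes), ]
}
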