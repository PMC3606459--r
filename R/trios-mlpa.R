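# Gene-level CNV calling from MLPA probe ratios, trio inheritance
# classification, and aggregation of SNP-based and MLPA evidence per gene.
#
# MLPA reports a normalized ratio per probe relative to the two-copy state
# (~0.5 per heterozygous deletion, ~1.5 per one extra copy). The exact
# normalization of the original assay is not published, so calling uses
# conventional single-copy loss/gain ratio thresholds, both tunable.

#' Call gene-level CNVs from MLPA probe ratios
#'
#' Per sample and target gene, probes are ordered by genomic position and
#' maximal runs of consecutive probes with `normalized_ratio <= del_threshold`
#' become one deletion call; runs with `normalized_ratio >= dup_threshold`
#' become one duplication call. Intermediate ratios yield no call. A gene
#' with both deletion and duplication runs produces two separate calls with a
#' warning. Probes whose `gene` is in `reference_genes` are control probes:
#' they are excluded from calling, and a sample whose reference probes stray
#' far from 1.0 is reported via a message.
#'
#' @param mlpa MLPA tibble (see [read_mlpa_table()]).
#' @param del_threshold Ratio at or below which a probe supports a deletion
#'   (default 0.75).
#' @param dup_threshold Ratio at or above which a probe supports a
#'   duplication (default 1.30).
#' @param reference_genes Gene labels marking reference (non-target) probes
#'   (default `"REF"`).
#' @return A gene-level call tibble: `sample_id`, `gene`, `state`,
#'   `probes` (list-column of probe ids in the run), `exons` (list-column of
#'   exon labels), `n_probes`, `source = "MLPA"`.
#' @export
call_mlpa_cnv <- function(mlpa, del_threshold = 0.75, dup_threshold = 1.30,
                          reference_genes = "REF") {
  if (any(mlpa$normalized_ratio <= 0)) abort("normalized ratios must be positive")
  if (del_threshold >= dup_threshold) {
    abort("del_threshold must be below dup_threshold")
  }
  ref <- filter(mlpa, .data$gene %in% reference_genes)
  if (nrow(ref) > 0) {
    off <- ref %>%
      group_by(.data$sample_id) %>%
      summarise(m = mean(.data$normalized_ratio), .groups = "drop") %>%
      filter(abs(.data$m - 1) > 0.15)
    if (nrow(off) > 0) {
      inform(sprintf("reference probes deviate from 1.0 in %d sample(s): %s",
                     nrow(off), paste(off$sample_id, collapse = ", ")))
    }
  }
  target <- mlpa %>%
    filter(!.data$gene %in% reference_genes) %>%
    arrange(.data$sample_id, .data$gene, .data$position)
  if (nrow(target) == 0) return(empty_gene_calls())
  out <- target %>%
    group_by(.data$sample_id, .data$gene) %>%
    dplyr::group_modify(~ mlpa_gene_runs(.x, del_threshold, dup_threshold)) %>%
    ungroup()
  if (nrow(out) == 0) return(empty_gene_calls())
  both <- out %>%
    count(.data$sample_id, .data$gene) %>%
    filter(.data$n > 1)
  if (nrow(both) > 0) {
    warn(sprintf("mixed or multiple CNV runs within one gene in %d sample-gene pair(s)",
                 nrow(both)))
  }
  out %>%
    mutate(source = "MLPA") %>%
    select("sample_id", "gene", "state", "probes", "exons", "n_probes",
           "source")
}

mlpa_gene_runs <- function(g, del_threshold, dup_threshold) {
  cls <- case_when(
    g$normalized_ratio <= del_threshold ~ "DEL",
    g$normalized_ratio >= dup_threshold ~ "DUP",
    TRUE ~ "NORMAL"
  )
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != "NORMAL")
  if (length(keep) == 0) {
    return(tibble(state = character(), probes = list(), exons = list(),
                  n_probes = integer()))
  }
  tibble(
    state = r$values[keep],
    probes = purrr::map2(starts[keep], ends[keep],
                         ~ g$probe_id[.x:.y]),
    exons = purrr::map2(starts[keep], ends[keep], ~ g$exon[.x:.y]),
    n_probes = r$lengths[keep]
  )
}

empty_gene_calls <- function() {
  tibble(sample_id = character(), gene = character(), state = character(),
         probes = list(), exons = list(), n_probes = integer(),
         source = character())
}

#' Classify trio inheritance of gene-level CNVs
#'
#' For every proband gene-level CNV called from the MLPA table, determines
#' whether each parent carries the variant: a parent carries it iff the
#' parent has a same-state call in the same gene sharing at least one
#' affected probe with the proband's call (exact breakpoint equality is not
#' required; MLPA cannot resolve breakpoints). Verdicts: both parents
#' non-carriers is `DE_NOVO`; exactly one carrier is `INHERITED_PATERNAL` or
#' `INHERITED_MATERNAL`; both is `INHERITED_BOTH`; a parent with no MLPA
#' measurements leaves the trio `UNRESOLVED`.
#'
#' @param mlpa MLPA tibble covering probands and parents on the same probes.
#' @param pedigree Trio tibble (see [read_pedigree()]); every proband with a
#'   call must belong to a trio.
#' @param ... Passed to [call_mlpa_cnv()] (thresholds, reference genes).
#' @return A tibble with one row per proband gene-level call: `proband`,
#'   `gene`, `state`, `probes` (list-column), `father_state`, `mother_state`
#'   (`"absent"`, `"present-DEL"`, `"present-DUP"` or `"missing"`), and
#'   `verdict`.
#' @export
classify_inheritance <- function(mlpa, pedigree, ...) {
  calls <- call_mlpa_cnv(mlpa, ...)
  proband_calls <- filter(calls, .data$sample_id %in% pedigree$proband)
  if (nrow(proband_calls) == 0) {
    return(tibble(proband = character(), gene = character(),
                  state = character(), probes = list(),
                  father_state = character(), mother_state = character(),
                  verdict = character()))
  }
  measured <- unique(mlpa$sample_id)
  rows <- purrr::pmap(proband_calls, function(sample_id, gene, state,
                                              probes, exons, n_probes,
                                              source) {
    trio <- pedigree[pedigree$proband == sample_id, ]
    if (nrow(trio) != 1) {
      abort(paste0("proband ", sample_id, " not found in exactly one trio"))
    }
    parent <- function(id) {
      if (!id %in% measured) {
        return(list(state = "missing", carrier = NA))
      }
      pcalls <- filter(calls, .data$sample_id == id, .data$gene == .env$gene)
      if (nrow(pcalls) == 0) return(list(state = "absent", carrier = FALSE))
      shares <- purrr::map2_lgl(
        pcalls$state, pcalls$probes,
        ~ .x == state && length(intersect(.y, probes)) > 0)
      st <- if (any(shares)) {
        paste0("present-", pcalls$state[which(shares)[1]])
      } else {
        paste0("present-", pcalls$state[1])
      }
      list(state = st, carrier = any(shares))
    }
    f <- parent(trio$father)
    m <- parent(trio$mother)
    verdict <- if (is.na(f$carrier) || is.na(m$carrier)) {
      "UNRESOLVED"
    } else if (f$carrier && m$carrier) {
      "INHERITED_BOTH"
    } else if (f$carrier) {
      "INHERITED_PATERNAL"
    } else if (m$carrier) {
      "INHERITED_MATERNAL"
    } else {
      "DE_NOVO"
    }
    tibble(proband = sample_id, gene = gene, state = state,
           probes = list(probes), father_state = f$state,
           mother_state = m$state, verdict = verdict)
  })
  bind_rows(rows)
}

#' Aggregate SNP-based and MLPA evidence per gene
#'
#' Combines, per gene, the cases found by SNP-array calls, the additional
#' cases found only by MLPA among the re-assayed subset, and cases from an
#' MLPA-only follow-up cohort. MLPA validations of SNP-called samples are
#' never double-counted: the aggregated case total is
#' `SNP-based + MLPA-additional + follow-up`. A one-tailed Fisher exact test
#' compares aggregated case and control carrier totals.
#'
#' @param snp_hits Tibble of gene-level hits from the SNP-array pipeline:
#'   columns `gene`, `sample_id`, `status`.
#' @param mlpa_hits Tibble of gene-level MLPA hits on samples from the
#'   SNP-based cohort (same columns); samples also present in `snp_hits` for
#'   the same gene count as validations.
#' @param followup_hits Tibble of gene-level MLPA hits in the follow-up-only
#'   cohort (same columns); these samples must not appear in the other two
#'   sources.
#' @param n_case_total Aggregated case denominator (SNP-based cases plus
#'   follow-up cases).
#' @param n_control_total Control denominator.
#' @param mid_p Use the mid-p Fisher variant (default `FALSE`).
#' @return A tibble with one row per gene: `gene`, `n_snp_cases`,
#'   `n_mlpa_validated`, `n_mlpa_additional`, `n_followup`, `total_cases`,
#'   `total_controls`, `fisher_p`.
#' @export
aggregate_gene_counts <- function(snp_hits, mlpa_hits, followup_hits,
                                  n_case_total, n_control_total,
                                  mid_p = FALSE) {
  empty <- tibble(gene = character(), sample_id = character(),
                  status = character())
  snp_hits <- if (is.null(snp_hits)) empty else snp_hits
  mlpa_hits <- if (is.null(mlpa_hits)) empty else mlpa_hits
  followup_hits <- if (is.null(followup_hits)) empty else followup_hits
  clash <- intersect(unique(followup_hits$sample_id),
                     unique(c(snp_hits$sample_id, mlpa_hits$sample_id)))
  if (length(clash) > 0) {
    abort(paste0("follow-up samples overlap the SNP-based cohort: ",
                 paste(clash, collapse = ", ")))
  }
  genes <- sort(unique(c(snp_hits$gene, mlpa_hits$gene, followup_hits$gene)))
  if (length(genes) == 0) {
    return(tibble(gene = character(), n_snp_cases = integer(),
                  n_mlpa_validated = integer(), n_mlpa_additional = integer(),
                  n_followup = integer(), total_cases = integer(),
                  total_controls = integer(), fisher_p = double()))
  }
  rows <- purrr::map(genes, function(g) {
    snp_case <- unique(snp_hits$sample_id[
      snp_hits$gene == g & snp_hits$status == "case"])
    mlpa_case <- unique(mlpa_hits$sample_id[
      mlpa_hits$gene == g & mlpa_hits$status == "case"])
    fu_case <- unique(followup_hits$sample_id[
      followup_hits$gene == g & followup_hits$status == "case"])
    validated <- intersect(mlpa_case, snp_case)
    additional <- setdiff(mlpa_case, snp_case)
    controls <- unique(c(
      snp_hits$sample_id[snp_hits$gene == g & snp_hits$status == "control"],
      mlpa_hits$sample_id[mlpa_hits$gene == g & mlpa_hits$status == "control"],
      followup_hits$sample_id[
        followup_hits$gene == g & followup_hits$status == "control"]))
    total_cases <- length(snp_case) + length(additional) + length(fu_case)
    tab <- rbind(c(total_cases, n_case_total - total_cases),
                 c(length(controls), n_control_total - length(controls)))
    p <- if (total_cases + length(controls) == 0) {
      1
    } else {
      fisher_one_sided(tab, mid_p = mid_p)
    }
    tibble(gene = g, n_snp_cases = length(snp_case),
           n_mlpa_validated = length(validated),
           n_mlpa_additional = length(additional),
           n_followup = length(fu_case), total_cases = total_cases,
           total_controls = length(controls), fisher_p = p)
  })
  bind_rows(rows)
}
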