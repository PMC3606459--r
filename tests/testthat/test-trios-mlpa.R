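mlpa_row <- function(sample_id, gene, exon, ratio, chrom = "2",
                     pos_base = 1000) {
  tibble::tibble(sample_id = sample_id, probe_id = paste0(gene, "_", exon),
                 gene = gene, exon = exon, chrom = chrom,
                 position = pos_base + as.integer(sub("ex", "", exon)) * 100,
                 normalized_ratio = ratio)
}

sample_probes <- function(sample_id, ratios, gene = "NRXN1") {
  purrr::map2(paste0("ex", seq_along(ratios)), ratios,
              ~ mlpa_row(sample_id, gene, .x, .y)) |> dplyr::bind_rows()
}

test_that("consecutive low-ratio probes form one deletion call", {
  mlpa <- sample_probes("P1", c(1, 0.5, 0.5, 1))
  out <- call_mlpa_cnv(mlpa)
  expect_equal(nrow(out), 1)
  expect_equal(out$state, "DEL")
  expect_equal(out$exons[[1]], c("ex2", "ex3"))
  expect_equal(out$n_probes, 2L)
  expect_equal(out$source, "MLPA")

  dup <- call_mlpa_cnv(sample_probes("P1", c(1.5, 1.5)))
  expect_equal(dup$state, "DUP")
  expect_equal(dup$n_probes, 2L)

  expect_equal(nrow(call_mlpa_cnv(sample_probes("P1", c(1, 0.99, 1.02)))), 0)
})

test_that("thresholds are inclusive and tunable; invalid inputs rejected", {
  expect_equal(call_mlpa_cnv(sample_probes("P1", c(0.75, 0.75)))$state, "DEL")
  expect_equal(call_mlpa_cnv(sample_probes("P1", c(1.30, 1.30)))$state, "DUP")
  expect_equal(nrow(call_mlpa_cnv(sample_probes("P1", c(0.76, 1.29)))), 0)
  loose <- call_mlpa_cnv(sample_probes("P1", c(0.8, 0.8)),
                         del_threshold = 0.85)
  expect_equal(loose$state, "DEL")
  expect_error(call_mlpa_cnv(sample_probes("P1", c(1, -0.1))), "positive")
  expect_error(call_mlpa_cnv(sample_probes("P1", 1), del_threshold = 1.4),
               "below")
})

test_that("probes are ordered by position before run detection", {
  mlpa <- sample_probes("P1", c(0.5, 1, 0.5, 0.5))[c(3, 1, 4, 2), ]
  out <- suppressWarnings(call_mlpa_cnv(mlpa))
  expect_equal(nrow(out), 2)  # ex1 alone and ex3-ex4, split by normal ex2
  expect_equal(out$n_probes, c(1L, 2L))
})

test_that("mixed runs warn and reference probes are excluded from calling", {
  mixed <- sample_probes("P1", c(0.5, 0.5, 1.5, 1.5))
  expect_warning(out <- call_mlpa_cnv(mixed), "mixed")
  expect_equal(sort(out$state), c("DEL", "DUP"))

  with_ref <- dplyr::bind_rows(
    sample_probes("P1", c(1, 1)),
    mlpa_row("P1", "REF", "ex1", 0.5, chrom = "9"))
  expect_equal(nrow(suppressMessages(call_mlpa_cnv(with_ref))), 0)
  expect_message(call_mlpa_cnv(with_ref), "reference probes deviate")
})

test_that("trio verdicts cover inherited, de novo and unresolved parents", {
  ped <- tibble::tibble(proband = "kid", father = "dad", mother = "mum")
  kid <- sample_probes("kid", c(1, 0.5, 0.5, 1))
  dad_carrier <- sample_probes("dad", c(1, 0.5, 0.5, 1))
  mum_clear <- sample_probes("mum", c(1, 1, 1, 1))

  res <- classify_inheritance(dplyr::bind_rows(kid, dad_carrier, mum_clear),
                              ped)
  expect_equal(res$verdict, "INHERITED_PATERNAL")
  expect_equal(res$father_state, "present-DEL")
  expect_equal(res$mother_state, "absent")

  dad_clear <- sample_probes("dad", c(1, 1, 1, 1))
  res <- classify_inheritance(dplyr::bind_rows(kid, dad_clear, mum_clear),
                              ped)
  expect_equal(res$verdict, "DE_NOVO")

  # a parent with no measurements at all leaves the trio unresolved
  res <- classify_inheritance(dplyr::bind_rows(kid, dad_clear), ped)
  expect_equal(res$verdict, "UNRESOLVED")
  expect_equal(res$mother_state, "missing")

  # same gene, same state, but disjoint probes: not the same variant
  dad_other <- sample_probes("dad", c(0.5, 1, 1, 0.5))[c(1, 4), ]
  res <- classify_inheritance(dplyr::bind_rows(kid, dad_other, mum_clear),
                              ped)
  expect_equal(res$verdict, "DE_NOVO")
  expect_equal(res$father_state, "present-DEL")

  # duplication in the parent never explains a deletion in the child
  dad_dup <- sample_probes("dad", c(1, 1.5, 1.5, 1))
  res <- classify_inheritance(dplyr::bind_rows(kid, dad_dup, mum_clear), ped)
  expect_equal(res$verdict, "DE_NOVO")

  # probands without calls produce no rows
  calm <- sample_probes("kid", c(1, 1, 1, 1))
  expect_equal(nrow(classify_inheritance(
    dplyr::bind_rows(calm, dad_clear, mum_clear), ped)), 0)
})

test_that("simulated trios are classified back to their planted verdicts", {
  sim <- sim_default()
  layout <- mlpa_layout_from_genes(sim$genes)
  tr <- simulate_trios(layout, n_trios = 3, de_novo_fraction = 2 / 3,
                       seed = 99)
  res <- classify_inheritance(tr$mlpa, tr$pedigree)
  res <- res[match(tr$truth$proband, res$proband), ]
  expect_equal(res$verdict, tr$truth$verdict)
  expect_equal(res$gene, tr$truth$gene)
  expect_equal(res$state, tr$truth$state)
  for (i in seq_len(nrow(res))) {
    expect_setequal(res$probes[[i]], tr$truth$probes[[i]])
  }
  # two of three planted as de novo at the default fraction
  expect_equal(sum(res$verdict == "DE_NOVO"), 2)
})

test_that("aggregation combines SNP, MLPA and follow-up evidence per gene", {
  snp <- tibble::tibble(gene = "NRXN1", sample_id = c("a", "b"),
                        status = "case")
  mlpa <- tibble::tibble(gene = "NRXN1", sample_id = c("a", "b", "c"),
                         status = "case")
  fu <- tibble::tibble(gene = "NRXN1", sample_id = paste0("f", 1:4),
                       status = "case")
  out <- aggregate_gene_counts(snp, mlpa, fu, 232, 234)
  expect_equal(out$n_snp_cases, 2L)
  expect_equal(out$n_mlpa_validated, 2L)
  expect_equal(out$n_mlpa_additional, 1L)
  expect_equal(out$n_followup, 4L)
  expect_equal(out$total_cases, 7L)      # never double-counting validations
  expect_equal(out$total_controls, 0L)
  # 7 case carriers in 232 vs 0 in 234: single-term hypergeometric tail
  expect_equal(out$fisher_p, prod((232 - 0:6) / (466 - 0:6)),
               tolerance = 1e-12)
  expect_equal(round(out$fisher_p, 3), 0.007)
  mid <- aggregate_gene_counts(snp, mlpa, fu, 232, 234, mid_p = TRUE)
  expect_equal(mid$fisher_p, out$fisher_p / 2, tolerance = 1e-12)
  expect_equal(round(mid$fisher_p, 3), 0.004)

  four <- aggregate_gene_counts(
    NULL, NULL, tibble::tibble(gene = "G2", sample_id = paste0("f", 5:8),
                               status = "case"), 232, 234)
  expect_equal(four$total_cases, 4L)
  expect_equal(round(four$fisher_p, 2), 0.06)
  expect_equal(round(aggregate_gene_counts(
    NULL, NULL, four_hits <- tibble::tibble(
      gene = "G2", sample_id = paste0("f", 5:8), status = "case"),
    232, 234, mid_p = TRUE)$fisher_p, 2), 0.03)
})

test_that("aggregation rejects follow-up samples from the discovery cohort", {
  snp <- tibble::tibble(gene = "G", sample_id = "a", status = "case")
  fu <- tibble::tibble(gene = "G", sample_id = c("a", "x"), status = "case")
  expect_error(aggregate_gene_counts(snp, NULL, fu, 100, 100), "overlap")
  empty <- aggregate_gene_counts(NULL, NULL, NULL, 100, 100)
  expect_equal(nrow(empty), 0)
})

test_that("aggregation is invariant to row order and counts controls once", {
  snp <- tibble::tibble(gene = c("G", "G", "H"),
                        sample_id = c("a", "k1", "b"),
                        status = c("case", "control", "case"))
  mlpa <- tibble::tibble(gene = c("G", "G"), sample_id = c("a", "k1"),
                         status = c("case", "control"))
  out1 <- aggregate_gene_counts(snp, mlpa, NULL, 50, 60)
  out2 <- aggregate_gene_counts(snp[c(3, 1, 2), ], mlpa[2:1, ], NULL, 50, 60)
  expect_equal(out1, out2)
  g <- out1[out1$gene == "G", ]
  expect_equal(g$total_controls, 1L)  # k1 seen by both assays counts once
  expect_equal(g$total_cases, 1L)
  expect_equal(g$n_mlpa_validated, 1L)
})
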