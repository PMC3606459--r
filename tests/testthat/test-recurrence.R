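# Shared toy annotation: two genes, five 150 bp exons each, 30 kb apart.
toy_genes <- function() {
  dplyr::bind_rows(
    tibble::tibble(gene = "GA", chrom = "1", start = 2e6 + (0:4) * 3e4,
                   end = 2e6 + (0:4) * 3e4 + 149, exon = paste0("ex", 1:5)),
    tibble::tibble(gene = "GB", chrom = "2", start = 2e6 + (0:4) * 3e4,
                   end = 2e6 + (0:4) * 3e4 + 149, exon = paste0("ex", 1:5))
  )
}

toy_samples <- function() {
  tibble::tibble(sample_id = c("C1", "C2", "C3", "K1", "K2"),
                 status = c("case", "case", "case", "control", "control"))
}

test_that("intron-only overlap does not count as a gene hit", {
  genes <- toy_genes()
  # strictly between exon 1 (ends 2000149) and exon 2 (starts 2030000)
  intronic <- make_calls(start = 2000150, end = 2029999)
  expect_equal(nrow(gene_exon_hits(intronic, genes)), 0)
  # a single base of exon 2 counts
  exonic <- make_calls(start = 2029000, end = 2030000)
  hits <- gene_exon_hits(exonic, genes)
  expect_equal(hits$gene, "GA")
  # a call spanning both genes' coordinates hits only the same-chromosome gene
  wide <- make_calls(start = 1e6, end = 3e6, chrom = "2")
  expect_equal(gene_exon_hits(wide, genes)$gene, "GB")
})

test_that("case-only filtering removes 1 bp control overlaps, keeps adjacency", {
  samples <- toy_samples()
  case_call <- make_calls(start = 1e6, end = 1.7e6, sample_id = "C1")
  touching <- dplyr::bind_rows(
    case_call, make_calls(start = 1.7e6, end = 1.8e6, sample_id = "K1"))
  expect_equal(nrow(case_only_calls(touching, samples)), 0)
  adjacent <- dplyr::bind_rows(
    case_call, make_calls(start = 1.7e6 + 1, end = 1.8e6, sample_id = "K1"))
  out <- case_only_calls(adjacent, samples)
  expect_equal(out$sample_id, "C1")
  # a small control call still disqualifies a large case call
  small_ctrl <- dplyr::bind_rows(
    case_call, make_calls(start = 1.2e6, end = 1.22e6, sample_id = "K2"))
  expect_equal(nrow(case_only_calls(small_ctrl, samples)), 0)
  expect_error(case_only_calls(make_calls(1, 6e5, sample_id = "ghost"),
                               samples), "absent")
})

test_that("recurrent genes need min_cases distinct cases and zero control exon hits", {
  genes <- toy_genes()
  samples <- toy_samples()
  over_ga <- function(sid, chrom = "1") {
    make_calls(start = 1.9e6, end = 2.55e6, sample_id = sid, chrom = chrom)
  }
  two_cases <- dplyr::bind_rows(over_ga("C1"), over_ga("C2"))
  rec <- recurrent_genes(two_cases, samples, genes, "large")
  expect_equal(rec$gene, "GA")
  expect_equal(rec$n_cases_hit, 2L)
  expect_equal(rec$n_control_hits, 0L)
  expect_equal(rec$n_dup, 2L)

  one_case <- over_ga("C1")
  expect_equal(nrow(recurrent_genes(one_case, samples, genes, "large")), 0)
  expect_equal(
    recurrent_genes(one_case, samples, genes, "large", min_cases = 1)$gene,
    "GA")

  # one case hitting the gene with two calls counts once
  twice <- dplyr::bind_rows(
    make_calls(start = 1.4e6, end = 2.0005e6, sample_id = "C1"), over_ga("C1"))
  expect_equal(nrow(recurrent_genes(twice, samples, genes, "large")), 0)

  # any control exon hit vetoes the gene, even a small intragenic one ...
  vetoed <- dplyr::bind_rows(
    two_cases, make_calls(start = 2.0001e6, end = 2.031e6, sample_id = "K1"))
  expect_equal(nrow(recurrent_genes(vetoed, samples, genes, "large")), 0)
  # ... but an intron-only control call does not
  intron_ctrl <- dplyr::bind_rows(
    two_cases, make_calls(start = 2000150, end = 2029999, sample_id = "K1"))
  expect_equal(recurrent_genes(intron_ctrl, samples, genes, "large")$gene,
               "GA")
})

test_that("mixed deletion/duplication hits are reported, not rejected", {
  genes <- toy_genes()
  samples <- toy_samples()
  calls <- dplyr::bind_rows(
    make_calls(start = 1.9e6, end = 2.55e6, sample_id = "C1"),
    cnv_calls(sample_id = "C2", chrom = "1", start = 1.9e6, end = 2.55e6,
              copy_number = 1L, num_snps = 20L))
  rec <- recurrent_genes(calls, samples, genes, "large")
  expect_equal(rec$n_del, 1L)
  expect_equal(rec$n_dup, 1L)
  expect_equal(nrow(rec$case_calls[[1]]), 2)
})

test_that("the size class splits at the >500 kb bin", {
  genes <- toy_genes()
  samples <- toy_samples()
  small <- make_calls(start = c(1.9e6, 1.9e6), end = c(2.2e6, 2.2e6),
                      sample_id = c("C1", "C2"))  # 300 kb + 1
  expect_equal(nrow(recurrent_genes(small, samples, genes, "large")), 0)
  expect_equal(recurrent_genes(small, samples, genes, "small")$gene, "GA")
})

test_that("recurrent gene reports match a brute-force scan on random data", {
  genes <- toy_genes()
  samples <- toy_samples()
  overlaps1 <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    start <- round(runif(n, 1.8e6, 2.2e6))
    calls <- make_calls(start = start, end = start + round(runif(n, 1e4, 7e5)),
                        sample_id = sample(samples$sample_id, n, replace = TRUE),
                        chrom = sample(c("1", "2"), n, replace = TRUE))
    got <- recurrent_genes(calls, samples, genes, "small")
    status <- samples$status[match(calls$sample_id, samples$sample_id)]
    want <- character(0)
    for (g in unique(genes$gene)) {
      ex <- genes[genes$gene == g, ]
      hit <- purrr::pmap_lgl(calls, function(chrom, start, end, ...) {
        any(ex$chrom == chrom & overlaps1(start, end, ex$start, ex$end))
      })
      in_class <- cnv_size(calls) <= 5e5
      n_case <- length(unique(calls$sample_id[hit & in_class &
                                                status == "case"]))
      n_ctrl <- sum(hit & status == "control")
      if (n_case >= 2 && n_ctrl == 0) want <- c(want, g)
    }
    expect_setequal(got$gene, want)
  }
})

test_that("raising min_cases never grows the reported gene set", {
  sim <- sim_default()
  pr <- sim_default_processed()
  sets <- purrr::map(1:4, function(k) {
    recurrent_genes(pr$final, pr$pass, sim$genes, "large", min_cases = k)$gene
  })
  for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("planted recurrent genes are recovered exactly from synthetic data", {
  sim <- sim_default()
  pr <- sim_default_processed()
  truth <- sim$truth$recurrent
  large_truth <- truth[truth$size_class == "large", ]
  large <- recurrent_genes(pr$final, pr$pass, sim$genes, "large")
  expect_equal(large$gene, large_truth$gene)
  expect_equal(large$n_cases_hit, lengths(large_truth$hits))
  expect_setequal(large$case_calls[[1]]$sample_id, large_truth$hits[[1]])
  expect_equal(large$n_dup, sum(large_truth$state == "DUP") *
                 large$n_cases_hit)

  small_truth <- truth[truth$size_class == "small", ]
  small <- recurrent_genes(pr$final, pr$pass, sim$genes, "small")
  expect_equal(small$gene, small_truth$gene)
  expect_equal(small$n_cases_hit, lengths(small_truth$hits))
  expect_setequal(small$case_calls[[1]]$sample_id, small_truth$hits[[1]])
})

test_that("calls with no exon overlap are reported as a complement", {
  genes <- toy_genes()
  calls <- dplyr::bind_rows(
    make_calls(start = 1.9e6, end = 2.55e6),                 # hits GA
    make_calls(start = 8e6, end = 8.7e6, sample_id = "S2"))  # gene desert
  left <- calls_without_exon_overlap(calls, genes)
  expect_equal(left$sample_id, "S2")
  expect_equal(nrow(gene_exon_hits(left, genes)), 0)
  expect_equal(nrow(calls_without_exon_overlap(calls, genes)) +
                 nrow(dplyr::distinct(
                   dplyr::select(gene_exon_hits(calls, genes), -"gene"))),
               nrow(calls))
})
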