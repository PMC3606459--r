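# Independent oracles and shared fixtures.

# Hypergeometric upper-tail by direct enumeration with choose(); independent
# of the dhyper-based implementation.
fisher_tail_oracle <- function(a, b, c_, d, mid_p = FALSE) {
  n1 <- a + b
  k <- a + c_
  n <- a + b + c_ + d
  if (k == 0 || k == n || n1 == 0 || n1 == n) return(1)
  support <- max(0, k - (n - n1)):min(k, n1)
  probs <- choose(k, support) * choose(n - k, n1 - support) / choose(n, n1)
  p <- sum(probs[support >= a])
  if (mid_p) p <- p - 0.5 * probs[support == a]
  min(p, 1)
}

# Two-sided Fisher by enumeration: sum of table probabilities <= P(observed).
fisher_two_sided_oracle <- function(tab) {
  a <- tab[1, 1]
  n1 <- sum(tab[1, ])
  k <- sum(tab[, 1])
  n <- sum(tab)
  if (k == 0 || k == n || n1 == 0 || n1 == n) return(1)
  support <- max(0, k - (n - n1)):min(k, n1)
  probs <- choose(k, support) * choose(n - k, n1 - support) / choose(n, n1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Any-pair fixed-point merge oracle on one (sample, chrom, state) group of
# intervals: repeatedly merge ANY pair satisfying gap < span / 2.
merge_oracle <- function(start, end) {
  iv <- cbind(start, end)
  repeat {
    n <- nrow(iv)
    if (n < 2) break
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- max(iv[i, 1], iv[j, 1]) - min(iv[i, 2], iv[j, 2]) - 1
        span <- max(iv[i, 2], iv[j, 2]) - min(iv[i, 1], iv[j, 1]) + 1
        if (gap < span / 2) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# Quick builder for call tables in tests.
make_calls <- function(start, end, sample_id = "S1", chrom = "1",
                       copy_number = 3L, num_snps = 20L) {
  cnv_calls(sample_id = sample_id, chrom = chrom, start = start, end = end,
            copy_number = copy_number, num_snps = num_snps)
}

# Default synthetic cohort plus its processed calls, generated once per test
# session and reused across test files.
.sim_cache <- new.env(parent = emptyenv())
sim_default <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_cohort(simulation_config(seed = 20130322))
  }
  .sim_cache$sim
}
sim_default_processed <- function() {
  if (is.null(.sim_cache$processed)) {
    sim <- sim_default()
    samples <- suppressWarnings(
      apply_qc(compute_num_cnv(sim$samples, sim$calls)))
    pass <- qc_passing(samples)
    calls_pass <- dplyr::semi_join(sim$calls, pass, by = "sample_id")
    final <- suppressMessages(suppressWarnings(
      process_calls(calls_pass, sim$marker_map, sim$regions, quiet = TRUE)))
    .sim_cache$processed <- list(sim = sim, samples = samples, pass = pass,
                                 final = final)
  }
  .sim_cache$processed
}
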