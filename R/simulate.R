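# Synthetic cohort generator. Emits every input the pipeline consumes (raw
# call file, sample table, marker map, gene exon models, excluded regions,
# PC table) together with the planted ground truth, so each stage can be
# tested end to end without access to raw genotype data.
#
# Layout: 22 autosomes of 25 Mb with markers on a uniform ~4 kb grid.
# Each chromosome is partitioned into non-interacting zones -- telomeres and
# a centromere (excluded regions), a gene zone (2-5.5 Mb), a zone of 2-Mb
# slots for planted large CNVs (6-12 Mb) and a background zone (14-23.5 Mb).
# Under the merge rule, two calls coalesce iff their gap is smaller than the
# sum of their sizes; the inter-zone gaps exceed the largest possible size
# sum, so planted features, background calls and filter-exercising decoys
# can never merge across zones. Case planted large calls live in odd-indexed
# slots and control ones in even-indexed slots, keeping case regions free of
# control CNVs by construction.

N_CHROM <- 22L
CHROM_LEN <- 25e6
MARKER_SPACING <- 4000
GENE_ZONE <- c(2e6, 5.5e6)
SLOT_ZONE <- c(6e6, 12e6)
SLOT_WIDTH <- 2e6
BACKGROUND_ZONE <- c(14e6, 23.5e6)
CENTROMERE <- c(12.4e6, 12.6e6)
TELOMERE_LEN <- 1e5
LARGE_SIZE_RANGE <- c(6e5, 1.2e6)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a two-population rare-CNV
#' case-control analysis: 179 cases and 234 controls after QC, about 3.5
#' final calls per subject, 60% deletions among background calls, a
#' large-CNV (>500 kb) carrier rate of 14% in cases versus 6.4% in controls
#' with two case double carriers, one recurrent large duplication gene hit
#' in four cases and one recurrent small deletion gene hit in two cases,
#' plus fragmented calls and QC-failing outlier samples.
#'
#' @param seed Integer RNG seed; the generator is fully reproducible from it.
#' @param n_cases,n_controls Numbers of QC-passing cases and controls.
#' @param mean_calls_per_sample Mean of the per-sample Poisson count of true
#'   (post-processing) calls.
#' @param del_fraction Fraction of background calls that are deletions.
#' @param size_distribution Log-normal size parameters per state for
#'   background calls; sizes are truncated to `background_size_range`.
#' @param background_size_range Background call sizes in bp; the lower bound
#'   keeps every true call above the 10-marker filter, the upper below the
#'   large-CNV threshold.
#' @param large_carrier_rate_case,large_carrier_rate_control Fractions of
#'   each group planted as >500 kb carriers (realized counts are
#'   `round(rate * n)`).
#' @param n_double_carriers_case Case carriers planted with two large CNVs.
#' @param large_dup_fraction Fraction of planted large CNVs that are
#'   duplications (duplication excess among large calls).
#' @param recurrent Tibble describing planted recurrent genes: columns
#'   `size_class` (`"large"`/`"small"`), `state`, `n_cases`.
#' @param fragmentation_rate Fraction of true calls emitted as 2-3 fragments
#'   that the merge stage must reassemble.
#' @param n_outlier_samples QC-failing samples appended to the cohort.
#' @param n_filter_test_calls Isolated sub-10-marker decoy calls that the
#'   marker filter must remove.
#' @param n_region_test_calls Decoy calls overlapping telomeres that the
#'   region exclusion must remove.
#' @param n_genes Number of gene models.
#' @param cvcr_case_fraction Fraction of cases from the second population
#'   (they form the second genotyping batch).
#' @param n_trios,de_novo_fraction Trio simulation defaults (see
#'   [simulate_trios()]).
#' @param mlpa_noise_sd Gaussian noise on simulated MLPA ratios (default 0,
#'   keeping trio recovery deterministic).
#' @return A named list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 179L, n_controls = 234L,
                              mean_calls_per_sample = 3.5,
                              del_fraction = 0.60,
                              size_distribution = list(
                                DEL = c(meanlog = log(65e3), sdlog = 0.9),
                                DUP = c(meanlog = log(1.0e5), sdlog = 0.9)),
                              background_size_range = c(44e3, 450e3),
                              large_carrier_rate_case = 0.14,
                              large_carrier_rate_control = 0.064,
                              n_double_carriers_case = 2L,
                              large_dup_fraction = 0.7,
                              recurrent = tibble(
                                size_class = c("large", "small"),
                                state = c("DUP", "DEL"),
                                n_cases = c(4L, 2L)),
                              fragmentation_rate = 0.15,
                              n_outlier_samples = 8L,
                              n_filter_test_calls = 6L,
                              n_region_test_calls = 4L,
                              n_genes = 24L,
                              cvcr_case_fraction = 0.6,
                              n_trios = 3L,
                              de_novo_fraction = 2 / 3,
                              mlpa_noise_sd = 0) {
  cfg <- as.list(environment())
  rates <- c(cfg$large_carrier_rate_case, cfg$large_carrier_rate_control,
             cfg$del_fraction, cfg$fragmentation_rate, cfg$large_dup_fraction,
             cfg$de_novo_fraction, cfg$cvcr_case_fraction)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (any(c(cfg$n_cases, cfg$n_controls) < 1)) abort("need >= 1 sample per group")
  if (sum(cfg$recurrent$n_cases) > cfg$n_cases) {
    abort("more recurrent-gene hits requested than cases")
  }
  n_large_case <- round(cfg$large_carrier_rate_case * cfg$n_cases)
  n_rec_large <- sum(cfg$recurrent$n_cases[cfg$recurrent$size_class == "large"])
  if (n_rec_large > n_large_case) {
    abort("recurrent large-gene hits exceed the planted large-carrier cases")
  }
  if (nrow(cfg$recurrent) > cfg$n_genes) {
    abort("more recurrent genes than gene models")
  }
  structure(cfg, class = "sim_config")
}

sim_marker_map <- function() {
  pos <- seq(2001, CHROM_LEN, by = MARKER_SPACING)
  tibble(
    marker = paste0("rs", rep(seq_len(N_CHROM), each = length(pos)), "_",
                    rep(seq_along(pos), times = N_CHROM)),
    chrom = as.character(rep(seq_len(N_CHROM), each = length(pos))),
    pos = rep(pos, times = N_CHROM)
  )
}

sim_excluded_regions <- function() {
  bind_rows(
    tibble(chrom = as.character(1:N_CHROM), start = 1, end = TELOMERE_LEN,
           label = "telomere_p"),
    tibble(chrom = as.character(1:N_CHROM), start = CENTROMERE[1],
           end = CENTROMERE[2], label = "centromere"),
    tibble(chrom = as.character(1:N_CHROM), start = CHROM_LEN - TELOMERE_LEN + 1,
           end = CHROM_LEN, label = "telomere_q")
  )
}

sim_gene_models <- function(n_genes) {
  purrr::map(seq_len(n_genes), function(g) {
    ch <- as.character((g - 1) %% N_CHROM + 1)
    gstart <- GENE_ZONE[1] + ((g - 1) %/% N_CHROM) * 1.5e6
    ex_start <- gstart + (0:4) * 3e4
    tibble(gene = sprintf("GENE%02d", g), chrom = ch,
           start = ex_start, end = ex_start + 149,
           exon = paste0("ex", 1:5))
  }) %>% bind_rows()
}

#' Count markers inside genomic intervals
#'
#' @param chrom,start,end Parallel vectors of 1-based inclusive intervals.
#' @param marker_map Marker map tibble (`marker`, `chrom`, `pos`).
#' @return Integer vector of marker counts.
#' @export
count_markers <- function(chrom, start, end, marker_map) {
  pos_by_chrom <- lapply(split(marker_map$pos, marker_map$chrom), sort)
  purrr::pmap_int(list(as.character(chrom), start, end), function(ch, s, e) {
    p <- pos_by_chrom[[ch]]
    if (is.null(p)) return(0L)
    findInterval(e, p) - findInterval(s - 1, p)
  })
}

rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= range[1] & draw <= range[2]
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  round(out)
}

# Slot table for planted large CNVs: chrom varies fastest so consecutive
# indices land on different chromosomes.
sim_slot_tbl <- function() {
  slots_per_chrom <- floor((SLOT_ZONE[2] - SLOT_ZONE[1]) / SLOT_WIDTH)
  tidyr::expand_grid(rank = seq_len(slots_per_chrom),
                     chrom = as.character(seq_len(N_CHROM))) %>%
    mutate(slot_start = SLOT_ZONE[1] + (.data$rank - 1) * SLOT_WIDTH,
           idx = row_number())
}

#' Generate a synthetic case-control CNV cohort
#'
#' Produces raw (fragmented, decoy-laden) CNV calls, the sample table with
#' QC statistics, the marker map, gene models, excluded regions and a PC
#' table, together with the planted ground truth. Running the pipeline
#' (QC, merge, marker filter, region exclusion) on the QC-passing samples'
#' calls recovers the planted true calls exactly; see the package vignette
#' for what the generator does and does not emulate.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `calls` (raw call tibble), `samples`,
#'   `marker_map`, `genes`, `regions`, `pc_table`, and `truth` (a list with
#'   `intended_calls`, `large_carriers`, `recurrent`, `outliers`,
#'   `fragmented`, `decoys`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_cohort_impl(config))
}

sim_cohort_impl <- function(cfg) {
  marker_map <- sim_marker_map()
  regions <- sim_excluded_regions()
  genes <- sim_gene_models(cfg$n_genes)
  slot_tbl <- sim_slot_tbl()

  case_ids <- sprintf("TS%04d", seq_len(cfg$n_cases))
  control_ids <- sprintf("CT%04d", seq_len(cfg$n_controls))
  samples <- bind_rows(
    tibble(sample_id = case_ids, status = "case",
           cohort = if_else(runif(cfg$n_cases) < cfg$cvcr_case_fraction,
                            "CVCR", "Antioquia")),
    tibble(sample_id = control_ids, status = "control", cohort = "Antioquia")
  ) %>%
    mutate(batch = if_else(.data$cohort == "CVCR", "batch2", "batch1"),
           lrr_sd = round(runif(n(), 0.08, 0.20), 3))

  # --- planted large (>500 kb) carriers -----------------------------------
  n_large_case <- round(cfg$large_carrier_rate_case * cfg$n_cases)
  n_large_control <- round(cfg$large_carrier_rate_control * cfg$n_controls)
  carriers_case <- sample(case_ids, n_large_case)
  carriers_control <- sample(control_ids, n_large_control)
  double_case <- head(carriers_case, cfg$n_double_carriers_case)

  # recurrent gene definitions; large-class hits come from within the
  # planted case carriers so carrier counts stay exactly as configured
  rec <- cfg$recurrent
  rec_rows <- list()
  rec_large_hits <- character(0)
  rec_small_hits <- character(0)
  gene_ids <- unique(genes$gene)
  rec_gene_names <- head(gene_ids, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    g <- rec_gene_names[i]
    gx <- genes[genes$gene == g, ]
    if (rec$size_class[i] == "large") {
      hits <- head(setdiff(carriers_case, rec_large_hits), rec$n_cases[i])
      rec_large_hits <- c(rec_large_hits, hits)
    } else {
      pool <- setdiff(case_ids, c(rec_large_hits, rec_small_hits))
      hits <- if (rec$n_cases[i] > 0) sample(pool, rec$n_cases[i]) else character(0)
      rec_small_hits <- c(rec_small_hits, hits)
    }
    span_mid <- (min(gx$start) + max(gx$end)) / 2
    base_size <- if (rec$size_class[i] == "large") 6e5 else 3.9e5
    rec_rows[[i]] <- list(gene = g, chrom = gx$chrom[1],
                          state = rec$state[i],
                          size_class = rec$size_class[i],
                          mid = span_mid, base_size = base_size, hits = hits)
  }

  # odd slot indices for cases, even for controls; wrap-around reuse is safe
  # because overlap only matters within a sample and across groups
  case_slots <- slot_tbl[slot_tbl$idx %% 2 == 1, ]
  control_slots <- slot_tbl[slot_tbl$idx %% 2 == 0, ]
  slot_cursor <- c(case = 0L, control = 0L)
  used_slot_idx <- integer(0)
  take_slot <- function(group, avoid_chrom) {
    pool <- if (group == "case") case_slots else control_slots
    for (tries in seq_len(nrow(pool) + 1)) {
      slot_cursor[[group]] <<- slot_cursor[[group]] + 1L
      j <- (slot_cursor[[group]] - 1L) %% nrow(pool) + 1L
      if (!pool$chrom[j] %in% avoid_chrom) {
        used_slot_idx <<- c(used_slot_idx, pool$idx[j])
        return(pool[j, ])
      }
    }
    abort("infeasible config: cannot place planted large CNVs")
  }

  plant_large <- function(sid, group) {
    n_calls <- if (sid %in% double_case) 2L else 1L
    is_rec <- sid %in% rec_large_hits
    used_chrom <- character(0)
    out <- list()
    if (is_rec) {
      ri <- rec_rows[[which(purrr::map_lgl(
        rec_rows, ~ .x$size_class == "large" && sid %in% .x$hits))[1]]]
      size <- ri$base_size + round(runif(1, -3e4, 3e4))
      st <- round(ri$mid - size / 2)
      out[[1]] <- tibble(sample_id = sid, chrom = ri$chrom, start = st,
                         end = st + size - 1, state = ri$state,
                         origin = "recurrent_large", gene = ri$gene)
      used_chrom <- ri$chrom
    }
    while (length(out) < n_calls) {
      s <- take_slot(group, used_chrom)
      used_chrom <- c(used_chrom, s$chrom)
      size <- round(runif(1, LARGE_SIZE_RANGE[1], LARGE_SIZE_RANGE[2]))
      st <- round(s$slot_start + 2e5)
      state <- if (runif(1) < cfg$large_dup_fraction) "DUP" else "DEL"
      out[[length(out) + 1]] <- tibble(
        sample_id = sid, chrom = s$chrom, start = st, end = st + size - 1,
        state = state, origin = "large_planted", gene = NA_character_)
    }
    bind_rows(out)
  }
  planted <- c(
    purrr::map(carriers_case, plant_large, group = "case"),
    purrr::map(carriers_control, plant_large, group = "control")
  )
  planted_large <- bind_rows(planted)

  # recurrent small-gene hits (ordinary 100-500 kb calls in the gene zone)
  rec_small <- purrr::map(rec_rows, function(ri) {
    if (ri$size_class != "small" || length(ri$hits) == 0) return(NULL)
    purrr::map(ri$hits, function(sid) {
      size <- ri$base_size + round(runif(1, -3e4, 3e4))
      st <- round(ri$mid - size / 2)
      tibble(sample_id = sid, chrom = ri$chrom, start = st,
             end = st + size - 1, state = ri$state,
             origin = "recurrent_small", gene = ri$gene)
    }) %>% bind_rows()
  }) %>% bind_rows()

  # --- background calls ----------------------------------------------------
  all_ids <- samples$sample_id
  n_draw <- rpois(length(all_ids), cfg$mean_calls_per_sample)
  pre <- bind_rows(planted_large, rec_small)
  n_planted <- as.integer(table(factor(
    if (nrow(pre) > 0) pre$sample_id else character(0), levels = all_ids)))
  n_background <- pmax(n_draw, n_planted) - n_planted

  background <- purrr::map(seq_along(all_ids), function(i) {
    k <- n_background[i]
    if (k == 0) return(NULL)
    sid <- all_ids[i]
    st_state <- if_else(runif(k) < cfg$del_fraction, "DEL", "DUP")
    sizes <- purrr::map_dbl(st_state, function(s) {
      p <- cfg$size_distribution[[s]]
      rlnorm_trunc(1, p[["meanlog"]], p[["sdlog"]],
                   cfg$background_size_range)
    })
    placed <- list()
    for (j in seq_len(k)) {
      repeat {
        ch <- as.character(sample.int(N_CHROM, 1))
        st <- round(runif(1, BACKGROUND_ZONE[1],
                          BACKGROUND_ZONE[2] - sizes[j]))
        en <- st + sizes[j] - 1
        # same-sample calls merge iff gap < size sum; keep them farther apart
        clash <- purrr::some(placed, function(p) {
          p$chrom == ch &&
            max(st, p$start) - min(en, p$end) - 1 <
              (en - st + 1) + (p$end - p$start + 1)
        })
        if (!clash) break
      }
      placed[[j]] <- tibble(sample_id = sid, chrom = ch, start = st, end = en,
                            state = st_state[j], origin = "background",
                            gene = NA_character_)
    }
    bind_rows(placed)
  }) %>% bind_rows()

  intended <- bind_rows(pre, background)
  intended <- intended %>%
    mutate(copy_number = if_else(.data$state == "DEL", 1L, 3L),
           num_snps = count_markers(.data$chrom, .data$start, .data$end,
                                    marker_map)) %>%
    arrange(.data$sample_id, .data$chrom, .data$start)

  # --- fragmentation -------------------------------------------------------
  frag <- fragment_calls(as_call_tbl(intended), cfg$fragmentation_rate,
                         marker_map)
  raw_calls <- frag$calls

  # --- decoy calls: marker filter and region exclusion ---------------------
  decoys <- sim_decoys(cfg, slot_tbl, used_slot_idx, planted_large,
                       all_ids, marker_map)
  if (nrow(decoys) > 0) raw_calls <- bind_rows(raw_calls, decoys[names(raw_calls)])

  # --- QC outlier samples --------------------------------------------------
  out_n <- cfg$n_outlier_samples
  outliers <- NULL
  if (out_n > 0) {
    kinds <- rep(c("NUM_CNV", "LRR_SD", "NUM_CNV,LRR_SD"),
                 length.out = out_n)
    outliers <- tibble(
      sample_id = sprintf("QX%04d", seq_len(out_n)),
      status = rep(c("case", "control"), length.out = out_n),
      cohort = "Antioquia", batch = "batch1",
      lrr_sd = if_else(grepl("LRR_SD", kinds),
                       round(runif(out_n, 0.25, 0.35), 3),
                       round(runif(out_n, 0.08, 0.20), 3)),
      qc_kind = kinds
    )
    out_calls <- purrr::map(seq_len(out_n), function(i) {
      k <- if (grepl("NUM_CNV", kinds[i])) {
        sample(35:50, 1)
      } else {
        max(1L, rpois(1, cfg$mean_calls_per_sample))
      }
      size <- round(runif(k, 8e3, 3e4))
      st <- round(runif(k, BACKGROUND_ZONE[1], BACKGROUND_ZONE[2] - 3e4))
      tibble(sample_id = outliers$sample_id[i],
             chrom = as.character(sample.int(N_CHROM, k, replace = TRUE)),
             start = st, end = st + size - 1,
             state = if_else(runif(k) < cfg$del_fraction, "DEL", "DUP"))
    }) %>% bind_rows()
    out_calls <- out_calls %>%
      mutate(copy_number = if_else(.data$state == "DEL", 1L, 3L),
             num_snps = pmax(1L, count_markers(.data$chrom, .data$start,
                                               .data$end, marker_map)))
    raw_calls <- bind_rows(raw_calls, as_call_tbl(out_calls))
    samples <- bind_rows(samples, select(outliers, -"qc_kind"))
  }

  pc_table <- tibble(
    sample_id = samples$sample_id,
    PC1 = rnorm(nrow(samples), if_else(samples$cohort == "CVCR", 0.02, 0),
                0.05),
    PC2 = rnorm(nrow(samples), 0, 0.04),
    PC3 = rnorm(nrow(samples), 0, 0.03),
    PC4 = rnorm(nrow(samples), 0, 0.02),
    batch = samples$batch
  )

  raw_calls <- raw_calls[sample.int(nrow(raw_calls)), ]  # shuffle file order

  list(
    calls = raw_calls,
    samples = samples,
    marker_map = marker_map,
    genes = genes,
    regions = regions,
    pc_table = pc_table,
    truth = list(
      intended_calls = intended,
      large_carriers = list(case = carriers_case, control = carriers_control,
                            double_case = double_case),
      recurrent = tibble(
        gene = purrr::map_chr(rec_rows, "gene"),
        size_class = purrr::map_chr(rec_rows, "size_class"),
        state = purrr::map_chr(rec_rows, "state"),
        hits = purrr::map(rec_rows, "hits")),
      outliers = if (is.null(outliers)) tibble(sample_id = character(),
                                               qc_kind = character())
                 else select(outliers, "sample_id", "qc_kind"),
      fragmented = frag$map,
      decoys = decoys
    )
  )
}

as_call_tbl <- function(x) {
  cnv_calls(sample_id = x$sample_id, chrom = x$chrom, start = x$start,
            end = x$end, copy_number = x$copy_number, num_snps = x$num_snps)
}

sim_decoys <- function(cfg, slot_tbl, used_slot_idx, planted_large,
                       all_ids, marker_map) {
  rows <- list()
  # sub-10-marker calls in slots free of planted calls: isolated from
  # everything, removed by the marker filter. If all slots are occupied the
  # decoy is nested inside a planted call of the same sample and state so
  # merging absorbs it without disturbing the planted interval.
  free <- slot_tbl[!slot_tbl$idx %in% used_slot_idx, ]
  for (i in seq_len(cfg$n_filter_test_calls)) {
    size <- round(runif(1, 8e3, 2e4))
    state <- sample(c("DEL", "DUP"), 1)
    if (i <= nrow(free)) {
      st <- round(free$slot_start[i] + 9e5)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = sample(all_ids, 1), chrom = free$chrom[i], start = st,
        end = st + size - 1, state = state, origin = "decoy_filter")
    } else if (nrow(planted_large) > 0) {
      host <- planted_large[(i - 1) %% nrow(planted_large) + 1, ]
      st <- round(host$start + 1e5)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = host$sample_id, chrom = host$chrom, start = st,
        end = st + size - 1, state = host$state, origin = "decoy_absorbed")
    }
  }
  # calls straddling a q-telomere: pass the marker filter, removed by
  # region exclusion; far from the background zone so they never merge
  for (i in seq_len(cfg$n_region_test_calls)) {
    ch <- as.character(sample.int(N_CHROM, 1))
    st <- CHROM_LEN - TELOMERE_LEN - 7e4
    rows[[length(rows) + 1]] <- tibble(
      sample_id = sample(all_ids, 1), chrom = ch, start = st,
      end = st + 1e5 - 1, state = sample(c("DEL", "DUP"), 1),
      origin = "decoy_region")
  }
  if (length(rows) == 0) {
    out <- cnv_calls()
    out$origin <- character(0)
    return(out)
  }
  d <- bind_rows(rows) %>%
    mutate(copy_number = if_else(.data$state == "DEL", 1L, 3L),
           num_snps = pmax(1L, count_markers(.data$chrom, .data$start,
                                             .data$end, marker_map)))
  dplyr::bind_cols(as_call_tbl(d), select(d, "origin"))
}

#' Fragment calls into mergeable pieces
#'
#' Splits a fraction of calls into 2-3 pieces whose gaps satisfy the merge
#' inequality `gap < span / 2`, so that [merge_adjacent()] must reconstitute
#' the original interval exactly. Calls shorter than `min_size` are left
#' intact. Uses the current RNG state; seed outside (e.g. via
#' [simulate_cohort()] or `withr::with_seed()`).
#'
#' @param calls CNV call tibble.
#' @param rate Fraction of eligible calls to fragment, in \[0, 1\].
#' @param marker_map Marker map used to recount markers per fragment.
#' @param min_size Minimum call size eligible for splitting (default 60 kb).
#' @return A list with `calls` (the fragmented call tibble) and `map`
#'   (a tibble pairing each fragmented original, as
#'   `sample_id`/`chrom`/`start`/`end`, with its `n_pieces`).
#' @export
fragment_calls <- function(calls, rate, marker_map, min_size = 6e4) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  empty_map <- tibble(sample_id = character(), chrom = character(),
                      start = double(), end = double(), n_pieces = integer())
  if (rate == 0 || nrow(calls) == 0) {
    return(list(calls = calls, map = empty_map))
  }
  eligible <- which(cnv_size(calls) >= min_size)
  pick <- eligible[runif(length(eligible)) < rate]
  if (length(pick) == 0) return(list(calls = calls, map = empty_map))
  pieces <- purrr::map(pick, function(i) {
    row <- calls[i, ]
    k <- sample(2:3, 1)
    s <- row$start
    e <- row$end
    size <- e - s + 1
    # equal pieces separated by gaps of 20% of a piece: every consecutive
    # pair then satisfies gap < span / 2 and left-to-right merging restores
    # the original interval
    piece <- floor(size / (k + 0.2 * (k - 1)))
    gap <- floor(0.2 * piece)
    starts <- s + (seq_len(k) - 1) * (piece + gap)
    ends <- starts + piece - 1
    ends[k] <- e
    tibble(sample_id = row$sample_id, chrom = row$chrom,
           start = starts, end = ends, copy_number = row$copy_number,
           k = k)
  })
  frag_tbl <- bind_rows(pieces) %>%
    mutate(num_snps = pmax(1L, count_markers(.data$chrom, .data$start,
                                             .data$end, marker_map)))
  out <- bind_rows(calls[-pick, ], as_call_tbl(frag_tbl))
  map <- calls[pick, c("sample_id", "chrom", "start", "end")] %>%
    mutate(n_pieces = purrr::map_int(pieces, ~ .x$k[1]))
  list(calls = out, map = map)
}

#' Simulate MLPA measurements for parent-offspring trios
#'
#' Each trio's proband carries one gene-level CNV over a run of 2-3
#' consecutive probes of one assayed gene. A `de_novo_fraction` of probands
#' (realized as `round(n_trios * de_novo_fraction)`) have two unaffected
#' parents; the rest inherit the variant from one parent carrying the same
#' probes. Ratios are 0.5 per deleted probe, 1.5 per duplicated probe and
#' 1.0 otherwise, plus optional Gaussian noise.
#'
#' @param layout Probe layout: tibble with `gene`, `exon`, `probe_id`,
#'   `chrom`, `position` (see [mlpa_layout_from_genes()]).
#' @param n_trios Number of trios.
#' @param de_novo_fraction Fraction of probands with a de novo variant.
#' @param state CNV state planted in probands (`"DEL"` or `"DUP"`).
#' @param noise_sd Gaussian noise SD on ratios (default 0).
#' @param seed RNG seed.
#' @return A list with `mlpa` (measurement tibble), `pedigree`, and `truth`
#'   (tibble `proband`, `gene`, `state`, `probes` list-column, `verdict`).
#' @export
simulate_trios <- function(layout, n_trios = 3, de_novo_fraction = 2 / 3,
                           state = "DEL", noise_sd = 0, seed = 1L) {
  if (n_trios < 1) abort("n_trios must be >= 1")
  withr::with_seed(seed, {
    n_de_novo <- round(n_trios * de_novo_fraction)
    verdicts <- c(rep("DE_NOVO", n_de_novo),
                  rep(NA_character_, n_trios - n_de_novo))
    rows <- list()
    truth <- list()
    ped <- tibble(proband = sprintf("GT%d.1", seq_len(n_trios)),
                  father = sprintf("GT%d.2", seq_len(n_trios)),
                  mother = sprintf("GT%d.3", seq_len(n_trios)))
    target <- filter(layout, .data$gene != "REF")
    genes_avail <- unique(target$gene)
    for (i in seq_len(n_trios)) {
      g <- genes_avail[(i - 1) %% length(genes_avail) + 1]
      probes <- arrange(filter(target, .data$gene == g), .data$position)
      run_len <- min(nrow(probes), sample(2:3, 1))
      run_start <- sample.int(nrow(probes) - run_len + 1, 1)
      affected <- probes$probe_id[run_start:(run_start + run_len - 1)]
      verdict <- verdicts[i]
      carrier_parent <- NA_character_
      if (is.na(verdict)) {
        carrier_parent <- sample(c("father", "mother"), 1)
        verdict <- if (carrier_parent == "father") {
          "INHERITED_PATERNAL"
        } else {
          "INHERITED_MATERNAL"
        }
      }
      members <- c(ped$proband[i], ped$father[i], ped$mother[i])
      for (m in members) {
        has_cnv <- m == ped$proband[i] ||
          (!is.na(carrier_parent) && m == ped[[carrier_parent]][i])
        ratio <- rep(1, nrow(layout))
        if (has_cnv) {
          idx <- layout$probe_id %in% affected
          ratio[idx] <- if (state == "DEL") 0.5 else 1.5
        }
        if (noise_sd > 0) {
          ratio <- pmax(0.05, ratio + rnorm(length(ratio), 0, noise_sd))
        }
        rows[[length(rows) + 1]] <- mutate(layout, sample_id = m,
                                           normalized_ratio = ratio)
      }
      truth[[i]] <- tibble(proband = ped$proband[i], gene = g, state = state,
                           probes = list(affected), verdict = verdict)
    }
    mlpa <- bind_rows(rows) %>%
      select("sample_id", "probe_id", "gene", "exon", "chrom", "position",
             "normalized_ratio")
    list(mlpa = mlpa, pedigree = ped, truth = bind_rows(truth))
  })
}

#' Build an MLPA probe layout from gene models
#'
#' One target probe per exon of the selected genes, plus reference probes
#' (labelled gene `"REF"`) elsewhere in the genome.
#'
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @param gene_names Genes to assay (default: first two).
#' @param n_ref Number of reference probes (default 4).
#' @return A probe layout tibble (`gene`, `exon`, `probe_id`, `chrom`,
#'   `position`).
#' @export
mlpa_layout_from_genes <- function(genes,
                                   gene_names = head(unique(genes$gene), 2),
                                   n_ref = 4) {
  target <- genes %>%
    filter(.data$gene %in% gene_names) %>%
    mutate(probe_id = paste0(.data$gene, "_", .data$exon),
           position = (.data$start + .data$end) / 2) %>%
    select("gene", "exon", "probe_id", "chrom", "position")
  ref <- tibble(
    gene = "REF", exon = paste0("r", seq_len(n_ref)),
    probe_id = paste0("REF_", seq_len(n_ref)),
    chrom = as.character(N_CHROM - seq_len(n_ref) + 1),
    position = 2e7
  )
  bind_rows(target, ref)
}
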