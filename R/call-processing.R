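# Call-level post-processing: (i) merge neighbouring fragments of one event,
# (ii) drop weakly supported calls, (iii) drop calls in excluded regions.
# The stage order is fixed; merging must see fragments before the marker
# filter can judge the reassembled call.

#' Size of a CNV call in base pairs
#'
#' Under the 1-based inclusive convention, size = end - start + 1.
#'
#' @param calls CNV call tibble (or any tibble with `start` and `end`).
#' @return A numeric vector of sizes, one per row.
#' @examples
#' cnv_size(tibble::tibble(start = 100269291, end = 100876782)) # 607492
#' @export
cnv_size <- function(calls) {
  calls$end - calls$start + 1
}

#' Size bins for burden stratification
#'
#' @return Character vector of the four bin labels in order.
#' @export
size_bins <- function() {
  c("<10 kb", "10-100 kb", "100-500 kb", ">500 kb")
}

#' Assign CNV sizes to the four burden size bins
#'
#' Bins: `<10 kb` (size < 10,000), `10-100 kb` (10,000 <= size < 100,000),
#' `100-500 kb` (100,000 <= size <= 500,000) and `>500 kb` (size strictly
#' greater than 500,000 bp). The upper category is strict: exactly 500,000 bp
#' falls in 100-500 kb.
#'
#' @param size Numeric vector of sizes in bp (all >= 1).
#' @return An ordered factor with levels [size_bins()].
#' @export
assign_size_bin <- function(size) {
  if (any(size < 1)) abort("CNV size must be >= 1 bp")
  bins <- case_when(
    size < 1e4 ~ "<10 kb",
    size < 1e5 ~ "10-100 kb",
    size <= 5e5 ~ "100-500 kb",
    TRUE ~ ">500 kb"
  )
  factor(bins, levels = size_bins(), ordered = TRUE)
}

#' Merge neighbouring CNV fragments
#'
#' Array CNV callers fragment single events into neighbouring calls. Within
#' each (sample, chromosome, state) group sorted by start, two consecutive
#' calls A and B are merged when the gap separating them is less than half
#' the total span from the start of A to the end of B:
#' `gap = B.start - A.end - 1`, `span = B.end - A.start + 1`, merge iff
#' `gap < span / 2`. Merging is repeated until a fixed point. Deletions never
#' merge with duplications; overlapping same-state calls always merge (their
#' gap is non-positive). Overlapping calls of opposite state in one sample
#' are both kept, with a warning.
#'
#' The merged call spans from the first start to the last end. Its marker
#' count is recounted from `marker_map` when one is supplied (the markers in
#' the closed gaps genuinely lie inside the merged call); without a map it is
#' the sum of the parts. When fragments carry different copy numbers
#' (e.g. cn=0 with cn=1) they still merge on state, the leftmost fragment's
#' copy number is kept, and the mixture is reported via a message.
#'
#' @param calls CNV call tibble (any order).
#' @param marker_map Optional marker map (see [read_marker_map()]).
#' @return The merged call tibble, sorted by sample, chromosome, start.
#' @export
merge_adjacent <- function(calls, marker_map = NULL) {
  validate_cnv_calls(calls)
  if (nrow(calls) < 2) return(calls)
  warn_cross_state_overlap(calls)
  merged <- calls %>%
    group_by(.data$sample_id, .data$chrom, .data$state) %>%
    dplyr::group_modify(~ merge_group(.x)) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$chrom, .data$start) %>%
    select(all_of(names(calls)))
  if (!is.null(marker_map) && nrow(merged) > 0) {
    merged$num_snps <- count_markers(merged$chrom, merged$start, merged$end,
                                     marker_map)
    if (any(merged$num_snps < 1)) {
      warn("merged call spans no markers in the supplied map")
      merged$num_snps[merged$num_snps < 1] <- 1L
    }
  }
  merged
}

merge_group <- function(g) {
  g <- arrange(g, .data$start, .data$end)
  repeat {
    n <- nrow(g)
    if (n < 2) return(g)
    changed <- FALSE
    i <- 1
    while (i < nrow(g)) {
      gap <- g$start[i + 1] - g$end[i] - 1
      span <- max(g$end[i + 1], g$end[i]) - g$start[i] + 1
      if (gap < span / 2) {
        if (g$copy_number[i] != g$copy_number[i + 1]) {
          inform(sprintf(
            "merging fragments with mixed copy numbers (%d, %d) in sample %s",
            g$copy_number[i], g$copy_number[i + 1], g$sample_id[i]))
        }
        g$end[i] <- max(g$end[i], g$end[i + 1])
        g$num_snps[i] <- g$num_snps[i] + g$num_snps[i + 1]
        g$end_snp[i] <- g$end_snp[i + 1]
        g <- g[-(i + 1), ]
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!changed) return(g)
  }
}

warn_cross_state_overlap <- function(calls) {
  dels <- filter(calls, .data$state == "DEL")
  dups <- filter(calls, .data$state == "DUP")
  if (nrow(dels) == 0 || nrow(dups) == 0) return(invisible(NULL))
  clash <- inner_join(dels, dups, by = c("sample_id", "chrom"),
                      relationship = "many-to-many") %>%
    filter(pmax(.data$start.x, .data$start.y) <=
             pmin(.data$end.x, .data$end.y))
  if (nrow(clash) > 0) {
    warn(sprintf(
      "%d overlapping deletion/duplication pair(s) in the same sample; both kept",
      nrow(clash)))
  }
  invisible(NULL)
}

#' Filter calls on minimum marker support
#'
#' @param calls CNV call tibble.
#' @param min_snps Minimum number of supporting markers (default 10; a call
#'   with exactly `min_snps` markers is kept).
#' @return Calls with `num_snps >= min_snps`, input order preserved.
#' @export
filter_min_snps <- function(calls, min_snps = 10) {
  filter(calls, .data$num_snps >= min_snps)
}

#' Remove calls overlapping excluded regions
#'
#' A call is removed if it overlaps any region by at least one base
#' (1-based inclusive: `max(starts) <= min(ends)`). Adjacency is not overlap.
#' Intended for centromeric and telomeric intervals.
#'
#' @param calls CNV call tibble.
#' @param regions Region tibble (see [read_regions()]).
#' @return The calls with no region overlap, input order preserved.
#' @export
exclude_regions <- function(calls, regions) {
  if (is.null(regions) || nrow(regions) == 0 || nrow(calls) == 0) return(calls)
  calls[!overlaps_any(calls, regions), ]
}

# For each row of x, TRUE iff it overlaps >= 1 bp with some row of y on the
# same chromosome.
overlaps_any <- function(x, y) {
  hit <- rep(FALSE, nrow(x))
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(start = x$start[xi], end = x$end[xi]),
      IRanges::IRanges(start = y$start[yi], end = y$end[yi])
    )
    hit[xi] <- ov
  }
  hit
}

#' Run the full call-processing pipeline
#'
#' Applies, in order: fragment merging, the minimum-marker filter, and
#' excluded-region removal, then annotates size and size bin. Per-stage call
#' counts are reported as messages. Input calls should be restricted to
#' QC-passing samples first.
#'
#' @param calls Raw CNV call tibble (QC-passing samples).
#' @param marker_map Optional marker map for recounting markers in merged
#'   calls.
#' @param regions Optional excluded-region tibble.
#' @param min_snps Minimum marker support (default 10).
#' @param quiet Suppress per-stage count messages.
#' @return The final call tibble with added `size` and `size_bin` columns.
#' @export
process_calls <- function(calls, marker_map = NULL, regions = NULL,
                          min_snps = 10, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  say("input: %d calls", nrow(calls))
  merged <- merge_adjacent(calls, marker_map)
  say("after merging neighbours: %d calls", nrow(merged))
  kept <- filter_min_snps(merged, min_snps)
  say("after >=%d-marker filter: %d calls", min_snps, nrow(kept))
  final <- exclude_regions(kept, regions)
  say("after excluded-region removal: %d calls", nrow(final))
  final %>%
    mutate(size = cnv_size(final), size_bin = assign_size_bin(.data$size))
}
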