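# Size-stratified burden table and the carrier-level test: the headline
# comparison is a one-sided Fisher exact test on the 2x2 of individuals
# carrying >= 1 large CNV, cases vs controls; per-bin event counts are
# reported descriptively alongside.

#' One-sided Fisher exact test on a 2x2 carrier table
#'
#' Computes the exact hypergeometric upper-tail probability `P(X >= a)` with
#' all margins fixed, where `a` is the top-left cell (case carriers) and the
#' alternative is enrichment in cases. With `mid_p = TRUE` the mid-p variant
#' `p - 0.5 * P(X = a)` is returned; the default is the standard
#' (conservative) tail.
#'
#' @param tab 2x2 matrix of nonnegative integers:
#'   `rbind(c(case carriers, case non-carriers),
#'          c(control carriers, control non-carriers))`.
#' @param mid_p Use the mid-p correction (default `FALSE`).
#' @return The p-value, a number in (0, 1].
#' @examples
#' fisher_one_sided(rbind(c(25, 154), c(15, 219)))
#' @export
fisher_one_sided <- function(tab, mid_p = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("tab must contain nonnegative integers")
  }
  a <- tab[1, 1]
  n1 <- sum(tab[1, ])  # cases
  k <- sum(tab[, 1])   # carriers
  n <- sum(tab)
  if (k == 0 || k == n || n1 == 0 || n1 == n) {
    warn("degenerate margin in 2x2 table; p = 1")
    return(1)
  }
  support <- max(0, k - (n - n1)):min(k, n1)
  upper <- support[support >= a]
  p <- sum(dhyper(upper, k, n - k, n1))
  if (mid_p) p <- p - 0.5 * dhyper(a, k, n - k, n1)
  min(p, 1)
}

#' Carrier counts per group for one size bin
#'
#' An individual carrying two or more calls in the bin counts once.
#'
#' @param calls Final processed call tibble with a `size_bin` column (see
#'   [process_calls()]); calls restricted to QC-passing samples.
#' @param samples Sample tibble with `status`; only QC-passing rows should be
#'   supplied.
#' @param bin One of [size_bins()].
#' @return 2x2 integer matrix: rows case/control, columns
#'   carrier/non-carrier.
#' @export
carrier_table <- function(calls, samples, bin = ">500 kb") {
  bin <- match.arg(bin, size_bins())
  if (!"size_bin" %in% names(calls)) {
    calls <- mutate(calls, size_bin = assign_size_bin(cnv_size(calls)))
  }
  carriers <- unique(calls$sample_id[calls$size_bin == bin])
  a <- sum(samples$status == "case" & samples$sample_id %in% carriers)
  c_ <- sum(samples$status == "control" & samples$sample_id %in% carriers)
  n1 <- sum(samples$status == "case")
  n2 <- sum(samples$status == "control")
  matrix(c(a, n1 - a, c_, n2 - c_), nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("carrier", "non_carrier")))
}

#' Case-control excess of carriers with a Wald confidence interval
#'
#' Computes the percentage of carriers in each group, the case excess in
#' percentage points, and its 95% Wald (normal-approximation, unpooled
#' variance) confidence interval:
#' `excess +- 1.96 * 100 * sqrt(p1 (1-p1)/n1 + p2 (1-p2)/n2)`.
#' Values are returned unrounded; display at 1 decimal.
#'
#' @param a Case carriers. @param n1 Number of cases.
#' @param c_ Control carriers. @param n2 Number of controls.
#' @return One-row tibble with `pct_case`, `pct_control`, `excess_pct`,
#'   `ci95_low`, `ci95_high` (all in percentage points).
#' @examples
#' carrier_excess_ci(25, 179, 15, 234) # excess ~7.6, CI ~1.6-13.5
#' @export
carrier_excess_ci <- function(a, n1, c_, n2) {
  if (n1 <= 0 || n2 <= 0) abort("group sizes must be positive")
  if (a < 0 || a > n1 || c_ < 0 || c_ > n2) abort("carrier counts out of range")
  p1 <- a / n1
  p2 <- c_ / n2
  excess <- 100 * (p1 - p2)
  margin <- 1.96 * 100 * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  tibble(
    pct_case = 100 * p1, pct_control = 100 * p2,
    excess_pct = excess,
    ci95_low = excess - margin, ci95_high = excess + margin
  )
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / bc` on the carrier 2x2; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to both the
#' estimate and the interval. The 95% CI is Woolf's log-normal interval,
#' `exp(log(OR) +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param tab 2x2 matrix as in [fisher_one_sided()].
#' @return One-row tibble with `odds_ratio`, `or_ci_low`, `or_ci_high` and a
#'   logical `corrected` flag.
#' @export
odds_ratio_ci <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("tab must be a 2x2 matrix")
  if (any(rowSums(tab) == 0)) {
    warn("a row of the 2x2 table is all zero; odds ratio undefined")
    return(tibble(odds_ratio = NA_real_, or_ci_low = NA_real_,
                  or_ci_high = NA_real_, corrected = NA))
  }
  corrected <- any(tab == 0)
  t2 <- tab + if (corrected) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  tibble(
    odds_ratio = or,
    or_ci_low = exp(log(or) - 1.96 * se),
    or_ci_high = exp(log(or) + 1.96 * se),
    corrected = corrected
  )
}

#' Build the size-stratified burden table
#'
#' One row per size bin plus a Total row, with event counts and per-individual
#' frequencies (`count / n`) for cases and controls, and a one-sided Fisher
#' exact p-value on carrier status per bin. Frequencies are stored unrounded;
#' the print method shows them to 2 decimals.
#'
#' @param calls Final processed call tibble (QC-passing samples).
#' @param samples QC-passing sample tibble with `status`.
#' @param mid_p Use the mid-p Fisher variant for the per-bin tests.
#' @return A tibble of class `cnv_burden` with columns `size_bin`,
#'   `count_case`, `freq_case`, `count_control`, `freq_control`, `p_value`,
#'   and attributes `n_case`, `n_control`.
#' @export
build_burden_table <- function(calls, samples, mid_p = FALSE) {
  n_case <- sum(samples$status == "case")
  n_control <- sum(samples$status == "control")
  if (n_case == 0 || n_control == 0) {
    abort("both cases and controls are required")
  }
  if (!"size_bin" %in% names(calls)) {
    calls <- mutate(calls, size_bin = assign_size_bin(cnv_size(calls)))
  }
  calls <- left_join(calls,
                     select(samples, "sample_id", "status"),
                     by = "sample_id")
  if (any(is.na(calls$status))) {
    abort("calls present for samples absent from the sample table")
  }
  per_bin <- purrr::map(size_bins(), function(b) {
    in_bin <- filter(calls, .data$size_bin == b)
    tab <- carrier_table(calls, samples, b)
    tibble(
      size_bin = b,
      count_case = sum(in_bin$status == "case"),
      count_control = sum(in_bin$status == "control"),
      p_value = fisher_one_sided(tab, mid_p = mid_p)
    )
  })
  out <- bind_rows(per_bin) %>%
    bind_rows(tibble(
      size_bin = "Total",
      count_case = sum(calls$status == "case"),
      count_control = sum(calls$status == "control"),
      p_value = NA_real_
    )) %>%
    mutate(
      freq_case = .data$count_case / n_case,
      freq_control = .data$count_control / n_control
    ) %>%
    select("size_bin", "count_case", "freq_case",
           "count_control", "freq_control", "p_value")
  attr(out, "n_case") <- n_case
  attr(out, "n_control") <- n_control
  class(out) <- c("cnv_burden", class(out))
  out
}

#' @export
print.cnv_burden <- function(x, ...) {
  cat(sprintf("CNV burden: %d cases, %d controls\n",
              attr(x, "n_case"), attr(x, "n_control")))
  shown <- as_tibble(x) %>%
    mutate(freq_case = round(.data$freq_case, 2),
           freq_control = round(.data$freq_control, 2),
           p_value = signif(.data$p_value, 2))
  print(shown, ...)
  invisible(x)
}

#' Carrier-level burden test for one size bin
#'
#' Combines the carrier 2x2 table, the one-sided Fisher exact test, the Wald
#' excess interval and the odds ratio into one fitted-object summary of the
#' headline comparison (by default, carriers of >500 kb CNVs).
#'
#' @inheritParams carrier_table
#' @param mid_p Use the mid-p Fisher variant.
#' @return An object of class `cnv_carrier_test` with [tidy.cnv_carrier_test()]
#'   and [glance.cnv_carrier_test()] methods.
#' @export
carrier_test <- function(calls, samples, bin = ">500 kb", mid_p = FALSE) {
  tab <- carrier_table(calls, samples, bin)
  excess <- carrier_excess_ci(tab[1, 1], sum(tab[1, ]),
                              tab[2, 1], sum(tab[2, ]))
  structure(
    list(
      bin = bin, table = tab,
      p_one_sided = fisher_one_sided(tab, mid_p = mid_p),
      mid_p = mid_p, excess = excess, odds = odds_ratio_ci(tab)
    ),
    class = "cnv_carrier_test"
  )
}

#' @export
print.cnv_carrier_test <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Carriers of %s CNVs: %d/%d cases (%.1f%%) vs %d/%d controls (%.1f%%)\n",
              x$bin, tab[1, 1], sum(tab[1, ]), x$excess$pct_case,
              tab[2, 1], sum(tab[2, ]), x$excess$pct_control))
  cat(sprintf("Excess in cases: %.1f%% (95%% CI %.1f-%.1f%%)\n",
              x$excess$excess_pct, x$excess$ci95_low, x$excess$ci95_high))
  cat(sprintf("One-sided Fisher%s p = %s; OR = %.2f (95%% CI %.2f-%.2f)\n",
              if (x$mid_p) " (mid-p)" else "", signif(x$p_one_sided, 2),
              x$odds$odds_ratio, x$odds$or_ci_low, x$odds$or_ci_high))
  invisible(x)
}

#' Tidy a carrier-level burden test
#'
#' @param x A `cnv_carrier_test`.
#' @param ... Unused.
#' @return A one-row tibble with the carrier counts, percentages, excess and
#'   its CI, p-value, and odds ratio with its CI.
#' @export
tidy.cnv_carrier_test <- function(x, ...) {
  tab <- x$table
  tibble(
    size_bin = x$bin,
    carriers_case = tab[1, 1], n_case = sum(tab[1, ]),
    carriers_control = tab[2, 1], n_control = sum(tab[2, ]),
    pct_case = x$excess$pct_case, pct_control = x$excess$pct_control,
    excess_pct = x$excess$excess_pct,
    ci95_low = x$excess$ci95_low, ci95_high = x$excess$ci95_high,
    p_one_sided = x$p_one_sided,
    odds_ratio = x$odds$odds_ratio,
    or_ci_low = x$odds$or_ci_low, or_ci_high = x$odds$or_ci_high
  )
}

#' Glance at a carrier-level burden test
#'
#' @param x A `cnv_carrier_test`.
#' @param ... Unused.
#' @return A one-row tibble with `excess_pct`, `p_one_sided`, `odds_ratio`.
#' @export
glance.cnv_carrier_test <- function(x, ...) {
  tibble(excess_pct = x$excess$excess_pct, p_one_sided = x$p_one_sided,
         odds_ratio = x$odds$odds_ratio)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
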