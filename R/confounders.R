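# Stratification checks: is large-CNV carriership associated with ancestry
# (principal components) or with genotyping batch?

#' Association between carrier status and ancestry principal components
#'
#' For each principal component, computes the point-biserial correlation
#' between the 0/1 carrier indicator and the PC (identical to the Pearson
#' correlation on those vectors) and the exact two-sided p-value from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom. No multiplicity correction is applied across PCs.
#'
#' @param pc_table Tibble with `sample_id` and PC columns (see
#'   [read_pc_table()]).
#' @param carriers Character vector of carrier sample ids.
#' @param pcs Names of the PC columns to test (default `PC1`..`PC4`).
#' @return A tibble with one row per PC: `pc`, `r`, `t`, `df`, `p_value`.
#'   A PC with zero variance, or a degenerate carrier split (fewer than two
#'   carriers or two non-carriers), yields `NA` statistics with a warning.
#' @export
pc_association <- function(pc_table, carriers, pcs = paste0("PC", 1:4)) {
  missing_pcs <- setdiff(pcs, names(pc_table))
  if (length(missing_pcs) > 0) {
    abort(paste0("PC columns absent: ", paste(missing_pcs, collapse = ", ")))
  }
  y <- as.numeric(pc_table$sample_id %in% carriers)
  n <- length(y)
  degenerate_split <- sum(y) < 2 || sum(1 - y) < 2
  if (degenerate_split) warn("fewer than 2 carriers or 2 non-carriers")
  rows <- purrr::map(pcs, function(pc) {
    x <- pc_table[[pc]]
    if (degenerate_split || var(x) == 0) {
      if (!degenerate_split) warn(paste0(pc, " has zero variance"))
      return(tibble(pc = pc, r = NA_real_, t = NA_real_,
                    df = n - 2, p_value = NA_real_))
    }
    r <- cor(y, x)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    tibble(pc = pc, r = r, t = tstat, df = n - 2,
           p_value = 2 * pt(-abs(tstat), df = n - 2))
  })
  bind_rows(rows)
}

#' Association between carrier status and genotyping batch
#'
#' Builds the carrier-by-batch 2x2 table and applies a two-sided Fisher exact
#' test ([stats::fisher.test()]). Exactly two batch labels are required.
#'
#' @param samples Sample tibble with a `batch` column.
#' @param carriers Character vector of carrier sample ids.
#' @return A list with elements `table` (the 2x2 matrix, batches as rows)
#'   and `p_value`.
#' @export
batch_association <- function(samples, carriers) {
  batches <- sort(unique(samples$batch))
  if (length(batches) != 2) {
    abort("exactly two batch labels are required; test batch pairs separately")
  }
  is_carrier <- samples$sample_id %in% carriers
  tab <- matrix(
    c(sum(samples$batch == batches[1] & is_carrier),
      sum(samples$batch == batches[1] & !is_carrier),
      sum(samples$batch == batches[2] & is_carrier),
      sum(samples$batch == batches[2] & !is_carrier)),
    nrow = 2, byrow = TRUE,
    dimnames = list(batches, c("carrier", "non_carrier"))
  )
  if (sum(tab[, 1]) == 0) {
    return(list(table = tab, p_value = 1))
  }
  list(table = tab, p_value = stats::fisher.test(tab)$p.value)
}
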