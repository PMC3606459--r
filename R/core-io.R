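# Domain tables, coordinate conventions and readers/writers.
#
# All internal coordinates are 1-based inclusive, so size = end - start + 1
# (the convention under which the published per-call sizes reproduce exactly).
# BED inputs are 0-based half-open on disk and are converted at the boundary.

#' Construct a CNV call table
#'
#' The central data structure of the package: one row per copy-number variant
#' call in one sample. Coordinates are 1-based inclusive; `state` is derived
#' from the integer copy number (`cn < 2` is a deletion, `cn > 2` a
#' duplication; two copies is not a variant and is rejected).
#'
#' @param sample_id Character, sample identifiers.
#' @param chrom Character or integer chromosome labels; a leading `"chr"` is
#'   stripped.
#' @param start,end Integer 1-based inclusive base positions, `start <= end`.
#' @param copy_number Integer copy number (0, 1, 3, 4, ...; never 2).
#' @param num_snps Integer number of array markers supporting the call
#'   (at least 1).
#' @param start_snp,end_snp Optional marker names at the call boundaries.
#'
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `state` (`"DEL"`/`"DUP"`), `copy_number`, `num_snps`, `start_snp`,
#'   `end_snp`.
#' @examples
#' cnv_calls("S01", "3", 100269291, 100876782, copy_number = 3, num_snps = 105)
#' @export
cnv_calls <- function(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      copy_number = integer(), num_snps = integer(),
                      start_snp = NA_character_, end_snp = NA_character_) {
  calls <- tibble(
    sample_id = as.character(sample_id),
    chrom = normalize_chrom(chrom),
    start = as.double(start),
    end = as.double(end),
    copy_number = as.integer(copy_number),
    num_snps = as.integer(num_snps),
    start_snp = as.character(start_snp),
    end_snp = as.character(end_snp)
  )
  calls$state <- state_from_cn(calls$copy_number)
  calls <- calls[, c("sample_id", "chrom", "start", "end", "state",
                     "copy_number", "num_snps", "start_snp", "end_snp")]
  validate_cnv_calls(calls)
}

state_from_cn <- function(cn) {
  if (any(cn == 2, na.rm = TRUE)) {
    abort("copy_number = 2 is the diploid state, not a CNV")
  }
  if_else(cn < 2, "DEL", "DUP")
}

normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Validate a CNV call table
#'
#' Checks the structural invariants (start <= end, state consistent with copy
#' number, positive marker counts) and returns the table invisibly unchanged.
#'
#' @param calls A tibble as produced by [cnv_calls()].
#' @return `calls`, invisibly validated.
#' @export
validate_cnv_calls <- function(calls) {
  required <- c("sample_id", "chrom", "start", "end", "state",
                "copy_number", "num_snps")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0) {
    abort(paste0("call table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(calls) == 0) return(calls)
  if (any(calls$start > calls$end)) abort("call with start > end")
  if (any(calls$start < 1)) abort("call with start < 1")
  if (any(calls$copy_number == 2)) {
    abort("copy_number = 2 is the diploid state, not a CNV")
  }
  bad_state <- calls$state != if_else(calls$copy_number < 2, "DEL", "DUP")
  if (any(bad_state)) abort("state inconsistent with copy_number")
  if (any(calls$num_snps < 1)) abort("call with num_snps < 1")
  calls
}

#' Read a PennCNV-style call file
#'
#' Parses the whitespace-separated one-call-per-line dialect written by
#' array CNV callers: `chr<C>:<start>-<end>  numsnp=<n>  length=<L>
#' state<s>,cn=<c>  <sample_id>  [startsnp=<id> endsnp=<id>]`. The `length`
#' field is validated against `end - start + 1`; on mismatch the computed
#' value wins with a warning. Lines with `cn=2` are rejected (two copies is
#' not a variant) so that upstream calling errors surface rather than vanish.
#'
#' @param path Path to the call file.
#' @return A CNV call tibble (see [cnv_calls()]), one row per input line,
#'   in file order.
#' @export
read_cnv_calls <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  lines_keep <- which(!grepl("^\\s*$", lines))
  if (length(lines_keep) == 0) return(cnv_calls())
  parsed <- purrr::map(lines_keep, function(i) {
    parse_cnv_line(lines[[i]], i)
  })
  bind_rows(parsed)
}

parse_cnv_line <- function(line, line_no) {
  fields <- strsplit(trimws(line), "\\s+")[[1]]
  loc <- regmatches(fields[1],
                    regexec("^chr([^:]+):([0-9,]+)-([0-9,]+)$", fields[1]))[[1]]
  if (length(loc) != 4) {
    abort(sprintf("line %d: malformed locus field '%s'", line_no, fields[1]))
  }
  grab <- function(key) {
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  numsnp <- grab("numsnp")
  len <- grab("length")
  state_field <- grep("^state[0-9]+,cn=", fields, value = TRUE)
  if (is.na(numsnp) || length(state_field) == 0) {
    abort(sprintf("line %d: missing numsnp or state/cn field", line_no))
  }
  cn <- as.integer(sub("^state[0-9]+,cn=", "", state_field[1]))
  if (is.na(cn)) abort(sprintf("line %d: unparseable copy number", line_no))
  if (cn == 2) {
    abort(sprintf("line %d: cn=2 is not a CNV call", line_no))
  }
  keyed <- grepl("=", fields)
  keyed[1] <- TRUE  # locus field
  sample_field <- fields[!keyed]
  if (length(sample_field) != 1) {
    abort(sprintf("line %d: expected exactly one sample id field", line_no))
  }
  start <- as.double(gsub(",", "", loc[3]))
  end <- as.double(gsub(",", "", loc[4]))
  if (is.na(start) || is.na(end) || start > end) {
    abort(sprintf("line %d: invalid interval", line_no))
  }
  if (!is.na(len)) {
    len <- as.double(gsub(",", "", len))
    if (!is.na(len) && len != end - start + 1) {
      warn(sprintf(
        "line %d: length field %s disagrees with end - start + 1 = %s; using computed size",
        line_no, format(len, scientific = FALSE),
        format(end - start + 1, scientific = FALSE)))
    }
  }
  cnv_calls(
    sample_id = sample_field, chrom = loc[2], start = start, end = end,
    copy_number = cn, num_snps = as.integer(numsnp),
    start_snp = grab("startsnp"), end_snp = grab("endsnp")
  )
}

#' Write a CNV call table in the PennCNV-style dialect
#'
#' Round-trips with [read_cnv_calls()]: reading a written file reproduces the
#' call table field for field.
#'
#' @param calls A CNV call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  validate_cnv_calls(calls)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- character(nrow(calls))
  if (nrow(calls) > 0) {
    lines <- paste0(
      "chr", calls$chrom, ":", fmt(calls$start), "-", fmt(calls$end),
      " numsnp=", calls$num_snps,
      " length=", fmt(calls$end - calls$start + 1),
      " state", if_else(calls$state == "DEL", 2L, 5L), ",cn=",
      calls$copy_number,
      " ", calls$sample_id,
      if_else(is.na(calls$start_snp), "",
              paste0(" startsnp=", calls$start_snp)),
      if_else(is.na(calls$end_snp), "",
              paste0(" endsnp=", calls$end_snp))
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}

bed_to_tibble <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start0", "end0", "name"),
    col_types = readr::cols(
      chrom = readr::col_character(), start0 = readr::col_double(),
      end0 = readr::col_double(), name = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  if (nrow(bed) > 0 && any(bed$end0 <= bed$start0)) {
    abort("BED interval with end <= start")
  }
  # 0-based half-open -> 1-based inclusive; length is preserved
  mutate(bed,
         chrom = normalize_chrom(.data$chrom),
         start = .data$start0 + 1, end = .data$end0) %>%
    select("chrom", "start", "end", "name")
}

#' Read gene exon models from a 4-column BED file
#'
#' Exon names follow `<gene>_<exon label>`; the gene is everything up to the
#' last underscore. BED coordinates (0-based half-open) are converted to
#' 1-based inclusive at this boundary. Overlapping exons within a gene are
#' merged with a warning; exons are returned sorted within gene.
#'
#' @param path Path to the exon BED file.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `exon`
#'   (the label after the last underscore), one row per exon.
#' @export
read_gene_models <- function(path) {
  bed <- bed_to_tibble(path)
  if (nrow(bed) == 0) {
    return(tibble(gene = character(), chrom = character(),
                  start = double(), end = double(), exon = character()))
  }
  bed <- mutate(bed,
                gene = sub("_[^_]*$", "", .data$name),
                exon = sub("^.*_", "", .data$name))
  out <- bed %>%
    group_by(.data$gene, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    ungroup()
  merged <- out %>%
    group_by(.data$gene, .data$chrom) %>%
    mutate(clump = cumsum(.data$start > lag(cummax(.data$end),
                                            default = -Inf) + 0)) %>%
    group_by(.data$gene, .data$chrom, .data$clump) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              exon = first(.data$exon), n_in = n(), .groups = "drop") %>%
    select(-"clump")
  if (any(merged$n_in > 1)) {
    warn("overlapping exons within a gene were merged")
  }
  merged %>%
    select("gene", "chrom", "start", "end", "exon") %>%
    arrange(.data$gene, .data$start)
}

#' Read excluded genomic regions from a 4-column BED file
#'
#' Intended for centromere/telomere interval tables; which coordinate table
#' to use is a study choice, so the file is a required input rather than a
#' packaged constant.
#'
#' @param path Path to the region BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`
#'   (1-based inclusive).
#' @export
read_regions <- function(path) {
  bed <- bed_to_tibble(path)
  rename(bed, label = "name")
}

#' Read the per-sample table
#'
#' Header-bearing TSV with columns `sample_id`, `cohort`, `status`
#' (`case`/`control`), `batch`, `lrr_sd`, and optionally `num_cnv`.
#'
#' @param path Path to the TSV.
#' @return A sample tibble.
#' @export
read_sample_table <- function(path) {
  s <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), cohort = readr::col_character(),
    status = readr::col_character(), batch = readr::col_character(),
    lrr_sd = readr::col_double(), .default = readr::col_guess()
  ), progress = FALSE)
  bad <- setdiff(unique(s$status), c("case", "control"))
  if (length(bad) > 0) {
    abort(paste0("unknown status values: ", paste(bad, collapse = ", ")))
  }
  s
}

#' Read a marker map
#'
#' TSV with columns `marker`, `chrom`, `pos` (1-based). Marker names must be
#' unique; the map supports recounting markers inside merged calls.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `marker`, `chrom`, `pos`.
#' @export
read_marker_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double()
  ), progress = FALSE)
  m <- mutate(m, chrom = normalize_chrom(.data$chrom))
  if (anyDuplicated(m$marker)) abort("duplicate marker names in marker map")
  if (nrow(m) > 0 && any(m$pos < 1)) abort("marker position < 1")
  m
}

#' Read a principal-component table
#'
#' TSV with columns `sample_id`, `PC1`..`PC4` and optionally `batch`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_pc_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
}

#' Read a trio pedigree
#'
#' Three-column TSV (`proband`, `father`, `mother`), one trio per row; the
#' three ids in a trio must be distinct.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `proband`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("proband", "father", "mother") %in% names(ped))) {
    abort("pedigree must have columns proband, father, mother")
  }
  dup <- ped$proband == ped$father | ped$proband == ped$mother |
    ped$father == ped$mother
  if (any(dup)) abort("trio with non-distinct member ids")
  ped
}

#' Read an MLPA probe-ratio table
#'
#' TSV with columns `sample_id`, `probe_id`, `gene`, `exon`, `chrom`,
#' `position`, `normalized_ratio`. Ratios are relative to the two-copy state
#' (about 1.0 for diploid) and must be positive.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_mlpa_table <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), probe_id = readr::col_character(),
    gene = readr::col_character(), exon = readr::col_character(),
    chrom = readr::col_character(), position = readr::col_double(),
    normalized_ratio = readr::col_double()
  ), progress = FALSE)
  if (nrow(m) > 0 && any(m$normalized_ratio <= 0)) {
    abort("MLPA normalized_ratio must be positive")
  }
  mutate(m, chrom = normalize_chrom(.data$chrom))
}
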