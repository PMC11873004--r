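#' Parse read names into base id and UMI
#'
#' AMP-style libraries carry the unique molecular identifier (UMI) in the read
#' name. The default dialect expects the UMI as a trailing token introduced by
#' `_UMI:`/`:UMI:` (or `UMI_`); reads whose names do not match keep an empty
#' UMI and are never collapsed by UMI-based deduplication.
#'
#' @param read_name Character vector of read names.
#' @param umi_regex Regex with one capture group for the UMI; everything the
#'   whole match covers is stripped from the name to form the base read id.
#' @return A tibble with columns `read_id` and `umi`.
#' @examples
#' parse_read_meta(c("R0001_UMI:ACGTACGT", "R0002"))
#' @export
parse_read_meta <- function(read_name, umi_regex = "(?:_|:)UMI[:_]?([ACGTN]+)$") {
  m <- str_match(read_name, umi_regex)
  umi <- ifelse(is.na(m[, 2]), "", m[, 2])
  read_id <- ifelse(is.na(m[, 1]), read_name,
                    substr(read_name, 1L, nchar(read_name) - nchar(m[, 1])))
  tibble(read_id = read_id, umi = umi)
}

sam_tag <- function(tagfields, tag) {
  pre <- paste0(tag, ":Z:")
  hit <- map_chr(tagfields, function(tf) {
    x <- tf[startsWith(tf, pre)]
    if (length(x)) substring(x[1], nchar(pre) + 1L) else NA_character_
  })
  hit
}

#' Read split-read alignments from a SAM (or BAM) file
#'
#' Reads alignment records and returns one row per primary alignment with the
#' fields the fusion-calling path needs: position, MAPQ, CIGAR, strand, the
#' raw `SA:Z` (supplementary alignment) and `XA:Z` (alternative alignment)
#' tags, sequence/quality for later read extraction, and the UMI parsed from
#' the read name. Only the first 10 standard SAM fields plus `SA`/`XA` are
#' required, which is exactly what a BWA-MEM-aligned file provides; secondary
#' and supplementary lines are skipped because the primary record's `SA` tag
#' carries the supplementary coordinates.
#'
#' @param path Path to a SAM text file; a `.bam` file is converted via
#'   `Rsamtools::asSam()` when that package is available.
#' @param umi_regex UMI dialect passed to [parse_read_meta()].
#' @return A tibble with one row per primary alignment: `read_id`, `umi`,
#'   `flag`, `strand`, `chrom`, `pos`, `mapq`, `cigar`, `sa`, `xa`, `seq`,
#'   `qual`, `is_read1`, `read_length`.
#' @export
read_split_sam <- function(path, umi_regex = "(?:_|:)UMI[:_]?([ACGTN]+)$") {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      abort("Reading BAM requires the Rsamtools package; supply SAM text instead.")
    }
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asSam(path, dest)
  }
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(
      read_id = character(), umi = character(), flag = integer(),
      strand = character(), chrom = character(), pos = integer(),
      mapq = integer(), cigar = character(), sa = character(),
      xa = character(), seq = character(), qual = character(),
      is_read1 = logical(), read_length = integer()
    ))
  }
  fields <- str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    abort(sprintf("SAM line %d has %d fields; at least the 11 standard fields are required.",
                  which(nf < 11L)[1], min(nf)))
  }
  flag <- as.integer(map_chr(fields, 2))
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L &
    bitwAnd(flag, 4L) == 0L
  fields <- fields[keep]
  flag <- flag[keep]
  tagfields <- map(fields, function(f) if (length(f) > 11L) f[12:length(f)] else character())
  cigar <- map_chr(fields, 6)
  meta <- parse_read_meta(map_chr(fields, 1), umi_regex)
  cs <- cigar_summaries(cigar, max_indel = 0L)
  out <- tibble(
    read_id = meta$read_id,
    umi = meta$umi,
    flag = flag,
    strand = if_else(bitwAnd(flag, 16L) > 0L, "-", "+"),
    chrom = map_chr(fields, 3),
    pos = as.integer(map_chr(fields, 4)),
    mapq = as.integer(map_chr(fields, 5)),
    cigar = cigar,
    sa = sam_tag(tagfields, "SA"),
    xa = sam_tag(tagfields, "XA"),
    seq = map_chr(fields, 10),
    qual = map_chr(fields, 11),
    is_read1 = bitwAnd(flag, 128L) == 0L,
    read_length = cs$q_lead + cs$q_mapped + cs$q_trail
  )
  if (any(out$pos < 1L) || any(out$mapq < 0L | out$mapq > 60L)) {
    warn("Records with out-of-range POS or MAPQ encountered.")
  }
  out
}

#' Soft-clip-adjusted ligation sites
#'
#' The ligation site (LS) is the genomic coordinate of the adaptor-ligated
#' fragment end. Short unmapped leading sequence (the soft clip) means the
#' alignment starts inside the fragment, so the mapped position is pushed back
#' by the clip length: on the plus strand `ls = pos - leading_clip`; on the
#' minus strand the fragment end is past the alignment's reference end,
#' `ls = ref_end + trailing_clip` (clips taken in reference orientation).
#' Positions are clamped at 1.
#'
#' @param records A tibble of primary alignment records from
#'   [read_split_sam()].
#' @param ligation_end Which mate carries the ligation end; echoed into the
#'   result for bookkeeping (`"read1_start"`, the default, or
#'   `"read2_start"`).
#' @return `records` with added columns `ls_chrom`, `ls_pos`, `ls_strand`.
#' @examples
#' recs <- tibble::tibble(
#'   read_id = "r1", umi = "ACGT", strand = "+", chrom = "chr1",
#'   pos = 1000L, mapq = 60L, cigar = "5S50M45S", read_length = 100L
#' )
#' compute_ligation_sites(recs)$ls_pos  # 995
#' @export
compute_ligation_sites <- function(records, ligation_end = c("read1_start", "read2_start")) {
  ligation_end <- match.arg(ligation_end)
  if (nrow(records) == 0L) {
    return(mutate(records, ls_chrom = character(), ls_pos = integer(),
                  ls_strand = character()))
  }
  cs <- cigar_summaries(records$cigar, max_indel = 0L)
  records |>
    mutate(
      ls_chrom = .data$chrom,
      ls_pos = if_else(
        .data$strand == "+",
        pmax(1L, .data$pos - cs$q_lead),
        .data$pos + cs$ref_span - 1L + cs$q_trail
      ),
      ls_strand = .data$strand
    )
}

#' Consolidate duplicate reads by UMI and ligation site
#'
#' Reads sharing a UMI and a soft-clip-adjusted ligation site (UMI-LS) are PCR
#' duplicates of one source molecule; exactly one representative is kept per
#' key, together with all of its supplementary alignments (which inherit the
#' read-1 UMI-LS). The representative is the read with the highest primary
#' MAPQ, ties broken by the lexicographically smallest read id, so output is
#' deterministic. Reads without a parsed UMI are never collapsed in `umi_ls`
#' mode. `ls` mode collapses on ligation site alone (for UMI-free libraries,
#' off by default because position-only collapse destroys depth);
#' `off` disables deduplication.
#'
#' @param records A tibble with `ls_*` columns from [compute_ligation_sites()].
#' @param dedup One of `"umi_ls"` (default), `"ls"`, `"off"`.
#' @return The consolidated tibble, one row per distinct key, with an added
#'   `n_dup` column giving the number of reads the representative stands for.
#' @export
dedup_reads <- function(records, dedup = c("umi_ls", "ls", "off")) {
  dedup <- match.arg(dedup)
  if (dedup == "off" || nrow(records) == 0L) {
    return(mutate(records, n_dup = 1L))
  }
  ls_key <- paste(records$ls_chrom, records$ls_pos, records$ls_strand, sep = ":")
  key <- switch(dedup,
    umi_ls = if_else(records$umi == "",
                     paste0("read:", records$read_id),
                     paste(records$umi, ls_key, sep = "@")),
    ls = ls_key
  )
  records |>
    mutate(.key = key) |>
    group_by(.data$.key) |>
    arrange(desc(.data$mapq), .data$read_id, .by_group = TRUE) |>
    mutate(n_dup = n()) |>
    slice(1L) |>
    ungroup() |>
    select(-".key") |>
    arrange(.data$read_id)
}

parse_sa_tag <- function(sa) {
  # SA:Z: semicolon-terminated entries "rname,pos,strand,CIGAR,mapQ,NM;"
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  parts <- str_split(entries, ",")
  ok <- lengths(parts) == 6L
  if (!all(ok)) return(NULL)
  tibble(
    chrom = map_chr(parts, 1),
    pos = as.integer(map_chr(parts, 2)),
    strand = map_chr(parts, 3),
    cigar = map_chr(parts, 4),
    mapq = as.integer(map_chr(parts, 5))
  )
}

#' Expand primary records and their SA tags into alignment segments
#'
#' Each read with supplementary alignments is expanded into one segment per
#' alignment (the primary plus one per `SA` entry). Reads without any
#' supplementary alignment carry no split and are dropped from the fusion
#' path unless `keep_unsplit = TRUE`. Records whose `SA` tag is malformed
#' (entries without exactly 6 fields) are skipped with a warning.
#'
#' @param records Consolidated records from [dedup_reads()] (or any tibble
#'   with the [read_split_sam()] columns plus `ls_*`).
#' @param keep_unsplit Keep reads without SA entries as single segments.
#' @return A tibble with one row per alignment segment: read metadata columns
#'   plus `chrom`, `pos`, `strand`, `cigar`, `mapq`, `is_primary`, `xa`.
#' @export
expand_alignments <- function(records, keep_unsplit = FALSE) {
  empty <- tibble(
    read_id = character(), umi = character(), ls_chrom = character(),
    ls_pos = integer(), ls_strand = character(), is_read1 = logical(),
    read_length = integer(), chrom = character(), pos = integer(),
    strand = character(), cigar = character(), mapq = integer(),
    is_primary = logical(), xa = character()
  )
  if (nrow(records) == 0L) return(empty)
  if (!"ls_pos" %in% names(records)) records <- compute_ligation_sites(records)
  if (!"xa" %in% names(records)) records$xa <- NA_character_
  rows <- pmap(
    list(seq_len(nrow(records))),
    function(i) {
      rec <- records[i, ]
      prim <- tibble(
        read_id = rec$read_id, umi = rec$umi, ls_chrom = rec$ls_chrom,
        ls_pos = rec$ls_pos, ls_strand = rec$ls_strand,
        is_read1 = rec$is_read1, read_length = rec$read_length,
        chrom = rec$chrom, pos = rec$pos, strand = rec$strand,
        cigar = rec$cigar, mapq = rec$mapq, is_primary = TRUE, xa = rec$xa
      )
      if (is.na(rec$sa) || !nzchar(rec$sa)) {
        if (keep_unsplit) return(prim) else return(NULL)
      }
      sa <- parse_sa_tag(rec$sa)
      if (is.null(sa)) {
        warn(sprintf("Read '%s': malformed SA tag, record skipped.", rec$read_id))
        return(NULL)
      }
      bind_rows(prim, mutate(sa,
        read_id = rec$read_id, umi = rec$umi, ls_chrom = rec$ls_chrom,
        ls_pos = rec$ls_pos, ls_strand = rec$ls_strand,
        is_read1 = rec$is_read1, read_length = rec$read_length,
        is_primary = FALSE, xa = NA_character_
      ))
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  select(out, names(empty))
}
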