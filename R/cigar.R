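#' Parse a CIGAR string into its operations
#'
#' Splits a CIGAR string into `(op, len)` pairs. Operations are normalised for
#' downstream split-read logic: `X` and `=` fold into `M`, `P` is dropped, and
#' `N` (splice gap, absent from BWA-MEM output) is kept as a reference-consuming
#' gap that terminates an `M` run. `S`/`H` clips and `I`/`D` indels are kept
#' as-is. Hard clips are treated throughout the package as query-consuming
#' placeholders, because aligners emit them on supplementary records in place
#' of the soft clips of the primary record.
#'
#' @param cigar A single CIGAR string, e.g. `"30S70M"`.
#' @return A tibble with columns `op` (character, one of S, M, I, D, H, N) and
#'   `len` (integer).
#' @examples
#' parse_cigar("30S70M")
#' parse_cigar("20M1D30M")
#' @export
parse_cigar <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || !nzchar(cigar)) {
    abort("`cigar` must be a single non-empty string.")
  }
  m <- str_match_all(cigar, "([0-9]+)([MIDNSHPX=])")[[1]]
  if (nrow(m) == 0L || sum(nchar(m[, 1])) != nchar(cigar)) {
    abort(paste0("Unparsable CIGAR string: '", cigar, "'"))
  }
  op <- m[, 3]
  len <- as.integer(m[, 2])
  if (any(len <= 0L)) abort(paste0("CIGAR with non-positive length: '", cigar, "'"))
  op[op %in% c("X", "=")] <- "M"
  keep <- op != "P"
  tibble(op = op[keep], len = len[keep])
}

#' Smooth short indels out of a parsed CIGAR
#'
#' Insertions and deletions no longer than `max_indel` bases (default 1) that
#' are flanked by mapped (`M`) runs are absorbed into a single `M` run, the
#' convention used when reconstructing the split layout of a read: a 1-base
#' indel is alignment noise, not a fusion breakpoint. The merged run preserves
#' the *query* extent exactly (an absorbed insertion adds its length, an
#' absorbed deletion adds nothing); a single `M` cannot also preserve the
#' reference extent, so reference spans are always measured on the raw
#' operations (see [layout_segments()]).
#' The pass is applied left-to-right and repeated to a fixpoint so chains such
#' as `M 1D M 1D M` collapse fully. Indels longer than `max_indel` are left
#' intact. The total query length consumed is invariant under smoothing.
#'
#' @param ops A tibble of `(op, len)` pairs from [parse_cigar()].
#' @param max_indel Maximum indel length to absorb (default 1).
#' @return A tibble of `(op, len)` like the input.
#' @examples
#' smooth_cigar(parse_cigar("20M1D30M"))
#' smooth_cigar(parse_cigar("10M2D40M"))  # length-2 indel is kept
#' @export
smooth_cigar <- function(ops, max_indel = 1L) {
  op <- ops$op
  len <- ops$len
  repeat {
    hit <- which(op %in% c("I", "D") & len <= max_indel &
                   c(FALSE, head(op, -1) == "M") &
                   c(tail(op, -1) == "M", FALSE))
    if (length(hit) == 0L) break
    i <- hit[1L]
    q_extra <- if (op[i] == "I") len[i] else 0L
    len[i - 1L] <- len[i - 1L] + len[i + 1L] + q_extra
    op <- op[-c(i, i + 1L)]
    len <- len[-c(i, i + 1L)]
  }
  tibble(op = op, len = len)
}

cigar_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I")])
cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N")])
cigar_clip_lead <- function(ops) {
  i <- which(!ops$op %in% c("S", "H"))
  if (length(i) == 0L) return(sum(ops$len))
  sum(ops$len[seq_len(i[1L] - 1L)])
}
cigar_clip_trail <- function(ops) {
  i <- which(!ops$op %in% c("S", "H"))
  if (length(i) == 0L) return(0L)
  n <- nrow(ops)
  j <- i[length(i)]
  if (j == n) 0L else sum(ops$len[(j + 1L):n])
}

#' Strand-aware query interval of one alignment record
#'
#' Computes which bases of the as-sequenced read an alignment record covers.
#' On the plus strand the interval starts after the leading clip; on the minus
#' strand the record's coordinates are in reference orientation and the
#' interval is reflected so that coordinates always refer to the read as it
#' came off the sequencer: `start' = L - end + 1`, `end' = L - start + 1`.
#'
#' @param ops Parsed (optionally smoothed) CIGAR operations.
#' @param strand `"+"` or `"-"`.
#' @param read_length Total read length in bases (clips included).
#' @return A named list with `query_start`, `query_end`, `mapped_len`
#'   (query bases consumed by M/I) and `ref_span` (reference bases consumed).
#' @examples
#' cigar_query_interval(parse_cigar("60S40M"), "+", 100L)
#' cigar_query_interval(parse_cigar("40M60S"), "-", 100L)
#' @export
cigar_query_interval <- function(ops, strand, read_length) {
  lead <- cigar_clip_lead(ops)
  qlen <- cigar_query_len(ops)
  trail <- cigar_clip_trail(ops)
  if (lead + qlen + trail != read_length) {
    abort(sprintf(
      "CIGAR consumes %d query bases but read_length is %d.",
      lead + qlen + trail, read_length
    ))
  }
  qs <- lead + 1L
  qe <- lead + qlen
  if (strand == "-") {
    tmp <- qs
    qs <- read_length - qe + 1L
    qe <- read_length - tmp + 1L
  }
  list(
    query_start = as.integer(qs), query_end = as.integer(qe),
    mapped_len = as.integer(qlen), ref_span = as.integer(cigar_ref_span(ops))
  )
}

# Vectorised core used by layout_segments(): one row per cigar string.
# Query quantities come from the smoothed operations; the reference span is
# always measured on the raw operations, because collapsing an indel into a
# single M cannot preserve both query and reference extent at once.
cigar_summaries <- function(cigars, max_indel = 1L) {
  uniq <- unique(cigars)
  raw <- map(uniq, parse_cigar)
  parsed <- map(raw, smooth_cigar, max_indel = max_indel)
  idx <- match(cigars, uniq)
  tibble(
    q_lead = map_int(parsed, cigar_clip_lead)[idx],
    q_trail = map_int(parsed, cigar_clip_trail)[idx],
    q_mapped = map_int(parsed, cigar_query_len)[idx],
    ref_span = map_int(raw, cigar_ref_span)[idx]
  )
}

#' Compute query intervals and order split segments along the read
#'
#' Takes the expanded alignment segments of split reads (see
#' [expand_alignments()]), computes each segment's strand-aware query interval
#' and reference interval from its CIGAR, and sorts the segments of each read
#' by query start (ties broken by chromosome, then reference start). Reads are
#' expected to be split (two or more segments) for the junction path, but the
#' function accepts any segment table.
#'
#' @param segments A tibble with at least `read_id`, `chrom`, `pos`, `strand`,
#'   `cigar`, `mapq`, `read_length` (one row per alignment segment).
#' @param max_smoothed_indel Indels up to this length are smoothed out of the
#'   CIGAR before interval computation (default 1).
#' @return The input tibble with added columns `query_start`, `query_end`,
#'   `mapped_len`, `ref_start`, `ref_end`, and a per-read `seg_rank`, sorted
#'   by `read_id` then query order.
#' @export
layout_segments <- function(segments, max_smoothed_indel = 1L) {
  if (nrow(segments) == 0L) {
    return(mutate(segments,
      query_start = integer(), query_end = integer(), mapped_len = integer(),
      ref_start = integer(), ref_end = integer(), seg_rank = integer()
    ))
  }
  cs <- cigar_summaries(segments$cigar, max_smoothed_indel)
  bad <- cs$q_lead + cs$q_mapped + cs$q_trail != segments$read_length
  if (any(bad)) {
    abort(sprintf(
      "CIGAR/read-length mismatch for read '%s' (cigar '%s', read_length %d).",
      segments$read_id[which(bad)[1]], segments$cigar[which(bad)[1]],
      segments$read_length[which(bad)[1]]
    ))
  }
  segments |>
    mutate(
      mapped_len = cs$q_mapped,
      ref_start = .data$pos,
      ref_end = .data$pos + cs$ref_span - 1L,
      query_start = if_else(.data$strand == "+", cs$q_lead + 1L,
                            .data$read_length - (cs$q_lead + cs$q_mapped) + 1L),
      query_end = .data$query_start + cs$q_mapped - 1L
    ) |>
    arrange(.data$read_id, .data$query_start, .data$chrom, .data$ref_start) |>
    group_by(.data$read_id) |>
    mutate(seg_rank = row_number()) |>
    ungroup()
}
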