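#' Query overlap and gap between two neighboring split segments
#'
#' Split alignments of the same read commonly share a few identical bases at
#' the junction (micro-homology from seed extension through canonical splice
#' sequences) or leave a few unaligned bases between them. Both are mutually
#' exclusive by construction: `overlap = max(0, left_end - right_start + 1)`,
#' `gap = max(0, right_start - left_end - 1)`.
#'
#' @param left_query_end,right_query_start Query coordinates (vectors) of the
#'   junction-adjacent segment ends.
#' @return A tibble with `overlap_len` and `gap_len`.
#' @examples
#' junction_overlap_gap(55L, 50L)  # 6-base overlap
#' junction_overlap_gap(50L, 54L)  # 3-base gap
#' @export
junction_overlap_gap <- function(left_query_end, right_query_start) {
  tibble(
    overlap_len = pmax(0L, left_query_end - right_query_start + 1L),
    gap_len = pmax(0L, right_query_start - left_query_end - 1L)
  )
}

# Junction-adjacent reference coordinates: the left segment contributes its
# query-3' terminus, the right segment its query-5' terminus. On a minus-strand
# record the query-3' terminus is the reference start.
bp_left_pos <- function(strand, ref_start, ref_end) {
  if_else(strand == "+", ref_end, ref_start)
}
bp_right_pos <- function(strand, ref_start, ref_end) {
  if_else(strand == "+", ref_start, ref_end)
}

# TRUE when two neighboring segments cannot be joined by ordinary splicing:
# different chromosomes, opposite strands (inversion), or more than
# max_intron_distance bases between the junction-adjacent coordinates.
is_partner_pair <- function(a, b, max_intron_distance) {
  if (a$chrom != b$chrom) return(TRUE)
  if (a$strand != b$strand) return(TRUE)
  bpa <- if (a$strand == "+") a$ref_end else a$ref_start
  bpb <- if (b$strand == "+") b$ref_start else b$ref_end
  abs(bpb - bpa) > max_intron_distance
}

empty_candidates <- function() {
  tibble(
    read_id = character(), umi = character(), ls_chrom = character(),
    ls_pos = integer(), ls_strand = character(), is_read1 = logical(),
    read_length = integer(), intragenic = logical(),
    left_chrom = character(), left_strand = character(), left_mapq = integer(),
    left_ref_start = integer(), left_ref_end = integer(),
    left_query_start = integer(), left_query_end = integer(),
    right_chrom = character(), right_strand = character(),
    right_mapq = integer(), right_ref_start = integer(),
    right_ref_end = integer(), right_query_start = integer(),
    right_query_end = integer(), bp_left_pos = integer(),
    bp_right_pos = integer(), overlap_len = integer(), gap_len = integer(),
    n_mid = integer(), mid = list()
  )
}

candidate_row <- function(left, right, mids, first_block_start, last_block_end,
                          intragenic) {
  og <- junction_overlap_gap(left$query_end, right$query_start)
  tibble(
    read_id = left$read_id, umi = left$umi,
    ls_chrom = left$ls_chrom, ls_pos = left$ls_pos, ls_strand = left$ls_strand,
    is_read1 = left$is_read1, read_length = left$read_length,
    intragenic = intragenic,
    left_chrom = left$chrom, left_strand = left$strand, left_mapq = left$mapq,
    left_ref_start = left$ref_start, left_ref_end = left$ref_end,
    left_query_start = first_block_start, left_query_end = left$query_end,
    right_chrom = right$chrom, right_strand = right$strand,
    right_mapq = right$mapq,
    right_ref_start = right$ref_start, right_ref_end = right$ref_end,
    right_query_start = right$query_start, right_query_end = last_block_end,
    bp_left_pos = bp_left_pos(left$strand, left$ref_start, left$ref_end),
    bp_right_pos = bp_right_pos(right$strand, right$ref_start, right$ref_end),
    overlap_len = og$overlap_len, gap_len = og$gap_len,
    n_mid = nrow(mids),
    mid = list(mids)
  )
}

#' Detect candidate fusion junctions in split-read layouts
#'
#' Walks the query-ordered segments of each read and partitions them into
#' blocks of consecutive segments joinable by ordinary splicing (same
#' chromosome, same strand, within `max_intron_distance` between the
#' junction-adjacent coordinates). Two or more blocks mean the read crosses at
#' least one fusion junction: the candidate is formed between the last segment
#' of the first block and the first segment of the last block ("leftmost query
#' start ... nearest end to junction" construct), and any segments between
#' those two go to the `mid` channel for downstream annotation. Breakpoints
#' are the strand-aware reference coordinates adjacent to the query split.
#'
#' With `keep_intragenic = TRUE` (Target mode) the within-block neighbor pairs
#' are additionally emitted as `intragenic` candidates, so whitelisted events
#' such as exon skipping — which the distance rule would otherwise absorb into
#' normal splicing — can be matched later.
#'
#' @param segments Laid-out segments from [layout_segments()].
#' @param max_intron_distance Distance rule threshold (default 750000;
#'   strictly greater-than).
#' @param keep_intragenic Also emit within-block neighbor pairs.
#' @return A tibble of junction candidates, one row per candidate, with block
#'   query spans, junction-adjacent reference intervals, raw breakpoint
#'   coordinates (`bp_left_pos`, `bp_right_pos`), `overlap_len`, `gap_len`,
#'   an `intragenic` flag and a `mid` list-column.
#' @export
detect_junction_candidates <- function(segments,
                                       max_intron_distance = 750000L,
                                       keep_intragenic = FALSE) {
  per_read <- function(sr) {
    n <- nrow(sr)
    out <- list()
    if (n >= 2L) {
      qualifies <- map_lgl(seq_len(n - 1L), function(i) {
        is_partner_pair(sr[i, ], sr[i + 1L, ], max_intron_distance)
      })
      if (any(qualifies)) {
        li <- which(qualifies)[1L]            # last segment of first block
        ri <- which(qualifies)[sum(qualifies)] + 1L  # first of last block
        mids <- if (ri - li > 1L) sr[(li + 1L):(ri - 1L), ] else sr[0, ]
        out <- c(out, list(candidate_row(
          sr[li, ], sr[ri, ], mids,
          first_block_start = sr$query_start[1L],
          last_block_end = sr$query_end[n],
          intragenic = FALSE
        )))
      }
      if (keep_intragenic) {
        for (i in which(!qualifies)) {
          out <- c(out, list(candidate_row(
            sr[i, ], sr[i + 1L, ], sr[0, ],
            first_block_start = sr$query_start[i],
            last_block_end = sr$query_end[i + 1L],
            intragenic = TRUE
          )))
        }
      }
    }
    bind_rows(out)
  }
  if (nrow(segments) == 0L) return(empty_candidates())
  out <- segments |>
    group_by(.data$read_id) |>
    group_split() |>
    map(per_read) |>
    bind_rows()
  if (nrow(out) == 0L) empty_candidates() else out
}

#' Assign ligation-end and anchored-end roles to a candidate's sides
#'
#' In AMP libraries the two sides of a split read play different roles: the
#' ligation end (adaptor-proximal, where the UMI and ligation site live)
#' starts at query position 1 of read 1, while the anchored end
#' (primer-proximal) holds the read's final base. Read-2 records see the
#' fragment from the other end, so their roles are swapped. In `plain` mode
#' (ordinary RNA-seq) both sides are symmetric and a single length cutoff
#' applies.
#'
#' @param cands Candidates from [detect_junction_candidates()].
#' @param mode `"anchored"` or `"plain"`.
#' @return `cands` with columns `end_mode`, `ligation_side` (`"left"`,
#'   `"right"` or `"symmetric"`), `ligation_len`, `anchored_len`, and the
#'   per-side spans `left_len`, `right_len`.
#' @export
assign_end_roles <- function(cands, mode = c("anchored", "plain")) {
  mode <- match.arg(mode)
  cands <- cands |>
    mutate(
      left_len = .data$left_query_end - .data$left_query_start + 1L,
      right_len = .data$right_query_end - .data$right_query_start + 1L,
      end_mode = mode
    )
  if (mode == "plain") {
    return(mutate(cands,
      ligation_side = "symmetric",
      ligation_len = pmin(.data$left_len, .data$right_len),
      anchored_len = pmin(.data$left_len, .data$right_len)
    ))
  }
  mutate(cands,
    ligation_side = if_else(.data$is_read1, "left", "right"),
    ligation_len = if_else(.data$ligation_side == "left",
                           .data$left_len, .data$right_len),
    anchored_len = if_else(.data$ligation_side == "left",
                           .data$right_len, .data$left_len)
  )
}

#' Initial candidate filtering by overlap, gap and end lengths
#'
#' Applies the first-pass junction filters: query overlap at most
#' `max_overlap`, query gap at most `max_gap`, ligation-end mapped span at
#' least `min_map_len_ligation` (default 25), anchored-end span at least
#' `min_map_len_anchored` (default 18; in symmetric mode this single cutoff
#' applies to both sides), and each side's exclusive (non-overlapping) span at
#' least `min_exclusive_len`. Survivors receive a `junction_key` that groups
#' reads supporting the same exact breakpoint pair.
#'
#' @param cands Candidates with end roles from [assign_end_roles()].
#' @param config A [fusion_config()].
#' @return The surviving candidates with an added `junction_key` column.
#' @export
filter_junction_candidates <- function(cands, config = fusion_config()) {
  out <- cands |>
    filter(
      .data$overlap_len <= config$max_overlap,
      .data$gap_len <= config$max_gap,
      if (config$end_mode == "plain" || all(cands$ligation_side == "symmetric"))
        .data$left_len >= config$min_map_len_anchored &
          .data$right_len >= config$min_map_len_anchored
      else
        .data$ligation_len >= config$min_map_len_ligation &
          .data$anchored_len >= config$min_map_len_anchored,
      .data$left_len - .data$overlap_len >= config$min_exclusive_len,
      .data$right_len - .data$overlap_len >= config$min_exclusive_len
    )
  mutate(out, junction_key = paste0(
    .data$left_chrom, ":", .data$bp_left_pos, ":", .data$left_strand, "|",
    .data$right_chrom, ":", .data$bp_right_pos, ":", .data$right_strand
  ))
}
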