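#' Annotate junction breakpoints with gene, exon and cDNA position
#'
#' Split alignments commonly extend a few bases past the true junction through
#' shared (micro-homologous) sequence, so a breakpoint coordinate can sit just
#' inside the partner gene's intron. Gene and exon lookup therefore shifts the
#' coordinate `shift` bases inward, toward the centre of the breakpoint's own
#' alignment (for the left side of the read that is upstream along the read;
#' for the right side downstream), and annotates at the shifted position. The
#' reported coordinate stays unshifted, and the cDNA position is computed at
#' the unshifted coordinate on the gene's canonical transcript (`NA` when that
#' coordinate is intronic or intergenic).
#'
#' @param bps A tibble with columns `chrom`, `pos`, `strand` (segment strand)
#'   and `side` (`"left"` or `"right"`: which end of the read the segment is).
#' @param models A transcript-model tibble (see [read_refflat()]).
#' @param shift Inward shift in bases (default 6).
#' @return `bps` with added columns `lookup_pos`, `gene`, `gene_strand`,
#'   `transcript_id`, `region` (`exon`/`intron`/`intergenic`), `exon_number`,
#'   `cdna_pos`.
#' @export
annotate_breakpoints <- function(bps, models, shift = 6L) {
  canon <- filter(models, .data$canonical)
  ann <- pmap(
    list(bps$chrom, bps$pos, bps$strand, bps$side),
    function(chrom, pos, strand, side) {
      inward <- if (side == "left") {
        if (strand == "+") -shift else shift
      } else {
        if (strand == "+") shift else -shift
      }
      lookup <- pos + inward
      hits <- canon[canon$chrom == chrom &
                      canon$tx_start <= lookup & lookup <= canon$tx_end, ]
      if (nrow(hits) == 0L) {
        return(tibble(
          lookup_pos = lookup, gene = NA_character_,
          gene_strand = NA_character_, transcript_id = NA_character_,
          region = "intergenic", exon_number = NA_integer_,
          cdna_pos = NA_integer_
        ))
      }
      if (nrow(hits) > 1L) {
        exonic <- map_lgl(seq_len(nrow(hits)), function(i) {
          any(hits$exon_starts[[i]] <= lookup & lookup <= hits$exon_ends[[i]])
        })
        hits <- if (any(exonic)) hits[exonic, ] else hits
        hits <- hits[order(hits$gene), ][1, ]
      }
      en <- tx_exon_number(hits$strand, hits$exon_starts[[1]],
                           hits$exon_ends[[1]], lookup)
      tibble(
        lookup_pos = lookup,
        gene = hits$gene,
        gene_strand = hits$strand,
        transcript_id = hits$transcript_id,
        region = en$region,
        exon_number = en$number,
        cdna_pos = tx_cdna_pos(hits$strand, hits$exon_starts[[1]],
                               hits$exon_ends[[1]], pos)
      )
    }
  )
  bind_cols(bps, bind_rows(ann))
}

#' Is a breakpoint on a known exon boundary?
#'
#' A 5'-side (donor) junction is on a boundary when its coordinate equals the
#' transcribed-strand 3' terminus of an exon of any transcript of its gene; a
#' 3'-side (acceptor) junction when it equals an exon 5' terminus. Comparison
#' is exact by default (`tolerance = 0`), after junction micro-homology has
#' been assigned to the 5' side.
#'
#' @param pos Genomic coordinate(s) of the breakpoint.
#' @param gene Gene symbol(s) (as annotated); `NA` yields `FALSE`.
#' @param role `"donor"` (5' side) or `"acceptor"` (3' side).
#' @param models A transcript-model tibble.
#' @param tolerance Allowed distance from an exon terminus in bases.
#' @return Logical vector.
#' @export
judge_exon_boundary <- function(pos, gene, role = c("donor", "acceptor"),
                                models, tolerance = 0L) {
  role <- match.arg(role)
  map2_lgl(pos, gene, function(p, g) {
    if (is.na(g) || is.na(p)) return(FALSE)
    term <- gene_exon_termini(models, g, role)
    length(term) > 0L && min(abs(term - p)) <= tolerance
  })
}

frame_for_pair <- function(row5, pos5, row3, pos3) {
  b5 <- tx_cds_bounds(row5)
  b3 <- tx_cds_bounds(row3)
  if (is.null(b5) || is.null(b3)) return(NA)
  cdna5 <- tx_cdna_pos(row5$strand, row5$exon_starts[[1]], row5$exon_ends[[1]], pos5)
  cdna3 <- tx_cdna_pos(row3$strand, row3$exon_starts[[1]], row3$exon_ends[[1]], pos3)
  if (is.na(cdna5) || is.na(cdna3)) return(NA)
  if (cdna5 < b5[1] || cdna5 > b5[2]) return(NA)
  if (cdna3 < b3[1] || cdna3 > b3[2]) return(NA)
  c5 <- cdna5 - b5[1] + 1L  # coding bases retained through the junction base
  c3 <- cdna3 - b3[1]       # coding bases lost before the first retained base
  (c5 %% 3L) == (c3 %% 3L)
}

#' Infer the reading-frame status of a fusion junction
#'
#' Counts coding bases on each side of the junction: `c5`, from the 5'
#' partner's CDS start through the last retained base, and `c3`, from the 3'
#' partner's CDS start up to (excluding) the first retained base. The fusion
#' is in frame when `c5 mod 3 == c3 mod 3`. The status is `NA` whenever either
#' junction-adjacent base lies outside its transcript's CDS — intronic
#' coordinates, 5'/3' UTRs, and non-coding partners. Frame is evaluated on
#' canonical transcripts; if the canonical call is `NA` but some other isoform
#' pair yields in-frame, that isoform call is reported and flagged
#' (`frame_isoform = TRUE`).
#'
#' @param gene5,pos5 Gene symbol and genomic junction coordinate of the 5'
#'   (donor) side.
#' @param gene3,pos3 Likewise for the 3' (acceptor) side.
#' @param models A transcript-model tibble.
#' @param isoform_fallback Try non-canonical isoform pairs when the canonical
#'   call is `NA`.
#' @return A one-row tibble: `frame_status` (`"in-frame"`, `"out-of-frame"`,
#'   `"NA"`) and `frame_isoform` (logical).
#' @export
infer_frame <- function(gene5, pos5, gene3, pos3, models,
                        isoform_fallback = TRUE) {
  na_out <- tibble(frame_status = "NA", frame_isoform = FALSE)
  if (is.na(gene5) || is.na(gene3)) return(na_out)
  t5 <- models[models$gene == gene5, ]
  t3 <- models[models$gene == gene3, ]
  if (nrow(t5) == 0L || nrow(t3) == 0L) return(na_out)
  c5 <- t5[t5$canonical, ][1, ]
  c3 <- t3[t3$canonical, ][1, ]
  fr <- frame_for_pair(c5, pos5, c3, pos3)
  if (!is.na(fr)) {
    return(tibble(frame_status = if (fr) "in-frame" else "out-of-frame",
                  frame_isoform = FALSE))
  }
  if (isoform_fallback && (nrow(t5) > 1L || nrow(t3) > 1L)) {
    for (i in seq_len(nrow(t5))) {
      for (j in seq_len(nrow(t3))) {
        if (t5$canonical[i] && t3$canonical[j]) next
        fr2 <- frame_for_pair(t5[i, ], pos5, t3[j, ], pos3)
        if (isTRUE(fr2)) {
          return(tibble(frame_status = "in-frame", frame_isoform = TRUE))
        }
      }
    }
  }
  na_out
}

# Inward adjustment of the acceptor-side breakpoint past the query overlap:
# shared junction bases are attributed to the 5' side, so the 3' breakpoint
# retreats `overlap` bases into its own segment.
adjust_acceptor_bp <- function(pos, side, strand, overlap) {
  if (overlap == 0L) return(pos)
  inward <- if (side == "right") {
    if (strand == "+") overlap else -overlap
  } else {
    if (strand == "+") -overlap else overlap
  }
  pos + inward
}

#' Aggregate filtered candidates into annotated fusion calls
#'
#' Groups surviving candidates by exact breakpoint pair, orients each junction
#' (the 5' partner is the side whose segment strand matches its gene strand,
#' so antisense reads are flipped), assigns query-overlap bases to the 5' side
#' and retreats the 3' breakpoint accordingly, annotates both breakpoints,
#' judges exon-boundary status, infers frame status, and applies the
#' partner-end calling thresholds: 1 partner end when both junctions are on
#' exon boundaries, 3 when one is, and rejection when none is (unless the
#' junction matches a whitelisted target event; see [match_target_events()]).
#'
#' Supporting evidence per call: `n_umi_reads` is the number of distinct UMIs
#' (UMI-less reads each count once) and `n_partner_ends` the number of
#' distinct adjusted ligation sites.
#'
#' @param cands Filtered candidates from [filter_junction_candidates()].
#' @param models A transcript-model tibble.
#' @param config A [fusion_config()].
#' @param targets Optional target-event tibble from [read_target_events()];
#'   whitelisted junctions bypass the boundary thresholds.
#' @param keep_rejected Keep rejected junctions in the result (flagged by
#'   `called = FALSE`) — useful for diagnostics.
#' @return A tibble of annotated calls, one row per exact junction, sorted by
#'   `fusion_name` then descending `n_umi_reads`.
#' @export
call_fusions <- function(cands, models, config = fusion_config(),
                         targets = NULL, keep_rejected = FALSE) {
  empty <- tibble(
    junction_key = character(), fusion_name = character(),
    gene5 = character(), gene3 = character(), junction = character(),
    chrom5 = character(), pos5 = integer(), chrom3 = character(),
    pos3 = integer(), n_umi_reads = integer(), n_partner_ends = integer(),
    frame_status = character(), frame_isoform = logical(),
    boundary_status = character(), on_boundary5 = logical(),
    on_boundary3 = logical(), transcript5 = character(),
    exon5 = integer(), region5 = character(), cdna5 = integer(),
    transcript3 = character(), exon3 = integer(), region3 = character(),
    cdna3 = integer(), overlap_len = integer(), intragenic = logical(),
    targeted_event = character(), called = logical(), n_reads = integer(),
    read_ids = list(), mid_annotations = list()
  )
  if (nrow(cands) == 0L) return(empty)

  grouped <- cands |>
    group_by(.data$junction_key) |>
    summarise(
      n_reads = n(),
      n_umi_reads = n_distinct(if_else(.data$umi == "",
                                       paste0("read:", .data$read_id),
                                       .data$umi)),
      n_partner_ends = n_distinct(paste0(.data$ls_chrom, ":", .data$ls_pos)),
      read_ids = list(sort(unique(.data$read_id))),
      overlap_len = max(.data$overlap_len),
      intragenic = any(.data$intragenic),
      left_chrom = first(.data$left_chrom), left_strand = first(.data$left_strand),
      right_chrom = first(.data$right_chrom), right_strand = first(.data$right_strand),
      bp_left = first(.data$bp_left_pos), bp_right = first(.data$bp_right_pos),
      mid = list(bind_rows(.data$mid)),
      .groups = "drop"
    )

  rows <- map(seq_len(nrow(grouped)), function(i) {
    g <- grouped[i, ]
    raw <- tibble(
      chrom = c(g$left_chrom, g$right_chrom),
      pos = c(g$bp_left, g$bp_right),
      strand = c(g$left_strand, g$right_strand),
      side = c("left", "right")
    )
    pre <- annotate_breakpoints(raw, models, shift = config$annotation_shift)
    left_is_5p <- if (!is.na(pre$gene[1])) {
      pre$strand[1] == pre$gene_strand[1]
    } else if (!is.na(pre$gene[2])) {
      pre$strand[2] == pre$gene_strand[2]
    } else TRUE
    i5 <- if (left_is_5p) 1L else 2L
    i3 <- 3L - i5
    bp3_pos <- adjust_acceptor_bp(pre$pos[i3], pre$side[i3], pre$strand[i3],
                                  g$overlap_len)
    ann <- annotate_breakpoints(
      tibble(
        chrom = c(pre$chrom[i5], pre$chrom[i3]),
        pos = c(pre$pos[i5], bp3_pos),
        strand = c(pre$strand[i5], pre$strand[i3]),
        side = c(pre$side[i5], pre$side[i3])
      ),
      models, shift = config$annotation_shift
    )
    ob5 <- judge_exon_boundary(ann$pos[1], ann$gene[1], "donor", models,
                               config$boundary_tolerance)
    ob3 <- judge_exon_boundary(ann$pos[2], ann$gene[2], "acceptor", models,
                               config$boundary_tolerance)
    fr <- infer_frame(ann$gene[1], ann$pos[1], ann$gene[2], ann$pos[2], models)
    mids <- g$mid[[1]]
    mid_ann <- if (!is.null(mids) && nrow(mids) > 0L) {
      annotate_breakpoints(
        tibble(chrom = mids$chrom,
               pos = as.integer(round((mids$ref_start + mids$ref_end) / 2)),
               strand = mids$strand, side = "left"),
        models, shift = 0L
      )
    } else tibble()
    tibble(
      junction_key = g$junction_key,
      gene5 = ann$gene[1], gene3 = ann$gene[2],
      fusion_name = paste0(ann$gene[1] %|na|% "NA", "::",
                           ann$gene[2] %|na|% "NA"),
      chrom5 = ann$chrom[1], pos5 = ann$pos[1],
      chrom3 = ann$chrom[2], pos3 = ann$pos[2],
      junction = paste0(ann$chrom[1], ":", ann$pos[1], "_",
                        ann$chrom[2], ":", ann$pos[2]),
      n_umi_reads = g$n_umi_reads, n_partner_ends = g$n_partner_ends,
      frame_status = fr$frame_status, frame_isoform = fr$frame_isoform,
      on_boundary5 = ob5, on_boundary3 = ob3,
      boundary_status = c("none", "one", "both")[1L + ob5 + ob3],
      transcript5 = ann$transcript_id[1], exon5 = ann$exon_number[1],
      region5 = ann$region[1], cdna5 = ann$cdna_pos[1],
      transcript3 = ann$transcript_id[2], exon3 = ann$exon_number[2],
      region3 = ann$region[2], cdna3 = ann$cdna_pos[2],
      overlap_len = g$overlap_len, intragenic = g$intragenic,
      n_reads = g$n_reads, read_ids = g$read_ids,
      mid_annotations = list(mid_ann)
    )
  })
  calls <- bind_rows(rows)

  calls$targeted_event <- NA_character_
  if (!is.null(targets) && nrow(targets) > 0L) {
    calls <- match_target_events(calls, targets, models,
                                 window = config$target_window)
  }
  calls <- calls |>
    mutate(called = case_when(
      !is.na(.data$targeted_event) ~ TRUE,
      .data$intragenic ~ FALSE,
      .data$boundary_status == "both" &
        .data$n_partner_ends >= config$min_partner_ends_both ~ TRUE,
      .data$boundary_status == "one" &
        .data$n_partner_ends >= config$min_partner_ends_one ~ TRUE,
      TRUE ~ FALSE
    ))
  out <- if (keep_rejected) calls else filter(calls, .data$called)
  out |>
    arrange(.data$fusion_name, desc(.data$n_umi_reads), .data$junction) |>
    select(any_of(names(empty)))
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x
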