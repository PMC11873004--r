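#' Fusion-calling run configuration
#'
#' Collects every tunable of the calling pipeline with its default. Defaults
#' reflect anchored multiplex PCR (AMP) short-read data: candidate junctions
#' require partner alignments on different chromosomes or more than 750,000
#' bases apart (the largest plausible intron), the ligation-end alignment must
#' map at least 25 bases and the anchored end at least 18, candidate split
#' pairs may overlap on the query by at most 6 bases (canonical splice-site
#' micro-homology) or gap by at most 5, each side must contribute at least 15
#' exclusive bases, gene/exon lookup shifts 6 bases inward from the junction,
#' and a fusion is called from 1 partner end when both junctions sit on known
#' exon boundaries or 3 partner ends when only one does.
#'
#' @param max_intron_distance Same-chromosome distance (bases) above which a
#'   neighboring split pair is a fusion candidate.
#' @param min_map_len_ligation Minimum mapped length of the ligation-end side.
#' @param min_map_len_anchored Minimum mapped length of the anchored-end side;
#'   also the single cutoff applied to both sides in `plain` (symmetric) mode.
#' @param max_overlap Maximum query overlap between the split pair.
#' @param max_gap Maximum query gap between the split pair.
#' @param min_exclusive_len Minimum non-overlapping mapped length per side.
#' @param annotation_shift Bases to shift the junction inward along its own
#'   alignment before gene/exon lookup.
#' @param min_partner_ends_both Partner ends required when both junctions are
#'   on exon boundaries (`minPartnerEnds_BothExonJunction`).
#' @param min_partner_ends_one Partner ends required when exactly one junction
#'   is on an exon boundary (`minPartnerEnds_OneExonJunction`).
#' @param boundary_tolerance Bases of slack when matching exon termini
#'   (default 0: exact).
#' @param n_extract_reads Supporting reads to sample per call.
#' @param dedup Deduplication mode: `"umi_ls"`, `"ls"`, or `"off"`.
#' @param end_mode `"anchored"` (AMP geometry, asymmetric cutoffs) or
#'   `"plain"` (symmetric RNA-seq reads).
#' @param umi_regex UMI dialect for [parse_read_meta()].
#' @param ligation_end Which mate carries the ligation end.
#' @param max_smoothed_indel CIGAR indels up to this length are smoothed.
#' @param target_window Coordinate slack (bases) for coordinate-pattern
#'   whitelist events.
#' @param seed Run seed (supporting-read sampling).
#' @return A named list of class `fusion_config`.
#' @export
fusion_config <- function(max_intron_distance = 750000L,
                          min_map_len_ligation = 25L,
                          min_map_len_anchored = 18L,
                          max_overlap = 6L,
                          max_gap = 5L,
                          min_exclusive_len = 15L,
                          annotation_shift = 6L,
                          min_partner_ends_both = 1L,
                          min_partner_ends_one = 3L,
                          boundary_tolerance = 0L,
                          n_extract_reads = 10L,
                          dedup = c("umi_ls", "ls", "off"),
                          end_mode = c("anchored", "plain"),
                          umi_regex = "(?:_|:)UMI[:_]?([ACGTN]+)$",
                          ligation_end = c("read1_start", "read2_start"),
                          max_smoothed_indel = 1L,
                          target_window = 5L,
                          seed = 1L) {
  cfg <- list(
    max_intron_distance = as.integer(max_intron_distance),
    min_map_len_ligation = as.integer(min_map_len_ligation),
    min_map_len_anchored = as.integer(min_map_len_anchored),
    max_overlap = as.integer(max_overlap),
    max_gap = as.integer(max_gap),
    min_exclusive_len = as.integer(min_exclusive_len),
    annotation_shift = as.integer(annotation_shift),
    min_partner_ends_both = as.integer(min_partner_ends_both),
    min_partner_ends_one = as.integer(min_partner_ends_one),
    boundary_tolerance = as.integer(boundary_tolerance),
    n_extract_reads = as.integer(n_extract_reads),
    dedup = match.arg(dedup),
    end_mode = match.arg(end_mode),
    umi_regex = umi_regex,
    ligation_end = match.arg(ligation_end),
    max_smoothed_indel = as.integer(max_smoothed_indel),
    target_window = as.integer(target_window),
    seed = as.integer(seed)
  )
  stopifnot(cfg$max_intron_distance >= 1L)
  lens <- c(
    cfg$min_map_len_ligation, cfg$min_map_len_anchored, cfg$max_overlap,
    cfg$max_gap, cfg$min_exclusive_len, cfg$annotation_shift,
    cfg$min_partner_ends_both, cfg$min_partner_ends_one,
    cfg$boundary_tolerance, cfg$n_extract_reads
  )
  stopifnot(all(lens >= 0L))
  structure(cfg, class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, as.character(x[[nm]])))
  invisible(x)
}
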