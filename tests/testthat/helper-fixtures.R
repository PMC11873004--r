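# Shared fixture builders for the test suite. Everything is seeded and
# deterministic; datasets are built in tempdirs and cached per session.

basic_scenario <- function(...) {
  fusion_scenario(
    gene5 = gene_spec("GENEA"),
    gene3 = gene_spec("GENEB"),
    junctions = junction_spec(),
    ...
  )
}

basic_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sim_fusion_dataset(basic_scenario(), seed = 1L,
                                   dir = file.path(tempdir(), "fx_basic"))
    }
    cache
  }
})

# A minimal hand-written transcript model: one plus-strand gene with three
# 100-base exons at 101-200, 401-500, 701-800, CDS 151-750 (cDNA 51-250).
hand_model <- function() {
  finish_models(tibble::tibble(
    gene = "HG1", transcript_id = "HG1.t1", chrom = "chr1", strand = "+",
    tx_start = 101L, tx_end = 800L, cds_start = 151L, cds_end = 750L,
    exon_starts = list(c(101L, 401L, 701L)),
    exon_ends = list(c(200L, 500L, 800L))
  ))
}

# A synthetic laid-out segment pair for junction-rule unit tests.
segment_pair <- function(chrom2 = "chr2", pos2 = 5000L, strand2 = "+",
                         q1 = c(1L, 50L), q2 = c(51L, 100L),
                         chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
                         is_read1 = TRUE, read_id = "r1", umi = "ACGTACGT") {
  len1 <- q1[2] - q1[1] + 1L
  len2 <- q2[2] - q2[1] + 1L
  segs <- tibble::tibble(
    read_id = read_id, umi = umi, ls_chrom = chrom1, ls_pos = pos1,
    ls_strand = strand1, is_read1 = is_read1, read_length = 100L,
    chrom = c(chrom1, chrom2), pos = c(pos1, pos2),
    strand = c(strand1, strand2),
    cigar = c(
      paste0(if (q1[1] > 1L) paste0(q1[1] - 1L, "S") else "", len1, "M",
             paste0(100L - q1[2], "S")),
      paste0(q2[1] - 1L, "S", len2, "M",
             if (q2[2] < 100L) paste0(100L - q2[2], "S") else "")
    ),
    mapq = 60L, is_primary = c(TRUE, FALSE), xa = NA_character_
  )
  layout_segments(segs)
}
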