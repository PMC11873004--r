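test_that("same-chromosome distance rule is strictly greater than 750 kb", {
  # left segment ends at ref 1049; right segment starts `d` bases downstream
  mk <- function(d) segment_pair(chrom2 = "chr1", pos2 = 1049L + d)
  expect_equal(nrow(detect_junction_candidates(mk(750000L))), 0L)
  cand <- detect_junction_candidates(mk(750001L))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$bp_left_pos, 1049L)
  expect_equal(cand$bp_right_pos, 1049L + 750001L)
})

test_that("different chromosomes and opposite strands always qualify", {
  expect_equal(nrow(detect_junction_candidates(
    segment_pair(chrom2 = "chr9", pos2 = 1100L))), 1L)
  # inversion: same chromosome, nearby, opposite strand
  segs <- segment_pair(chrom2 = "chr1", pos2 = 1100L)
  segs$strand[2] <- "-"
  segs$cigar[2] <- "50M50S"  # minus-strand query interval reflects to 51..100
  segs <- layout_segments(segs)
  cand <- detect_junction_candidates(segs)
  expect_equal(nrow(cand), 1L)
  # query-3'/5' termini: minus-strand right segment contributes its ref end
  expect_equal(cand$bp_right_pos, segs$ref_end[segs$strand == "-"])
})

test_that("three-segment reads form one candidate with a mid segment", {
  # A (chr1) - B (chr5) - C (chr9): candidate joins A and C, B goes to mid
  segs <- tibble::tibble(
    read_id = "r1", umi = "ACGT", ls_chrom = "chr1", ls_pos = 1000L,
    ls_strand = "+", is_read1 = TRUE, read_length = 99L,
    chrom = c("chr1", "chr5", "chr9"),
    pos = c(1000L, 5000L, 9000L), strand = "+",
    cigar = c("33M66S", "33S33M33S", "66S33M"),
    mapq = 60L, is_primary = c(TRUE, FALSE, FALSE), xa = NA_character_
  )
  cand <- detect_junction_candidates(layout_segments(segs))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$left_chrom, "chr1")
  expect_equal(cand$right_chrom, "chr9")
  expect_equal(cand$n_mid, 1L)
  expect_equal(cand$mid[[1]]$chrom, "chr5")
})

test_that("query overlap and gap are computed and bounded", {
  og <- junction_overlap_gap(c(55L, 50L, 50L), c(50L, 54L, 51L))
  expect_equal(og$overlap_len, c(6L, 0L, 0L))
  expect_equal(og$gap_len, c(0L, 3L, 0L))
  # overlap 7 > max 6 is filtered; overlap 6 survives
  mk_ov <- function(q2_start) {
    segs <- segment_pair(q2 = c(q2_start, 100L))
    assign_end_roles(detect_junction_candidates(segs), "anchored")
  }
  expect_equal(nrow(filter_junction_candidates(mk_ov(44L))), 0L)
  expect_equal(nrow(filter_junction_candidates(mk_ov(45L))), 1L)
})

test_that("end-length cutoffs: ligation >= 25, anchored >= 18", {
  mk_len <- function(split_at) {
    segs <- segment_pair(q1 = c(1L, split_at), q2 = c(split_at + 1L, 100L))
    assign_end_roles(detect_junction_candidates(segs), "anchored")
  }
  # read 1: ligation end is the left side
  expect_equal(nrow(filter_junction_candidates(mk_len(24L))), 0L)
  expect_equal(nrow(filter_junction_candidates(mk_len(25L))), 1L)
  # anchored end is the right side
  expect_equal(nrow(filter_junction_candidates(mk_len(100L - 17L))), 0L)
  expect_equal(nrow(filter_junction_candidates(mk_len(100L - 18L))), 1L)
})

test_that("read-2 records swap ligation and anchored roles", {
  segs <- segment_pair(q1 = c(1L, 24L), q2 = c(25L, 100L), is_read1 = FALSE)
  cand <- assign_end_roles(detect_junction_candidates(segs), "anchored")
  expect_equal(cand$ligation_side, "right")
  expect_equal(cand$ligation_len, 76L)
  expect_equal(cand$anchored_len, 24L)
  # 24 >= 18 anchored and 76 >= 25 ligation: survives where read 1 would not
  expect_equal(nrow(filter_junction_candidates(cand)), 1L)
})

test_that("plain mode applies the anchored cutoff to both sides", {
  segs <- segment_pair(q1 = c(1L, 17L), q2 = c(18L, 100L))
  cand <- assign_end_roles(detect_junction_candidates(segs), "plain")
  expect_equal(unique(cand$ligation_side), "symmetric")
  expect_equal(nrow(filter_junction_candidates(
    cand, fusion_config(end_mode = "plain", min_exclusive_len = 10L))), 0L)
  segs <- segment_pair(q1 = c(1L, 18L), q2 = c(19L, 100L))
  cand <- assign_end_roles(detect_junction_candidates(segs), "plain")
  expect_equal(nrow(filter_junction_candidates(
    cand, fusion_config(end_mode = "plain", min_exclusive_len = 10L))), 1L)
})
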