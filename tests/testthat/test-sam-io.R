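test_that("parse_read_meta extracts UMIs and strips them from the id", {
  meta <- parse_read_meta(c("R0001_UMI:ACGTACGT", "R0002", "x:UMI:TTTT"))
  expect_equal(meta$read_id, c("R0001", "R0002", "x"))
  expect_equal(meta$umi, c("ACGTACGT", "", "TTTT"))
})

test_that("ligation sites are soft-clip adjusted per strand", {
  recs <- tibble::tibble(
    read_id = c("p", "m"), umi = "", strand = c("+", "-"), chrom = "chr1",
    pos = 1000L, mapq = 60L, cigar = c("5S50M45S", "40M10S"),
    read_length = c(100L, 50L)
  )
  ls <- compute_ligation_sites(recs)
  # plus: pos - leading clip; minus: ref_end + trailing clip
  expect_equal(ls$ls_pos, c(995L, 1049L))
  # clamped at 1
  recs$pos <- c(3L, 1000L)
  expect_equal(compute_ligation_sites(recs)$ls_pos[1], 1L)
})

test_that("dedup collapses UMI + ligation-site duplicates deterministically", {
  recs <- tibble::tibble(
    read_id = c("a", "b", "c", "d", "e"),
    umi = c("AAAA", "AAAA", "AAAA", "", ""),
    strand = "+", chrom = "chr1",
    pos = c(100L, 100L, 200L, 100L, 100L),
    mapq = c(10L, 60L, 60L, 60L, 60L),
    cigar = "50M", read_length = 50L
  )
  recs <- compute_ligation_sites(recs)
  out <- dedup_reads(recs)
  # a+b share UMI@LS (b wins on MAPQ); c differs by LS; d, e have no UMI
  expect_equal(sort(out$read_id), c("b", "c", "d", "e"))
  expect_equal(out$n_dup[out$read_id == "b"], 2L)
  # idempotence
  expect_equal(dedup_reads(out)$read_id, out$read_id)
  # off mode keeps everything
  expect_equal(nrow(dedup_reads(recs, "off")), 5L)
  # ls mode collapses on position alone
  expect_equal(sort(dedup_reads(recs, "ls")$read_id), c("b", "c"))
})

test_that("dedup output size equals the number of distinct keys (property)", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    recs <- tibble::tibble(
      read_id = sprintf("r%03d", seq_len(n)),
      umi = sample(c("", "AAAA", "CCCC", "GGGG"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      chrom = "chr1",
      pos = sample(c(100L, 200L, 300L), n, replace = TRUE),
      mapq = sample(0:60, n, replace = TRUE),
      cigar = "50M", read_length = 50L
    )
    recs <- compute_ligation_sites(recs)
    out <- dedup_reads(recs)
    ls_key <- paste(recs$ls_chrom, recs$ls_pos, recs$ls_strand)
    key <- ifelse(recs$umi == "", paste0("read:", recs$read_id),
                  paste(recs$umi, ls_key))
    expect_equal(nrow(out), length(unique(key)))
    expect_equal(sum(out$n_dup), n)
  }
})

test_that("read_split_sam keeps primaries and parses tags", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1_UMI:ACGT", 0, "chr1", 100, 60, "50M50S", "*", 0, 0,
          strrep("A", 100), strrep("I", 100),
          "SA:Z:chr2,500,+,50H50M,60,0;", sep = "\t"),
    paste("r1_UMI:ACGT", 2048, "chr2", 500, 60, "50H50M", "*", 0, 0,
          strrep("A", 50), strrep("I", 50), sep = "\t"),
    paste("r2", 16, "chr1", 200, 0, "100M", "*", 0, 0,
          strrep("C", 100), strrep("I", 100),
          "XA:Z:chr9,+800,100M,0;", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t")
  )
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  recs <- read_split_sam(path)
  # supplementary and unmapped lines are dropped
  expect_equal(recs$read_id, c("r1", "r2"))
  expect_equal(recs$umi, c("ACGT", ""))
  expect_equal(recs$strand, c("+", "-"))
  expect_equal(recs$sa[1], "chr2,500,+,50H50M,60,0;")
  expect_equal(recs$xa[2], "chr9,+800,100M,0;")
  expect_equal(recs$read_length, c(100L, 100L))

  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\t0\tchr1\t100", bad)
  expect_error(read_split_sam(bad), "standard fields")
})

test_that("expand_alignments yields one segment per alignment", {
  ds <- basic_dataset()
  recs <- read_split_sam(ds$paths$sam)
  recs <- compute_ligation_sites(recs)
  segs <- expand_alignments(recs)
  # every read in the basic fixture splits into exactly two alignments
  expect_equal(nrow(segs), 2L * nrow(recs))
  expect_true(all(table(segs$read_id) == 2L))
  # malformed SA entries skip the record with a warning
  recs$sa[1] <- "chr2,500,+;"
  expect_warning(segs2 <- expand_alignments(recs), "malformed SA")
  expect_equal(nrow(segs2), 2L * (nrow(recs) - 1L))
})
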