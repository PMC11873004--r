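test_that("pseudogene rescue only touches MAPQ-0 segments in regions", {
  regions <- tibble::tibble(chrom = "chrR", start = 1000L, end = 2000L,
                            label = "rep")
  segs <- tibble::tibble(
    read_id = c("keep_hi", "self", "via_xa", "no_hit"),
    umi = "", ls_chrom = "chr1", ls_pos = 1L, ls_strand = "+",
    is_read1 = TRUE, read_length = 100L,
    chrom = c("chrR", "chrR", "chrD", "chrD"),
    pos = c(1100L, 1100L, 50L, 50L),
    strand = "+", cigar = "50M50S",
    mapq = c(60L, 0L, 0L, 0L),
    is_primary = TRUE,
    xa = c(NA, NA, "chrZ,+5,50M50S,0;chrR,+1500,50M50S,1;", "chrZ,+5,50M50S,0;")
  )
  out <- remap_pseudogene_segments(segs, regions)
  # mapq > 0: untouched even inside the region
  expect_false(out$remapped[1])
  # mapq 0 and already overlapping: flagged, coordinates kept
  expect_true(out$remapped[2])
  expect_equal(out$pos[2], 1100L)
  # mapq 0 with an overlapping XA entry: moved to the first such entry
  expect_true(out$remapped[3])
  expect_equal(out$chrom[3], "chrR")
  expect_equal(out$pos[3], 1500L)
  # no overlapping alternative: untouched
  expect_false(out$remapped[4])
  expect_equal(out$chrom[4], "chrD")
})

test_that("XA tags parse BWA's signed-position entries", {
  xa <- parse_xa_tag("chr9,+800,100M,0;chr4,-120,50M50S,1;")
  expect_equal(xa$chrom, c("chr9", "chr4"))
  expect_equal(xa$pos, c(800L, 120L))
  expect_equal(xa$strand, c("+", "-"))
})

test_that("target events load, validate genes, and match junctions", {
  hm <- hand_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tgene\ttype\tj5\tj3\tmin_partner_ends",
    "skip2\tHG1\texon\t1\t3\t3",
    "crypt\tNA\tcoord\tchr1:200\tchr9:555\t2"
  ), path)
  ev <- read_target_events(path, hm)
  expect_equal(ev$name, c("skip2", "crypt"))
  # unknown gene in an exon event fails at load
  writeLines(c("name\tgene\ttype\tj5\tj3", "x\tNOPE\texon\t1\t2"), path)
  expect_error(read_target_events(path, hm), "unknown gene")

  calls <- tibble::tibble(
    gene5 = "HG1", gene3 = "HG1", chrom5 = "chr1", pos5 = 200L,
    chrom3 = c("chr1", "chr1", "chr9"), pos3 = c(701L, 702L, 553L),
    n_partner_ends = c(5L, 5L, 5L), targeted_event = NA_character_
  )
  out <- match_target_events(calls, ev[1, ], hm)
  # exon pattern: donor of exon 1 (200) -> acceptor of exon 3 (701), exact
  expect_equal(out$targeted_event, c("skip2", NA, NA))
  # coord pattern matches within the window on both sides
  out <- match_target_events(calls, ev[2, ], hm, window = 5L)
  expect_equal(out$targeted_event, c(NA, NA, "crypt"))
  # insufficient partner-end support blocks the match
  calls$n_partner_ends <- 1L
  out <- match_target_events(calls, ev, hm)
  expect_true(all(is.na(out$targeted_event)))
})

test_that("blacklist removes gene pairs and exact junctions", {
  calls <- tibble::tibble(
    gene5 = c("A", "B", "C"), gene3 = c("B", "A", "D"),
    chrom5 = "chr1", pos5 = c(100L, 200L, 300L),
    chrom3 = "chr2", pos3 = c(110L, 210L, 310L)
  )
  bl_pair <- tibble::tibble(gene_a = "A", gene_b = "B",
                            chrom_a = NA, pos_a = NA_integer_,
                            chrom_b = NA, pos_b = NA_integer_)
  expect_equal(
    suppressMessages(apply_blacklist(calls, bl_pair))$gene5, "C"
  )
  bl_coord <- tibble::tibble(gene_a = "A", gene_b = "B",
                             chrom_a = "chr1", pos_a = 100L,
                             chrom_b = "chr2", pos_b = 110L)
  out <- suppressMessages(apply_blacklist(calls, bl_coord))
  expect_equal(out$gene5, c("B", "C"))
  expect_equal(apply_blacklist(calls, NULL), calls)
})

test_that("panel restriction keeps calls touching panel regions", {
  calls <- tibble::tibble(
    gene5 = c("A", "B"), gene3 = c("X", "Y"),
    chrom5 = c("chr1", "chr3"), pos5 = c(150L, 150L),
    chrom3 = "chr2", pos3 = c(110L, 110L)
  )
  panel <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                          label = "A")
  expect_equal(restrict_to_panel(calls, panel)$gene5, "A")
  expect_equal(restrict_to_panel(calls, NULL), calls)
})

test_that("BED regions load as 1-based inclusive coordinates", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tmyregion", path)
  bed <- read_bed_regions(path)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 200L)
  expect_equal(bed$label, "myregion")
})
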