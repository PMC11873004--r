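test_that("refFlat writing and reading round-trip the simulated models", {
  ds <- basic_dataset()
  loaded <- read_refflat(ds$paths$refflat)
  orig <- ds$ref$models
  key <- c("gene", "transcript_id", "chrom", "strand", "tx_start", "tx_end",
           "cds_start", "cds_end", "n_exons", "tx_len", "cds_len", "canonical")
  expect_equal(as.data.frame(loaded[order(loaded$gene), key]),
               as.data.frame(orig[order(orig$gene), key]))
  expect_equal(loaded$exon_starts, orig$exon_starts)
  expect_equal(loaded$exon_ends, orig$exon_ends)
})

test_that("GTF loading matches the refFlat dialect", {
  skip_if_not_installed("rtracklayer")
  ds <- basic_dataset()
  from_gtf <- read_gtf_models(ds$paths$gtf)
  from_rf <- read_refflat(ds$paths$refflat)
  key <- c("gene", "transcript_id", "chrom", "strand", "tx_start", "tx_end",
           "cds_start", "cds_end", "n_exons")
  expect_equal(as.data.frame(from_gtf[order(from_gtf$gene), key]),
               as.data.frame(from_rf[order(from_rf$gene), key]))
})

test_that("canonical transcript selection prefers CDS, then length, then id", {
  two <- tibble::tibble(
    gene = "G", transcript_id = c("G.t2", "G.t1"), chrom = "chr1",
    strand = "+",
    tx_start = c(101L, 101L), tx_end = c(800L, 500L),
    cds_start = c(151L, 151L), cds_end = c(750L, 450L),
    exon_starts = list(c(101L, 401L, 701L), c(101L, 401L)),
    exon_ends = list(c(200L, 500L, 800L), c(200L, 500L))
  )
  m <- finish_models(two)
  expect_equal(m$transcript_id[m$canonical], "G.t2")
  # equal CDS and length: smallest transcript id wins
  tie <- two
  tie$tx_end <- c(500L, 500L)
  tie$cds_end <- c(450L, 450L)
  tie$exon_starts <- list(c(101L, 401L), c(101L, 401L))
  tie$exon_ends <- list(c(200L, 500L), c(200L, 500L))
  m2 <- finish_models(tie)
  expect_equal(m2$transcript_id[m2$canonical], "G.t1")
})

test_that("cDNA positions and exon numbers follow transcript orientation", {
  hm <- hand_model()
  s <- hm$exon_starts[[1]]; e <- hm$exon_ends[[1]]
  expect_equal(tx_cdna_pos("+", s, e, 101L), 1L)
  expect_equal(tx_cdna_pos("+", s, e, 450L), 150L)
  expect_equal(tx_cdna_pos("+", s, e, 300L), NA_integer_)  # intronic
  # the same exon layout on the minus strand counts from the other end
  expect_equal(tx_cdna_pos("-", s, e, 800L), 1L)
  expect_equal(tx_cdna_pos("-", s, e, 450L), 151L)
  en <- tx_exon_number("+", s, e, 450L)
  expect_equal(list(en$region, en$number), list("exon", 2L))
  en <- tx_exon_number("-", s, e, 450L)
  expect_equal(en$number, 2L)
  en <- tx_exon_number("+", s, e, 300L)
  expect_equal(list(en$region, en$number), list("intron", 1L))
  en <- tx_exon_number("+", s, e, 50L)
  expect_equal(en$region, "intergenic")
})

test_that("exon termini cover all transcripts and respect strand", {
  hm <- hand_model()
  expect_equal(gene_exon_termini(hm, "HG1", "donor"), c(200L, 500L, 800L))
  expect_equal(gene_exon_termini(hm, "HG1", "acceptor"), c(101L, 401L, 701L))
  minus <- hm
  minus$strand <- "-"
  expect_equal(gene_exon_termini(minus, "HG1", "donor"), c(101L, 401L, 701L))
  expect_equal(gene_exon_termini(hm, "NOPE", "donor"), integer())
})
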