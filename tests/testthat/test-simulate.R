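test_that("simulation is deterministic under a seed", {
  sc <- basic_scenario()
  r1 <- sim_fusion_reference(sc, seed = 4L)
  r2 <- sim_fusion_reference(sc, seed = 4L)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$models, r2$models)
  rd1 <- sim_fusion_reads(r1, seed = 5L)
  rd2 <- sim_fusion_reads(r2, seed = 5L)
  expect_identical(rd1$sam_lines, rd2$sam_lines)
  r3 <- sim_fusion_reference(sc, seed = 6L)
  expect_false(identical(r1$genome, r3$genome))
})

test_that("planted junction truth is internally consistent", {
  ds <- basic_dataset()
  tr <- ds$reads$truth
  jt <- ds$ref$junctions[[1]]
  # exon-boundary junctions sit on annotated termini on both sides
  expect_equal(tr$boundary_status, "both")
  expect_true(jt$bp5 %in% gene_exon_termini(ds$ref$models, "GENEA", "donor"))
  expect_true(jt$bp3 %in% gene_exon_termini(ds$ref$models, "GENEB", "acceptor"))
  # read sequences really come from the reference at the planted coordinates:
  # the 5' half of a junction-spanning read matches the genome at bp5
  rd <- ds$reads$reads[1, ]
  s <- rd$split_pos
  genome5 <- ds$ref$genome[["chrA"]]
  expect_equal(substr(rd$seq, 1, s),
               substr(genome5, jt$bp5 - s + 1L, jt$bp5))
  # planned support counts are respected in the emitted reads
  expect_equal(dplyr::n_distinct(ds$reads$reads$umi), tr$n_umis)
  expect_equal(dplyr::n_distinct(ds$reads$reads$ls_pos), tr$n_partner_ends)
  expect_equal(nrow(ds$reads$reads), tr$n_reads)
})

test_that("the translation oracle flags planted frame structure", {
  # exon lengths divisible by 3 with matching phase: in frame
  sc_in <- fusion_scenario(
    gene5 = gene_spec("FA"), gene3 = gene_spec("FB"),
    junctions = junction_spec()
  )
  ref <- sim_fusion_reference(sc_in, seed = 21L)
  expect_true(ref$junctions[[1]]$frame)
  # offset by one base inside an exon: phase mismatch
  sc_out <- fusion_scenario(
    gene5 = gene_spec("FA"),
    gene3 = gene_spec("FB"),
    junctions = junction_spec(
      side5 = list(kind = "intra_exon", exon = 2L, offset = 100L),
      side3 = list(kind = "exon_boundary", exon = 3L)
    )
  )
  ref <- sim_fusion_reference(sc_out, seed = 21L)
  expect_false(ref$junctions[[1]]$frame)
  # intronic junction side: oracle abstains
  sc_na <- fusion_scenario(
    gene5 = gene_spec("FA"),
    gene3 = gene_spec("FB"),
    junctions = junction_spec(
      side5 = list(kind = "intronic", intron = 2L, offset = 40L),
      side3 = list(kind = "exon_boundary", exon = 3L)
    )
  )
  ref <- sim_fusion_reference(sc_na, seed = 21L)
  expect_true(is.na(ref$junctions[[1]]$frame))
})

test_that("fused transcripts never carry a chimeric junction stop codon", {
  # phase-matched intra-exon junctions are where chimeric stops can appear;
  # scan many seeds and check the translated fusion never stops early when
  # the planted junction is in frame
  for (seed in 1:15) {
    sc <- fusion_scenario(
      gene5 = gene_spec("CA"),
      gene3 = gene_spec("CB"),
      junctions = junction_spec(
        side5 = list(kind = "intra_exon", exon = 2L, offset = 50L),
        side3 = list(kind = "intra_exon", exon = 2L, offset = 51L)
      )
    )
    ref <- sim_fusion_reference(sc, seed = seed)
    jt <- ref$junctions[[1]]
    expect_true(jt$frame, label = sprintf("seed %d planted in-frame", seed))
  }
})

test_that("dataset files are text and within fixture size budgets", {
  dir <- file.path(tempdir(), "fx_size")
  ds <- sim_fusion_dataset(basic_scenario(), seed = 2L, dir = dir)
  files <- list.files(dir, full.names = TRUE)
  expect_true(length(files) >= 5L)
  sizes <- file.size(files)
  expect_true(all(sizes <= 64 * 1024))
  expect_lte(sum(sizes), 256 * 1024)
})
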