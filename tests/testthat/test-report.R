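test_that("Fisher exact test reproduces known values", {
  # degenerate concentrated tables
  expect_equal(fisher_exact_2x2(1, 0, 0, 1)$p_value, 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, 2 / choose(10, 5))
  # all-margin-zero style: single possible table
  expect_equal(fisher_exact_2x2(3, 0, 2, 0)$p_value, 1)
  expect_error(fisher_exact_2x2(-1, 0, 0, 1), "non-negative")
})

test_that("Fisher enumeration agrees with the reference implementation", {
  set.seed(77)
  for (i in 1:40) {
    cells <- sample(0:30, 4, replace = TRUE)
    mine <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("subclone counting is the number of distinct junctions per pair", {
  rows <- tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S1", "S2"),
    fusion_name = c("A::B", "A::B", "A::B", "C::D", "A::B"),
    junction = c("chr1:1_chr2:2", "chr1:9_chr2:2", "chr1:1_chr2:2",
                 "chr3:3_chr4:4", "chr1:1_chr2:2")
  )
  sc <- count_subclones(rows)
  expect_equal(sc$n_subclones[sc$sample_id == "S1" & sc$fusion_name == "A::B"], 2L)
  expect_equal(sc$n_subclones[sc$sample_id == "S1" & sc$fusion_name == "C::D"], 1L)
  expect_equal(sc$n_subclones[sc$sample_id == "S2"], 1L)
  expect_equal(nrow(count_subclones(rows[0, ])), 0L)
})

test_that("fusion summaries are deterministic and ordered", {
  ds <- basic_dataset()
  res <- run_fusion_pipeline(ds$paths$sam, ds$paths$refflat, sample_id = "S1")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_summary(res$calls[res$calls$called, ], "S1", f1)
  write_fusion_summary(res$calls[res$calls$called, ], "S1", f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty input still yields the full header
  hdr <- write_fusion_summary(res$calls[0, ], "S1")
  expect_equal(names(hdr), fuseseq:::summary_columns)
  expect_equal(nrow(hdr), 0L)
})

test_that("supporting-read extraction is seeded and bounded", {
  ds <- basic_dataset()
  res <- run_fusion_pipeline(ds$paths$sam, ds$paths$refflat)
  call <- res$calls[res$calls$called, ][1, ]
  sel1 <- extract_supporting_reads(call, res$records, n = 5L, seed = 42L)
  sel2 <- extract_supporting_reads(call, res$records, n = 5L, seed = 42L)
  expect_equal(nrow(sel1), 5L)
  expect_identical(sel1$read_id, sel2$read_id)
  sel3 <- extract_supporting_reads(call, res$records, n = 5L, seed = 43L)
  expect_true(all(sel3$read_id %in% unlist(call$read_ids)))
  # n larger than the support set returns everything
  all_reads <- extract_supporting_reads(call, res$records, n = 1000L)
  expect_equal(sort(all_reads$read_id), sort(unique(unlist(call$read_ids))))
  # FASTQ/SAM outputs are written when paths are given
  fq <- withr::local_tempfile(fileext = ".fastq")
  sm <- withr::local_tempfile(fileext = ".sam")
  extract_supporting_reads(call, res$records, n = 5L, seed = 42L,
                           fastq_path = fq, sam_path = sm)
  expect_equal(length(readLines(fq)), 20L)
  expect_true(any(startsWith(readLines(sm), "@SQ")))
})
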