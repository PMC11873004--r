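#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table — the standard two-sided convention (not mid-p, not doubling).
#' Probabilities within a relative tolerance of 1e-7 of the observed one are
#' included, the usual guard against floating-point ties.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return A one-row tibble with `p_value`, the observed-table probability
#'   (`p_table`), and the cells.
#' @examples
#' fisher_exact_2x2(11, 9, 6, 25)  # p = 0.0143
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- base::c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("All four cells must be non-negative integers.")
  }
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p0 <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p0 * (1 + 1e-7)])
  tibble(p_value = min(1, p), p_table = p0, a = a, b = b, c = c, d = d)
}

#' Count fusion-junction-defined subclones
#'
#' Tumor subpopulations carrying the same gene fusion can differ in their
#' exact fusion junction; each distinct junction string for a gene pair in a
#' sample defines one subclone. Input rows are fusion-summary rows (or any
#' tibble with `sample_id`, `fusion_name`, `junction`).
#'
#' @param rows A summary tibble.
#' @return A tibble with one row per `sample_id` x `fusion_name` and the
#'   number of distinct junctions `n_subclones`.
#' @export
count_subclones <- function(rows) {
  if (nrow(rows) == 0L) {
    return(tibble(sample_id = character(), fusion_name = character(),
                  n_subclones = integer()))
  }
  rows |>
    group_by(.data$sample_id, .data$fusion_name) |>
    summarise(n_subclones = n_distinct(.data$junction), .groups = "drop")
}

summary_columns <- c(
  "sample_id", "fusion_name", "junction", "n_umi_reads", "n_partner_ends",
  "frame_status", "boundary_status", "transcript5", "exon5", "cdna5",
  "transcript3", "exon3", "cdna3", "targeted_event", "mode_flags"
)

#' Build and optionally write the final fusion summary
#'
#' One row per exact junction per sample, with the junction string, UMI-read
#' and partner-end support, frame and exon-boundary status, and per-side
#' transcript annotation. Rows are sorted by fusion name then descending
#' UMI-read support; writing the same calls twice produces byte-identical
#' files.
#'
#' @param calls Calls tibble from [call_fusions()].
#' @param sample_id Sample identifier stamped on every row.
#' @param path Optional output path; when given, the summary is written as
#'   TSV.
#' @return The summary tibble (invisibly when `path` is given).
#' @export
write_fusion_summary <- function(calls, sample_id = "sample", path = NULL) {
  summ <- calls |>
    mutate(
      sample_id = sample_id,
      mode_flags = paste0(
        if_else(.data$intragenic, "intragenic;", ""),
        if_else(!is.na(.data$targeted_event), "targeted;", "")
      )
    ) |>
    select(any_of(summary_columns)) |>
    arrange(.data$fusion_name, desc(.data$n_umi_reads), .data$junction)
  if (nrow(calls) == 0L) {
    summ <- as_tibble(setNames(
      rep(list(character(0)), length(summary_columns)), summary_columns
    ))
  }
  if (!is.null(path)) {
    readr::write_tsv(summ, path, progress = FALSE)
    return(invisible(summ))
  }
  summ
}

#' Extract supporting reads for a fusion call
#'
#' Samples up to `n` fusion-supporting split reads (without replacement,
#' reproducibly under the run seed) from the consolidated records and writes
#' them as FASTQ plus a mini SAM suitable for loading in a genome browser.
#'
#' @param call One row of a calls tibble (with its `read_ids` list-column).
#' @param records Consolidated records from [dedup_reads()] (must carry
#'   `seq`/`qual`).
#' @param n Number of reads to sample (default 10).
#' @param seed Sampling seed.
#' @param fastq_path,sam_path Optional output paths.
#' @return A tibble of the selected records (invisibly when paths are given).
#' @export
extract_supporting_reads <- function(call, records, n = 10L, seed = 1L,
                                     fastq_path = NULL, sam_path = NULL) {
  ids <- sort(unique(unlist(call$read_ids)))
  if (length(ids) == 0L) abort("Call has no supporting reads.")
  picked <- if (length(ids) <= n) {
    ids
  } else {
    withr_seed <- function(code) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      code
    }
    sort(withr_seed(sample(ids, n)))
  }
  sel <- filter(records, .data$read_id %in% picked) |> arrange(.data$read_id)
  if (!is.null(fastq_path)) {
    fq <- as.vector(rbind(paste0("@", sel$read_id),
                          sel$seq, "+", sel$qual))
    readr::write_lines(fq, fastq_path)
  }
  if (!is.null(sam_path)) {
    chroms <- sort(unique(sel$chrom))
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", chroms, "\tLN:536870911"),
             paste0("@CO\textraction seed: ", seed))
    body <- paste(sel$read_id, sel$flag, sel$chrom, sel$pos, sel$mapq,
                  sel$cigar, "*", 0L, 0L, sel$seq, sel$qual,
                  ifelse(is.na(sel$sa), "", paste0("SA:Z:", sel$sa)),
                  sep = "\t")
    readr::write_lines(c(hdr, sub("\t$", "", body)), sam_path)
  }
  if (is.null(fastq_path) && is.null(sam_path)) sel else invisible(sel)
}
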