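#' Read transcript models from a refFlat file
#'
#' refFlat is the UCSC tab-separated transcript table: geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds,
#' with 0-based half-open coordinates. Coordinates are converted to 1-based
#' inclusive on load. A transcript with `cdsStart == cdsEnd` is non-coding
#' (CDS bounds are `NA`). CDS bounds include the stop codon (UCSC convention).
#'
#' @param path Path to a refFlat file (plain text, optionally with `#`
#'   comment lines).
#' @return A transcript-model tibble: `gene`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, `n_exons`,
#'   `exon_starts`/`exon_ends` (list-columns), `tx_len`, `cds_len`, and a
#'   `canonical` flag (see [select_canonical()]).
#' @export
read_refflat <- function(path) {
  cols <- c("gene", "transcript_id", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  raw <- readr::read_tsv(path, col_names = cols, comment = "#",
                         col_types = "ccccddddccc", progress = FALSE)
  bad <- is.na(raw$txStart) | is.na(raw$txEnd) | !raw$strand %in% c("+", "-")
  if (any(bad)) {
    warn(sprintf("%d malformed refFlat line(s) skipped.", sum(bad)))
    raw <- raw[!bad, ]
  }
  if (nrow(raw) == 0L) abort("No transcript models could be read.")
  parse_list <- function(x) map(x, ~ as.integer(strsplit(.x, ",")[[1]]))
  models <- tibble(
    gene = raw$gene,
    transcript_id = raw$transcript_id,
    chrom = raw$chrom,
    strand = raw$strand,
    tx_start = as.integer(raw$txStart) + 1L,
    tx_end = as.integer(raw$txEnd),
    cds_start = if_else(raw$cdsStart == raw$cdsEnd, NA_integer_,
                        as.integer(raw$cdsStart) + 1L),
    cds_end = if_else(raw$cdsStart == raw$cdsEnd, NA_integer_,
                      as.integer(raw$cdsEnd)),
    exon_starts = map(parse_list(raw$exonStarts), ~ .x + 1L),
    exon_ends = parse_list(raw$exonEnds)
  )
  finish_models(models)
}

#' Read transcript models from a GTF file
#'
#' Builds the same transcript-model tibble as [read_refflat()] from `exon` and
#' `CDS` features of a GTF file (via `rtracklayer`). CDS bounds are taken as
#' the span of the transcript's CDS features, which in this package's
#' convention include the stop codon, matching the refFlat dialect.
#'
#' @param path Path to a GTF file.
#' @return A transcript-model tibble; see [read_refflat()].
#' @export
read_gtf_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GTF requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as_tibble(S4Vectors::mcols(gr))
  feats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene = if ("gene_name" %in% names(md)) md$gene_name else md$gene_id,
    transcript_id = md$transcript_id
  )
  exons <- filter(feats, .data$type == "exon") |> arrange(.data$transcript_id, .data$start)
  if (nrow(exons) == 0L) abort("No transcript models could be read.")
  cds <- filter(feats, .data$type == "CDS") |>
    group_by(.data$transcript_id) |>
    summarise(cds_start = min(.data$start), cds_end = max(.data$end))
  models <- exons |>
    group_by(.data$gene, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(
      tx_start = min(.data$start), tx_end = max(.data$end),
      exon_starts = list(.data$start), exon_ends = list(.data$end),
      .groups = "drop"
    ) |>
    left_join(cds, by = "transcript_id")
  finish_models(models)
}

finish_models <- function(models) {
  models <- models |>
    mutate(
      n_exons = lengths(.data$exon_starts),
      tx_len = map2_int(.data$exon_starts, .data$exon_ends, ~ sum(.y - .x + 1L)),
      cds_len = if_else(is.na(.data$cds_start), 0L,
                        .data$cds_end - .data$cds_start + 1L)
    ) |>
    arrange(.data$gene, .data$transcript_id)
  ok <- map_lgl(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    all(s <= e) && !is.unsorted(s, strictly = TRUE) && all(head(e, -1) < tail(s, -1))
  })
  if (!all(ok)) {
    warn(sprintf("%d model(s) with overlapping or unsorted exons skipped.", sum(!ok)))
    models <- models[ok, ]
  }
  if (nrow(models) == 0L) abort("No transcript models could be read.")
  select_canonical(models)
}

#' Flag the canonical transcript of each gene
#'
#' One canonical transcript per gene is used for cDNA positions and frame
#' inference: the transcript with the longest CDS, ties broken by total
#' transcript (exonic) length, then by the smallest transcript id. All
#' isoforms are retained for exon-boundary judgment and isoform-fallback
#' frame calls.
#'
#' @param models A transcript-model tibble.
#' @return The tibble with a logical `canonical` column.
#' @export
select_canonical <- function(models) {
  models |>
    group_by(.data$gene) |>
    mutate(canonical = row_number(order(-.data$cds_len, -.data$tx_len,
                                        .data$transcript_id)) == 1L) |>
    ungroup()
}

# cDNA (transcript-space, 1-based, transcript orientation) position of a
# genomic coordinate on one transcript; NA when intronic or outside.
tx_cdna_pos <- function(strand, exon_starts, exon_ends, gpos) {
  k <- which(exon_starts <= gpos & gpos <= exon_ends)
  if (length(k) == 0L) return(NA_integer_)
  k <- k[1L]
  lens <- exon_ends - exon_starts + 1L
  if (strand == "+") {
    sum(lens[seq_len(k - 1L)]) + (gpos - exon_starts[k] + 1L)
  } else {
    n <- length(lens)
    (if (k < n) sum(lens[(k + 1L):n]) else 0L) + (exon_ends[k] - gpos + 1L)
  }
}

# Exon (or intron) number at a genomic position in transcript orientation.
# Returns list(region, number): region "exon" or "intron"; intergenic -> NA.
tx_exon_number <- function(strand, exon_starts, exon_ends, gpos) {
  n <- length(exon_starts)
  if (gpos < min(exon_starts) || gpos > max(exon_ends)) {
    return(list(region = "intergenic", number = NA_integer_))
  }
  k <- which(exon_starts <= gpos & gpos <= exon_ends)
  if (length(k) > 0L) {
    k <- k[1L]
    num <- if (strand == "+") k else n - k + 1L
    return(list(region = "exon", number = as.integer(num)))
  }
  j <- max(which(exon_ends < gpos))  # intron after genomic exon j
  num <- if (strand == "+") j else n - j
  list(region = "intron", number = as.integer(num))
}

# cDNA bounds of the CDS in transcript orientation: c(start, end) or NULL.
tx_cds_bounds <- function(row) {
  if (is.na(row$cds_start)) return(NULL)
  s <- row$exon_starts[[1]]; e <- row$exon_ends[[1]]
  if (row$strand == "+") {
    c(tx_cdna_pos("+", s, e, row$cds_start), tx_cdna_pos("+", s, e, row$cds_end))
  } else {
    c(tx_cdna_pos("-", s, e, row$cds_end), tx_cdna_pos("-", s, e, row$cds_start))
  }
}

# Genomic coordinates of transcribed-strand exon termini of a gene, across all
# of its transcripts. role "donor": exon 3' termini; "acceptor": 5' termini.
gene_exon_termini <- function(models, gene, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  rows <- models[models$gene == gene, ]
  if (nrow(rows) == 0L) return(integer())
  out <- map(seq_len(nrow(rows)), function(i) {
    s <- rows$exon_starts[[i]]; e <- rows$exon_ends[[i]]
    if ((rows$strand[i] == "+") == (role == "donor")) e else s
  })
  sort(unique(unlist(out)))
}
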