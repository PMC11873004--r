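#' Read genomic regions from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted to 1-based
#' inclusive on load (via `rtracklayer`).
#'
#' @param path Path to a BED file (3+ columns; the 4th, if present, is a
#'   region label).
#' @return A tibble with `chrom`, `start`, `end`, `label`.
#' @export
read_bed_regions <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading BED requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    label = nm
  )
}

parse_xa_tag <- function(xa) {
  entries <- strsplit(xa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  parts <- str_split(entries, ",")
  ok <- lengths(parts) == 4L
  parts <- parts[ok]
  if (length(parts) == 0L) return(tibble(chrom = character(), pos = integer(),
                                         strand = character(), cigar = character()))
  posfield <- map_chr(parts, 2)
  tibble(
    chrom = map_chr(parts, 1),
    pos = as.integer(substring(posfield, 2L)),
    strand = substr(posfield, 1L, 1L),
    cigar = map_chr(parts, 3)
  )
}

overlaps_region <- function(chrom, start, end, regions) {
  any(regions$chrom == chrom & regions$start <= end & start <= regions$end)
}

#' Rescue MAPQ-0 alignments in designated repetitive regions
#'
#' Highly repetitive loci (pseudogene arrays such as the DUX4 repeat) receive
#' mapping quality 0 and a set of equally good alternative alignments in the
#' `XA` tag. For each segment with `mapq == 0`, if the segment itself or one
#' of its alternative alignments overlaps a user-designated region, the
#' segment's coordinates are updated to that overlapping alignment (the
#' primary location wins if it already overlaps; otherwise the first
#' overlapping `XA` entry in tag order), and the segment is flagged
#' `remapped`. Segments with `mapq > 0` are never altered.
#'
#' @param segments Segment tibble from [expand_alignments()].
#' @param regions Region tibble from [read_bed_regions()].
#' @return `segments` with possibly updated `chrom`, `pos`, `strand`, `cigar`
#'   and an added logical `remapped` column.
#' @export
remap_pseudogene_segments <- function(segments, regions) {
  segments$remapped <- FALSE
  if (nrow(segments) == 0L || is.null(regions) || nrow(regions) == 0L) {
    return(segments)
  }
  for (i in seq_len(nrow(segments))) {
    if (segments$mapq[i] != 0L) next
    span <- cigar_ref_span(parse_cigar(segments$cigar[i]))
    if (overlaps_region(segments$chrom[i], segments$pos[i],
                        segments$pos[i] + span - 1L, regions)) {
      segments$remapped[i] <- TRUE
      next
    }
    xa <- segments$xa[i]
    if (is.na(xa) || !nzchar(xa)) next
    alts <- parse_xa_tag(xa)
    for (j in seq_len(nrow(alts))) {
      aspan <- cigar_ref_span(parse_cigar(alts$cigar[j]))
      if (overlaps_region(alts$chrom[j], alts$pos[j],
                          alts$pos[j] + aspan - 1L, regions)) {
        segments$chrom[i] <- alts$chrom[j]
        segments$pos[i] <- alts$pos[j]
        segments$strand[i] <- alts$strand[j]
        segments$cigar[i] <- alts$cigar[j]
        segments$remapped[i] <- TRUE
        break
      }
    }
  }
  segments
}

#' Read whitelisted target events
#'
#' Target events describe intragenic or otherwise special junctions to report
#' by name: alternative splicing (exon skipping), exon deletion, gene
#' truncation, or cryptic-exon junctions given as coordinates. The file is
#' tab-separated with columns `name`, `gene`, `type` (`exon` or `coord`),
#' `j5`, `j3`, and optionally `min_partner_ends` (default 3). For `exon`
#' events `j5`/`j3` are exon numbers: the junction joins the 3' boundary of
#' exon `j5` to the 5' boundary of exon `j3` (e.g. an exon-14-skipping event
#' is `j5 = 13, j3 = 15`; an exon 2-7 deletion is `j5 = 1, j3 = 8`). For
#' `coord` events they are `chrom:pos` strings matched within
#' `target_window` bases.
#'
#' @param path Path to the targets TSV.
#' @param models Optional transcript models; when given, `exon`-type events
#'   referencing unknown genes raise an error at load time.
#' @return A tibble of events.
#' @export
read_target_events <- function(path, models = NULL) {
  ev <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("name", "gene", "type", "j5", "j3")
  if (!all(required %in% names(ev))) {
    abort(paste0("Target events file must have columns: ",
                 paste(required, collapse = ", ")))
  }
  if (!"min_partner_ends" %in% names(ev)) ev$min_partner_ends <- "3"
  ev$min_partner_ends <- as.integer(ev$min_partner_ends)
  ev$min_partner_ends[is.na(ev$min_partner_ends)] <- 3L
  if (!is.null(models)) {
    unknown <- setdiff(ev$gene[ev$type == "exon"], models$gene)
    if (length(unknown) > 0L) {
      abort(paste0("Target event references unknown gene(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  ev
}

canonical_exon_terminus <- function(models, gene, exon_number,
                                    role = c("donor", "acceptor")) {
  role <- match.arg(role)
  row <- models[models$gene == gene & models$canonical, ]
  if (nrow(row) == 0L) return(NA_integer_)
  row <- row[1, ]
  n <- row$n_exons
  if (exon_number < 1L || exon_number > n) return(NA_integer_)
  idx <- if (row$strand == "+") exon_number else n - exon_number + 1L
  if ((row$strand == "+") == (role == "donor")) {
    row$exon_ends[[1]][idx]
  } else {
    row$exon_starts[[1]][idx]
  }
}

parse_coord <- function(x) {
  m <- str_match(x, "^(.+):([0-9]+)$")
  list(chrom = m[, 2], pos = as.integer(m[, 3]))
}

#' Match annotated junctions against whitelisted target events
#'
#' Sets `targeted_event` on calls whose junction matches an event pattern and
#' whose partner-end support meets the event's `min_partner_ends`. Exon
#' patterns require exact boundary coordinates (3' terminus of exon `j5`, 5'
#' terminus of exon `j3` on the gene's canonical transcript); coordinate
#' patterns match within `window` bases on both sides.
#'
#' @param calls Calls tibble from [call_fusions()].
#' @param targets Events from [read_target_events()].
#' @param models A transcript-model tibble.
#' @param window Coordinate slack for `coord` events (default 5).
#' @return `calls` with `targeted_event` filled where matched.
#' @export
match_target_events <- function(calls, targets, models, window = 5L) {
  if (!"targeted_event" %in% names(calls)) calls$targeted_event <- NA_character_
  if (nrow(calls) == 0L || nrow(targets) == 0L) return(calls)
  for (e in seq_len(nrow(targets))) {
    ev <- targets[e, ]
    hit <- if (ev$type == "exon") {
      d <- canonical_exon_terminus(models, ev$gene, as.integer(ev$j5), "donor")
      a <- canonical_exon_terminus(models, ev$gene, as.integer(ev$j3), "acceptor")
      !is.na(d) & !is.na(a) &
        (calls$gene5 %in% ev$gene | calls$gene3 %in% ev$gene) &
        calls$pos5 == d & calls$pos3 == a
    } else {
      c5 <- parse_coord(ev$j5); c3 <- parse_coord(ev$j3)
      calls$chrom5 == c5$chrom & abs(calls$pos5 - c5$pos) <= window &
        calls$chrom3 == c3$chrom & abs(calls$pos3 - c3$pos) <= window
    }
    hit <- hit & calls$n_partner_ends >= ev$min_partner_ends &
      is.na(calls$targeted_event)
    calls$targeted_event[hit] <- ev$name
  }
  calls
}

#' Read a blacklist of recurrent false-positive fusions
#'
#' Tab-separated with columns `gene_a`, `gene_b` and optionally `chrom_a`,
#' `pos_a`, `chrom_b`, `pos_b`. Entries without coordinates suppress every
#' junction of the gene pair (in either orientation); entries with
#' coordinates suppress only the exact junction.
#'
#' @param path Path to the blacklist TSV.
#' @return A tibble of blacklist entries.
#' @export
read_blacklist <- function(path) {
  bl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(bl))) {
    abort("Blacklist must have columns gene_a and gene_b.")
  }
  for (col in c("chrom_a", "chrom_b")) if (!col %in% names(bl)) bl[[col]] <- NA_character_
  for (col in c("pos_a", "pos_b")) {
    bl[[col]] <- if (col %in% names(bl)) as.integer(bl[[col]]) else NA_integer_
  }
  bl
}

#' Remove blacklisted calls
#'
#' @param calls Calls tibble from [call_fusions()].
#' @param blacklist Entries from [read_blacklist()]; `NULL` or empty is the
#'   identity.
#' @return `calls` without the suppressed rows; the number removed is
#'   reported via a message.
#' @export
apply_blacklist <- function(calls, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L || nrow(calls) == 0L) {
    return(calls)
  }
  drop <- rep(FALSE, nrow(calls))
  for (e in seq_len(nrow(blacklist))) {
    b <- blacklist[e, ]
    pair_hit <-
      (calls$gene5 %in% b$gene_a & calls$gene3 %in% b$gene_b) |
      (calls$gene5 %in% b$gene_b & calls$gene3 %in% b$gene_a)
    if (!is.na(b$pos_a) && !is.na(b$pos_b)) {
      coord_hit <-
        (calls$chrom5 == b$chrom_a & calls$pos5 == b$pos_a &
           calls$chrom3 == b$chrom_b & calls$pos3 == b$pos_b) |
        (calls$chrom5 == b$chrom_b & calls$pos5 == b$pos_b &
           calls$chrom3 == b$chrom_a & calls$pos3 == b$pos_a)
      pair_hit <- pair_hit & coord_hit
    }
    drop <- drop | pair_hit
  }
  if (any(drop)) {
    inform(sprintf("Blacklist suppressed %d call(s).", sum(drop)))
  }
  calls[!drop, ]
}

#' Restrict calls to a target gene panel
#'
#' Keeps calls with at least one breakpoint inside a panel region, mirroring
#' Target-mode behaviour where only alignments involving the targeted genes
#' (plus any partner) are reported.
#'
#' @param calls Calls tibble.
#' @param panel Panel regions from [read_bed_regions()]; `NULL` is the
#'   identity.
#' @return The restricted calls tibble.
#' @export
restrict_to_panel <- function(calls, panel) {
  if (is.null(panel) || nrow(panel) == 0L || nrow(calls) == 0L) return(calls)
  keep <- map_lgl(seq_len(nrow(calls)), function(i) {
    overlaps_region(calls$chrom5[i], calls$pos5[i], calls$pos5[i], panel) ||
      overlaps_region(calls$chrom3[i], calls$pos3[i], calls$pos3[i], panel)
  })
  calls[keep, ]
}
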