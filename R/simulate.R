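# Seeded synthetic-data generator: reference sequences, transcript models and
# per-junction truth for fusion scenarios. Read emission lives in sim-reads.R.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste0, collapse = "")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Describe one synthetic gene
#'
#' @param name Gene symbol.
#' @param n_exons Number of exons.
#' @param exon_len Exon length(s): scalar or vector of `n_exons`.
#' @param intron_len Intron length(s): scalar or vector of `n_exons - 1`.
#' @param strand Genomic strand of the gene.
#' @param utr5,utr3 Untranslated lengths at the transcript ends; the remaining
#'   CDS length must be a positive multiple of 3 (start and stop codons are
#'   planted at its bounds, the interior is stop-free).
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(name, n_exons = 5L, exon_len = 120L, intron_len = 300L,
                      strand = "+", utr5 = 60L, utr3 = 60L) {
  exon_len <- as.integer(rep(exon_len, length.out = n_exons))
  intron_len <- if (n_exons > 1L) {
    as.integer(rep(intron_len, length.out = n_exons - 1L))
  } else integer()
  mrna_len <- sum(exon_len)
  cds_len <- mrna_len - utr5 - utr3
  if (cds_len < 6L || cds_len %% 3L != 0L) {
    abort(sprintf(
      "gene_spec('%s'): CDS length %d must be a positive multiple of 3 (>= 6).",
      name, cds_len
    ))
  }
  structure(list(
    name = name, n_exons = as.integer(n_exons), exon_len = exon_len,
    intron_len = intron_len, strand = strand, utr5 = as.integer(utr5),
    utr3 = as.integer(utr3), mrna_len = as.integer(mrna_len),
    cds_len = as.integer(cds_len)
  ), class = "gene_spec")
}

#' Describe one planted fusion junction
#'
#' Each side is given in transcript coordinates of its gene. `kind` options:
#' `"exon_boundary"` (5' side: 3' end of `exon`; 3' side: 5' start of
#' `exon`), `"intra_exon"` (`offset` bases from the exon's transcribed 5'
#' end), `"intronic"` (`offset` bases into intron `intron` in transcribed
#' direction: the 5' side retains that much intron, the 3' side's retained
#' suffix begins there).
#'
#' @param side5,side3 Lists with `kind` plus `exon`/`intron` and `offset`.
#' @param n_reads,n_umis,n_partner_ends Planned support: distinct ligation
#'   sites <= distinct UMIs <= reads.
#' @return A `junction_spec` list.
#' @export
junction_spec <- function(side5 = list(kind = "exon_boundary", exon = 2L),
                          side3 = list(kind = "exon_boundary", exon = 3L),
                          n_reads = 20L, n_umis = 12L, n_partner_ends = 5L) {
  if (!(n_partner_ends <= n_umis && n_umis <= n_reads)) {
    abort("Need n_partner_ends <= n_umis <= n_reads.")
  }
  structure(list(side5 = side5, side3 = side3, n_reads = as.integer(n_reads),
                 n_umis = as.integer(n_umis),
                 n_partner_ends = as.integer(n_partner_ends)),
            class = "junction_spec")
}

#' Describe a complete fusion simulation scenario
#'
#' A scenario is a 5' gene, a 3' gene, and one or more planted junctions
#' between them (several junctions emulate fusion-junction-defined subclones
#' of one tumor). By default the genes sit on different contigs; with
#' `same_contig = TRUE` they share one contig separated by `contig_gap`
#' bases. `repeat_partner` places decoy copies of the 5' gene on a separate
#' contig and emits its alignments there with MAPQ 0 plus `XA` alternatives
#' pointing at the annotated copy, emulating a highly repetitive partner.
#'
#' @param gene5,gene3 [gene_spec()]s.
#' @param junctions A [junction_spec()] or list of them.
#' @param read_length Read length in bases (default 100).
#' @param error_rate Per-base substitution rate applied to read sequences.
#' @param anchored Emit AMP-style reads (UMI in name, read 1 from the
#'   ligation end); `FALSE` emits plain reads without UMI suffixes.
#' @param adaptor_clip Unmapped adaptor bases at the read start (scalar).
#' @param same_contig,contig_gap Placement of the two genes.
#' @param intragenic Plant the junction(s) within a single gene (`gene3` is
#'   ignored): exon skipping, exon deletion and similar whitelist-only events.
#' @param repeat_partner,n_repeat_copies Repetitive-partner mode.
#' @param sample_id Sample name stamped on reads and truth.
#' @return A `fusion_scenario` list.
#' @export
fusion_scenario <- function(gene5 = gene_spec("GENE5A"),
                            gene3 = gene_spec("GENE3B"),
                            junctions = junction_spec(),
                            read_length = 100L,
                            error_rate = 0,
                            anchored = TRUE,
                            adaptor_clip = 0L,
                            same_contig = FALSE,
                            contig_gap = 800000L,
                            intragenic = FALSE,
                            repeat_partner = FALSE,
                            n_repeat_copies = 3L,
                            sample_id = "S1") {
  if (inherits(junctions, "junction_spec")) junctions <- list(junctions)
  if (intragenic) gene3 <- gene5
  structure(list(
    gene5 = gene5, gene3 = gene3, junctions = junctions,
    intragenic = intragenic,
    read_length = as.integer(read_length), error_rate = error_rate,
    anchored = anchored, adaptor_clip = as.integer(adaptor_clip),
    same_contig = same_contig, contig_gap = as.integer(contig_gap),
    repeat_partner = repeat_partner, n_repeat_copies = as.integer(n_repeat_copies),
    sample_id = sample_id
  ), class = "fusion_scenario")
}

# Build one gene's sequences in transcript ("sense") orientation.
# Returns mRNA, sense genomic sequence, exon intervals in sense coordinates,
# and cumulative exon lengths.
build_gene_seqs <- function(spec) {
  n_codons <- spec$cds_len %/% 3L
  interior <- if (n_codons > 2L) {
    paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = "")
  } else ""
  cds <- paste0("ATG", interior, "TAA")
  mrna <- paste0(random_dna(spec$utr5), cds, random_dna(spec$utr3))
  cum <- cumsum(spec$exon_len)
  exon_seq <- map2(c(1L, head(cum, -1) + 1L), cum, ~ substr(mrna, .x, .y))
  introns <- map(spec$intron_len, random_dna)
  pieces <- character(0)
  s_starts <- integer(spec$n_exons); s_ends <- integer(spec$n_exons)
  at <- 0L
  for (k in seq_len(spec$n_exons)) {
    s_starts[k] <- at + 1L
    at <- at + spec$exon_len[k]
    s_ends[k] <- at
    pieces <- base::c(pieces, exon_seq[[k]])
    if (k < spec$n_exons) {
      pieces <- base::c(pieces, introns[[k]])
      at <- at + spec$intron_len[k]
    }
  }
  list(
    mrna = mrna, sense = paste(pieces, collapse = ""), introns = introns,
    exon_s_start = s_starts, exon_s_end = s_ends,
    cum_exon = cum, gene_len = at
  )
}

# transcript (mRNA) position -> sense genomic position within the gene
mrna_to_sense <- function(g, t) {
  k <- findInterval(t - 1L, g$cum_exon) + 1L
  before <- if (k > 1L) g$cum_exon[k - 1L] else 0L
  g$exon_s_start[k] + (t - before - 1L)
}

# sense position within gene -> contig coordinate
sense_to_genomic <- function(strand, g0, gene_len, s) {
  if (strand == "+") g0 + s - 1L else g0 + gene_len - s
}

# Resolve one junction side to transcript bookkeeping.
# Returns list(kind, sense, fused_len5-or-start bookkeeping is done by caller):
#   sense: sense coordinate of the junction-defining base
#   cdna:  mRNA coordinate (NA when intronic)
resolve_side <- function(g, spec, side, is5) {
  kind <- side$kind
  if (kind == "exon_boundary") {
    k <- as.integer(side$exon)
    cdna <- if (is5) g$cum_exon[k] else (if (k > 1L) g$cum_exon[k - 1L] else 0L) + 1L
    return(list(kind = kind, cdna = cdna, sense = mrna_to_sense(g, cdna)))
  }
  if (kind == "intra_exon") {
    k <- as.integer(side$exon)
    before <- if (k > 1L) g$cum_exon[k - 1L] else 0L
    cdna <- before + as.integer(side$offset)
    return(list(kind = kind, cdna = cdna, sense = mrna_to_sense(g, cdna)))
  }
  if (kind == "intronic") {
    j <- as.integer(side$intron)
    o <- as.integer(side$offset)
    if (j < 1L || j >= spec$n_exons || o < 1L || o > spec$intron_len[j]) {
      abort("Intronic junction outside intron bounds.")
    }
    return(list(kind = kind, cdna = NA_integer_, sense = g$exon_s_end[j] + o,
                intron = j, offset = o))
  }
  abort(paste0("Unknown junction kind: ", kind))
}

# Fused-transcript piece and its sense-coordinate map for the 5' side
# (transcript start .. junction) or the 3' side (junction .. transcript end).
fused_piece <- function(g, spec, side_res, is5) {
  map_rows <- list(); seqs <- character(0); fpos <- 0L
  add <- function(seq, s_start, s_end) {
    n <- nchar(seq)
    map_rows[[length(map_rows) + 1L]] <<- tibble(
      f_start = fpos + 1L, f_end = fpos + n, s_start = s_start, s_end = s_end
    )
    seqs <<- base::c(seqs, seq)
    fpos <<- fpos + n
  }
  if (is5) {
    if (side_res$kind == "intronic") {
      j <- side_res$intron
      for (k in seq_len(j)) {
        add(substr(g$mrna, (if (k > 1L) g$cum_exon[k - 1L] else 0L) + 1L, g$cum_exon[k]),
            g$exon_s_start[k], g$exon_s_end[k])
      }
      add(substr(g$introns[[j]], 1L, side_res$offset),
          g$exon_s_end[j] + 1L, g$exon_s_end[j] + side_res$offset)
    } else {
      cd <- side_res$cdna
      k_last <- findInterval(cd - 1L, g$cum_exon) + 1L
      for (k in seq_len(k_last)) {
        before <- if (k > 1L) g$cum_exon[k - 1L] else 0L
        hi <- min(g$cum_exon[k], cd)
        add(substr(g$mrna, before + 1L, hi),
            g$exon_s_start[k], g$exon_s_start[k] + (hi - before - 1L))
      }
    }
  } else {
    n <- length(g$cum_exon)
    if (side_res$kind == "intronic") {
      j <- side_res$intron
      ilen <- nchar(g$introns[[j]])
      add(substr(g$introns[[j]], side_res$offset, ilen),
          g$exon_s_end[j] + side_res$offset, g$exon_s_end[j] + ilen)
      from_exon <- j + 1L
      from_cdna <- g$cum_exon[j] + 1L
    } else {
      cd <- side_res$cdna
      k <- findInterval(cd - 1L, g$cum_exon) + 1L
      before <- if (k > 1L) g$cum_exon[k - 1L] else 0L
      add(substr(g$mrna, cd, g$cum_exon[k]),
          g$exon_s_start[k] + (cd - before - 1L), g$exon_s_end[k])
      from_exon <- k + 1L
      from_cdna <- g$cum_exon[k] + 1L
    }
    if (from_exon <= n) {
      for (k in from_exon:n) {
        before <- g$cum_exon[k - 1L]
        add(substr(g$mrna, before + 1L, g$cum_exon[k]),
            g$exon_s_start[k], g$exon_s_end[k])
      }
    }
  }
  list(seq = paste(seqs, collapse = ""), map = bind_rows(map_rows))
}

#' Translation oracle for fusion frame status
#'
#' Independent frame check by actual translation: the fused transcript is
#' translated from the 5' gene's start codon; the fusion is in frame exactly
#' when the first stop codon encountered is the 3' gene's own annotated stop,
#' i.e. translation runs through the junction without a premature stop and
#' terminates where the 3' protein terminates. The oracle abstains (`NA`)
#' when either junction-adjacent base lies outside its gene's CDS (intron,
#' UTR, or non-coding transcript).
#'
#' @param jt One junction-truth entry from [sim_fusion_reference()]
#'   (`$junctions[[i]]`).
#' @return `TRUE` (in frame), `FALSE` (out of frame) or `NA`.
#' @export
oracle_frame_status <- function(jt) {
  if (is.na(jt$cdna5) || is.na(jt$cdna3)) return(NA)
  if (jt$cdna5 < jt$cds_cdna5[1] || jt$cdna5 > jt$cds_cdna5[2]) return(NA)
  if (jt$cdna3 < jt$cds_cdna3[1] || jt$cdna3 > jt$cds_cdna3[2]) return(NA)
  fused <- paste0(jt$fused5, jt$fused3)
  coding <- substr(fused, jt$cds_cdna5[1], nchar(fused))
  coding <- substr(coding, 1L, nchar(coding) - nchar(coding) %% 3L)
  if (nchar(coding) < 3L) return(FALSE)
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(coding), no.init.codon = TRUE
  )), "")[[1]]
  first_stop <- which(aa == "*")[1]
  # coding-coordinate start of the 3' gene's stop codon within the fusion
  len5_coding <- jt$cdna5 - jt$cds_cdna5[1] + 1L
  expected_nt <- len5_coding + (jt$cds_cdna3[2] - 2L) - jt$cdna3 + 1L
  expected_codon <- (expected_nt - 1L) %/% 3L + 1L
  if (expected_nt %% 3L != 1L) return(FALSE)   # stop cannot land on frame
  !is.na(first_stop) && first_stop == expected_codon
}

# Replace junction-chimeric stop codons when the planted truth is in-frame:
# resample the 3'-side bases of the offending codon so neither the fused
# reading frame nor the 3' gene's native frame sees a stop there.
patch_chimeric_stop <- function(jt, g3env) {
  if (is.na(jt$cdna5) || is.na(jt$cdna3)) return(jt)
  if (jt$cdna5 < jt$cds_cdna5[1] || jt$cdna5 > jt$cds_cdna5[2]) return(jt)
  if (jt$cdna3 < jt$cds_cdna3[1] || jt$cdna3 > jt$cds_cdna3[2]) return(jt)
  c5 <- jt$cdna5 - jt$cds_cdna5[1] + 1L
  c3 <- jt$cdna3 - jt$cds_cdna3[1]
  if ((c5 %% 3L) != (c3 %% 3L)) return(jt)
  r <- c5 %% 3L
  if (r == 0L) return(jt)  # junction at codon boundary: no chimeric codon
  n5 <- nchar(jt$fused5)
  head5 <- substr(jt$fused5, n5 - r + 1L, n5)
  free_n <- 3L - r
  tail3 <- substr(jt$fused3, 1L, free_n)
  codon <- paste0(head5, tail3)
  if (!codon %in% STOP_CODONS) return(jt)
  # mRNA coordinates (3' gene) of the free bases and their native codon phase
  mpos <- jt$cdna3 + seq_len(free_n) - 1L
  bases <- expand.grid(b1 = c("A", "C", "G", "T"),
                       b2 = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bases))) {
    repl <- unlist(bases[i, seq_len(free_n)], use.names = FALSE)
    cand <- paste0(head5, paste(repl, collapse = ""))
    if (cand %in% STOP_CODONS) next
    mrna <- g3env$mrna
    for (k in seq_len(free_n)) substr(mrna, mpos[k], mpos[k]) <- repl[k]
    # check the 3' gene's own codons touching the replaced bases
    ok <- TRUE
    cs <- jt$cds_cdna3[1]
    for (p in mpos) {
      if (p < cs || p > jt$cds_cdna3[2]) next
      cstart <- cs + ((p - cs) %/% 3L) * 3L
      if (substr(mrna, cstart, cstart + 2L) %in% STOP_CODONS) ok <- FALSE
    }
    if (!ok) next
    g3env$mrna <- mrna
    return(jt)  # caller rebuilds fused pieces from the patched mRNA
  }
  abort("Could not resolve a chimeric junction stop codon.")  # unreachable
}

#' Build the synthetic reference for a fusion scenario
#'
#' Generates seeded random gene sequences (stop-free CDS interiors with
#' planted start/stop codons), lays the genes out on contigs, derives
#' transcript models, and resolves every planted junction to genomic
#' breakpoint coordinates, fused-transcript sequences, cDNA bookkeeping and
#' expected exon-boundary flags. Identical seeds give identical output.
#'
#' @param scenario A [fusion_scenario()].
#' @param seed Integer seed.
#' @return A list: `genome` (named character vector of contig sequences),
#'   `models` (transcript-model tibble), `genes` (internal layout), and
#'   `junctions` (one truth entry per planted junction: `bp5`, `bp3`,
#'   `chrom5`, `chrom3`, `cdna5/3`, `cds_cdna5/3`, `fused5/3` sequences and
#'   maps, boundary flags and `frame` from the translation oracle).
#' @export
sim_fusion_reference <- function(scenario, seed = 1L) {
  with_seed(seed, {
    sc <- scenario
    flank <- 500L
    g5 <- build_gene_seqs(sc$gene5)
    g3 <- if (sc$intragenic) g5 else build_gene_seqs(sc$gene3)
    if (sc$intragenic) {
      chrom5 <- chrom3 <- "chrA"
      g5_0 <- g3_0 <- flank + 1L
    } else if (sc$same_contig) {
      chrom5 <- chrom3 <- "chrT"
      g5_0 <- flank + 1L
      g3_0 <- g5_0 + g5$gene_len + sc$contig_gap
    } else {
      chrom5 <- "chrA"; chrom3 <- "chrB"
      g5_0 <- flank + 1L
      g3_0 <- flank + 1L
    }

    g5env <- as.environment(g5)
    g3env <- if (sc$intragenic) g5env else as.environment(g3)

    junctions <- map(sc$junctions, function(jspec) {
      s5 <- resolve_side(g5, sc$gene5, jspec$side5, is5 = TRUE)
      s3 <- resolve_side(g3, sc$gene3, jspec$side3, is5 = FALSE)
      cds_cdna5 <- base::c(sc$gene5$utr5 + 1L, sc$gene5$utr5 + sc$gene5$cds_len)
      cds_cdna3 <- base::c(sc$gene3$utr5 + 1L, sc$gene3$utr5 + sc$gene3$cds_len)
      jt <- list(
        spec = jspec, side5 = s5, side3 = s3,
        cdna5 = s5$cdna, cdna3 = s3$cdna,
        cds_cdna5 = cds_cdna5, cds_cdna3 = cds_cdna3
      )
      p5 <- fused_piece(as.list(g5env), sc$gene5, s5, is5 = TRUE)
      p3 <- fused_piece(as.list(g3env), sc$gene3, s3, is5 = FALSE)
      jt$fused5 <- p5$seq; jt$fused3 <- p3$seq
      jt <- patch_chimeric_stop(jt, g3env)
      jt$map5 <- p5$map
      jt$chrom5 <- chrom5; jt$chrom3 <- chrom3
      jt$bp5 <- sense_to_genomic(sc$gene5$strand, g5_0, g5env$gene_len, s5$sense)
      jt$bp3 <- sense_to_genomic(sc$gene3$strand, g3_0, g3env$gene_len, s3$sense)
      jt
    })
    # second pass: all patches are in, rebuild the 3' pieces and take frames
    junctions <- map(junctions, function(jt) {
      p3 <- fused_piece(as.list(g3env), sc$gene3, jt$side3, is5 = FALSE)
      jt$fused3 <- p3$seq
      jt$map3 <- p3$map
      jt$frame <- oracle_frame_status(jt)
      jt
    })

    contig5 <- paste0(random_dna(flank),
                      if (sc$gene5$strand == "+") g5env$sense else revcomp(g5env$sense),
                      random_dna(flank))
    genomic3 <- local({
      # rebuild the 3' sense genomic from the (possibly patched) mRNA
      pieces <- character(0)
      for (k in seq_len(sc$gene3$n_exons)) {
        before <- if (k > 1L) g3env$cum_exon[k - 1L] else 0L
        pieces <- base::c(pieces, substr(g3env$mrna, before + 1L, g3env$cum_exon[k]))
        if (k < sc$gene3$n_exons) pieces <- base::c(pieces, g3env$introns[[k]])
      }
      paste(pieces, collapse = "")
    })
    g3env$sense <- genomic3
    contig3 <- paste0(random_dna(flank),
                      if (sc$gene3$strand == "+") genomic3 else revcomp(genomic3),
                      random_dna(flank))

    genome <- if (sc$intragenic) {
      stats::setNames(paste0(
        random_dna(flank),
        if (sc$gene3$strand == "+") genomic3 else revcomp(genomic3),
        random_dna(flank)
      ), "chrA")
    } else if (sc$same_contig) {
      stats::setNames(paste0(
        random_dna(flank),
        if (sc$gene5$strand == "+") g5env$sense else revcomp(g5env$sense),
        random_dna(sc$contig_gap),
        if (sc$gene3$strand == "+") genomic3 else revcomp(genomic3),
        random_dna(flank)
      ), "chrT")
    } else {
      stats::setNames(base::c(contig5, contig3), base::c("chrA", "chrB"))
    }

    decoys <- NULL
    if (sc$repeat_partner) {
      gene5_genomic <- if (sc$gene5$strand == "+") g5env$sense else revcomp(g5env$sense)
      n_extra <- max(2L, sc$n_repeat_copies - 1L)
      gap <- 400L
      pieces <- character(0); offsets <- integer(n_extra); at <- 0L
      for (i in seq_len(n_extra)) {
        pieces <- base::c(pieces, random_dna(gap), gene5_genomic)
        offsets[i] <- at + gap + 1L
        at <- at + gap + nchar(gene5_genomic)
      }
      pieces <- base::c(pieces, random_dna(gap))
      genome <- base::c(genome, stats::setNames(paste(pieces, collapse = ""), "chrDecoy"))
      decoys <- tibble(chrom = "chrDecoy", offset = offsets)
    }

    genes <- list(
      gene5 = list(spec = sc$gene5, chrom = chrom5, g0 = g5_0,
                   gene_len = g5env$gene_len, build = as.list(g5env)),
      gene3 = list(spec = sc$gene3, chrom = chrom3, g0 = g3_0,
                   gene_len = g3env$gene_len, build = as.list(g3env))
    )
    models <- sim_models(genes)
    junctions <- map(junctions, function(jt) {
      jt$on_boundary5 <- jt$bp5 %in% gene_exon_termini(models, sc$gene5$name, "donor")
      jt$on_boundary3 <- jt$bp3 %in% gene_exon_termini(models, sc$gene3$name, "acceptor")
      jt$boundary_status <- base::c("none", "one", "both")[1L + jt$on_boundary5 + jt$on_boundary3]
      jt
    })
    list(genome = genome, models = models, genes = genes,
         junctions = junctions, scenario = sc, decoys = decoys, seed = seed)
  })
}

# Transcript-model tibble for the two simulated genes.
sim_models <- function(genes) {
  single <- genes$gene5$spec$name == genes$gene3$spec$name &&
    genes$gene5$g0 == genes$gene3$g0 &&
    genes$gene5$chrom == genes$gene3$chrom
  row_for <- function(g) {
    spec <- g$spec; b <- g$build
    s <- map_int(seq_len(spec$n_exons), function(k) {
      sense_to_genomic(spec$strand, g$g0, g$gene_len, b$exon_s_start[k])
    })
    e <- map_int(seq_len(spec$n_exons), function(k) {
      sense_to_genomic(spec$strand, g$g0, g$gene_len, b$exon_s_end[k])
    })
    starts <- pmin(s, e); ends <- pmax(s, e)
    o <- order(starts)
    cds_t <- base::c(spec$utr5 + 1L, spec$mrna_len - spec$utr3)
    cds_g <- sort(base::c(
      sense_to_genomic(spec$strand, g$g0, g$gene_len, mrna_to_sense(b, cds_t[1])),
      sense_to_genomic(spec$strand, g$g0, g$gene_len, mrna_to_sense(b, cds_t[2]))
    ))
    tibble(
      gene = spec$name, transcript_id = paste0(spec$name, ".t1"),
      chrom = g$chrom, strand = spec$strand,
      tx_start = min(starts), tx_end = max(ends),
      cds_start = cds_g[1], cds_end = cds_g[2],
      exon_starts = list(starts[o]), exon_ends = list(ends[o])
    )
  }
  rows <- if (single) row_for(genes$gene5) else
    bind_rows(row_for(genes$gene5), row_for(genes$gene3))
  finish_models(rows)
}
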