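# Read emission for simulated fusion scenarios: AMP-style split reads with
# SA/XA tags, FASTQ, SAM text, and per-read truth rows.

# Map the read's coverage of one fused side to genomic alignment blocks.
side_blocks <- function(jt, gene, fmap, f_lo, f_hi, rpos_of_f) {
  hit <- fmap[fmap$f_end >= f_lo & fmap$f_start <= f_hi, ]
  if (nrow(hit) == 0L) return(tibble())
  g0 <- gene$g0; gl <- gene$gene_len; strand <- gene$spec$strand
  rows <- map(seq_len(nrow(hit)), function(i) {
    b <- hit[i, ]
    lo <- max(b$f_start, f_lo); hi <- min(b$f_end, f_hi)
    ss <- b$s_start + (lo - b$f_start)
    se <- b$s_start + (hi - b$f_start)
    if (strand == "+") {
      gs <- g0 + ss - 1L; ge <- g0 + se - 1L; st <- "+"
    } else {
      gs <- g0 + gl - se; ge <- g0 + gl - ss; st <- "-"
    }
    tibble(r1 = rpos_of_f(lo), r2 = rpos_of_f(hi),
           chrom = gene$chrom, gstart = gs, gend = ge, strand = st)
  })
  bind_rows(rows)
}

block_cigar <- function(r1, r2, read_length, strand, clip_char) {
  lead <- if (strand == "+") r1 - 1L else read_length - r2
  trail <- if (strand == "+") read_length - r2 else r1 - 1L
  paste0(
    if (lead > 0L) paste0(lead, clip_char) else "",
    r2 - r1 + 1L, "M",
    if (trail > 0L) paste0(trail, clip_char) else ""
  )
}

random_umis <- function(n, len = 8L) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(base::c(out, vapply(seq_len(n), function(i) {
      paste(sample(base::c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))))
  }
  out[seq_len(n)]
}

#' Emit aligned split reads for a simulated fusion reference
#'
#' For every planted junction, reads crossing the junction are emitted
#' directly as aligned SAM records, mirroring the BWA-MEM split-read
#' contract: the record covering the read start (the ligation end) is the
#' primary alignment with soft clips, every other alignment block is a
#' supplementary record with hard clips, and each record carries an `SA` tag
#' listing the others. Partner ends are planted as distinct split positions
#' (hence distinct ligation sites), UMIs are appended to read names in
#' anchored mode, planned duplicates share a UMI and ligation site, and
#' per-base errors are injected at the scenario's `error_rate`. In
#' repeat-partner mode the 5'-side primaries point at a decoy gene copy with
#' MAPQ 0 and `XA` alternatives including the annotated copy.
#'
#' @param ref Output of [sim_fusion_reference()].
#' @param seed Integer seed.
#' @return A list: `records` (one row per SAM line), `reads` (per-read truth:
#'   UMI, split position, expected ligation site), `truth` (per-junction
#'   expectations: junction string, dedup count, partner ends, frame and
#'   boundary truth), and `sam_lines`/`fastq_lines`.
#' @export
sim_fusion_reads <- function(ref, seed = 1L) {
  with_seed(seed, {
    sc <- ref$scenario
    L <- sc$read_length
    cc <- sc$adaptor_clip
    n_j <- length(ref$junctions)
    total_umis <- sum(map_int(ref$junctions, ~ .x$spec$n_umis))
    umi_pool <- random_umis(total_umis)
    umi_at <- 0L

    all_records <- list(); all_reads <- list(); truth_rows <- list()
    for (j in seq_len(n_j)) {
      jt <- ref$junctions[[j]]
      jspec <- jt$spec
      n5 <- nchar(jt$fused5); n3 <- nchar(jt$fused3)
      s_min <- max(30L, L - cc - n3)
      s_max <- min(L - cc - 30L, n5)
      if (s_min > s_max) {
        abort(sprintf(
          "Junction %d too close to a transcript end for %d-base reads.", j, L))
      }
      if (s_max - s_min + 1L < jspec$n_partner_ends) {
        abort(sprintf("Junction %d cannot host %d distinct partner ends.",
                      j, jspec$n_partner_ends))
      }
      n_pe <- jspec$n_partner_ends
      s_vals <- if (n_pe == 1L) s_min else {
        s_min + as.integer(floor((0:(n_pe - 1L)) * (s_max - s_min) / (n_pe - 1L)))
      }
      umis <- umi_pool[umi_at + seq_len(jspec$n_umis)]
      umi_at <- umi_at + jspec$n_umis
      umi_pe <- rep(seq_len(n_pe), length.out = jspec$n_umis)
      read_umi <- rep(seq_len(jspec$n_umis), length.out = jspec$n_reads)

      for (i in seq_len(jspec$n_reads)) {
        ui <- read_umi[i]
        s <- s_vals[umi_pe[ui]]
        umi <- if (sc$anchored) umis[ui] else ""
        rid <- sprintf("%s:J%d:R%05d", sc$sample_id, j, i)
        qname <- if (sc$anchored) paste0(rid, "_UMI:", umi) else rid

        prefix <- if (cc > 0L) random_dna(cc) else ""
        seq5 <- substr(jt$fused5, n5 - s + 1L, n5)
        seq3 <- substr(jt$fused3, 1L, L - cc - s)
        read_seq <- paste0(prefix, seq5, seq3)
        if (sc$error_rate > 0) {
          pos_err <- which(runif(L) < sc$error_rate)
          for (p in pos_err) {
            cur <- substr(read_seq, p, p)
            substr(read_seq, p, p) <- sample(setdiff(base::c("A", "C", "G", "T"), cur), 1L)
          }
        }

        b5 <- side_blocks(jt, ref$genes$gene5, jt$map5,
                          n5 - s + 1L, n5,
                          function(f) cc + (f - (n5 - s)))
        b3 <- side_blocks(jt, ref$genes$gene3, jt$map3,
                          1L, L - cc - s,
                          function(f) cc + s + f)
        b5$side <- "5"; b3$side <- "3"
        blocks <- bind_rows(b5, b3)
        blocks$mapq <- 60L
        blocks$xa <- NA_character_

        if (sc$repeat_partner) {
          i5 <- which(blocks$side == "5")
          if (length(i5) != 1L) {
            abort("Repeat-partner scenarios require a single 5'-side alignment block.")
          }
          tru <- blocks[i5, ]
          g0 <- ref$genes$gene5$g0
          dec <- ref$decoys
          cig <- block_cigar(tru$r1, tru$r2, L, tru$strand, "S")
          alt <- base::c(
            sprintf("%s,%s%d,%s,0", tru$chrom, tru$strand, tru$gstart, cig),
            if (nrow(dec) > 1L) sprintf("%s,%s%d,%s,0", dec$chrom[-1],
                                        tru$strand,
                                        tru$gstart - g0 + dec$offset[-1], cig)
          )
          blocks$chrom[i5] <- dec$chrom[1]
          blocks$gstart[i5] <- tru$gstart - g0 + dec$offset[1]
          blocks$gend[i5] <- tru$gend - g0 + dec$offset[1]
          blocks$mapq[i5] <- 0L
          blocks$xa[i5] <- paste0(paste(alt, collapse = ";"), ";")
        }

        nb <- nrow(blocks)
        cigs_own <- vapply(seq_len(nb), function(k) {
          block_cigar(blocks$r1[k], blocks$r2[k], L, blocks$strand[k],
                      if (k == 1L) "S" else "H")
        }, character(1))
        sa_entry <- sprintf("%s,%d,%s,%s,%d,0", blocks$chrom, blocks$gstart,
                            blocks$strand, cigs_own, blocks$mapq)
        recs <- map(seq_len(nb), function(k) {
          others <- setdiff(seq_len(nb), k)
          seq_k <- if (k == 1L) read_seq else
            substr(read_seq, blocks$r1[k], blocks$r2[k])
          tibble(
            qname = qname,
            flag = (if (blocks$strand[k] == "-") 16L else 0L) +
              (if (k == 1L) 0L else 2048L),
            chrom = blocks$chrom[k], pos = blocks$gstart[k],
            mapq = blocks$mapq[k], cigar = cigs_own[k],
            seq = seq_k, qual = strrep("I", nchar(seq_k)),
            sa = paste0(paste(sa_entry[others], collapse = ";"), ";"),
            xa = blocks$xa[k],
            junction_idx = j
          )
        })
        all_records <- base::c(all_records, recs)

        prim <- blocks[1, ]
        ls_expected <- if (prim$strand == "+") prim$gstart - cc else prim$gend + cc
        all_reads[[length(all_reads) + 1L]] <- tibble(
          read_id = rid, qname = qname, umi = umi, junction_idx = j,
          split_pos = s, adaptor_clip = cc,
          ls_chrom = prim$chrom, ls_pos = ls_expected, seq = read_seq
        )
      }

      truth_rows[[j]] <- tibble(
        junction_idx = j,
        fusion_name = paste0(sc$gene5$name, "::", sc$gene3$name),
        junction = paste0(jt$chrom5, ":", jt$bp5, "_", jt$chrom3, ":", jt$bp3),
        chrom5 = jt$chrom5, bp5 = jt$bp5, chrom3 = jt$chrom3, bp3 = jt$bp3,
        n_reads = jspec$n_reads, n_umis = jspec$n_umis,
        n_partner_ends = jspec$n_partner_ends,
        frame = list(jt$frame),
        on_boundary5 = jt$on_boundary5, on_boundary3 = jt$on_boundary3,
        boundary_status = jt$boundary_status
      )
    }

    records <- bind_rows(all_records)
    reads <- bind_rows(all_reads)
    truth <- bind_rows(truth_rows) |>
      mutate(frame_status = map_chr(.data$frame, function(f) {
        if (is.na(f)) "NA" else if (f) "in-frame" else "out-of-frame"
      })) |>
      select(-"frame")

    hdr <- base::c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome), nchar(ref$genome))
    )
    tags <- paste0(
      "SA:Z:", records$sa,
      ifelse(is.na(records$xa), "", paste0("\tXA:Z:", records$xa))
    )
    body <- paste(records$qname, records$flag, records$chrom, records$pos,
                  records$mapq, records$cigar, "*", 0L, 0L, records$seq,
                  records$qual, tags, sep = "\t")
    sam_lines <- base::c(hdr, body)
    prim_reads <- reads
    fastq_lines <- as.vector(rbind(paste0("@", prim_reads$qname),
                                   prim_reads$seq, "+",
                                   strrep("I", nchar(prim_reads$seq))))

    list(records = records, reads = reads, truth = truth,
         sam_lines = sam_lines, fastq_lines = fastq_lines, seed = seed)
  })
}

#' Write a simulated dataset to disk
#'
#' Builds the reference and reads for a scenario and writes genome FASTA,
#' refFlat and GTF transcript models, aligned SAM, FASTQ, a truth JSON, and —
#' in repeat-partner mode — the pseudogene BED covering the annotated copy.
#' Identical seeds produce byte-identical files.
#'
#' @param scenario A [fusion_scenario()].
#' @param seed Integer seed (reads use `seed + 1`).
#' @param dir Output directory (created if needed); `NULL` keeps everything
#'   in memory.
#' @return A list with `ref`, `reads`, and `paths` (when `dir` is given).
#' @export
sim_fusion_dataset <- function(scenario, seed = 1L, dir = NULL) {
  ref <- sim_fusion_reference(scenario, seed)
  reads <- sim_fusion_reads(ref, seed + 1L)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "genome.fa"),
      refflat = file.path(dir, "models.refFlat"),
      gtf = file.path(dir, "models.gtf"),
      sam = file.path(dir, "reads.sam"),
      fastq = file.path(dir, "reads.fastq"),
      truth = file.path(dir, "truth.json")
    )
    write_sim_fasta(ref$genome, paths$fasta)
    write_sim_refflat(ref$models, paths$refflat)
    write_sim_gtf(ref$models, paths$gtf)
    readr::write_lines(reads$sam_lines, paths$sam)
    readr::write_lines(reads$fastq_lines, paths$fastq)
    jsonlite::write_json(
      list(scenario_sample = scenario$sample_id, seed = seed,
           junctions = reads$truth),
      paths$truth, auto_unbox = TRUE, digits = NA
    )
    if (scenario$repeat_partner) {
      paths$pseudogene_bed <- file.path(dir, "pseudogene.bed")
      m5 <- ref$models[ref$models$gene == scenario$gene5$name, ][1, ]
      readr::write_lines(
        sprintf("%s\t%d\t%d\t%s", m5$chrom, m5$tx_start - 1L, m5$tx_end,
                paste0(m5$gene, "_region")),
        paths$pseudogene_bed
      )
    }
  }
  list(ref = ref, reads = reads, paths = paths)
}

#' @rdname sim_fusion_dataset
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_sim_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname sim_fusion_dataset
#' @param models A transcript-model tibble.
#' @export
write_sim_refflat <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    cds0 <- if (is.na(m$cds_start)) base::c(m$tx_end, m$tx_end) else
      base::c(m$cds_start - 1L, m$cds_end)
    paste(m$gene, m$transcript_id, m$chrom, m$strand,
          m$tx_start - 1L, m$tx_end, cds0[1], cds0[2], m$n_exons,
          paste0(paste(m$exon_starts[[1]] - 1L, collapse = ","), ","),
          paste0(paste(m$exon_ends[[1]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname sim_fusion_dataset
#' @export
write_sim_gtf <- function(models, path) {
  lines <- character(0)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                     m$gene, m$gene, m$transcript_id)
    s <- m$exon_starts[[1]]; e <- m$exon_ends[[1]]
    lines <- base::c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                                    m$chrom, s, e, m$strand, attrs))
    if (!is.na(m$cds_start)) {
      cs <- pmax(s, m$cds_start); ce <- pmin(e, m$cds_end)
      keep <- cs <= ce
      lines <- base::c(lines, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                      m$chrom, cs[keep], ce[keep], m$strand, attrs))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}
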