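#' Run the complete split-read fusion-calling pipeline
#'
#' End-to-end driver: read primary alignments, compute soft-clip-adjusted
#' ligation sites, consolidate PCR duplicates by UMI and ligation site, expand
#' `SA` tags into alignment segments (optionally rescuing MAPQ-0 segments in
#' designated repetitive regions), lay out query/reference coordinates with
#' CIGAR smoothing, detect and filter candidate junctions, and aggregate them
#' into annotated fusion calls with exon-boundary, frame and target-event
#' status. When `out_dir` is given, the run writes `summary.tsv`,
#' `junctions.tsv` (including rejected junctions for diagnostics),
#' `run_meta.json`, and per-call supporting reads under `supporting_reads/`.
#'
#' @param input Path to a SAM/BAM file, or a records tibble in
#'   [read_split_sam()] layout.
#' @param models Transcript models: a tibble from [read_refflat()] /
#'   [read_gtf_models()], or a path (`.refFlat`/`.txt` vs `.gtf` by
#'   extension).
#' @param config A [fusion_config()].
#' @param sample_id Sample identifier stamped on the summary.
#' @param out_dir Optional output directory.
#' @param pseudogene_regions Optional BED path or tibble from
#'   [read_bed_regions()]; activates repeat/pseudogene rescue.
#' @param panel Optional BED path or regions tibble; restricts calls to
#'   junctions touching the panel.
#' @param targets Optional target-events TSV path or tibble from
#'   [read_target_events()]; activates Target mode (intragenic candidates and
#'   whitelist matching).
#' @param blacklist Optional blacklist TSV path or tibble from
#'   [read_blacklist()].
#' @return A `fusion_result` object: list with `summary` (the report tibble),
#'   `calls` (all junctions incl. rejected, `called` flag), `records`,
#'   `segments`, `candidates`, counts, `config`, and output `paths`.
#' @export
run_fusion_pipeline <- function(input, models, config = fusion_config(),
                                sample_id = "sample", out_dir = NULL,
                                pseudogene_regions = NULL, panel = NULL,
                                targets = NULL, blacklist = NULL) {
  models <- resolve_models(models)
  pseudogene_regions <- resolve_regions(pseudogene_regions)
  panel <- resolve_regions(panel)
  if (is.character(targets)) targets <- read_target_events(targets, models)
  if (is.character(blacklist)) blacklist <- read_blacklist(blacklist)

  records <- if (is.character(input)) {
    read_split_sam(input, umi_regex = config$umi_regex)
  } else {
    input
  }
  n_input <- nrow(records)
  records <- compute_ligation_sites(records, ligation_end = config$ligation_end)
  consolidated <- dedup_reads(records, dedup = config$dedup)
  segments <- expand_alignments(consolidated, keep_unsplit = FALSE)
  if (!is.null(pseudogene_regions)) {
    segments <- remap_pseudogene_segments(segments, pseudogene_regions)
  }
  segments <- layout_segments(segments,
                              max_smoothed_indel = config$max_smoothed_indel)
  cands <- detect_junction_candidates(
    segments,
    max_intron_distance = config$max_intron_distance,
    keep_intragenic = !is.null(targets)
  )
  n_candidates <- nrow(cands)
  cands <- assign_end_roles(cands, mode = config$end_mode)
  cands <- filter_junction_candidates(cands, config)
  calls <- call_fusions(cands, models, config, targets = targets,
                        keep_rejected = TRUE)
  called <- filter(calls, .data$called)
  called <- restrict_to_panel(called, panel)
  called <- apply_blacklist(called, blacklist)
  summ <- write_fusion_summary(called, sample_id = sample_id)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      summary = file.path(out_dir, "summary.tsv"),
      junctions = file.path(out_dir, "junctions.tsv"),
      meta = file.path(out_dir, "run_meta.json")
    )
    readr::write_tsv(summ, paths$summary, progress = FALSE)
    readr::write_tsv(
      calls[, !vapply(calls, is.list, logical(1))],
      paths$junctions, progress = FALSE
    )
    jsonlite::write_json(
      list(
        sample_id = sample_id,
        n_input_reads = n_input,
        n_consolidated_reads = nrow(consolidated),
        n_split_candidates = n_candidates,
        n_junctions = nrow(calls),
        n_called = nrow(summ),
        config = unclass(config)
      ),
      paths$meta, auto_unbox = TRUE, digits = NA
    )
    if (nrow(called) > 0L && all(c("seq", "qual") %in% names(consolidated))) {
      sup_dir <- file.path(out_dir, "supporting_reads")
      dir.create(sup_dir, showWarnings = FALSE)
      for (i in seq_len(nrow(called))) {
        stem <- file.path(sup_dir, sprintf(
          "%s_%s", gsub("[^A-Za-z0-9_.-]", "-", called$fusion_name[i]),
          gsub("[^A-Za-z0-9_.-]", "-", called$junction[i])
        ))
        sup <- consolidated |>
          mutate(sa = .data$sa) |>
          filter(.data$read_id %in% unlist(called$read_ids[i]))
        extract_supporting_reads(
          called[i, ], sup,
          n = config$n_extract_reads, seed = config$seed,
          fastq_path = paste0(stem, ".fastq"),
          sam_path = paste0(stem, ".sam")
        )
      }
      paths$supporting_reads <- sup_dir
    }
  }

  structure(
    list(
      summary = summ, calls = calls, records = consolidated,
      segments = segments, candidates = cands,
      n_input_reads = n_input, n_consolidated_reads = nrow(consolidated),
      n_split_candidates = n_candidates,
      sample_id = sample_id, config = config, paths = paths
    ),
    class = "fusion_result"
  )
}

resolve_models <- function(models) {
  if (is.character(models)) {
    if (grepl("\\.gtf(\\.gz)?$", models, ignore.case = TRUE)) {
      read_gtf_models(models)
    } else {
      read_refflat(models)
    }
  } else {
    models
  }
}

resolve_regions <- function(x) {
  if (is.character(x)) read_bed_regions(x) else x
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> sample %s\n", x$sample_id))
  cat(sprintf("  input reads:        %d\n", x$n_input_reads))
  cat(sprintf("  after consolidation:%d\n", x$n_consolidated_reads))
  cat(sprintf("  junction candidates:%d\n", x$n_split_candidates))
  cat(sprintf("  called fusions:     %d\n", nrow(x$summary)))
  if (nrow(x$summary) > 0L) {
    print(select(x$summary, any_of(base::c(
      "fusion_name", "junction", "n_umi_reads", "n_partner_ends",
      "frame_status", "boundary_status"
    ))))
  }
  invisible(x)
}

#' Tidy a fusion-calling result
#'
#' Returns the per-junction summary tibble, one row per called fusion
#' junction with its support and annotation.
#'
#' @param x A `fusion_result` from [run_fusion_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fusion_result
#' @export
tidy.fusion_result <- function(x, ...) {
  x$summary
}

#' Glance at a fusion-calling result
#'
#' One-row run-level summary: read, candidate and call counts plus frame
#' breakdown.
#'
#' @param x A `fusion_result` from [run_fusion_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_input_reads = x$n_input_reads,
    n_consolidated_reads = x$n_consolidated_reads,
    n_split_candidates = x$n_split_candidates,
    n_junctions = nrow(x$calls),
    n_called = nrow(x$summary),
    n_in_frame = sum(x$summary$frame_status == "in-frame"),
    n_subclone_pairs = nrow(count_subclones(x$summary))
  )
}

#' Plot junction support for a fusion-calling result
#'
#' Horizontal bars of UMI-read support per called junction, coloured by frame
#' status, with partner-end counts as labels.
#'
#' @param object A `fusion_result` from [run_fusion_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_result
#' @export
autoplot.fusion_result <- function(object, ...) {
  summ <- object$summary
  if (nrow(summ) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "No fusions called") +
             ggplot2::theme_void())
  }
  summ <- mutate(summ, label = paste0(.data$fusion_name, "\n", .data$junction))
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$n_umi_reads,
    y = stats::reorder(.data$label, .data$n_umi_reads),
    fill = .data$frame_status
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n_partner_ends, " ends")),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = base::c(0, 0.15))) +
    ggplot2::labs(x = "UMI reads", y = NULL, fill = "Frame",
                  title = paste0("Fusion junction support - ", object$sample_id)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fusion_result
#' @export
plot_junction_support <- function(object, ...) {
  autoplot(object, ...)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
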