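---
title: "Calling gene fusions from split-read alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gene fusions from split-read alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseseq)
```

This vignette describes the method implemented by `fuseseq`: the model of a
split (chimeric) read, the junction-calling rules and their parameters, the
annotation arithmetic, the design of the seeded simulator used for
validation, and the numerical and representational choices made along the
way — including what the synthetic fixtures do *not* demonstrate.

## 1. Input model

The caller starts from SAM records produced by a local aligner (BWA-MEM
conventions are assumed). A read spanning a fusion junction receives a
**primary** alignment for one part and **supplementary** alignments for the
rest, summarized in the primary record's `SA:Z` tag as
`chrom,pos,strand,cigar,mapq,nm;`. `read_split_sam()` consumes the eleven
standard fields plus the `SA` and `XA` optional tags and nothing else;
records flagged unmapped, secondary, or supplementary are dropped (the
supplementary information is recovered from `SA`, which keeps one row per
*read* at this stage).

Library structure is carried in the read name. For UMI libraries the name
ends in `:UMI` (e.g. `frag12:ACGTACGT`); `parse_read_meta()` strips it. For
paired-end input, read 2 (`flag & 128`) is the anchored (primer-side) mate.

### Ligation site

In an anchored multiplex PCR (AMP) library every source molecule has exactly
one ligation point, so (UMI, ligation site) identifies a molecule. The
ligation site is the soft-clip-adjusted outer coordinate of the ligated end:

* plus strand: `pos − leading_clip`, clamped to ≥ 1;
* minus strand: `pos + ref_span − 1 + trailing_clip`.

The clip adjustment matters: two PCR duplicates of the same molecule may be
clipped differently by the aligner, yet project to the same ligation site.
`dedup_reads()` collapses reads sharing `(UMI, ligation site)` and keeps the
highest-MAPQ representative (ties broken by read id for determinism). Three
modes are supported: `"umi_ls"` (default; reads with an empty UMI are never
collapsed), `"ls"` (ligation site only, for UMI-free libraries), and
`"off"`.

## 2. Split layout

`expand_alignments()` turns each read into one row per alignment segment
(primary plus each `SA` entry). `layout_segments()` then computes, per
segment, which bases *of the read as sequenced* it covers:

1. The CIGAR is parsed (`X`/`=` fold into `M`, `P` dropped) and **smoothed**:
   insertions and deletions of at most 1 base flanked by `M` runs are
   absorbed, repeatedly to a fixpoint. A 1-base indel is alignment noise,
   not a breakpoint, and left unsmoothed it would split one physical
   segment into two and create a spurious "junction" with itself.
2. The query interval is `[lead_clip + 1, lead_clip + mapped_len]`,
   reflected on the minus strand (`start' = L − end + 1`) so all segments of
   a read share one coordinate system. Hard clips are treated as
   query-consuming, since aligners emit them on supplementary records in
   place of the primary's soft clips.
3. Segments are sorted by query start; adjacent pairs in this order are the
   potential junctions.

**Numerical choice — smoothing invariant.** A run of `M` operations merged
across an indel cannot preserve both the query extent and the reference
extent of the original operations. The package preserves the *query* extent
(an absorbed insertion adds its length to the merged run; a deletion adds
nothing), because query coordinates drive the overlap/gap geometry of the
junction. Reference spans — used for `ref_end` and the minus-strand
ligation site — are always measured on the **raw** operations, so genomic
coordinates are never perturbed by smoothing.

## 3. Junction candidates

Two consecutive segments of a read are joinable by ordinary splicing when
they lie on the same chromosome and strand, in colinear order, within the
largest plausible intron: **750,000 bases** (strictly more than 750,000
separates them into a candidate; exactly 750,000 is absorbed as splicing).
`detect_junction_candidates()` partitions each read's segments into
splicing-joinable blocks and emits one candidate per adjacent block pair:
the left end is the *last* segment of the earlier block, the right end the
*first* segment of the later block. Different chromosome, different strand,
reversed order, or excess distance all break a block.

With `keep_intragenic = TRUE` (enabled automatically in target mode),
within-block neighbor pairs are additionally emitted and flagged, so that
whitelisted intragenic events (exon skipping, intra-gene deletions) can be
matched; they are never called as fusions otherwise.

Each candidate records the query-space **overlap** (both sides claiming the
same read bases, typical of micro-homology at the junction) or **gap**
(unaligned bases between the sides).

## 4. Filters

`assign_end_roles()` labels one end of each candidate the **ligation end**
and the other the **anchored end**. In `"anchored"` mode (AMP libraries)
the anchored end is the primer-proximal side — read 2, or the right end of
read 1; in `"plain"` mode both ends are held to the ligation-end standard.
`filter_junction_candidates()` keeps a candidate when:

| parameter | default | meaning |
| --- | --- | --- |
| `min_ligation_len` | 25 | mapped query bases on the ligation-end side |
| `min_anchored_len` | 18 | mapped query bases on the anchored side |
| `max_overlap` | 6 | query-space overlap between the sides |
| `max_gap` | 5 | unaligned query bases between the sides |
| `max_intron_distance` | 750000 | same-chromosome splicing absorption |

All are fields of `fusion_config()` and flow through
`run_fusion_pipeline()`. The asymmetric length thresholds reflect the
library: the anchored side begins at a known primer, so less flanking
evidence is needed to trust it.

## 5. Breakpoints, orientation and grouping

For each surviving candidate the breakpoint on each side is the junction-
facing reference coordinate of that segment. The **5' partner** is the side
whose alignment strand matches its gene's annotated strand (the fused
transcript reads through it first); the other side is the 3' partner. When
the two sides overlap on the read, the overlapping bases are assigned to
the 5' side and the 3' (acceptor) breakpoint retreats `overlap` bases
inward, resolving the micro-homology ambiguity in favor of the donor.

Candidates from different reads supporting the same event are grouped by
the raw breakpoint pair. Per junction the caller reports `n_umi_reads`
(consolidated molecules) and `n_partner_ends` (distinct ligation sites —
independent source fragments, the stronger evidence unit, since PCR
duplicates cannot inflate it).

## 6. Annotation and the exon-boundary/frame rules

`annotate_breakpoints()` looks up gene, exon and cDNA position against
transcript models (`read_refflat()` or `read_gtf_models()`; one canonical
transcript per gene is chosen by longest CDS, then longest transcript, then
id). The gene/exon lookup uses a coordinate shifted **6 bases inward** from
the breakpoint: micro-homologous sequence lets alignments extend slightly
past the true junction, and a breakpoint that has crossed a few bases into
the intron should still be attributed to the adjacent exon. The cDNA
position is taken at the unshifted coordinate. When the breakpoint is
outside the canonical transcript, other isoforms are tried and the fallback
flagged.

`judge_exon_boundary()` is exact (tolerance 0): the 5' breakpoint must
equal a donor terminus, the 3' breakpoint an acceptor terminus, of an
annotated exon on the gene's strand. The call threshold then depends on
boundary status:

* both breakpoints on exon boundaries → **1** partner end suffices;
* exactly one on a boundary → **3** partner ends required;
* neither → not called (reported among rejected candidates).

This encodes the biological prior that genuine fusion transcripts are
spliced: exon-boundary junctions are enormously more likely to be real, so
a single independent molecule is accepted, whereas a non-boundary junction
needs corroboration.

**Frame.** With `c5` = coding bases of the 5' gene retained
(`cdna5 − cds_start + 1`) and `c3` = coding bases of the 3' gene lost
(`cdna3 − cds_start`), the fusion preserves reading frame iff
`c5 mod 3 == c3 mod 3`. Breakpoints in UTRs or introns yield `NA` — frame
is undefined when the junction is not inside both coding regions.

## 7. Special modes

**Pseudogene/repeat rescue.** Reads from genes with processed pseudogenes
(DUX4, CIC partners, …) map with MAPQ 0 and carry the true location only in
the `XA:Z` alternatives. `remap_pseudogene_segments()` takes a BED file of
regions of interest; a MAPQ-0 segment whose primary position already
overlaps a region is kept, otherwise its coordinates are replaced by the
first overlapping `XA` alternative (flagged `remapped`). Rescue can flip a
junction's boundary status from "one" to "both" and thereby its threshold
from 3 to 1 — which is exactly the regime the validation fixture exercises.

**Target mode.** `read_target_events()` loads a whitelist of intragenic
events, by exon pair (e.g. MET exon 13 joined to exon 15 — exon-14
skipping; EGFR exon 1 to exon 8 — the vIII deletion) or by coordinate
window, each with its own `min_partner_ends`. Only whitelisted intragenic
junctions are ever called.

**Panel and blacklist.** `restrict_to_panel()` drops junctions with neither
breakpoint in the capture panel; `apply_blacklist()` suppresses recurrent
artifacts by gene pair or coordinate window.

## 8. Statistics

`count_subclones()` counts, per sample and gene pair, the distinct fusion
junctions — distinct breakpoint pairs are independent rearrangement events
and hence subclones. `fisher_exact_2x2()` is an exact enumeration of the
hypergeometric tail: all tables with the observed margins are enumerated
and the probabilities of those no more likely than the observed table are
summed (two-sided). It exists as an independently-authored primitive; the
test suite cross-checks it against `stats::fisher.test()` to 1e-10 over
random tables. The reference contrast — 11/20 multi-subclone samples in
one group versus 6/31 in another — gives p = 0.0143.

## 9. The simulator, and what it does not show

All validation is against seeded synthetic data; there are no bundled real
reads. `sim_fusion_dataset()` builds, from a `fusion_scenario()`:

* per-gene genomic sequence with exon/intron structure (defaults: 6 exons
  of 120 bp, 90-bp introns, UTRs sized so the CDS is a whole number of
  codons), random bases from a generator seeded per dataset;
* `genome.fa`, `models.refFlat`, `models.gtf` (the two model formats are
  written from one structure and tested to load identically);
* reads that tile the junction: for each junction, `n_reads` 100-bp reads
  at distinct split positions, carrying `n_umis` UMIs over `n_partner_ends`
  distinct ligation sites, emitted as aligned SAM (primary + supplementary
  + `SA`, soft/hard clip conventions as a real aligner would) and FASTQ;
* a truth table: junction coordinates, expected molecule and partner-end
  counts, boundary status, and frame.

**Frame truth is computed two independent ways.** The annotation arithmetic
of section 6 is one; `oracle_frame_status()` is the other — it *translates*
the simulated fused CDS and declares the fusion in frame iff the first stop
codon is exactly the 3' gene's annotated stop. The acceptance suite checks
the two agree over a 300-scenario grid (breakpoint kinds × strands × exon
lengths 105/120/131, so all codon phases occur). One subtlety: a junction
can create a stop codon by chance where the two sequences meet, which would
make the translation oracle disagree with the arithmetic for a reason that
is real biology but not what the check is about; the generator therefore
deterministically resamples up to two unconstrained 3'-side bases at the
junction to avoid chance stops in both relevant frames, keeping the
comparison a pure test of the arithmetic.

Scenario parameters (`n_reads`, `n_umis`, `n_partner_ends`, exon geometry,
breakpoint kinds, `repeat_partner`, `intragenic`) are the study conditions;
the defaults above are the package's own choices, sized so that a full
dataset stays within a few tens of kilobytes of plain text and the entire
acceptance computation runs in well under two minutes.

Limitations worth stating plainly:

* The simulator emits *already-aligned* reads. Aligner behavior —
  seed-and-extend heuristics, MAPQ calibration, chimeric-alignment
  triggering — is assumed, not tested; only the parsing and calling logic
  downstream of the aligner is validated.
* Reads are error-free and uniformly covered. Sensitivity under sequencing
  error, low tumor fraction, or degraded RNA is out of scope.
* Transcript models are single-canonical-isoform per gene in the fixtures;
  the isoform-fallback path is exercised only lightly.
* The 2×2 exact test addresses one predefined contrast; no multiple-testing
  machinery is included.

## 10. End to end

```r
sc <- fusion_scenario(
  gene5 = gene_spec("EML4", n_exons = 8),
  gene3 = gene_spec("ALK", n_exons = 6),
  junctions = junction_spec(side5 = list(kind = "exon_boundary", exon = 6),
                            side3 = list(kind = "exon_boundary", exon = 2))
)
ds <- sim_fusion_dataset(sc, seed = 1, dir = tempfile("demo"))
res <- run_fusion_pipeline(ds$paths$sam, ds$paths$refflat, sample_id = "tumor1")
tidy(res)     # per-junction summary
glance(res)   # run-level counts
autoplot(res) # support by junction and frame status
```

`run_fusion_pipeline()` composes every stage above in order, optionally
writing a summary TSV, per-junction supporting reads (FASTQ + SAM) and a
run-metadata JSON to `out_dir`. The command-line driver in
`inst/scripts/fuseseq` exposes the same pipeline plus the simulator,
annotation lookups and the Fisher test as subcommands.
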