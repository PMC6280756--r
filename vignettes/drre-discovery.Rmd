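---
title: "Discovering damage-responsive regulatory elements with drrekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering damage-responsive regulatory elements with drrekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a tissue with regenerative capacity is injured — the wing imaginal
disc of a *Drosophila* larva after genetically induced cell death, the
zebrafish heart after resection, the mouse liver after hepatectomy — cells
near the wound switch transcriptional programs. The switch is executed by
regulatory DNA: regions of chromatin that open (or open further) after
damage and drive the regeneration expression program. `drrekit`
implements, end to end, a discovery pipeline for these
**damage-responsive regulatory elements (DRREs)** from expression tables,
peak calls and signal tracks, together with a seeded synthetic-study
generator that plants known truth in every layer so that each stage of
the pipeline can be validated exactly.

The pipeline has four arms:

1. **Expression**: fold-change differential-expression calling on FPKM
   tables, expression-profile classes, and detection of chromosomal
   clusters of co-regulated DE genes.
2. **Accessibility**: replicate-concordant peak handling, differential
   accessibility between control and regenerating tissue, and the
   *emerging* vs *increasing* DRRE taxonomy, with *reused* vs *novel*
   usage classification against open chromatin from other tissues and
   stages.
3. **Activity and conservation**: active-enhancer feature marking from
   ChIP data, delta-delta-Ct quantification for ChIP-qPCR and 3C-qPCR,
   summit-anchored conservation profiles and per-species alignment
   conservation.
4. **Cross-species**: fly-oriented ortholog mapping, up-regulation calls
   in zebrafish and mouse regeneration, and the intersection defining a
   regeneration core gene set, with a permutation null for ortholog
   enrichment.

## Differential expression and profiles

All expression rules operate on FPKM and are threshold-based rather than
count-based; there is no dispersion model and no p-value at this stage.
A gene is differentially expressed at a timepoint when the ratio of
replicate-averaged FPKM between regeneration and control reaches **1.7**
(up) or falls below 1/1.7 (down):

$$\mathrm{FC}_g = \frac{\bar{x}^{reg}_g + \varepsilon}{\bar{x}^{ctl}_g + \varepsilon},
\qquad \varepsilon = 0.01 .$$

The pseudocount makes zero-FPKM genes well defined; we apply the same
0.01 everywhere a ratio of expression or signal is formed, and to the
log-transform used for coregulation (`coregulation()` is the Pearson
correlation of `log(FPKM + 0.01)` across timepoints, undefined when a
profile is constant). Replicates are combined by arithmetic mean before
the ratio; no minimum-expression floor is applied before the fold rule.
Expression profiles over the three timepoints are classed as *variable*
(max/min ratio strictly above 2) or, by mean FPKM, *high* (> 30),
*moderate* (> 5, ≤ 30), *low* (> 1, ≤ 5) or *silenced* (≤ 1); boundary
values land in the lower class by construction.

## Chromosomal clusters of DE genes

Genes with similar expression are often linearly clustered. We tile each
chromosome with windows of **30 kb** advanced by **10 kb**; a gene
belongs to a window when its TSS does (the TSS of a multi-transcript
gene is the 5'-most transcript start, one deterministic anchor per
gene). For a window with $n$ genes of which $k$ are DE, the enrichment
p-value is the hypergeometric upper tail with the genome-wide gene count
$N$ and DE count $K$:

$$p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n).$$

Benjamini–Hochberg correction is applied across all windows holding at
least one gene (per direction and timepoint); windows with $k \ge 3$ and
$q \le 0.05$ survive, and overlapping survivors are merged. A cluster's
interval is the span of its member DE genes rather than the window
edges, since the biologically meaningful extent is the gene content. The
windowed procedure itself is this package's own construction (the
parameter set — 30 kb / 10 kb / 3 genes / BH at 0.05 — is the standard
one for this analysis); whether adjacent significant windows should be
merged or reported separately is a genuinely open design point, and we
merge, which can make cluster *counts* smaller than procedures that
report windows separately. **Hotspots** are maximal groups of at least 2
clusters whose starts fall within a sliding 1-Mb window; as a pure count
rule it involves no further testing. The minimum cluster count for a
hotspot is a package choice (2 is the smallest nontrivial grouping) and
is configurable.

## Differential accessibility and the DRRE taxonomy

ATAC fragments are classed nucleosome-free (**NF**, < 100 bp),
mononucleosomal (**MN**, 180–247 bp) or other. Peaks must be
*concordant* — called in both replicates (≥ 1 bp overlap; the retained
peak keeps the first replicate's coordinates and averages heights) — and
concordant peaks of all samples merge into consensus regions with
BEDOPS-style union semantics (book-ended intervals merge).

Differential accessibility compares regeneration against control at one
timepoint. A regeneration peak with no overlapping control peak is
called by **presence**; one overlapping control peak(s) is called when
its height fold (against the tallest overlapping control peak,
pseudocounted) reaches **1.5**. Height is the maximum per-base signal
over the region; summary tools report several statistics for a region
and the maximum is the one that matches summit height, with the mean
exposed as an option.

Classification then splits differential regions by prior openness:

* **emerging (eDRRE)** — overlaps neither the same-timepoint control
  open set nor the basal-stage (untreated L3) open set: open only after
  damage;
* **increasing (iDRRE)** — any prior openness. Mixed cases (open in
  control but not the basal set, or vice versa) are classed increasing,
  because "open only after damage" is the defining property of emerging;
  provenance columns (`overlaps_ctl`, `overlaps_l3`) preserve the
  distinction for inspection.

A presence-only region can still be increasing when it overlaps the
basal open set: replicate concordance at one timepoint and basal
openness are different observations.

## Genomic annotation

Each region receives exactly one category, decided by its summit (or
interval midpoint when no summit is available) with precedence **CP**
(± 100 bp of a TSS) > **FI** (within the first intron between the first
and second projected exons — the merged exon union over all transcripts)
> **proximal** (± 2 kb of a TSS) > **distal**. TSS windows are
unstranded; reported distances are signed with 5' negative relative to
the assigned gene's strand. Ties at one precedence level resolve to the
nearest TSS, then to the lexicographically smallest gene id, so
annotation is deterministic and invariant to gene input order. The CP
half-width is a parameter because the zebrafish arm uses 0.5 kb.

## Usage, conservation, activity

An emerging element is **reused** when it overlaps (≥ 1 bp) open
chromatin in at least one reference dataset from another stage or tissue
(embryo, L3 non-wing tissues, pharate appendages), and **novel**
otherwise; a reference labeled as the assayed sample itself (L3 wing) is
rejected as a configuration error. Conservation profiles average a
per-base score track at each offset within ± 500 bp of the NF summit.
Species-level conservation counts, for each element, the species whose
alignment mask covers at least a fraction τ of its bases; τ = 0.5 is a
declared package decision (the presence criterion is not standardized),
exposed as a parameter, and the percent-aligned summary is the mean
aligned fraction over species so each enhancer contributes one point.

Active-enhancer features (H3K4me1, H3K27ac, Pol II) are scored per
element: **marked** when a regeneration ChIP peak falls within 500 bp of
the element; else **higher_signal** when mean regeneration signal over
the element strictly exceeds control (a tie is not higher — the strict
rule and the averaging extent, the element interval itself, are package
decisions); else **not_marked**. An element has activity **presence**
when any feature is marked or higher. ChIP-qPCR and 3C-qPCR enrichments
use the delta-delta-Ct rule, $2^{-\Delta\Delta C_t}$, normalizing each
condition against its input (or a known interaction for 3C — same
arithmetic, different reference role), with the SEM propagated from
technical-replicate spread.

## Cross-species core

Orthology is consumed fly-oriented: each fly gene maps to sets of
zebrafish and mouse orthologs (many-to-many allowed). Up-regulation in
the vertebrate datasets uses a 1.5-fold injured/uninjured rule. The
**regeneration core** is the set of fly genes up-regulated after damage
(early and/or mid) with at least one up ortholog in zebrafish *and* one
in mouse; a fly gene counts once regardless of how many orthologs
support it. Whether late-only up genes should enter is ambiguous; we use
early ∪ mid. The by-chance control is a seeded permutation test (default
10,000 same-size draws from the background without replacement, p-value
with the add-one correction), cross-checked in the test suite against
the hypergeometric tail. The zebrafish accessibility arm reuses the
differential machinery without a basal open set (emerging = called
exclusively in regeneration) and annotates with the 0.5-kb CP window.

## The synthetic study and what it does (not) show

`simulate_study()` draws a complete toy study from one master seed, with
an independent RNG stream per layer (genome, expression, peaks,
references, ChIP, conservation, orthologs, zebrafish, qPCR) so changing
one layer's parameters does not perturb the others. Defaults: 2
chromosomes of 2 Mb, 400 genes on a 10-kb layout grid, 2 replicates, 3
timepoints; 8% of genes DE at early with 90% up; planted DE folds
log-normal floored at 2; replicate noise log-sd 0.05; 3 planted clusters
of 5 up genes spaced 3 kb; 360 increasing and 24 emerging regions (a
6.25% emerging share) over 120 background peaks, accessibility folds
drawn in [2, 3] against background jitter within ± 8%; 58% of emerging
elements copied into reference open sets; 80% of increasing and 63% of
emerging elements ChIP-marked; 10 species masks; a 12-gene planted core
with ortholog density 0.5 elsewhere. Planted margins (fold ≥ 2 against
thresholds of 1.7 and 1.5) are chosen so threshold rules recover the
planted labels exactly, which makes recovery tests deterministic;
scattered DE genes are kept ≥ 40 kb from planted cluster spans so
cluster membership recovery is unambiguous.

The generator emulates the *statistical structure* of such a study —
planted effects, replicate noise, genomic layout, reference overlap
fractions — not real data: there are no read-level artifacts, no GC or
mappability structure, no correlated replicate failure modes, no
partially overlapping peaks, and the effect-size margins are clean.
Passing recovery tests therefore demonstrates that the implementation
applies its stated rules correctly, not that the thresholds are optimal
for real tissue.

`null_study()` removes all planted structure (random DE labels over
unchanged expression; peaks identical across conditions up to symmetric
noise) and supports the error-control checks: the fraction of null
replicates yielding any cluster stays within Monte Carlo slack of the
0.05 window-level BH target, and permutation p-values are super-uniform.

## Numerical and scale choices

* Coordinates are 0-based half-open throughout (BED convention); GTF
  input/output converts at the parser boundary. Book-ended intervals
  merge. Missing signal reads as 0, never NA.
* All ratio rules share the 0.01 pseudocount; thresholds are inclusive
  (≥ 1.7, ≥ 1.5) except the variable-profile ratio and the
  higher-signal comparison, which are strict as stated.
* Test and validation problem sizes (400 genes, ~500 peaks, 100
  recovery seeds, 500 null replicates, 200 permutation nulls at B = 199)
  were chosen so the full suite completes in minutes on one CPU while
  keeping Monte Carlo standard errors well inside the asserted bounds.
* The pipeline orchestrator validates every requested stage's inputs
  before any stage runs and fails fast naming the stage; outputs are
  plain TSV with an md5 manifest, and identical inputs reproduce
  identical checksums (manifest timestamps are recorded but excluded
  from determinism comparisons).

## Known limitations

Peak calling, read alignment, quantification and quantile normalization
are out of scope: the package starts from peak calls, FPKM tables and
normalized tracks. Coordinate lifting between assemblies is not
performed — masks and references must share the query coordinate system.
The cluster procedure is this package's reconstruction of a windowed
hypergeometric scan, not a reimplementation of any specific executable,
and its merged-window counts are not directly comparable to tools with
different merge behavior.
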