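---
title: "Methods: splicing misregulation, motif enrichment, orthology and behavior in splicekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing misregulation, motif enrichment, orthology and behavior in splicekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicekit)
```

# Scope and model organisms

`splicekit` implements the computational layer of a muscleblind (MBNL)
loss-of-function study design: a panel of mutant genotypes (single,
double and triple knockouts of the *mbnl1*/*mbnl2*/*mbnl3* family) is
compared against wild type for transcriptome-wide alternative-splicing
misregulation, for the sequence signature of direct Mbnl binding (YGCY
motifs) around regulated cassette exons, for conservation of
mis-spliced exons with a second species, and for organism-level motor
phenotypes measured in a novel-tank swim assay. The package does not
run aligners or splicing callers; it consumes rMATS-style event tables
and standard genome annotation, and everything downstream of those
files is implemented and tested here. A synthetic-data module generates
inputs with known ground truth so that every stage is exercisable and
scoreable without any external dataset.

# Splicing events and thresholds

Inclusion levels (PSI) are kept on the 0–1 scale internally; the
percent scale is display-only. The RT-PCR estimator is
$\mathrm{PSI} = 100\,\cdot\,\mathrm{inc}/(\mathrm{inc}+\mathrm{exc})$
from background-corrected gel band intensity sums, and
$\Delta\mathrm{PSI}$ is always the difference of replicate means,
mutant minus wild type.

Threshold conventions follow the inequalities as printed in the
field's common usage: significance gates (FDR < 0.10 for event tallies
and consensus sets; FDR < 0.05 combined with $|\Delta\mathrm{PSI}| >
0.2$ for regulation classes) are strict, while the
differential-expression fold-change gate ($|\log_2 FC| \ge 1$) is
inclusive. The one ambiguous bound (the fold-change gate) is a
documented package decision. Events with missing replicate coverage
are dropped from variance and magnitude computations, never imputed.

Regulation classes name the protein's action, not the mutant's
phenotype: inclusion *rising* when Mbnl is lost means the protein
normally represses the exon (`mbnl_repressed`); inclusion falling
means it normally activates it (`mbnl_activated`).

The consensus set collects cassette exons significant in at least
`min_support` of the mutant genotypes (default 4, mirroring a
four-of-seven design). With `min_support = 1` it is provably the union
of per-genotype significant sets and with the full genotype count their
intersection; both identities are tested.

# Synthetic splicing tables

`simulate_splice_table()` draws a latent baseline PSI per event
(uniform on [0.05, 0.95]), plants a signed $\Delta$PSI shift in a
fraction of events, adds logit-normal replicate noise (sd 0.2 by
default), and observes binomial junction counts at a Poisson read
total (default mean 100; 500 in the high-power setting used for
recovery checks). The default design is three wild-type and three
mutant replicates, matching a typical bulk RNA-Seq muscle experiment.

Two design choices matter:

* **Direction-consistent planting.** The sign of the planted shift is
  a per-event property shared by every genotype in which that event is
  planted, emulating a protein family regulating each target in one
  direction. This also guarantees that a baseline accommodating all
  planted shifts exists; baselines that cannot fit a drawn shift are
  resampled, never clipped (clipping would silently shrink the planted
  effect and corrupt ground truth).
* **Significance stand-in.** Per-event significance is a two-sample
  t-test on logit-PSI with Benjamini–Hochberg correction across
  events. The schema (per-replicate inclusion levels, FDR column) is
  identical to an rMATS-style caller's, so the filtering, consensus and
  clustering layers are agnostic to which test produced the FDR.

Generators are pure functions of their spec, including the seed, and
restore the caller's RNG state.

# YGCY motif enrichment

Five windows are taken around each cassette exon, strand-aware and
coding-strand oriented: the exon itself, the intronic 1–250 nt
immediately 5′ and 3′ of it, and the intronic 1–250 nt adjacent to the
two flanking constitutive exons. When an intron is shorter than twice
the window, the two claims are truncated at the intron midpoint (a
package decision; a 300-nt intron yields two 150-nt windows).

The motif set default is canonical YGCY = {TGCT, TGCC, CGCT, CGCC}
(Y a pyrimidine). A second preset, {GCTT, CGCT, TGCT, GCGC}, reproduces
an alternative published listing that deviates from the strict YGCY
pattern; both are shipped and runnable, and no silent correction is
applied.

Controls for each motif are all 4-mers with the same A+T base count
and the same CpG (CG dinucleotide, counted at offsets 1–2, 2–3, 3–4)
content, excluding every motif in the analysis set to avoid
self-contamination of the control mean. Enrichment pools counts and
lengths over an exon set before dividing ("normalised for analysed
sequence length"), compares the mean per-motif frequency with the mean
per-control frequency, and adds a pseudocount (default 1 occurrence)
to each count so downstream $\log_2$ ratios stay finite. The mean (not
the sum) over the set's motifs is used in the numerator so that equal
motif and control densities give a ratio of exactly 1. Heatmap cells
are $\log_2$ of the regulated-set enrichment over the non-regulated-set
enrichment, separately per window and per regulation class; the cell
matrix is exactly antisymmetric under swapping the two exon sets.

Non-regulated exons (a definition the enrichment contrast needs but
that upstream tooling does not provide) default to tested cassette
exons with FDR > 0.5 and $|\Delta\mathrm{PSI}| < 0.05$; both cutoffs
are arguments.

The sequence generator rejects YGCY from the i.i.d. background (by
breaking each occurrence) and then plants motifs at requested
per-100-nt densities at non-overlapping offsets, recording every
coordinate. Planted-density recovery is therefore exact up to rare
junction artefacts where a planted motif's flank completes a second
occurrence. What the generator does **not** emulate: real intronic
composition bias, splice-site consensus, conservation structure, or
clustered binding sites — so passing tests demonstrate correctness of
the counting and normalisation machinery, not biological effect sizes.

# Orthologous exons

An exon pair is called orthologous when three criteria hold: the host
genes' proteins are at least 75% conserved; the exons occupy the same
1-based transcription-order position in at least one annotated
transcript of each gene (existential over isoform pairs); and a
translated local alignment of the exon sequences achieves an e-value
strictly below 0.05.

"75% conserved" is interpreted as global percent identity (identical
aligned pairs over all alignment columns, BLOSUM62, affine gaps 11/1)
between the genes' proteins; coverage-weighted or nucleotide-level
identity are reasonable alternatives and the threshold is an argument.
The translated search is the package's own Smith–Waterman over the
3 × 3 forward-frame pairings (exon sequences are extracted
coding-strand oriented; a flag adds reverse frames for unoriented
input) with the closed-form Karlin–Altschul e-value
$E = K m n e^{-\lambda S}$, using the standard gapped BLOSUM62
constants $K = 0.041$, $\lambda = 0.267$. The search space $m \times n$
uses the **total translated length over all searched frames** of each
sequence (approximately the nucleotide length), the convention of a
translated–translated search; with the single-frame-pair product the
expected number of chance high-scoring pairs across nine frame
pairings would be understated about nine-fold and random 120-nt pairs
would cross the 0.05 threshold far too often. With the all-frames
space, 100% of 200 random pairs stay at $E \ge 0.05$ in the shipped
null simulation. E-values are comparable within the package only,
which suffices for thresholding; `db_size_nt` substitutes a
database-style search space when desired.

# Clustering

Samples are clustered on the `n` most variable cassette events
(default 800; ties broken lexicographically by event id so selection is
deterministic), using raw PSI columns without rescaling since all
share the [0,1] scale (a scaling flag exists on the matrix itself via
standard tools). The cluster count is chosen by the gap statistic with
the PCA-aligned uniform reference distribution and the one-standard-
error rule ("smallest k with Gap(k) ≥ Gap(k+1) − s(k+1)"), delegated to
`cluster::clusGap`/`maxSE` with this package's own K-means as the
clustering engine. K-means itself is a best-of-restarts Lloyd
iteration (default 25 restarts; ties by restart order) that records
its per-iteration objective, which is asserted non-increasing in the
test suite and checked against an exhaustive partition search on small
inputs. Because the selection rule could in principle disagree with a
forced two-group analysis, both the selected k and the forced-k
partition are available to callers.

# Swim-test kinematics

Between-frame speeds are Euclidean displacements times the frame rate
(default 10 fps, under which 20 frames span 2 s). A pause is a maximal
run of at least 20 consecutive speed measurements none of which
exceeds 1.5 cm/s — the bound is strict, so a measurement of exactly
1.5 cm/s stays inside a pause run, and a 19-frame slow run is not a
pause. Percent time active, active-period mean speed, the fastest
100-frame window (50- and 30-frame windows and a top-30-seconds mode
with non-overlapping 1-s bins are alternates), total path length and
the vertical position index (0 = tank bottom, 100 = top, using the
18 cm default tank depth) complete the summary. Tracking gaps yield
undefined speeds that terminate pause runs, exclude the spanned
distance, and invalidate fastest-window candidates — a conservative
choice that never invents motion. No smoothing is applied.

The trajectory generator integrates piecewise-constant segment speeds
along per-frame random headings inside the tank; headings that would
cross a wall are redrawn, so every between-frame displacement is
exactly speed/fps and planted speeds and distances are recovered
without bias (a reflecting wall would record the chord of the folded
path and systematically shorten displacements). Positional jitter, if
requested, is added after integration. The generator does not model
fish inertia, wall-following or burst-glide gait.

# Statistics layer

Group comparisons use ordinary (equal-variance) one-way ANOVA — the
degenerate all-equal case returns F = 0, p = 1 rather than 0/0 — with
Tukey's studentized-range comparisons (Tukey–Kramer for unbalanced
groups, computed by `stats::TukeyHSD`), summarised as a compact letter
display built by the insert-and-absorb algorithm so that sharing a
letter encodes exactly the non-significant pairs at $\alpha = 0.05$.
Two-group designs reduce to the pooled t-test identically
($q = t\sqrt{2}$), which the tests assert. Spearman's $\rho$, BH FDR,
the chi-square goodness-of-fit check against an expected (e.g.
Mendelian) ratio, and comparative $C_T$ expression
($\mathrm{fold} = 2^{-\Delta\Delta C_T}$, normalised to a housekeeping
gene and a calibrator group) complete the layer; standard machinery is
delegated to base R (`aov`, `t.test`, `cor`, `p.adjust`, `chisq.test`)
behind a grouped-data interface, with type-I error calibration
verified by 10,000-replicate null simulations. Reporting supports
both mean ± s.d. and mean ± s.e.m.; the choice is explicit, never
implied.

# Problem sizes and numerical choices

The shipped test suite and the acceptance script use deliberately
desk-scale problem sizes chosen to exercise every code path with tight
statistical margins: 200–500 simulated splicing events, 200 exons per
regulation class (30 per set across 20–50 seeds for null heatmaps),
200 random sequence pairs for the alignment null, 50–100 seeds for
gap-statistic selection rates, and 10,000 replicates for type-I
calibration. Tolerances follow from the construction: exact identities
are asserted to floating-point precision, planted-recovery and
selection rates against the margins stated alongside each property.
Lloyd iterations stop when the objective improves by less than 1e-10;
the studentized-range distribution is evaluated by `stats::ptukey`.

# Known limitations

* Events only annotated in older genome assemblies are not lifted
  over; inputs are taken at face value on whatever assembly produced
  them.
* Counts in per-type event tallies are not deduplicated across event
  types; overlapping annotations count once per type.
* The e-value calibration is internal — absolute agreement with an
  external tblastx installation is not expected, only rank agreement
  and a usable 0.05 threshold.
* The synthetic generators are scoring instruments, not biological
  simulators; conclusions about real data require real inputs through
  the same interfaces.
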