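---
title: "Methods: chromatin organization at CpG islands and exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin organization at CpG islands and exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprofile)
```

# The measurement model

All sequencing tracks in this package are reduced to a single unit, the
normalized read count (NRC). Short tags are extended 5'-to-3' to the
library fragment length (150 bp by default: a tag on the + strand grows
rightward from its start, a tag on the - strand leftward from its end),
and the local density of extended fragments is compared with the
genome-average density:

$$\mathrm{NRC} = \log_2\frac{(\text{count} + c)/w_\mathrm{eff}}
{\text{total count}/\text{genome size}}$$

Counting is by overlap: a fragment contributes to every interval it
touches by at least one base pair. An extended fragment of length $f$
can overlap an interval of width $w$ from $w + f - 1$ distinct start
positions, so the effective width $w_\mathrm{eff} = w + f - 1$ is used
as the density denominator. This is the one numerical choice in the
track layer that deserves emphasis: with the raw width $w$ in the
denominator, a uniform library would sit at
$\log_2((w+f-1)/w) \approx 0.8$ rather than 0 for 200-bp bins, and
profiles over bins of different widths (exons versus introns, say)
would acquire width-dependent offsets that masquerade as biology. With
$w_\mathrm{eff}$, uniform libraries calibrate to NRC 0 at every scale,
which is also what the package's null tests assert. The raw formula
with a caller-chosen width remains available as `nrc()`.

The log2 is undefined at zero counts, so a pseudocount $c$ (default 1,
added to the target count only) keeps every bin finite and the NRC
monotone in the count. At typical bin occupancies (tens of fragments)
the pseudocount and the Jensen gap between mean-of-logs and
log-of-means each contribute only a few hundredths of a log2 unit; both
shrink as libraries deepen.

Per-feature values (`feature_nrc()`) are computed directly from
fragments with the feature's own length, never by resampling the 200-bp
genome track: exons are often shorter than a bin, and resampling would
blur exon/intron boundaries.

# CpG islands

Islands are detected by the classical composition criteria — GC
fraction at least 0.50, observed/expected CpG ratio above 0.6 with

$$\mathrm{obs/exp} = \frac{\#\mathrm{CpG} \times N}{\#C \times \#G},$$

and length greater than 200 bp. The criteria define what an island is
but not how to find one, so the scan is made explicit: every 200-bp
window (step 1) satisfying the GC and obs/exp criteria seeds an island,
overlapping or adjacent seeds are merged, and a merged region is
emitted only if it satisfies all three criteria itself, including the
length bound. This is a deliberately simple, deterministic scheme in
the spirit of the Takai-Jones scans but without iterative trimming or
extension, which makes it directly checkable against a brute-force
window-enumeration oracle — the package's tests do exactly that. The
cost of forgoing trimming is boundary diffusion: windows that straddle
an island edge qualify while roughly half their span is inside, so
detected islands overshoot each true edge by up to about half a window.
`N` bases are excluded from both denominators, and windows that are
more than half `N` never qualify, which keeps assembly gaps from
seeding spurious islands.

A promoter is CGI-containing when the window from 1,000 bp upstream to
500 bp downstream of the TSS (in transcription orientation, half-open
coordinates) overlaps an island by at least one base.

# DNA bendability

Bendability is the sum over all overlapping trinucleotides of a
bending-propensity parameter. Parameters are keyed on the 32 canonical
trinucleotides (each 3-mer merged with its reverse complement via the
lexicographic minimum), which makes the score strand-symmetric by
construction. The parameter values themselves are provenance, not
algorithm: they ship as an editable TSV, the file bundled under
`inst/extdata/` is synthetic (as its name says), and every test uses
arbitrary synthetic tables, so correctness of the summation is
decoupled from any particular published constant set.

# Exon classes and segmentation

Within each transcript, exons entirely outside the CDS are non-coding
exons (NCE); the first CDS-containing exon in transcription order is
the initial coding exon (ICE), split into `ICE_5prime` when it is also
the transcript's first exon; the last CDS-containing exon is the last
coding exon (LCE); CDS-containing exons between them are `internal`.
ICE and LCE are segmented into UTR and CDS parts at the start/stop
codons, and the segments tile each exon exactly. Two declared choices:

* A transcript whose CDS sits in a single exon has no distinct ICE and
  LCE; it is labeled LCE with a full UTR5+CDS+UTR3 segmentation,
  flagged, and excluded from ICE/LCE profile averages to avoid double
  counting.
* For splicing analyses, "internal exons" are exons that are neither
  first nor last in the transcript, regardless of coding status.

Transcripts are treated independently; no isoform collapsing is
attempted.

# Metagene profiles

Three profile families are produced, all as feature-by-bin matrices of
NRC values whose column means are the plotted curves:

* **Feature-anchored** (used for islands): fixed-width flank bins, ten
  scaled bins inside the feature, fixed-width flank bins after it.
* **TSS-anchored**: fixed-width bins across a window centered on the
  TSS, oriented 5'-to-3', split by promoter CGI status.
* **Exon/intron**: every exon and intron partitioned into ten scaled
  bins (lengths differing by at most 1 bp, remainder assigned
  left-to-right in transcription orientation; bin 1 is always 5').
  Profiles are produced per exon class, with ICE/LCE UTR and CDS
  segments profiled separately and introns keyed by the class of their
  5'-flanking exon.

Features shorter than the bin count cannot tile and are skipped, with
the count reported. The flank extent (1,000 bp) and flank bin width
(200 bp) are declared defaults. The split of islands into methylated
and unmethylated sets uses the top quartile of mean methylation NRC by
default — an explicit, reproducible stand-in for a threshold the
underlying analysis leaves unstated — with nearest-rank quantiles and
ties broken by feature order.

# Splicing statistics

**Exon inclusiveness** is an internal exon's RNA-seq NRC minus the mean
NRC over all exons of its transcript, so scores sum to zero within a
transcript by construction (a property asserted on every synthetic
run). Pooled internal-exon scores are classified by empirical
quantiles: lowest 10% skipped, top 10% highly expressed (a
sequencing-bias control group), the rest included. Quantiles are
nearest-rank with ties broken by record order; the classification is
purely quantile-based, treating the roughly two-fold count reduction of
the lowest decile as an observation rather than a second threshold.

**Weak exons**: eligibility requires an internal exon of 50-250 bp
(inclusive), flanking introns of at least 70 bp on both sides,
canonical AG acceptor and GT donor dinucleotides, and no U12 flag (an
optional annotation column; the generator never emits U12). Among
eligible exons the lowest-scoring 5% are very weak and the lowest 10%
weak, with very-weak contained in weak. Splice-site scores are
pluggable; a simple log-odds position-weight scorer over small built-in
donor/acceptor matrices is provided so the filter can run
self-contained, but any external model's scores can be substituted.

**Open-chromatin enrichment** is a base-level odds ratio: the fraction
$p_f$ of feature bases carrying the mark against the fraction $p_g$ of
the mappable genome carrying it, $\mathrm{OR} = [p_f/(1-p_f)] /
[p_g/(1-p_g)]$, with the mappable fraction (default 0.8) an explicit
parameter. Whether the published analysis counted bases or elements is
ambiguous, so an element-level variant (fraction of features touched by
at least one mark) is available behind a flag; base-level is the
default.

**Elongation efficiency** is expression divided by the
library-normalized linear-scale pol II fragment density over the
transcript span, reported in log2. The expression scale is whatever
positive scalar the caller supplies; only ratios across genes matter
downstream. **Quantile summaries** bin genes into equal-count
nearest-rank bins of expression or efficiency and average per-exon mark
levels on the linear scale before re-logging — one documented choice
that avoids mixing mean-of-logs and log-of-means across strata — along
with the percentage of CGI promoters per bin.

Methylation can be normalized by CpG density (linear level divided by
obs/exp, re-logged) and H3K36me3 by nucleosome occupancy (difference of
log2 NRCs), the decomposition that separates nucleosome-level from
per-nucleosome modification density.

# The synthetic-data generator

The generator exists so that every stage has known ground truth. It is
a piecewise-constant Poisson-style model: each track has an intensity
that is 1 everywhere, multiplied by planted factors over features
(exons, promoter NFR windows, islands, gene bodies); fragment centers
are drawn from that intensity, and 25-bp tags are written 5'-anchored
on a random strand, so the pipeline's own extension step is exercised
nontrivially. Expectations are therefore closed-form and every planted
factor is recoverable by the corresponding pipeline stage.

Default study conditions: a 10-Mb genome in two chromosomes, iid
background at 30% GC, 500 non-overlapping genes (4-8 exons of
300-900 bp, introns 800-2,400 bp, 90% coding), 100 intergenic planted
islands plus one island spanning the TSS of each CGI-promoter gene
(half the genes), log-normal expression, and 10^6 tags per track at
fragment length 150. Planted factors default to 2-fold exon enrichment
(nucleosome, methylation, H3K36me3), 4-fold NFR depletion over
[TSS-200, TSS) of CGI promoters only, 4-fold methylation depletion on
islands, 10% of internal exons skipped at 4-fold reduced RNA-seq
density, and an H3K36me3 gene-body intensity proportional to relative
expression.

Sizing choices made once, on closed-form grounds rather than after any
test:

* Background GC is 0.30. Under an iid background the obs/exp ratio is
  near 1 everywhere, so the GC criterion is the only barrier to
  spurious islands; at 40% GC a 200-bp window crosses 50% GC often
  enough to seed thousands of false islands genome-wide, while at 30%
  the expected count is far below one per 10 Mb.
* Planted islands are 1,000-2,500 bp at 70% GC. The trimming-free scan
  overshoots each edge by up to ~100 bp, so recovering islands at 80%
  reciprocal overlap requires islands several times that diffusion
  length.
* Parameter-recovery experiments use a long-feature variant
  (exons 1,500-2,500 bp, introns 4,000-8,000 bp). Overlap counting
  convolves any planted step with a fragment-length box filter; a
  ten-bin profile of a feature comparable in size to the fragment would
  report mostly edge blur. With features an order of magnitude longer
  than the fragment, the expected attenuation of a 2-fold planted
  contrast is a few hundredths of a log2 unit — within the stated
  recovery tolerance — and the edge bins visibly carry the residual
  blur, as they do in real data.
* The NFR recovery profile uses 50-bp bins phased so that one bin's
  fragment window lies wholly inside the 200-bp depletion window
  (offset -125 with the default fragment length); any coarser or
  unphased binning mixes depleted and undepleted sequence in every bin
  and cannot reach the planted depth. That experiment also uses a
  deeper library (4x10^6 tags) so that pseudocount and small-count bias
  do not mask a 4-fold depletion measured over 50-bp bins.

What the generator does *not* emulate: read errors, mappability
structure, GC amplification bias, duplicate reads, overlapping genes,
alternative isoforms, U12 introns, or sequence-dependent nucleosome
positioning. Passing recovery tests therefore demonstrates that the
statistics measure what they claim on data with known structure — not
that real chromatin behaves like the generator.

# Degenerate inputs and determinism

Zero-count intervals are kept finite by the pseudocount; bisulfite
sites with no coverage are missing, not zero; all-equal score vectors
classify everything as included (with a warning) rather than slicing
ties arbitrarily; quantile ties are broken by stable input order;
promoter windows and fragments are clipped at chromosome edges with the
clipped counts logged. Every generator output is a pure function of its
config (seed included), and the pipeline writes a manifest of content
hashes so a re-run can be verified byte-for-byte. Pipeline runs at the
default conditions complete in minutes on one CPU; the test suite
scales its fixtures accordingly.

# Known limitations

* The CGI scan does not trim merged regions, so island boundaries are
  systematically wide by up to half a window per side.
* The bundled splice-site scorer is a toy position-weight model meant
  to exercise the ranking machinery, not to rival maximum-entropy
  splice models; scores are pluggable for that reason.
* Overlap counting with effective-width normalization calibrates means
  correctly but still smooths true steps at fragment scale; analyses
  needing base-pair-sharp boundaries should work from fragment centers
  or shorter fragments.
* The odds-ratio mappability correction is a single global fraction,
  not a mappability track.
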