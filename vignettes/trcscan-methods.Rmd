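---
title: "Methods: binned ChIP-Seq enrichment and replication-stress quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned ChIP-Seq enrichment and replication-stress quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Inhibition of the BET bromodomain protein BRD4 (e.g. with JQ1) deregulates
RNA polymerase II elongation, promotes R-loop accumulation, and produces
DNA damage — marked by γH2AX — at a subset of BRD4-regulated genes.
Characterizing this phenotype requires several quantifications that share
no off-the-shelf tool: genome-binned ChIP-Seq densities with a Poisson
significance model, per-gene fold-enrichment calls intersected with
co-regulated gene sets, a sequential read-apportionment scheme over gene
features, DRIP-qPCR relative abundance of DNA:RNA hybrids, comparative-Ct
expression, and DNA-fiber fork speeds. `trcscan` implements these as one
tested pipeline, with a synthetic-data generator that emulates the paired
DMSO/JQ1 design for validation.

# Binned read density

Aligned reads are treated as stranded genomic intervals. Each read is
extended to a fixed fragment length $E$ (default 200 bp) in its 3'
direction from its 5' start, and tallied over fixed $B$-bp bins (default
25) tiling each chromosome from coordinate 0; a bin receives one count per
read whose extended interval overlaps it by at least one base. Counting is
presence/absence rather than base-fraction weighting: the bin value is a
count of read events, which is what a Poisson background model applies to.
An interior read therefore covers exactly $E/B$ bins when its 5' start is
grid-aligned and $E/B + 1$ otherwise (8 vs 9 at the defaults) — an identity
the tests verify exhaustively over all 25 offsets.

Tracks are compared across libraries after depth normalization: every bin
is scaled by $S/d$ where $d$ is the number of reads counted and $S$ the
target library size (default $10^6$, i.e. reads per million). The depth is
the number of reads supplied to the binning step, not a file line count,
so normalization always matches the counted population. Normalization is
flagged and protected against double application; duplicating every read
leaves the normalized track bit-identical.

# Poisson background significance

Significantly enriched bins are identified against a Poisson background.
The background rate λ is estimated from the whole-cell-extract input
library — the standard ChIP-Seq control — as the mean bin-overlap event
count scaled by the depth ratio between the target and input libraries
(`estimate_background`, global mode). A local mode replaces the global
mean with a sliding window mean (default 201 bins ≈ 5 kb) for genomes
with strong coverage structure. Both modes floor λ at `lambda_min`
(default 0.1) so zero-coverage regions cannot produce degenerate
significance.

A bin with raw count $k$ is significant when
$P(X \ge k \mid X \sim \mathrm{Pois}(\lambda)) \le \alpha$ with
$\alpha = 10^{-9}$. The extreme fixed threshold plays the role of
multiple-testing control: at $10^6$ bins the expected number of false
significant bins is $\le 10^{-3}$ per run. The upper tail is computed via
the regularized incomplete gamma function (`stats::ppois`), which the test
suite checks against direct extended pmf summation to $10^{-10}$ absolute
over $\lambda \in \{0.1, 1, 5, 20, 50\}$, $k \le 200$. Significance is
always computed on raw counts; normalized tracks are rejected because
scaling breaks the Poisson support.

# Gene-level fold enrichment and set intersection

Per gene, signal is the summed normalized track over the gene span
expanded by a flank $F$ (default 2,000 bp) on each side — gene coordinates
"expanded to a suitable distance" — and the treatment/control fold change is

$$\mathrm{fold} = \frac{s_T + c}{s_C + c}$$

with pseudocount $c$ defaulting to the normalized equivalent of one raw
read in the smaller library. A gene is called enriched when fold is
*strictly* greater than the threshold (default 2, so "greater than
2-fold") and, by default, at least one Poisson-significant bin from the
raw treatment track lies in the scored region (`require_significant`).
The significance gate suppresses ratio artifacts at low coverage; it is a
flag because a fold-only definition is also defensible. Called genes are
summarized per gene set (e.g. BRD4-regulated, BRD4–JMJD6 and BRD4–CHD4
co-regulated lists), mirroring the headline per-set counts such analyses
report.

Where the scored region should sit (whole gene body plus flank, promoter
only, or peak-level) is genuinely open; the flank is exposed as a
parameter and the default scores the whole expanded gene body, consistent
with damage signal propagating through genes.

# Feature apportionment

For gene-feature distributions, each *unextended* read is assigned to the
first class it overlaps by ≥ 1 base in the fixed order: TSS region
(−50/+300 bp around the start site), 5'UTR, TTS region (−50/+200 bp
around the transcript 3' end), 3'UTR, exonic, intronic; reads touching
none are intergenic. Windows are strand-aware (on the minus strand the
TSS sits at `tx_end` and "upstream" means larger coordinates) and clipped
to the chromosome. UTRs are the exonic sequence between the transcript
end and the CDS boundary; exonic excludes the UTRs; intronic is the
transcript span minus exons, so the span is partitioned exactly. The
priority rule is resolved genome-wide, not per gene: a read overlapping a
TSS window of one gene and an exon of another is a TSS-region read. The
class counts always sum to the library size — an exact partition the
tests assert on every fixture.

Coordinates are 0-based half-open everywhere internally (BED native; GTF
converted on read). Multi-transcript genes collapse to one model — union
span, union exons, CDS hull — because enrichment is reported per gene.
One reading of the annotation model deserves note: a CDS is stored as its
genomic hull (`thickStart`/`thickEnd` semantics), and validity requires
both CDS boundaries to lie inside exons rather than base-level exon
coverage of the hull, which no multi-exon CDS could satisfy.

# qPCR quantifications

All qPCR math uses the exponential model (quantity ∝ $E^{-C_t}$) with
amplification efficiency $E = 2$ by default; no standard curves are
assumed, and $E$ is a parameter for when they exist.

**DRIP-qPCR.** Relative abundance of DNA:RNA hybrids is the IP signal
normalized to equal template in the non-immunoprecipitated input: per
replicate, the input Ct is adjusted by $\log_E(f)$ for an input well
representing a fraction $f$ of the template pool (default $f = 1$,
"equal amounts of template"), and the value is
$E^{(C_t^{\mathrm{input,adj}} - C_t^{\mathrm{IP}})}$, aggregated as mean ±
SEM across replicates. An undetermined IP Ct is treated as absent signal
(value 0, flagged), never imputed. RNase H sensitivity is the ratio of
pre-treated to untreated relative abundance; hybrid-specific signal drives
it toward 0.

**RT-qPCR.** Relative expression uses the comparative-Ct (ΔΔCt) method
against an explicit reference amplicon; the reference gene is a required
parameter because no universal default is safe. Per-replicate treated
folds are taken against the mean control ΔCt to give mean ± SEM.

# Fiber combing

Tract lengths in micrometers convert to kilobases at 2.59 kb/µm. Fibers
with both IdU and CldU labels are *ongoing* forks; speed is the total
tract length over the total pulse time (20 + 20 min by default), matching
measurement of the total fiber tract. Only-first-label fibers are
*stalled*, only-second-label fibers are *new origins*; neither gets a
speed, and both are excluded from cohort mean speed (reported with class
fractions, mean ± SEM). A per-label speed variant (each segment over its
own pulse) is available behind a flag, and a configurable length
threshold (default 0 µm) decides when a marginal second label counts as
absent.

# The synthetic-data generator

`simulate_experiment` emulates the study design the analysis assumes:
eight libraries ({BRD4, γH2AX, RNAPII ser2, input} × {DMSO, JQ1}) on a
synthetic genome (default 4 × 2 Mb, 500 genes with exon/CDS structure and
overlapping gene sets of 120/150/120 genes). Background read 5' starts
are uniform; per-bin background counts are Poisson to within a chi-square
goodness-of-fit test the suite runs. Target libraries implant extra reads
over gene-set members at per-bin rate `background_rate × (fold − 1)`;
input libraries are background-only, and every library's total read count
equals its configured depth exactly. Defaults: background 0.5 reads per
25-bp bin per library (depth 160,000 reads per library), 36-base reads,
strand Bernoulli(0.5).

The 39 responsive genes (drawn from the BRD4 set) carry γH2AX fold 4
under JQ1 vs 1 under DMSO, while BRD4 (4 → 1.5) and RNAPII ser2 (3 → 1.2)
drop; non-responsive set members keep their folds across conditions.
BRD4 enrichment is TSS-weighted (half its reads in the −50/+300 window).
γH2AX enrichment spreads 2 kb beyond the gene body (`gh2ax_spread`),
reflecting propagation of damage signaling around a damaged locus; this
also means the configured fold is expressed over the same region the
calling stage scores, so the implanted fold is the recoverable quantity.
Each library draws from its own seeded stream, so adding a library never
perturbs another and a seed fixes the experiment byte-for-byte.

What the generator does *not* emulate: sequence content (no FASTQ or
mapping), GC or mappability bias, fragment-length distributions, duplicate
reads, replicate structure, or peak-shaped binding profiles beyond the
TSS weighting. Recovery results on synthetic data therefore demonstrate
the correctness and calibration of the statistical machinery under its
own assumptions — uniform background, known implants — not performance on
real libraries, where background is structured and effect sizes vary.

# Problem sizes and numerical choices

The shipped tests run the full default design (500 genes, 8 × 160k reads,
320k bins) once for recovery, ten 1-million-bin background-only runs for
type-I control, and property checks on small random fixtures; the whole
suite completes in a few minutes on one core. Ties and boundaries are
fixed as: strict `>` at the fold threshold, `p ≤ α` at significance, bins
closed on the left, final partial bins kept, windows clipped at
chromosome ends, and λ floored at 0.1. Zero-count bins are never reported
(their tail probability is 1). Depth-0 tracks cannot be normalized;
double normalization errors.

# Limitations

- The Poisson model ignores overdispersion; real input libraries are
  overdispersed, and the extreme α only partly compensates. A local λ
  window is provided but no negative-binomial alternative.
- Gene-level calls use a single scored region per gene; no peak-level or
  promoter-specific calling.
- SAM/BAM input is not parsed directly; convert alignments to BED6
  (e.g. `bedtools bamtobed`) upstream.
- The per-set summaries count genes, not loci; overlapping genes each
  receive their own call from the same signal.
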