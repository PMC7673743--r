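---
title: "Occupancy, enrichment and regulon inference at GATC resolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy, enrichment and regulon inference at GATC resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadaregulon)
```

# The scientific setting

Targeted DamID (TaDa) profiles where a chromatin protein sits on DNA in a
specific cell type: a Dam methyltransferase fusion (here, Dam::Pcl — the
Polycomb-like subunit that defines the PRC2.1 subcomplex) methylates GATC
motifs near its binding sites, and sequencing reads recover those marks.
Because methylation happens between GATC motifs, the native resolution of
the assay is the *GATC fragment* — the interval between two consecutive
GATC occurrences. A parallel Dam-only control measures chromatin
accessibility (CATaDa) and normalises away openness.

The biological question this pipeline serves is whether a repressive
complex *redistributes* on chromatin when an animal's diet changes (a
control diet, CD, versus a prolonged high-sugar diet, SD), and whether that
redistribution propagates through a small transcription-factor network into
a broadly repressive expression signature — visible as a negative skew in
the distribution of log2 fold changes (l2fc), a majority-negative set of
differentially expressed genes, and regulons (motif-defined target sets of
individual TFs) that collectively account for the changed genes.

The package implements every computational stage of that argument as
reusable functions and exercises them end to end on a synthetic genome with
planted ground truth, so that each stage's statistical behaviour
(calibration under the null, recovery of planted structure) is testable.

# Occupancy model

Fragment counts for construct $c$ at fragment $i$ are modelled (and
simulated) as Poisson,
$n_{ci} \sim \mathrm{Pois}(\lambda_{ci})$, with
$\lambda_{ci} \propto \ell_i \, a_i \, 2^{\beta \cdot 1[i \in \text{peak}]}$
— fragment length $\ell_i$, accessibility $a_i$, and a log2 occupancy
effect $\beta$ (`peak_effect`) that only the fusion construct sees and only
inside peaks planted for the matching condition. Every library is
renormalised to the same expected depth, so the fusion/Dam contrast between
peak and non-peak fragments equals $\beta$ exactly.

The occupancy track is

$$v_i = \log_2 \frac{\mathrm{cpm}^{\text{fusion}}_i + \psi}
                    {\mathrm{cpm}^{\text{Dam}}_i + \psi},$$

counts-per-million on both sides with a pseudocount $\psi = 1$ keeping the
track finite and depth-invariant. The upstream reference pipeline's
internal normalisation is not published in detail; CPM with a pseudocount
is the simplest depth-invariant choice and $\psi$ is exposed as a
parameter. Replicates are processed independently and averaged only for
display, metaprofiles and the per-gene condition comparison — whether the
original averaged before or after forming ratios is not stated, and
processing replicates separately is the conservative reading (peaks must
survive every replicate; see below).

Reads are assigned to fragments after 3'-ward extension to 300 bp or the
closest GATC boundary past the start, whichever comes first; every
fragment the extended read overlaps is incremented. Fragment boundaries
sit at the *start* coordinate of each GATC occurrence — the assay does
not distinguish which base of the motif delimits, and fixing the start
makes the convention unambiguous and testable. Minus-strand reads mirror
the rule leftward from their start base.

Accessibility tracks use the "1x genome" convention: per-bp coverage
scaled so its genome-wide mean is exactly 1,
$v_i = (n_i / \ell_i)\, L_G / N$ with $L_G$ the genome length and $N$ the
library size.

# Peak calling by shuffle FDR

A signal threshold is the `threshold_q` quantile of the track (default
0.90). Candidate peaks are maximal runs of at least `min_run = 2`
consecutive fragments strictly above it. The null distribution of run
lengths comes from permuting fragment values within each chromosome
`n_shuffles = 100` times; for a run of length $n$ the false-discovery
estimate is

$$\widehat{\mathrm{FDR}}(n) =
  \frac{\mathbb{E}_{\text{shuffle}}[\#\{\text{runs} \ge n\}]}
       {\#\{\text{observed runs} \ge n\}},$$

and runs with $\widehat{\mathrm{FDR}} < 0.01$ are reported on fragment
coordinates. Value permutation preserves both the marginal value
distribution and the fragment structure, which is the minimal null
consistent with "shuffle the dataset". The estimate is monotone
non-increasing in $n$ by construction. On pure-noise tracks the caller
produces at least one false peak in well under 5% of seeds at the default
settings (asserted over 50 seeds in the tests).

Replicate peak sets are combined by base-pair intersection (regions present
in *all* replicates), then bookended or overlapping intervals are merged
(mergeBed semantics). Genes are associated to peaks through the gene span
extended 2 kb 5' of the ORF start, strand-aware.

Per-gene occupancy differences between conditions take the mean track over
each gene's window per condition; $\Delta = \text{SD} - \text{CD}$, with
$|\Delta| \ge 0.5$ (half a log2 unit, i.e. at least a $\sqrt{2}$-fold
occupancy change) classifying genes as higher-on-SD (group 1) or
lower-on-SD (group 2).

# Interval enrichment

Overlap enrichment against an annotation (here, predicted Polycomb
response elements at prediction confidence $\ge 0.8$) uses a Monte Carlo
permutation test: the *query* peaks are placed uniformly at random on
their own chromosomes (lengths preserved, overlaps permitted) 1000 times;
the fold is observed over null mean, and the one-sided empirical p-value
uses the add-one rule $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_{\text{shuffles}})$, so it is never zero. Same-chromosome placement
preserves chromosome composition, the standard choice for genome-shuffle
nulls. For a reference covering fraction $f$ of the genome and short query
intervals, the null overlap probability per interval approaches $f$, which
the tests verify analytically on a half-genome block.

Chromatin-state enrichment is a simple observed/expected ratio: each gene
takes the state of the five-colour model (red/yellow active, blue
Polycomb, green/black repressive) at its transcription start, and the
fraction of bound genes per state is divided by the genome-wide fraction.

# Expression post-statistics

The pipeline consumes per-gene DE summaries (mean expression, l2fc,
gene-wise standard error, p) rather than refitting counts. Three
post-statistics matter:

**Skewness.** $\gamma = m_3 / m_2^{3/2}$ with denominator-$n$ central
moments $m_r = \sum_i (x_i - \bar x)^r / n$ — no bias correction, exactly
the moment form (equal to the e1071 type-1 estimator, cross-checked in the
tests). It is computed over *all detected* genes (mean expression > 0),
not only significant ones; a long negative tail of repressed genes drives
$\gamma < 0$.

**Practical equivalence.** A gene is "significantly unchanged" when the
composite null of at least a 1.5-fold true change is rejected. With
$\Delta = \log_2 1.5$ and the normality assumption on the l2fc estimate,
this is the two-one-sided-tests max-p

$$p = \max\!\left[\Phi\!\left(\tfrac{\hat\beta - \Delta}{\mathrm{se}}\right),
                  \Phi\!\left(\tfrac{-\hat\beta - \Delta}{\mathrm{se}}\right)\right],$$

BH-adjusted across the tested genes, flagged at $q < 0.1$. The max-p form
is conservative for the composite null: $p \ge 0.5$ whenever
$|\hat\beta| \ge \Delta$, and $p \to 0.5$ as the SE grows, so uninformative
genes are never declared unchanged. At the null boundary the per-test
rejection rate stays at or below the nominal $\alpha$ (verified on 10,000
simulated genes). Which gene subset enters the BH adjustment is the
caller's choice; the drivers test the genes repressed in the main contrast
within the mutant contrast.

**Support statistics.** BH FDR (step-up, via `stats::p.adjust` behind the
module surface, tested against an independent hand-rolled step-up),
IP/input cpm log-ratios for cell-type enrichment, and equally populated
rank bins (`ceiling(rank * k / n)`, stable ties) used to discretise l2fc
into seven bins for downstream category analysis.

# Regulon inference

Each TF's position weight matrix (log-odds against background) is scored
at every base on both strands. Scores become robust z,
$z = (s - \mathrm{median})/(1.4826\,\mathrm{MAD})$, with the median and
MAD always taken from the *complete* scan even though only the top 1% of
positions are retained as hits (a memory bound, configurable to 100%). A
gene joins the regulon of TF $t$ at threshold $\tau$ if it has a hit with
$z \ge \tau$ inside its 2-kb window upstream of the ORF start. Membership
is monotone: raising $\tau$ can only shrink a regulon.

The TF-specific threshold was chosen by eye in the original analysis; here
the choice is automated for reproducibility. For each candidate $\tau$ the
members' l2fc mean, SD and signal score $t(\tau) = |\bar x| \sqrt{n} / s$
are tabulated, and $\tau^\ast$ maximises $t(\tau)$ subject to a minimum
regulon size ($n \ge 20$). The full curve is always emitted so the
automatic choice can be overridden. Pairwise regulon overlaps are tested
with two-sided Fisher exact tests on the 2x2 table over the gene universe,
reporting the sample odds ratio $ad/bc$ and BH q-values.

# The synthetic study and what it does (not) show

`sim_config()` defaults define the study conditions: two 500-kb
chromosomes; GATC sites planted as a Poisson process at 1/250 bp (about
the density of a fly chromosome arm) on an i.i.d. uniform background that
is scrubbed of spontaneous GATCs, so the fragment structure is exactly
controlled; 400 genes in equal slots with 2-kb promoters; 20 shared, 20
gained and 20 lost occupancy peaks, each a run of 5-8 GATC fragments at
log2 effect 2 over a host gene; PRE-like intervals (confidence 0.8-1)
centered on 80% of peaks plus lower-confidence background PREs; a
five-colour chromatin tiling with peak-host slots blue; five TF motifs
(width-10 consensus, one exact site planted per true member promoter, so
the 2-kb window rule is the discriminating feature); 30% of genes
repressed at mean l2fc -1 (SD 0.3), each belonging to about two regulons
so the regulon union covers the changed set and pairwise overlaps are
enriched; gene-wise SEs $0.1 + 0.2\,\mathrm{Exp}(1)$ (a positive family
with a heavy-ish right tail mimicking low-count genes); read depth 5e5
per sample, chosen for desk-scale power so that per-fragment Poisson noise
does not fracture planted runs; two replicates per condition per
construct, matching the 2-3 of typical designs.

Each TF's *achieved* planted threshold (the robust z of its consensus
score against that genome's background score distribution) is recorded in
the truth object at simulation time, which is what makes
threshold-recovery assertions possible.

The generator emulates the statistical structure the analysis assumes —
Poisson counts, accessibility confounding, fragment-aligned peaks,
motif-driven repression — but not read-level artefacts (sequencing error,
mappability, PCR duplicates), overdispersion beyond Poisson, correlated
gene-gene effects, or realistic gene length and motif degeneracy. Passing
tests therefore demonstrate that the *procedures* are correct and
calibrated under their stated models, not that the biological conclusions
of any particular real dataset are right.

# Numerical choices and degenerate inputs

* Quantile thresholds use R's default type-7 quantile; runs are *strictly*
  above threshold, so constant tracks yield no peaks rather than an error.
* `scan_motif` on a degenerate (constant) score distribution warns and
  returns z = 0; the standalone `robust_z` errors on zero MAD and suggests
  a fallback dispersion.
* PWM scores are discrete sums, so the retention floor keeps all ties at
  the cut; N bases score 0 (background odds).
* Metaprofile bins are sampled at the fragment containing `mid + offset`;
  bins off the chromosome are dropped from the mean, not zero-filled.
* Empty intersections, empty peak sets and genes overlapping no fragment
  are data, not errors; they propagate as empty tables or NA with the
  grouping skipped.
* All coordinates are 0-based half-open throughout (BED convention); GFF3
  output converts to 1-based closed.
* Stage seeds derive arithmetically from the single global seed and the
  stage name, so any stage can be re-run in isolation bit-reproducibly.

# Problem sizes

The default study (1 Mb genome, ~3,900 fragments, 400 genes, five TFs,
100 peak-calling shuffles, 1000 enrichment shuffles) runs the full
pipeline in well under a minute on one core; the test suite's calibration
loops (50 noise seeds for the peak caller, 10,000 boundary genes for the
equivalence test) were sized to keep Monte Carlo error small relative to
the asserted bounds while staying desk-scale.

# Known limitations

* The shuffle null permutes fragment values, ignoring spatial
  autocorrelation of real occupancy tracks; on strongly autocorrelated
  data the FDR estimate is anti-conservative, and a block-shuffle variant
  would be the natural extension.
* The threshold-selection statistic assumes approximately independent
  member l2fcs; correlated regulons would inflate $t(\tau)$.
* Interval shuffling is not gap- or blacklist-aware.
* DE tables are consumed as given; no shrinkage or dispersion modelling is
  applied to the l2fc estimates beyond their reported SEs.
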