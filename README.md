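# tadaregulon

Targeted DamID (TaDa) occupancy analysis at GATC-fragment resolution, with
shuffle-FDR peak calling, Monte Carlo interval-overlap enrichment,
differential-expression post-statistics, and PWM-based transcription-factor
regulon inference — exercised end to end on a synthetic genome with planted
ground truth.

## Who this is for

TaDa profiles where a chromatin protein (here a Dam::Pcl fusion marking the
PRC2.1 Polycomb subcomplex) binds DNA in a chosen cell type; the Dam-only
control doubles as a chromatin-accessibility read-out (CATaDa). The
scientific claim the pipeline supports is that the complex *redistributes*
on chromatin between two conditions (control diet CD vs sugar diet SD) and
represses a transcription-factor network, visible as:

* occupancy peaks gained/lost between conditions,
* peak enrichment at predicted Polycomb response elements (PREs),
* bound genes concentrated in "blue" (Polycomb) chromatin,
* a negatively skewed log2 fold-change (l2fc) distribution with a
  majority-negative DEG set,
* TF regulons (genes with a high-z motif hit within 2 kb upstream of the
  ORF start) that collectively cover the changed genes.

Every stage is a plain R function over standard containers (data frames in
BED-style 0-based half-open coordinates, Biostrings sequences), so any
stage can be run on real data tables produced elsewhere.

## The statistics at the core

* Occupancy: `log2((cpm_fusion + psi) / (cpm_Dam + psi))` per GATC
  fragment; reads extended 3'-ward to 300 bp or the next GATC.
* Peaks: runs of >= 2 fragments above a track quantile; FDR(n) =
  E_shuffle[runs >= n] / observed[runs >= n] from within-chromosome value
  permutations; peaks kept at FDR < 0.01, intersected across replicates.
* Enrichment: fold = observed / mean(null) over 1000 uniform
  length-preserving placements of the query on its own chromosomes;
  add-one empirical p.
* Skewness: m3 / m2^(3/2), denominator-n central moments, over all
  detected genes.
* "Significantly unchanged": TOST max-p against the composite null of at
  least a 1.5-fold true change, p = max(Phi((b - D)/se), Phi((-b - D)/se))
  with D = log2(1.5), BH-adjusted, flagged at q < 0.1.
* Regulons: robust z = (s - median) / (1.4826 MAD) of genome-wide PWM
  scores; member iff a hit with z >= tau sits in the 2-kb upstream window;
  tau* maximises |mean l2fc| * sqrt(n) / sd over a grid (n >= 20), with the
  full threshold curve emitted for manual override; pairwise regulon
  overlaps tested by two-sided Fisher exact tests with BH FDR.

The methods vignette (`vignettes/tadaregulon-methods.Rmd`) derives and
motivates each of these, including the synthetic-data generator's design.

## Worked example

```r
library(tadaregulon)

run <- run_pipeline(pipeline_config(sim_config(seed = 1)))
print(run)
#> PipelineRun (seed 1 ): 40 CD / 40 SD peaks; skew(SD) = -0.707

r <- run$report
r$pre_enrichment$fold          # 5.22  — SD peaks vs confident PREs
r$pre_enrichment$p_empirical   # 0.000999 (1000 shuffles, add-one rule)
r$chromatin_states$blue        # 4.30  — blue is the maximal state ratio
r$expression$skewness$SD_vs_CD # -0.707 — repression signature
r$truth_recovery$peak_jaccard_SD        # 0.999 — called vs planted peaks
unlist(r$truth_recovery$regulon_jaccard) # 0.94-0.98 per TF
```

40 peaks per condition are the 20 shared + 20 condition-specific planted
peaks, recovered at bp Jaccard ~1; half the SD peaks overlap a CD peak
(the shared set). The negative skew comes from the 30% of genes planted
with mean l2fc -1; the mutant contrast (`PclSD_vs_CD`), in which all true
effects are abolished, shows skew near 0 and zero DEGs. Regulon inference
re-finds the planted z thresholds within one grid step and the planted
memberships at Jaccard >= 0.9.

The same computations are available step by step as narrative drivers:

```sh
Rscript analysis/01_simulate.R        # genome.fa, genes.gff3, counts/, de/
Rscript analysis/02_occupancy_tracks.R
Rscript analysis/03_peaks.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_expression.R
Rscript analysis/06_regulons.R
Rscript analysis/07_report.R          # consolidated run_report.json
```

Each writes plain-text artifacts (FASTA/GFF3/BED/bedGraph/TSV/JSON) under
`results/`.

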