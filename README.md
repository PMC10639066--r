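# pausekit

Analysis toolkit for promoter-proximal RNA polymerase II pausing from
nascent-transcription data.

Precision run-on sequencing (PRO-seq) maps the 3' end of every engaged
Pol II molecule to a single nucleotide, strand-specifically. The signal at a
gene splits into a promoter-proximal paused peak just downstream of the TSS
and a lower occupancy across the gene body; drugs that act on transcriptional
kinases shift mass between the two compartments. pausekit is for
computational biologists who want to quantify those shifts: it measures
pausing, tests gene-body transcription for treatment effects, profiles
average polymerase distributions, scores ranked gene lists against gene-set
collections, and quantifies drug-pair synergy — all on top of a synthetic
data generator with exact ground truth, so every stage is benchmarked
without any external download.

## What it computes

* **Window quantification** — promoter-proximal window (TSS −250 to +250 nt)
  and gene-body window (TSS +250 nt to CPS −500 nt), strand-matched,
  0-based half-open coordinates, from per-strand bedGraph tracks or
  simulated coverage.
* **Pausing index and its change**

      PI = [(p + ε)/500] / [(b + ε)/(L − 750)],   ΔPI = PI_treatment − PI_control

  with replicate-summed counts per condition and time-matched controls.
* **Differential transcription** — median-of-ratios size factors, a
  simplified negative-binomial Wald test (trended dispersion from
  method-of-moments estimates; `Var(log μ̂) ≈ (1/n)(1/μ + α)`), an own
  step-up Benjamini-Hochberg implementation, and the engaged-Pol II
  classification thresholds (padj ≤ 0.05, FC ≥ 1.25 up / ≤ 0.8 down) plus
  RNA-abundance thresholds (padj ≤ 0.001, |log2FC| ≥ 1).
* **Metagene profiles** — 10-nt bins over TSS ±1000 nt, a 50-bin scaled gene
  body, and CPS −1000 to +2000 nt, strand-aware and size-factor normalized.
* **Preranked GSEA** — weighted running-sum ES ∈ [−1, 1], NES and FDR q from
  random same-size gene sets (exact enumeration on small universes).
* **Bliss synergy** — vehicle normalization of dose matrices, per-cell
  expected effect `E = fA + fB − fA·fB`, excess and score (100 × excess);
  ΔΔCt relative quantification for qPCR.
* **Synthetic experiments** — non-overlapping gene annotations, NB-dispersed
  replicate tracks with a pause peak at +30..+60 nt, treatment scenarios
  that release pausing (promoter down, body up) or block release (promoter
  up, body down), and replicated dose matrices with planted synergy.

## Worked example

Simulate a 300-gene experiment in which 30% of genes respond to a gene-body
kinase inhibitor by releasing paused polymerase into the body
(promoter ×0.6, body ×1.5), then run the full pipeline:

```r
library(pausekit)
cfg <- simulation_config(
  n_genes = 300, genome_length = 6e6, depth_per_sample = 3e5,
  conditions = list(
    scenario_effect("DMSO"),
    scenario_effect("CDK12i", affected_fraction = 0.3,
                    pause_multiplier = 0.6, body_multiplier = 1.5)),
  seed = 42)
run <- run_analysis(run_config(cfg, contrasts = list(c("CDK12i", "DMSO"))))
print(run)
#> <pausekit_run>
#>   annotated     300 genes
#>   quantifiable  300 genes
#>   active        300 genes
#>   CDK12i_vs_DMSO: 81 UP, 9 DOWN, 210 NS
```

81 genes gain body transcription at the engaged-Pol II thresholds. The
pausing records show where the released polymerase came from:

```r
head(run$pausing[, c("gene_id", "pi_DMSO", "pi_CDK12i",
                     "dpi_CDK12i_vs_DMSO")], 4)
#>   gene_id pi_DMSO pi_CDK12i dpi_CDK12i_vs_DMSO
#> 1  G00001   1.190     1.118           -0.07169
#> 2  G00002   2.999     2.214           -0.78495
#> 3  G00003   3.939     3.526           -0.41292
#> 4  G00004   2.307     2.115           -0.19234

d <- run$diff[[1]]
head(d[order(d$padj), c("gene_id", "baseMean", "log2FC", "p", "padj",
                        "class")], 4)
#>     gene_id baseMean log2FC        p     padj class
#> 76   G00076     2325  0.685 1.03e-11 3.09e-09    UP
#> 243  G00243     1338  0.673 1.90e-10 2.86e-08    UP
#> 29   G00029      659  0.710 1.36e-09 1.36e-07    UP
#> 207  G00207      649  0.681 6.84e-09 5.13e-07    UP
```

Comparing against the generator's truth table: 85% of the planted genes are
recovered as UP, the median ΔPI of affected genes is −1.45 (pausing lost as
the body gains) while unaffected genes sit at −0.02 ≈ 0. The median log2FC
among affected genes is 0.42, attenuated below the generative
log2(1.5) = 0.585 because median-of-ratios normalization absorbs part of a
30%-asymmetric shift — exactly as it would on real libraries.

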