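# bifor

Quantification of dimeric protein-complex enrichment at a labelled genomic
locus from multi-channel nuclear images.

## The problem

Bimolecular fluorescence complementation (BiFC) makes a protein–protein
interaction visible as reconstituted fluorescence, and the ANCHOR
(ParB–*INT*) system marks a genomic region of interest as a bright
ParB–mCherry focus in the same nucleus. Combining the two lets one ask
whether a specific transcription-factor dimer — e.g. the Hox/cofactor pair
Scr/Exd on the *fkh250* enhancer in *Drosophila* salivary-gland nuclei — is
enriched at its target enhancer relative to the rest of the nucleus.

`bifor` turns that question into numbers. For each nucleus with locus region
$L$ inside nucleus region $N$ and green (BiFC) intensity $g$, it computes
the enrichment ratio

$$E = \frac{\max_{x \in L} g(x)}{\max_{x \in N} g(x)} \in (0, 1],$$

and compares conditions with two-sided per-nucleus tests labelled
`***` (p ≤ 1e-4), `*` (p ≤ 0.01) or `ns`.

The package covers the full pipeline:

* **Simulation** — a seeded generator of banded-DAPI nucleus scenes with a
  ParB-style red focus, a partially chromatin-coupled green background, an
  optional multiplicative green enrichment at the locus (`enrichment_beta`),
  Gaussian PSF, and Poisson + read noise; ground truth is returned with
  every scene. Seven condition presets mirror the reference experiment.
* **I/O** — multi-channel 16-bit TIFF stacks with channel-role metadata and
  CSV dataset manifests.
* **Segmentation** — Otsu-based nucleus mask from DAPI; brightest-focus
  locus ROI from the red channel with quantile thresholding and small
  dilation.
* **Statistic and statistics** — the ratio above (plus a robust quantile
  variant), Mann–Whitney and seeded/exhaustive permutation tests, replicate
  summaries, and pooled-plus-replicate-level comparison tables.

## Worked example

```r
library(bifor)

res <- run_pipeline(list(seed = 1L), outdir = "demo_run")
subset(res$comparisons,
       select = c(condition_a, condition_b, p, label, p_replicate))
```

With the default configuration (7 presets, 10 nuclei × 3 replicates each)
this prints:

```
   condition_a  condition_b            p label  p_replicate
1   SCR_EXD_WT   UBX_EXD_WT 4.573589e-12   *** 0.0002438420
2   SCR_EXD_WT SCR_ALONE_WT 1.211780e-12   *** 0.0065435313
3   SCR_EXD_WT UBX_ALONE_WT 1.211780e-12   *** 0.0006960933
4   SCR_EXD_WT  SCR_EXD_MUT 1.211780e-12   *** 0.0077077011
5  SCR_EXD_MUT SCR_ALONE_WT 7.618283e-01    ns 0.9846118021
6 SCR_EXD_CONS SCR_ALONE_WT 1.720251e-12   *** 0.0065451918
7 UBX_EXD_CONS UBX_ALONE_WT 1.720251e-12   *** 0.0006923954
8 SCR_EXD_CONS UBX_EXD_CONS 1.000000e+00    ns 0.5775158667
```

Read: the enrichment-positive conditions (Scr/Exd on the wild-type enhancer,
both Hox/Exd pairs on the consensus variant) separate cleanly from their
negative controls; the binding-site mutant shows no enrichment relative to
its null, and the two consensus-variant complexes are indistinguishable from
each other. `p` is the pooled per-nucleus Mann–Whitney p-value and
`p_replicate` the Welch t-test on per-replicate means; `label` applies the
three-tier convention to `p`. The run directory additionally holds
`scores.csv` (one row per analyzable nucleus with QC flags),
`exclusions.csv` (excluded nuclei with reasons), `manifest.csv`,
`replicate_summary.csv`, `config.yaml` (replays the run exactly), `run.log`
and an advisory `scores.pdf`.

A command-line front end with the same stages is installed at
`inst/scripts/bifor` (`simulate`, `quantify`, `compare`, `run`).

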