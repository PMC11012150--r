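---
title: "Quantifying dimeric-complex enrichment at a labelled locus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dimeric-complex enrichment at a labelled locus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Bimolecular fluorescence complementation (BiFC) reports a protein–protein
interaction as a reconstituted fluorescent signal: two candidate partners are
fused to complementary non-fluorescent fragments of a fluorophore, and
fluorescence appears where the partners interact. Coupling BiFC with the
ANCHOR (ParB–*INT*) DNA-labelling system marks a genomic region of interest
as a bright ParB–mCherry focus in the same nucleus, so one can ask whether a
specific dimeric transcription-factor complex is *enriched* at a specific
enhancer, rather than merely present in the nucleus. The reference
application is the Scr/Exd complex on the *fkh250* enhancer in *Drosophila*
salivary-gland nuclei, whose polytene chromosomes amplify both the locus
label and the binding signal.

`bifor` implements the quantification side of such an experiment. Its input
is a set of multi-channel nuclear images — DAPI (chromatin), red
(ParB–mCherry locus label) and green (BiFC or immunostaining) — plus a
manifest assigning each nucleus to a condition and biological replicate. Its
output is a per-nucleus enrichment score and per-condition significance
calls.

## The enrichment statistic

For one nucleus, with $L$ the locus region and $N$ the whole nucleus
($L \subseteq N$), the score is

$$E \;=\; \frac{\max_{x \in L}\, g(x)}{\max_{x \in N}\, g(x)} \in (0, 1],$$

where $g$ is the green-channel intensity. The whole-nucleus maximum includes
the locus, which is what bounds $E$ by 1; $E = 1$ exactly when the locus
contains a nucleus-global maximum voxel. The statistic deliberately has no
background subtraction; note that adding a constant offset $c$ moves
$(m+c)/(M+c)$ monotonically towards 1, so acquisition offsets compress the
dynamic range rather than bias the direction of an effect. An optional
in-nucleus median subtraction (clipped at zero) is available and off by
default.

Because a literal maximum is an extreme order statistic, it is sensitive to
shot noise. A robust variant replaces both maxima by the $q$-quantile of the
respective voxel sets (`estimator = "quantile"`, default $q = 0.999$). The
strict maximum remains the default; the quantile variant is shipped so the
two can be compared on identical data.

## Regions

**Nucleus (DAPI).** The channel is Gaussian-smoothed, thresholded with Otsu's
method on a 256-bin histogram over the observed range, holes are filled,
components below `min_size` (default 500 voxels) are dropped, and the
largest remaining connected component is returned. Otsu on the observed
range makes the mask invariant to intensity rescaling. The smoothing sigma
default is 6 voxels: it must exceed the polytene band wavelength (about 15
voxels at the default geometry), otherwise the threshold separates bands
from interbands instead of nucleus from background. Nuclei touching the
image border are flagged and excluded from scoring by default, since a
truncated nucleus biases a maximum-based statistic.

**Locus (red).** Within the nucleus, voxels above the `threshold_quantile`
(default 0.995) of in-nucleus red intensities form candidate foci; the focus
with the highest peak is kept. A quantile threshold adapts to dimmer foci —
the binding-site-mutant construct's ParB focus is typically dimmer — without
a per-dataset absolute threshold. The selected focus is dilated by
`dilation_radius` (default 2 voxels) and re-intersected with the nucleus, so
chromatic aberration or registration offsets of a voxel or two cannot zero
the overlap between the label and the signal; the tests verify that the ROI
and its maximum grow monotonically with this radius. Constructs carry a
single insertion, so extra candidate foci indicate noise or artefacts: they
are counted, reported in the score table's `qc` column, and a warning is
raised. The reported centroid is intensity-weighted over the pre-dilation
focus, because the dilated ROI's shape reflects the dilation and the nucleus
boundary rather than the focus itself.

All coordinates in the package are 1-based with axis order (Z,)Y,X, matching
R's array indexing; masks are logical arrays congruent with the channels.

## Group comparison

Scores are compared between conditions two-sidedly, per nucleus. The default
test is the Mann–Whitney U (normal approximation), a robust choice for a
bounded ratio with ties; a seeded permutation test on the difference of
means is the reference implementation — it enumerates all group assignments
exactly whenever there are at most `n_perm` of them, and otherwise uses
`n_perm` (default 10,000) seeded shuffles with an add-one Monte-Carlo
p-value. Significance is reported with three tiers: `***` for
$p \le 10^{-4}$, `*` for $p \le 0.01$, `ns` otherwise — no intermediate
`**` tier is defined.

The experimental unit is ambiguous in this design: scores are per nucleus,
but conditions come from a small number of biological replicates. The
package therefore always reports both: the pooled per-nucleus comparison
and, alongside it, a replicate-level comparison on per-replicate mean scores
(Welch's t-test). A rank test is not used at the replicate level because
with the usual three replicates per condition its smallest attainable
p-value is 0.1, which can never clear the 0.01 tier. No multiplicity
adjustment is applied by default (each contrast answers its own planned
question); Holm adjustment is available behind a flag.

## The synthetic-scene generator

Real acquisitions for this assay are not publicly deposited, so the package
ships a seeded generator that renders nucleus scenes with known ground
truth; it is first-class, tested code, and every downstream stage is
validated against it.

A scene is an elliptical (2D, default) or ellipsoidal (3D) nucleus:

* **DAPI**: sinusoidal stripes of random orientation and phase, warped by a
  smooth random field — a stand-in for polytene banding. Only the
  band/interband contrast statistics matter downstream, not anatomy.
* **Red**: one Gaussian focus of amplitude `locus_amplitude` at
  `locus_center` with per-axis widths `locus_sigma`; the per-scene jitter of
  position and widths reproduces the variable size and shape of real ParB
  foci.
* **Green**: a background mixing a band-following and a band-independent
  smooth texture with weight `green_band_coupling` (default 0.6 — the real
  signal overlaps chromatin only partially), multiplied by
  $1 + \beta\,p(x)$, where the profile $p$ is 1 on the 2-sigma locus
  ellipsoid and decays as a Gaussian outside. $\beta$
  (`enrichment_beta`) is the effect-size knob the pipeline must recover;
  $\beta = 0$ is the null.

Each channel is convolved with a Gaussian PSF and then sampled as Poisson
photons plus Gaussian read noise, clipped at zero. Two numerical choices are
deliberate: the enrichment factor is applied *after* PSF blurring (the
factor field is already smooth at the PSF scale), which makes the
construction exactly multiplicative — the noise-free green maximum inside
the locus scales exactly by $1 + \beta$ — and the smooth textures are drawn
on a stride-4 coarse grid and bilinearly upsampled, which is statistically
equivalent at their correlation lengths and much faster. Ground truth
(masks, centre, $\beta$, noise-free channels, and the pre-enrichment green
background) is returned with every scene.

Default geometry is a single 256×256 optical section at 60 nm pixels with a
PSF sigma of 0.85 px, i.e. a FWHM of about 120 nm — the resolution scale of
a deconvolved confocal acquisition; full-frame acquisition sizes are
unnecessary for validating the statistic, and a section suffices to exercise
per-nucleus maxima. 3D volumes are supported throughout with an anisotropic
PSF.

Seven condition presets mirror the validation experiment's contrasts:
Scr/Exd on the wild-type enhancer and both Hox/Exd pairs on the consensus
variant are enriched ($\beta = 1.5$); Ubx/Exd on wild type, either Hox
alone, and Scr/Exd on the binding-site mutant are null ($\beta = 0$). The
Ubx/Exd BiFC background is set to three times the Scr/Exd level, and the
mutant's locus amplitude to half the wild type, reflecting the reported
phenomenology. These presets are fixed study conditions, not tuning knobs.

What the generator does **not** emulate: a realistic Airy/vendor PSF and
deconvolution artefacts, spectral bleed-through, chromatic mis-registration
beyond what the dilation absorbs, multi-nucleus fields, autofluorescence
gradients, and real polytene anatomy. Passing tests therefore demonstrate
that the pipeline recovers known effects under controlled optics and noise —
not that segmentation would survive arbitrary real-world acquisitions.

## Determinism and problem sizes

Every stochastic step — scene noise, per-scene jitter, permutation shuffles —
runs under a private, seeded RNG scope that restores the caller's stream, so
one config plus one seed reproduces a run byte-identically (the test suite
asserts identical CSVs across reruns). Seeds derived internally stay below
$2^{31}$.

The shipped validation uses desk-scale problem sizes chosen to exercise each
claim: exactness of the statistic on 200 brute-force-checked toy scenes;
segmentation/detection on 20 ground-truth scenes per preset (nucleus IoU,
locus centroid error, detection of the dimmer mutant focus); the
seven-condition pattern at 30 nuclei per condition across 3 replicates with
the per-pair significance pattern repeated over 50 seeded experiments;
type-I error of the default test at $\alpha = 0.01$ over 200 null
comparisons of 30 vs 30; and Poisson variance-to-mean calibration over more
than $10^5$ flat voxels.

## A minimal run

```{r, eval = FALSE}
library(bifor)
res <- run_pipeline(list(seed = 1L), outdir = "demo_run")
read.csv(file.path("demo_run", "comparisons.csv"))
```

The run directory contains the manifest, per-nucleus scores with QC flags,
exclusions with reasons, the comparison table with both pooled and
replicate-level p-values, the replayable YAML config, a log, and an advisory
box/strip plot of the per-condition score distributions with significance
labels.

## Known limitations

* The locus ROI delimitation (quantile threshold + dilation) is this
  package's choice; assays differing strongly in focus brightness may need
  `threshold_quantile` adjusted.
* The strict-max statistic is noise-sensitive by construction; comparisons
  between acquisitions with very different photon budgets should prefer the
  quantile estimator.
* Scores near saturation ($E \to 1$) compress real effect differences; the
  statistic discriminates enrichment presence well, not its magnitude.
* 3D morphology (labelling, dilation) is implemented in plain R and is
  slower than the 2D path, which uses compiled EBImage routines.
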