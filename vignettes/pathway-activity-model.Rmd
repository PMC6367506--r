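---
title: "Quantifying signal transduction pathway activity with a calibrated Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying signal transduction pathway activity with a calibrated Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathact)
library(dplyr)
```

## The model

A signal transduction pathway ends in a transcription complex (TC) — the
pathway-associated transcription factor — that, when active, transcribes a
characteristic set of direct target genes. `pathact` infers the probability
that the TC is in its active state in a *single* expression sample from the
mRNA levels of those target genes, using a tree-structured Bayesian network
with three layers:

* **TC** — one latent binary node (active / inactive) with prior
  `P(active)` (default 0.5, symmetric ignorance, overridable per model);
* **target genes (TG)** — one latent binary node per gene (up / down),
  connected to the TC by `P(up | active)` and `P(up | inactive)`. These
  describe how reliably the gene responds to the complex and are
  literature-derived model inputs with defaults 0.90/0.10 for up-regulated
  genes (mirrored for down-regulated ones). Down-regulation is encoded
  purely by the ordering `P(up|active) < P(up|inactive)`; probeset tables
  are never flipped, so there is a single canonical encoding;
* **probesets (PS)** — one observed binary node (high / low) per microarray
  probeset measuring a gene, connected to its gene by `P(high | up)` and
  `P(high | down)`. These are *calibrated* from ground-truth samples (below).

Because the network is a tree, exact inference is closed-form: conditional
on the TC state the genes are independent, and conditional on a gene its
probesets are independent, so the likelihood of the evidence factorises
over genes. For TC state $s$,

$$ L(s) \;=\; \prod_j \Big[ P(\mathrm{up}\mid s)\prod_k f_{jk}(\mathrm{up})
 \;+\; P(\mathrm{down}\mid s)\prod_k f_{jk}(\mathrm{down}) \Big], $$

and the posterior is $P = \pi L(\mathrm{act}) / (\pi L(\mathrm{act}) +
(1-\pi) L(\mathrm{inact}))$. The result is reported as the **pathway
activity score** $\log_2 (P / (1-P))$, which shows more detail than $P$
near 0 or 1; scores are additive — the prior log2odds plus one
log-likelihood-ratio contribution per gene — which is what
`tidy(infer_activity(...))` exposes. Optionally the score is standardised
to a 0–100 scale by a clipped affine map.

`infer_activity()` is verified against `joint_enumeration_oracle()`, a
deliberately naive summation over every joint configuration of all hidden
nodes, on hundreds of random networks to $10^{-10}$.

### Soft evidence

The network's probeset nodes are binary, but hybridization intensities are
continuous. Each probeset has a discretization threshold on the
`log2(intensity + 1)` scale and a steepness parameter; the weight of the
"high" state is

$$ w = \operatorname{logistic}\big((\log_2(x+1) - \tau)\,\kappa\big), $$

so `soft_scale` $\kappa \to \infty$ recovers a hard high/low cut, which is
also available as `mode = "hard"`. Both modes keep the binary conditional
probability semantics; soft weighting simply propagates measurement
uncertainty near the threshold instead of forcing a call. Missing values
(and probesets absent from a sample) contribute **no** evidence and are
marginalised out — dropping a probeset from the evidence is exactly
equivalent to removing it from the network, a property the tests assert.

### Numerical choices

Likelihoods are accumulated in log space. The probability entering the
log2odds transform is clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-12}$, capping scores at $\pm\log_2((1-\varepsilon)/
\varepsilon) \approx \pm 39.86$: scores stay finite and comparable. At a
decision threshold the tie goes to "inactive" — a deterministic,
conservative rule. Threshold recalibration scans midpoints between
adjacent sorted scores and breaks objective ties toward the candidate
nearest 0.

## Calibration, freezing, thresholds

Intensities are absolute, so the probeset layer must be calibrated on
samples whose pathway state is known (the "ground truth" — e.g. a
ligand-stimulated versus deprived cell line). `calibrate_model()`:

1. places each probeset's discretization threshold at the midpoint of the
   per-class medians of `log2(intensity + 1)`;
2. hard-assigns each gene's latent state from the sample label and the
   gene's direction (an active label puts up-regulated genes in the "up"
   state; no EM refinement — the labels *are* the ground truth), then
   estimates `P(high | up)` and `P(high | down)` by Laplace-smoothed
   counting with pseudocount $a = 1$:
   $\hat p = (k + a)/(n + 2a)$, guaranteeing non-degenerate probabilities;
3. freezes the model.

A frozen model rejects any refit of its probabilities; every subsequent
dataset is scored by *exactly the same model*, so scores are directly
comparable across datasets and tissue types. What may still change is the
decision threshold: a new cell or tissue context can get its own cut
(`set_threshold(model, 5, "brain")`) without touching the model. The
default cut is log2odds 0, i.e. probability 0.5.

### What hard assignment estimates — and when recovery is exact

Hard label-based assignment makes the fitted probeset probabilities
estimates of $P(\text{high} \mid \text{TC state})$, not of
$P(\text{high} \mid \text{gene state})$. The two differ by two mixing
terms: gene-layer discordance contributes a bias
$(1 - P(\mathrm{up}\mid\mathrm{active}))\,(p_{\mathrm{hi|up}} -
p_{\mathrm{hi|down}})$, and overlap of the two intensity components
attenuates the estimate by about $\Phi(-\Delta\mu/2\sigma)(2p-1)$. With
the default simulator settings (gene layer 0.90/0.10, $\Delta\mu = 4$,
$\sigma = 1$) these biases are each of order 0.02–0.06 — an inherent
property of calibrating through a noisy gene layer, not an estimator bug.
The parameter-recovery tests therefore simulate *calibration-grade*
conditions — near-deterministic gene concordance (0.995), strongly
informative probesets (0.95/0.05) and well-separated intensity components
($\sigma = 0.5$) — under which the fitted tables recover the generating
ones to within ±0.05 at 500 samples per class. Under weaker, more
realistic conditions calibration still separates the classes (the
round-trip test below); it just no longer targets the literal generating
numbers.

## The synthetic-data generator

`simulate_dataset()` is the generative mirror of the network: the TC state
is set by the sample label, gene states are drawn from the gene layer,
probeset states from the probeset layer, and the linear-scale intensity is
emitted as $2^x - 1$ with $x \sim N(\mu_{\text{state}}, \sigma)$. Defaults
$\mu_{\text{low}} = 6$, $\mu_{\text{high}} = 10$, $\sigma = 1$ emulate
well-separated hybridization signals on a MAS5-like scale; `dropout_rate`
produces missing measurements; a single seed drives one generator stream,
so datasets are bit-reproducible. $\sigma = 0$ is allowed as a degenerate
noiseless limit used to check the generator's state mixture in closed
form.

The generator emulates the two-class latent structure of calibration
arrays and nothing else: no probe-level structure, batch effects,
cross-hybridization, or tissue-specific baselines. Passing tests on
simulated data demonstrate the *internal consistency* of the
calibrate–freeze–score machinery, not performance on real arrays.

### Study sizes used by tests and the acceptance script

Chosen to make each check statistically decisive: inference vs oracle on
100 random networks of up to ~18 hidden nodes; recovery at 500
samples/class over 10 seeds; round-trip classification with a
pathway-scale signature of 25 target genes × 2 probesets (the method is
designed around signatures of roughly 25–35 genes; a 3-gene toy is
dominated by single-gene discordance and is *not* expected to reach 95%
hold-out accuracy), calibrated on 200/class and scored on 50/class held
out. The label-shuffled control needs care: a model calibrated on shuffled
labels carries a small *shared* residual signal, so its hold-out accuracy
on any single shuffle is widely dispersed around 0.5 (sd ≈ 0.25 for a
6-probeset model) rather than binomially concentrated. The control is
therefore the mean over 30–50 independent shuffles, which concentrates
near 50%.

## The PI3K–FOXO readout and the SOD2 stress rule

The PI3K pathway model actually measures the transcriptional activity of
FOXO, which PI3K signalling removes from the nucleus: in the absence of
cellular oxidative stress, PI3K activity is the *inverse* of FOXO activity
(`pi3k_log2odds = -foxo_log2odds`). Under oxidative stress FOXO is
alternatively phosphorylated and transcribes stress-protective targets —
notably SOD2 — so high FOXO activity no longer implies low PI3K activity.
`assess_oxidative_stress()` flags a sample as stressed when its SOD2
expression strictly exceeds the reference mean plus two standard
deviations of normal (non-stressed) tissue; at or below the threshold the
sample is non-stressed. The SD uses the sample (n−1) denominator — the
reference set is a sample of normal tissue — and when several probesets
measure SOD2 their mean is used (`sod2_level()`, configurable list). For a
stressed sample the PI3K call is `"indeterminate"` and no score is
emitted: formally no conclusion can be drawn. Reference levels and
designated probesets are configuration inputs, per tissue type.

## Quality control

Twelve quality parameters are conventionally checked on this array
platform. Five are computable from an expression matrix and implemented:
no negative intensities, no saturated (>65535, 16-bit) intensities, mean
intensity inside a configured band, and GAPDH and ACTB 3′/5′ ratios below
a cap (default 3). The other seven (spike-in controls, border controls,
centre of intensity, RNA degradation slope, present calls) require
probe-level CEL data; they are reported as explicit not-evaluable rows so
the report format keeps their slots, and they fail a sample only in
strict mode. All numeric cut-offs are configuration defaults following
platform convention, with no claim of reproducing any published values.

## Worked example

```{r example}
m <- read_model_spec(system.file("extdata", "ar_example_model.json",
                                 package = "pathact"))
sim <- simulate_dataset(m, n_active = 30, n_inactive = 30, seed = 11)
frozen <- calibrate_model(m, sim$expression, sim$labels)
glance(frozen)

holdout <- simulate_dataset(m, 10, 10, seed = 12)
scores <- score_samples(holdout$expression, frozen) |>
  left_join(holdout$labels, by = "sample_id")
scores |> count(label, call)
```

```{r plot, fig.width = 5, fig.height = 3}
plot_activity_scores(scores, group = "label", threshold = 0)
```

## Statistics

Group comparisons use Wilcoxon tests: the unpaired rank-sum test (one- or
two-sided) and the paired two-sided signed-rank test. For small samples
the p-value comes from full enumeration of the permutation distribution of
the observed midranks — exact under ties too — and above the cutoff the
tie-corrected normal approximation with continuity correction is used.
Unpaired inputs default to the rank-sum test, and the choice is logged.
Raw p-values are reported (no multiplicity correction by default).
Pathway–pathway association computes both Pearson and Spearman
correlation; reports surface Pearson, with Spearman as a rank-level
consistency check. Constant inputs and all-zero paired differences are
reported as not-evaluable rather than erroring.

## Known limitations

* Matrix-level QC only; CEL-level checks are out of scope by design.
* Calibration assumes the ground-truth labels are correct and hard-assigns
  gene states; an EM refinement is deliberately not provided.
* The example model file ships with *synthetic* conditional probabilities
  and an illustrative gene list; it is an editable template, not a
  validated assay.
* The simulator's Gaussian two-component intensity model is the simplest
  generative counterpart of the binary probeset nodes; real arrays are
  messier in every direction listed above.
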