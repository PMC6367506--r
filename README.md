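# pathact

Quantitative measurement of signal transduction pathway activity —
androgen receptor (AR), Hedgehog (HH), TGFβ, NFκB, Wnt, ER, PI3K–FOXO and
similar — in **individual** expression samples.

Most enrichment-style tools tell you which gene sets differ between two
*groups* of samples. A diagnostic question is different: *is this pathway
functionally active in this one patient's sample?* `pathact` answers it
with a calibrated, tree-structured Bayesian network built on signalling
biology: an active pathway means its transcription complex (TC) is
transcribing its direct target genes, so the mRNA levels of a signature of
those targets carry the evidence.

## The model

Three layers, all binary:

```
TC (active/inactive)  →  target gene_j (up/down)  →  probeset_jk (high/low)
```

* `P(up | TC)` per gene encodes how reliably the gene responds to the
  complex (literature-derived input; defaults 0.90/0.10, mirrored for
  down-regulated targets);
* `P(high | gene)` per probeset is **calibrated** on ground-truth samples
  (cells or tissues whose pathway state is known), then the model is
  **frozen** and never refitted;
* continuous intensities enter as soft evidence via a per-probeset
  logistic cut on the `log2(x+1)` scale; missing probesets are
  marginalised out.

Exact inference gives the posterior probability `P` that the pathway is
active, reported as the activity score

```
log2odds = log2(P / (1 - P))
```

with the additive per-gene contributions available via `tidy()`. The
default active/inactive cut is log2odds 0 (probability 0.5); new tissue
contexts get their own threshold (`set_threshold()`,
`recalibrate_threshold()`) while the frozen model — and hence score
comparability — stays fixed. A PI3K readout is derived from the FOXO model
by sign inversion, guarded by the SOD2 oxidative-stress rule (stressed
samples are `indeterminate`). Matrix-level array QC, a generative
simulator, GEO series-matrix / TSV / JSON-model IO, and Wilcoxon /
correlation statistics round out the toolkit.

## Worked example

Calibrate the shipped example model (a *synthetic* AR-style signature —
an editable template, not a validated assay) on simulated ground-truth
samples, freeze it, and score held-out samples:

```r
library(pathact)
library(dplyr)

m <- read_model_spec(system.file("extdata", "ar_example_model.json",
                                 package = "pathact"))
sim <- simulate_dataset(m, n_active = 30, n_inactive = 30, seed = 11)
frozen <- calibrate_model(m, sim$expression, sim$labels)

holdout <- simulate_dataset(m, 10, 10, seed = 12)
scores <- score_samples(holdout$expression, frozen) |>
  left_join(holdout$labels, by = "sample_id")
head(scores, 4)
#> # A tibble: 4 × 5
#>   sample_id probability_active log2odds call   label
#>   <chr>                  <dbl>    <dbl> <chr>  <chr>
#> 1 S0001                  0.870    2.74  active active
#> 2 S0002                  0.795    1.96  active active
#> 3 S0003                  0.774    1.78  active active
#> 4 S0004                  0.639    0.827 active active
scores |> count(label, call)
#> # A tibble: 3 × 3
#>   label    call         n
#>   <chr>    <chr>    <int>
#> 1 active   active      10
#> 2 inactive active       1
#> 3 inactive inactive     9
```

Each row is one sample: its posterior probability of pathway activity,
the log2odds activity score, and the qualitative call at the model's
threshold (log2odds 0). Nineteen of twenty held-out samples are
classified correctly by this deliberately small 7-gene example signature;
production-scale signatures use ~25–35 target genes. Per-gene evidence for
a single sample:

```r
ev <- evidence_weights(frozen, setNames(holdout$expression$S0001,
                                        holdout$expression$probeset_id))
tidy(infer_activity(frozen, ev))
#> # A tibble: 7 × 2
#>   gene     log2_contribution
#>   <chr>                <dbl>
#> 1 KLK3                 1.85
#> 2 KLK2                 0.272
#> 3 TMPRSS2             -0.573
#> ...
```

Positive contributions push toward "active"; their sum plus the prior
log2odds is the sample's score. `plot_activity_scores()`,
`plot_pathway_heatmap()` and `autoplot()` provide the standard views;
`multi_pathway_report()` assembles the per-sample multi-pathway table. A
thin command-line wrapper (`inst/cli/pathact`) exposes
`build-model / calibrate / freeze / score / qc / simulate / compare /
correlate / report` over the same functions.

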