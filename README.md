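# scarscreen

Cross-dataset temporal expression screening for fibrosis-driver candidate
genes.

## The problem

Skin fibrosis — the hallmark of scleroderma — is a wound-healing program
that fails to switch off, whereas oral mucosa heals without a scar. A gene
that is **transiently** induced during scarless healing but **persistently**
upregulated throughout experimental skin fibrosis is a candidate driver of
the fibrotic state. Amphiregulin (*Areg*), an EGFR ligand, is the archetype:
~10-fold induction within 24 h of an oral wound, back to baseline by day 3,
yet elevated at every timepoint of a bleomycin-induced fibrosis course.

`scarscreen` implements that discovery filter as a tested R pipeline for
anyone re-analysing paired time-course expression datasets (or validating
hits by qPCR): compute per-gene fold changes against baseline, call
transient induction and sustained upregulation, intersect the two screens,
and quantify validation plates by the comparative-Ct method. A synthetic
generator with planted temporal classes makes every stage runnable and
testable with no external data.

## The screen

For gene *g* at timepoint *t*,

    FC_g(t) = geomean(x_g at t) / geomean(x_g at baseline)

with a two-sided Welch *t* (or exact Mann–Whitney) on the log2 replicate
values. A wound-course gene is `TRANSIENT_INDUCED` when

* FC ≥ 2 at **both** 12 h and 24 h (inclusive threshold),
* p < 0.01 at both timepoints, and
* FC at 72 h lies within ±20% of baseline, i.e. in [0.80, 1.20].

A fibrosis-course gene (treated vs timepoint-matched control) is
`SUSTAINED_UP` when FC ≥ 2 with p < 0.01 at **every** treated timepoint.
The candidate list is the intersection of the two calls. All thresholds,
the significance gate, and an optional Benjamini–Hochberg correction are
configurable via `screen_criteria()`. The comparative-Ct module computes
RQ = 2^(−ΔΔCt) with the reference-gene and calibrator normalization.

## Worked example

The tutorial config simulates a 60-gene paired study at zero noise with one
planted Areg-pattern gene (transient in the wound course, sustained in the
fibrosis course):

```r
library(scarscreen)
cfg <- system.file("extdata", "tutorial_config.yaml", package = "scarscreen")
out <- run_pipeline(cfg, out_dir = "tutorial_out")
read.delim(file.path(out$out_dir, "candidates.tsv"))
```

which prints

```
simulate: 60 genes, wound 18 samples, fibrosis 24 samples, seed 1
wound screen gates: genes_in=60 -> induced=12 -> significant=12 -> returned=6
fibrosis screen gates: genes_in=60 -> fold_pass=1 -> sustained=1
intersect: 1 candidate gene(s): Areg
  gene_id       wound_class fibrosis_class wound_max_fc fibrosis_min_fc
1    Areg TRANSIENT_INDUCED   SUSTAINED_UP           10              10
```

Reading the gate counts: of 60 genes, 12 pass the 2-fold induction gate at
12 h and 24 h (the 6 transient + 6 sustained planted genes), all 12 pass
the significance gate, 6 return to within ±20% of baseline by 72 h
(`TRANSIENT_INDUCED`), and exactly one of those — *Areg* — is also
upregulated at every treated timepoint of the fibrosis course, so it is
the sole candidate, with its planted 10-fold wound peak recovered exactly.

The `analysis/` directory runs the same workflow at realistic scale
(500 genes, log2 noise SD 0.2) as numbered stages —
`01_simulate.R` … `05_qpcr.R` — writing summary tables under `results/`
and full matrices under `scratch/`. On that run the transient screen
recovers 49 of 50 planted transient genes at precision 1.00, the sustained
screen calls exactly the planted overlap gene, and the ΔΔCt stage recovers
planted 1/7/9/10-fold inductions within replicate error.

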