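---
title: "Isolating genes differentially expressed in successful CNS axon regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating genes differentially expressed in successful CNS axon regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desrseq)
```

## The comparative design

Some regions of the vertebrate central nervous system regenerate severed
axons and others do not, and in *Xenopus laevis* both states coexist in
one organism: retinal ganglion cells regrow optic axons after optic
nerve crush throughout life, and hindbrain neurons regrow spinal axons
after spinal cord injury as tadpoles but not as post-metamorphic frogs.
`desrseq` implements the three-way bulk RNA-seq comparison built on this
contrast. Two axon-regenerative tissues (`regenA`, tadpole hindbrain
after spinal cord injury, with age-matched paired controls; `regenB`,
frog eye after optic nerve crush, with contralateral-eye paired
controls) and one non-regenerative tissue (`nonregen`, frog hindbrain
after spinal cord injury, with a single unpaired control group shared
across time points) are profiled at an early trauma phase, the peak
phase of regenerative axon outgrowth, and a late refinement phase, with
three pooled biological replicates per condition. A surgically naive eye
group participates only in ordination. The full layout is 17 conditions
and 51 samples (`design_template()`).

A gene is *Differentially Expressed in Successful Regeneration* (DESR)
when it passes the FDR criterion in the same direction in **both**
regenerative tissues at a time point and is **not** significant in that
direction in the non-regenerative tissue at the same time point. Because
membership requires passing an FDR threshold of $\alpha$ independently
in two experiments, the expected false-discovery level of the DESR list
is bounded by $\alpha^2$; `compound_false_count()` turns that into an
expected count of false members.

## The pipeline stage by stage

### Homeolog read assignment

*X. laevis* carries an ancestrally duplicated genome, so a read may
align comparably to the L and S copies of a homeologous gene pair.
`resolve_duplicates()` applies the rule: a strictly higher alignment
score wins; an exact tie is broken uniformly at random with a seeded
generator. "Strictly higher" is taken literally — scores are compared
exactly, with no epsilon, because any tolerance would itself be an
arbitrary parameter; equality is the tie case. Reads with more than two
candidate genes, or whose candidates are not homeolog partners, are
rejected as hard errors rather than resolved heuristically: the rule is
defined only for the two-homeolog situation, and anything else signals
malformed input. The flagged-duplicate fraction is an emergent property
of the data, not a parameter of the rule.

### Quantification and the active-expression threshold

`compute_fpkm()` is the plain FPKM definition,
$\mathrm{fpkm}_{gs} = 10^9 c_{gs} / (L_g N_s)$ with $L_g$ the length of
the union of the gene's exons in bases and $N_s$ the sample's total
aligned reads. Genes whose mean FPKM falls below the active-expression
threshold in *both* conditions of a contrast are excluded from testing.
The threshold default is 0.45 FPKM; alternatively
`estimate_expression_threshold()` recovers it from the data as the
minimum of a Gaussian kernel density (Silverman bandwidth, 512-point
grid) of log10 mean FPKM between the two highest modes of the bimodal
gene-density histogram — the dip separating the unexpressed from the
expressed population. Local maxima below 10% of the density maximum are
not counted as modes, so sampling wiggles on a unimodal density do not
fake a second mode; genuinely unimodal input falls back to the
configured default. Zero-mean genes are excluded from the density (their
log is undefined, and they sit below any positive threshold by
construction). One global threshold is used by default, since a single
value is the natural reporting convention; per-group estimates can be
obtained by passing sample subsets.

### Differential expression on replicate log fold-changes

Where the design defines pairs, each gene yields per-pair replicate
ratios $r_i = \log_2\frac{\mathrm{fpkm}^{inj}_i + c}{\mathrm{fpkm}^{ctl}_i + c}$
(pseudocount $c = 0.1$ FPKM stabilizes ratios at zero counts) and the
mean of $\{r_i\}$ is tested against zero; the unpaired non-regenerative
design compares $\log_2(\mathrm{fpkm}+c)$ between groups. Significance
is FDR $\le$ 0.05 by Benjamini–Hochberg within each contrast, without
regard to fold-change magnitude.

The variance model deserves its own paragraph. With three replicates a
per-gene $t$ statistic has two degrees of freedom, and a df-2 null is so
heavy-tailed that even a four-fold change with tight replicates rarely
reaches $p < 10^{-2}$; after step-up adjustment over thousands of genes
essentially nothing survives, at any effect size this design can carry.
Count-based DE tools escape this by pooling dispersion information
across the transcriptome (per-condition dispersion fitting), which is
why the original analyses had power at $n = 3$. `test_contrast()`
therefore moderates the per-gene variance across genes by empirical
Bayes (limma's `eBayes`, without the mean-variance trend; the no-trend
variant was the better calibrated of the two on zero-effect synthetic
data) as its default method. The literal replicate-level test is kept as
`method = "t"` — it is the transparent, closed-form reading of "a
difference of means test across the biological replicates on the log2
fold-changes", and the unit tests pin its arithmetic — but it is not the
default precisely because its power at $n = 3$ does not support the
procedure the pipeline exists for. Zero-variance ratio vectors are
handled explicitly: all-zero ratios give $p = 1$; identical nonzero
ratios are untestable and excluded from the FDR ranking.

### The DESR filter, opposing genes, and summaries

`extract_desr()` performs the three-way filter *per direction*: the
non-regenerative UP list is subtracted only from the regenerative UP
intersection, and likewise for DOWN. Direction-aware removal is the only
reading under which a gene can simultaneously be a DESR gene and be
significantly regulated in the *opposite* direction in the
non-regenerative tissue — the "opposing expression" genes that are the
most informative class, flagged in `opposing_genes`. Genes significant
in both regenerative tissues with discordant signs fit neither list and
are reported separately rather than silently dropped. All filtering is
per time point; cross-time unions are reporting options.
`tabulate_overlaps()` tallies the seven membership regions of the three
significant sets (the regions of an UpSet plot), `temporal_summary()`
counts UP/DOWN genes per tissue and time point (L and S homeologs
tallied separately) with percentages of an annotated genome of 24,382
genes by default, and `desr_share()` reports the DESR fraction of all DE
genes as a one-decimal percentage.

### Condition-profile PCA

`condition_pca()` works on $\log_{10}(\mathrm{fpkm} + 0.1)$, averaging
replicates within conditions (or keeping samples in
`replicate_scatter` mode), centering each profile across genes, and
decomposing by SVD. Genes are the observations and conditions the
variables, so each condition contributes an eigenvector direction: its
vector is the unit-normalized projection of its profile onto (PC1,
PC2), and the angle between two condition vectors measures profile
correlation — near 0° for tightly correlated conditions, 90° for
unrelated ones, up to 180° for anti-correlated ones. Component signs
follow a first-nonzero-loading-positive convention so output is
reproducible across linear-algebra backends. `top_gene_selection()`
restricts the analysis to the most highly expressed genes
(deterministic lexicographic tie-break at the boundary).

## The synthetic experiment generator

`simulate_experiment()` exists so that every stage is testable, with
known truth, without any external download. What it emulates, and its
defaults, are fixed study conditions rather than tuning knobs:

* **Genome**: 10,000 genes, 55% in L/S homeolog pairs, S copies at half
  the L baseline (L homeologs are the higher-expressed copies). Exonic
  lengths lognormal around 1.5 kb.
* **Expression**: lognormal baselines (log10 mean 0.5, sd 0.8),
  rescaled so baselines are on the FPKM scale; expected counts
  $\mu = \mathrm{fpkm} \times L_g/10^3 \times N/10^6$ at a nominal depth
  of $N = 30 \times 10^6$ aligned reads, matching the study's
  sequencing depth; replicate counts negative binomial with a single
  global dispersion $\phi = 0.05$
  ($\mathrm{var} = \mu + \phi\mu^2$).
* **Planted truth**: 50 DESR genes with identical effects
  ($|\log_2 \mathrm{fc}| = 2$, up with probability 253/324 — the
  published up/total ratio) in both regenerative tissues at the mid
  time point, of which 20 carry the opposite-sign effect in the
  non-regenerative tissue; tissue-specific DE genes with
  $|\log_2 \mathrm{fc}|$ uniform in [0.3, 3] in per-tissue counts that
  peak at mid in the regenerative and at early in the non-regenerative
  tissue (`default_temporal_profile()`). Planted genes are drawn from
  genes with baseline $\ge$ 1 FPKM and at most 1% of the library:
  planting a fold-change on a library-dominating gene would shift every
  other gene's FPKM through the per-sample total — a compositional
  artifact that count pipelines remove by cross-sample normalization,
  which the plain FPKM definition used here deliberately does not.
* **Randomness**: one root seed; each stage draws from a derived
  stream, so identical configurations reproduce byte-identically across
  platforms and stages can be re-run independently.

`simulate_alignment_records()` adds the homeolog-ambiguity layer: the
marginal flagged-duplicate fraction defaults to 0.096 and the exact-tie
fraction among duplicates to 0.08, mirroring the reported 9.6% flagged
reads with under a tenth of them randomly distributed.

What the generator does **not** emulate: sequence-level errors, GC and
positional bias, batch effects, correlated gene modules, per-gene
dispersion variation, and library-composition shifts. Tests passing on
synthetic data therefore demonstrate the correctness and calibration of
the procedure under its own assumptions, not robustness to artifacts of
real libraries.

## Numerical choices and degenerate inputs

* Exact score comparison in homeolog assignment; ties only at exact
  equality.
* GTF coordinates are treated as 1-based inclusive and gene length is
  the union of exon intervals.
* Written tables carry full-precision (`%.17g`) numbers so write/read
  round-trips are exact and repeated writes are byte-identical; every
  pipeline output file carries a hash of the configuration in a header
  comment.
* The threshold estimator requires at least 100 expressed genes;
  below-minimum input is an error rather than a silent default.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` behind
  the package's own surface; the test suite checks it against an
  independently coded step-up oracle.
* PCA on fewer than two conditions or an all-constant matrix is an
  error; angle diagonals are exactly zero.

## Problem sizes in the test and acceptance runs

The test suite and `scripts/acceptance.R` use reduced genomes (2,000 to
10,000 genes) at the full 51-sample design and the full 30 M nominal
depth. Depth, not gene count, controls per-gene power, so shrinking the
genome keeps each gene's behavior identical while scaling only the
multiple-testing denominator; the end-to-end run uses the complete
10,000-gene default. Planted-truth recovery is summarized over 20
independent simulation replicates.

## Known limitations

* The moderated test approximates, but is not, the original tool's
  beta-negative-binomial variance model; per-gene results on real data
  will differ in detail from published tables even at matched inputs.
* FPKM totals are per-sample constants, so strong composition changes
  between conditions bias fold-changes; real analyses with suspected
  composition shifts should renormalize counts upstream.
* The non-regenerative tissue's single shared control group means its
  three contrasts are not independent of one another.
* Homeolog resolution handles exactly two candidates; multi-mapping
  across non-partner paralogs is out of scope.
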