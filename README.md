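# desrseq

Comparative bulk RNA-seq analysis for isolating genes **Differentially
Expressed in Successful Regeneration** (DESR): the transcriptional
program shared by axon-regenerative central nervous system tissues but
absent from a non-regenerative one.

## The scientific problem

In *Xenopus laevis*, retinal ganglion cells regenerate optic axons after
optic nerve crush throughout life, while hindbrain neurons regenerate
spinal axons after spinal cord injury only as tadpoles — the same
neurons fail after metamorphosis. Profiling two regenerative tissues
(tadpole SCI hindbrain, frog ONC eye) and one non-regenerative tissue
(frog SCI hindbrain) at three post-injury time points lets the
tissue-specific bulk of the injury response be subtracted away, leaving
the genes tied to *successful* regeneration. This package implements
that three-way procedure as a reusable, tested pipeline, together with a
synthetic allotetraploid experiment generator with planted ground truth,
so every stage can be exercised and validated without any external data.

The core filter, per time point and per direction:

```
up_DESR(t)   = UP_regenA(t) ∩ UP_regenB(t) \ UP_nonregen(t)
down_DESR(t) = DOWN_regenA(t) ∩ DOWN_regenB(t) \ DOWN_nonregen(t)
```

with significance defined as Benjamini–Hochberg FDR q ≤ 0.05 on a
replicate-level test of log2(FPKM_injury/FPKM_control), after filtering
genes below the active-expression threshold (FPKM 0.45, or estimated
from the bimodal gene-density histogram) in both conditions. Because a
DESR gene passes the FDR criterion independently in two experiments, its
expected false-discovery level is bounded by α² — `alpha^2 * n` expected
false genes among n calls. Genes regulated in the *opposite* direction
in the non-regenerative tissue remain DESR members and are flagged as
opposing-expression genes, the most informative class.

Around this core the package covers: duplicate-alignment resolution
between L/S homeologs of the duplicated genome (higher score wins, exact
ties split at random), FPKM quantification, density-based expression
thresholding, per-contrast DE testing with empirical-Bayes variance
moderation (a plain replicate-level t is available as `method = "t"`),
UpSet-style overlap tables, temporal DE-count summaries, and
eigenvector PCA of condition profiles where the angle between condition
vectors measures profile correlation.

## Worked example

```r
library(desrseq)

cfg <- pipeline_config(seed = 42)   # synthetic mode, full default design
rep <- run_pipeline(cfg)
print(rep)
#> desrseq pipeline report (synthetic mode, seed 42, config 067afb42)
#>   10000 genes x 51 samples; threshold FPKM 0.45; FDR 0.05
#>   DESR genes: 51 of 1781 DE genes (2.9%); expected false ~ 0
#>   regenA DE-count peak: mid
#>   regenB DE-count peak: mid
#>   nonregen DE-count peak: early

print(rep$desr_sets$mid)
#> DESR set (mid): 38 up, 13 down, 20 opposing, 1 discordant

str(rep$summary$desr_eval)
#> List of 5
#>  $ recall        : num 1
#>  $ empirical_fdr : num 0.0196
#>  $ n_called      : int 51
#>  $ n_planted     : int 50
#>  $ opposing_match: logi TRUE
```

Reading this: from 10,000 simulated genes across the 17-condition,
51-sample design, the pipeline calls 1,781 differentially expressed
genes over the nine tissue × time contrasts, of which 51 survive the
three-way DESR filter (2.9%). The DE-count peaks recover the planted
temporal program — regenerative tissues peak at the mid (peak axon
outgrowth) phase, the non-regenerative tissue at the early trauma
phase. Against the planted truth, all 50 planted DESR genes are
recovered (recall 1.0) with one false member (empirical FDR 0.020,
consistent with the compound-FDR expectation), and the 20 planted
opposing-expression genes are classified exactly.

The published worked arithmetic is reproduced by the same reporting
functions:

```r
desr_share(324, 12059)          # 2.7  (% of all DE genes that are DESR)
compound_false_count(0.05, 324) # expected 0.81 false genes, i.e. ~1
```

## Command line

```sh
Rscript inst/scripts/desr-pipeline.R --mode synthetic --seed 1 --out-dir out/
Rscript inst/scripts/desr-pipeline.R --mode real \
    --counts counts.tsv --model model.tsv --design design.csv --out-dir out/
```

Stage outputs (per-contrast DE tables, per-time-point DESR and overlap
tables, PCA vectors and angles, JSON summary) are plain TSV/JSON with
the configuration hash in a header comment.

See the methods vignette (`vignettes/desr-methods.Rmd`) for the model,
its assumptions, the generator's design, and known limitations.
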