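---
title: "Cross-sample concordance benchmarking of somatic SNV pipelines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sample concordance benchmarking of somatic SNV pipelines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvconcord)
library(dplyr)
```

## The problem

Somatic single-nucleotide variants (SNVs) are called from tumor/normal
sequencing by a pipeline of one read mapper and one variant caller. Different
mapper-caller combinations disagree substantially, and for real tumors there
is no ground truth to arbitrate. When many samples derive from the *same*
tumor — regions of a primary tumor, cultured polyclones, single-cell-derived
monoclones — the disagreement itself can be exploited: a variant detected in
two independent samples is very unlikely to be the same false discovery
twice, so the cross-sample recurrent variants can serve as a proxy truth
("validated variants"). snvconcord implements this validation statistic and
everything built on it: per-pipeline precision/recall/F1, pipeline
similarity and clustering, exhaustive union-combination optimization, and a
truth-known simulator that can audit the validation statistic itself.

## Variant identity and filtering

The atom of all set algebra is the variant key `(contig, position, ref,
alt)` — genotype, quality and per-pipeline annotations never enter identity.
Only biallelic SNV ALT alleles are kept (multiallelic records are split;
indels, MNVs and symbolic alleles are dropped and counted), because indel
calls are too discordant across callers to compare meaningfully. Calls are
filtered to a minimum tumor read depth of 10 (inclusive) and, by default, to
`FILTER` = `PASS`/`.`. A record with missing depth fails the depth filter:
the floor exists for fairness across pipelines, and a record whose depth is
unknowable cannot be shown to satisfy it. Contig names are compared
verbatim; `strip_chr_prefix = TRUE` is available because mixed `chr`
conventions would silently zero every overlap. The tumor genotype column
defaults to the last sample column; callers that order columns differently
can be accommodated with `tumor_sample`.

## The validation rule

`build_index()` records, for every variant, the set of (pipeline, sample)
pairs that detected it. `validate_variants(index, min_samples = 2,
min_pipelines = 1)` declares a variant validated when it appears in at least
`min_samples` distinct samples, regardless of which pipeline found it where.
The two support axes are deliberately separate parameters: "detected in two
independent samples" and "discovered by only a single pipeline" are
different statements, and conflating them silently would change the
statistic. The default follows the two-samples reading; the single-pipeline
reading is expressible as `min_pipelines = 2`.

Classification per (pipeline, sample) unit: TP = called and validated, FP =
called and not validated, FN = validated but not called. The default FN
scope is `per_sample`: a unit is charged only for validated variants that
some pipeline detected in that same sample, because samples genuinely differ
in mutation content — a variant absent from a sample's cells is not a miss
there. `fn_scope = "global"` (every validated variant charged to every
unit) is retained for sensitivity analysis.

Undefined ratios stay missing. A unit with no calls has no precision; F1 is
computed from counts (`2tp / (2tp + fp + fn)`), not from rounded
precision/recall, and is missing whenever either component is undefined.
Aggregation by mapper (mean over the callers sharing it, per sample) and by
caller (mean over mappers) averages only the defined entries — coercing
undefined to 0 would let zero-call edge cases drag group means.
Per-sample F1 values are averaged rather than pooling counts across
samples; pooled scoring can be obtained by summing the classification
counts before `prf()`.

## Pipeline similarity and clustering

For one sample type, the incidence matrix has one row per (sample, variant)
detection event observed in *any* pipeline, and one 0/1 column per pipeline.
Events are pooled within the type — one matrix per type, matching a
one-heatmap-per-type presentation — and a per-sample variant is available
(`per_sample = TRUE`) for the average-of-per-sample-similarities
alternative, since the pooled-vs-averaged choice is a genuine design
freedom. Binary (not count-weighted) incidence is the default for the same
reason: detection is the observable, depth is pipeline-specific metadata.

Similarities: cosine `x·y / (|x||y|)`, Jaccard `|x∧y| / |x∨y|`, Pearson
correlation of the 0/1 columns. For 0/1 vectors Jaccard ≤ cosine always;
pairs involving an all-zero column (cosine/Jaccard) or constant column
(Pearson) are reported missing rather than 0. Clustering is agglomerative
with average linkage (UPGMA) on distance `1 − similarity`; no linkage is
canonical for this task, and average linkage is the least shape-biased
default. Determinism under ties: leaves are reordered within the merge
topology by input column position, so identical inputs give identical
dendrograms and an all-equidistant matrix keeps input order.

## Union combinations

A combination is a non-empty set of pipelines scored as the set-union of
their calls, identified canonically by its sorted, `+`-joined member list.
All `2^n − 1` subsets (4095 for 12 pipelines) are enumerated by size then
lexicographic id. The validated set is computed **once** from the individual
pipelines and held fixed while combinations are scored; unions do not feed
back into validation, which would make combination scores self-referential.

Scoring all subsets naively would union thousands of call sets; instead each
variant's detection profile across the n pipelines is packed into an n-bit
pattern and collapsed to pattern counts, after which a subset's TP/FP are
two masked sums. This is an exact reformulation (tested against direct
union-and-classify and against a brute-force subset loop) and scores the
full 4095 × 50 grid in seconds on one CPU, holding one sample in memory at
a time.

Best-per-sample selection takes the argmax F1; ties break toward the
smaller combination, then lexicographic id — parsimony, because union gains
saturate with size while the FP load keeps growing. Per-size winners feed
the occurrence tally (per sample type) and the F1-versus-size distribution.
No unimodality of F1 in size is asserted anywhere; the curve is reported as
observed. Both the best-per-size view and the all-combinations view of the
distribution are available, as the choice between them is presentational.

## The simulator

The generator models *calls*, not reads: read-level simulation and the real
mapper/caller stacks are out of scope, and the downstream analysis consumes
call sets only. The minimal structure that reproduces every phenomenon the
analysis measures is:

* **Truth pool** — `n_variants` SNVs (default 4800) placed uniformly at
  distinct positions in a toy exome (10 contigs × 10 intervals × 10 kb;
  reference bases are simulated, so no genome is needed), each assigned to
  one of `K = 8` clones with Dirichlet weights. Uniform placement is a
  documented divergence from mutation-model-based placement; position
  distribution does not enter any downstream statistic, only key identity
  does.
* **Sample design** — 7 parental, 13 in vivo polyclones, 7 in vitro
  polyclones, 19 monoclones, 4 secondary monoclones (50 samples).
  Heterogeneity per type: monoclones carry one clone at fraction 1;
  polyclones 2–4 clones with Dirichlet fractions; parental samples all
  clones plus a 0.3 normal-contamination fraction. These produce the
  observed gradient from homogeneous (clonal VAF 0.5) to heterogeneous
  (many sub-0.1 VAFs) samples.
* **Site evidence** — expected VAF = `purity × clone_fraction × 0.5`
  (heterozygous diploid; no copy-number or LOH modeling, because the purity
  argument is linear in allele fraction and needs none), depth ~
  Poisson(coverage = 80), alt reads ~ Binomial(depth, VAF). Purity is the
  call-level analog of read mixing: `purity_from_mixing(20, 80)` = 20%,
  `(80, 80)` = 50%, `(80, 0)` = 100%.
* **Pipeline behavior** — a pipeline calls a truth site iff alt reads ≥ 3
  and a draw with probability `plogis((vaf − v50) / w)` succeeds; caller
  tokens set `v50`/`w` (Strelka2-like 0.06 … SomaticSniper-like 0.20),
  mapper tokens shift them slightly. False calls are Poisson (base rate 40
  per sample) **scaled by the pipeline's permissiveness** (multipliers 3.0
  … 0.3 by caller, 0.9–1.6 by mapper), which reproduces the across-pipeline
  precision/recall trade-off: permissive pipelines find more true variants
  *and* proportionally more false ones. A fraction `fp_shared_prob`
  (default 0.25) of false calls comes from a recurrent artifact pool shared
  by all pipelines — exactly the mechanism that can fool cross-sample
  validation, and the knob the truth-audit turns (0 for clean runs, 0.9 to
  demonstrate the failure mode).
* **Correlated noise** — detection noise is shared along the preset's
  dominant axis via a Gaussian copula (`detect_cor = 0.8`), and false-call
  candidates are drawn once per (sample, axis token) with per-pipeline
  Poisson thinning (so same-axis false-call sets are nested). Marginal
  detection probabilities and false-call rates are unchanged. The rationale
  is physical: a missed borderline site or a systematic artifact is a
  property of the shared algorithm given the evidence, not an independent
  coin flip per pipeline. Without this, binary incidence columns of
  same-parameter pipelines are no more similar than cross-parameter ones
  and no clustering structure exists to find. `"caller_dominant"` (default)
  places the sharing on the caller axis, `"mapper_dominant"` on the mapper
  axis.

All randomness flows from one master seed through named substreams (truth,
per-sample clones and evidence, per-unit detection, per-axis noise), so
adding a pipeline never perturbs other units and identical seeds give
byte-identical written studies.

### What the simulator does not emulate

Real read-level error processes, mapping ambiguity, germline leakage,
copy-number and LOH, indels, and the actual output quirks of the twelve real
tool stacks. Passing tests therefore demonstrate that the *analysis
machinery* is correct and that the validation statistic behaves as designed
under its stated assumptions — not that any particular real pipeline has a
particular precision.

## Truth-based audit of the validation statistic

In simulation the truth is known, so every unit can be scored twice:
against the validated set and against the truth ("truth for a sample" = the
variants of its active clones; a pipeline cannot find a variant absent from
the sample's cells). With no recurrent artifacts, per-pipeline
validation-based precision tracks truth-based precision closely (within
0.05 at 50 samples / 5000 variants; observed deviations are ~10⁻⁴). With
`fp_shared_prob = 0.9` the validated set absorbs recurrent artifacts and
validation-based precision exceeds truth, quantifying the statistic's
stated assumption that identical false discoveries across samples are
unlikely.

One caution discovered by this audit and worth stating: the precision
half of the union trade-off ("adding pipelines never increases precision")
is *not* a per-pair law. Adding a high-recall pipeline to a low-recall,
lower-precision subset raises the union's precision, because the added
detections are mostly validated. Only TP, FP and recall are monotone under
union as theorems; precision falls in aggregate but not for every nested
pair, and the package asserts exactly the monotone parts.

## Numerical and operational choices

* Problem sizes in the test suite: full-design studies (12 × 50, 4800–5000
  variants) for the bookkeeping, recovery and monotonicity checks; reduced
  designs (10–14 samples, 800–3000 variants) for property loops. These are
  the package's chosen demonstration scales; the machinery is linear in
  total calls and was exercised well beyond them.
* Clustering-regime demonstrations run at purity 0.2: at purity 1.0 every
  caller saturates on clonal VAF 0.5 and incidence vectors carry no
  behavioral signal — the borderline-VAF regime is where algorithmic
  differences express, which is also why heterogeneous sample types are the
  interesting ones on real data.
* Degenerate inputs: empty call sets are scored (missing metrics), an empty
  validated set classifies every call as FP with a warning, single-sample
  manifests warn that the validation rule is unreachable, and zero-variance
  similarity columns refuse clustering rather than fabricate a distance.
* `write_vcf()` emits minimal VCF 4.2 with `DP/AD/AF` and is the exact
  inverse of `parse_vcf()` on key/depth/alt-read content; manifests store
  relative paths so a written study is location-independent.

## Known limitations

The validation statistic remains a proxy: genuinely sample-unique variants
are counted against precision on real data (an equal handicap across
pipelines, but a handicap). The behavioral pipeline model is
phenomenological; its parameters are chosen to reproduce regimes, not
calibrated to any specific tool version. Combination search is exhaustive
union only — no intersection, majority-vote or weighted ensembles.
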