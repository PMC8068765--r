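# snvconcord

Cross-sample concordance benchmarking of somatic SNV calling pipelines.

## What it is for

Somatic SNV calling runs one read mapper and one variant caller in sequence;
different mapper × caller combinations disagree substantially, and for real
tumors no ground truth exists to say who is right. When many sequenced
samples derive from the *same* tumor (regions of the primary, cultured
polyclones, single-cell-derived monoclones), recurrence across samples can
stand in for truth: an identical false discovery in two independent samples
is unlikely, so variants detected in ≥ 2 samples are treated as **validated**
and every pipeline is scored against them. snvconcord is for
bioinformaticians benchmarking somatic pipelines on such multi-sample
designs — and for checking, in simulation, when that validation statistic
can be trusted.

The package provides, as piped tidyverse-style functions over call tables:

* **VCF I/O** — SNV-only parsing (multiallelic split, indels dropped),
  depth/PASS filtering (`depth ≥ 10`), minimal VCF writing, manifests.
* **Validation & metrics** — the cross-sample detection index, the
  validated set `{v : |samples(v)| ≥ 2}`, per-(pipeline, sample) TP/FP/FN
  with precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, F1 `2tp/(2tp+fp+fn)`,
  and mapper/caller aggregation.
* **Similarity** — cosine / Jaccard / Pearson similarity of pipelines on
  binary (sample, variant) detection incidence per sample type, with UPGMA
  clustering and Newick export.
* **Combinations** — exhaustive scoring of all 2ⁿ−1 pipeline unions
  (4095 for 12 pipelines), best-F1 winners per sample with parsimony
  tie-breaks, occurrence tallies, F1-vs-size distributions.
* **Simulator + truth audit** — a truth-known call-level generator of the
  whole study (clone structure, tumor purity via coverage mixing,
  per-pipeline logistic detection in VAF, recurrent-artifact false calls)
  and truth-based scoring to quantify when validation-based precision is
  honest and when recurrent artifacts inflate it.

## Worked example

Simulate a reduced study (12 pipelines × 12 samples, 1500 truth variants),
validate across samples, score pipelines, and search union combinations:

```r
library(snvconcord)
library(dplyr)

study <- generate_study(design = sample_design(2, 3, 2, 4, 1),
                        n_variants = 1500, seed = 7)
calls     <- apply_filters(study$calls)            # depth >= 10, PASS only
idx       <- build_index(calls)                    # who found what, where
validated <- validate_variants(idx)                # seen in >= 2 samples

units   <- distinct(study$manifest, pipeline_id, sample_id, sample_type)
metrics <- classify_calls(calls, validated, idx, units = units) |>
  score_metrics()

metrics |>
  group_by(pipeline_id) |>
  summarise(precision = mean(precision), recall = mean(recall),
            f1 = mean(f1)) |>
  arrange(desc(f1))
#> 1 Novoalign_Strelka2     0.664  0.810 0.723
#> 2 Bwa_Strelka2           0.726  0.716 0.714
#> 3 Bowtie2_Strelka2       0.737  0.689 0.704
#> 4 Novoalign_Mutect2      0.731  0.653 0.677
#> 5 Bwa_Mutect2            0.781  0.596 0.659
#> # ... 7 more rows
```

The permissive Strelka2-like pipelines trade precision for recall and lead
on F1 — the precision/recall trade-off the framework is designed to expose.
Union search over all 4095 combinations per sample:

```r
combo   <- score_combinations(calls, validated)
winners <- best_per_sample(combo, by_size = TRUE)
f1_by_size(combo) |> group_by(size) |> summarise(mean_best_f1 = mean(best_f1))
#> 1     1        0.756
#> 2     2        0.764
#> 3     3        0.762
#> 4     4        0.757
```

Complementary pairs beat every single pipeline on average, and gains
saturate quickly as more pipelines join the union. `tally_winners(winners)`
tabulates which combinations win most often per sample type;
`plot_f1_by_size()`, `plot_precision_recall()`, `plot_count_heatmap()` and
`autoplot()` on similarity matrices render the standard figures, and the
truth side (`score_vs_truth()`, `compare_validation_to_truth()`) quantifies
how far validation-based metrics sit from truth-based ones.

End-to-end orchestration, including TSV artifacts and a checksummed status
file, is one call: `run_study(study, outdir = "results/")`.

## Documentation

The methods vignette (`vignettes/concordance-methods.Rmd`) documents the
validation rule and its two support axes, FN scoping, the similarity and
clustering conventions, the union-scoring bitmask reformulation, the
simulator's model and defaults, and known limitations — including which
union-monotonicity statements are theorems (TP, FP, recall) and why
per-pair precision monotonicity is not one.
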