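# nestcoex

Coexpression analysis of **opposite nested protein-coding gene pairs** — a
gene (the *nested* gene) whose genomic span lies entirely inside the span of
another gene (the *host*) on the opposite strand, as *ceh-10* sits inside
*polq-1* in *C. elegans*. Hundreds of worm protein-coding genes are in this
configuration, and because host and nested gene share a locus transcribed in
opposite directions, the package asks: how often are the two genes active in
the same cell types, is that more or less coexpression than unrelated or
merely adjacent genes show, and do their individual transcription bursts at
a single locus fire independently?

It is aimed at genomicists with a gene-level annotation (GFF3) and
cell-type-resolved expression summaries (e.g. per-cell-type average
"adjusted tpm" tables from a single-cell atlas), plus optionally two-color
smFISH transcription-site scores.

## What it computes

* **Pair discovery** — opposite nested pairs by whole-span interval
  containment (`host.start <= nested.start`, `nested.end <= host.end`,
  opposite strands, non-identical spans), and neighboring
  opposite-orientation non-nested pairs with intergenic gap < 1 kb.
* **Coefficient of coexpression** — for expressed-cell-type sets `S_A`,
  `S_B` (expressed = value > 0):

  ```
  c(A,B) = |S_A ∩ S_B| / |S_A ∪ S_B|      (0 when the union is empty)
  ```

  the Jaccard index of the two sets, plus the directional conditionals
  `P(host|nested) = |S_A ∩ S_B| / |S_B|` and
  `P(nested|host) = |S_A ∩ S_B| / |S_A|`.
* **Resampling nulls** — the distribution of the mean coefficient over 1000
  re-drawn cohorts of random cross-chromosome pairs and of neighboring
  (< 1 kb, opposite-strand) pairs, with the observed nested-pair mean placed
  at its empirical quantile.
* **smFISH co-occurrence** — per-locus state tabulation and the independence
  ratio `f_both / (f_A · f_B)` (≈ 1 for independent transcription bursts),
  plus nucleus-level co-activity.
* **Synthetic data** — a genome generator with planted nested/neighbor pairs
  and a Bernoulli coexpression model (`p_nested`, `q1`, `q0`) with
  closed-form large-T expectations, so the whole pipeline is verifiable
  offline.

## Worked example

Everything below runs offline on generated data:

```r
library(nestcoex)

gcfg <- synthetic_genome_config(n_nested_pairs = 40, n_neighbor_pairs = 30,
                                n_singletons = 200, n_chromosomes = 6, seed = 7)
fx <- write_synthetic_fixtures(gcfg,
        coexpression_model_params(n_cell_types = 500, seed = 8),
        "demo", dataset_labels = "lineage")

genes  <- parse_gene_annotation(fx$paths$annotation)   # GFF3 -> gene_set
nested <- find_nested_pairs(genes)
head(nested, 3)
#>   gene_a_id gene_b_id pair_class gap_bp
#> 1 SYNG00014 SYNG00015     nested     NA
#> 2 SYNG00023 SYNG00024     nested     NA
#> 3 SYNG00031 SYNG00032     nested     NA

sets   <- binarize(load_expression_table(fx$paths$expression$lineage,
                                         "long", "lineage"))
cohort <- summarize_cohort(sets, nested)
cohort
#> cohort_summary 'lineage': 40 pairs
#>   coexpressed in >=1 cell type: 100.0%
#>   mean coefficient of coexpression: 0.1400
#>   mean P(host | nested): 0.5126  (over 40 pairs)
#>   mean P(nested | host): 0.1612  (over 40 pairs)

null <- null_mean_distribution(sets, genes, "random",
                               n_pairs = nrow(nested),
                               n_iterations = 1000, seed = 99)
compare_to_null(cohort$summary$mean_coefficient, null)
#> null_comparison (random, 'lineage'): observed mean 0.1400 at empirical quantile 1.000 (1000 iterations)
```

Reading: each of the 40 nested pairs shares at least one expressing cell
type; on average 14% of the cell types expressing either gene express both.
The nested gene predicts host expression much better (0.51) than the host
predicts the nested gene (0.16) — the generator plants exactly this
host-on-nested dependence (`q1 > q0`), and the observed mean sits above all
1000 random-pair null means (quantile 1.000). The full pipeline
(`run_full_analysis()` on a `run_config()` or YAML file) writes the pair
table, per-dataset coexpression TSV/JSON summaries, both null
distributions, and a checksummed manifest; identical seeds give
byte-identical outputs.

For the smFISH side:

```r
obs <- simulate_independent_loci(n_nuclei = 50000, p_a = 0.45, p_b = 0.45, seed = 1)
tabulate_cooccurrence(obs)   # ratio ~ 1: independent bursts
```

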