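# siamscreen

Ligand-based virtual screening (LBVS) with an enhanced Siamese
multi-layer perceptron similarity model, for cheminformatics researchers
benchmarking similarity-searching methods on count fingerprints.

Classical similarity searching ranks a compound library by the
continuous Tanimoto coefficient between extended-connectivity count
fingerprints,

    T(a, b) = Σ a_i b_i / (Σ a_i² + Σ b_i² − Σ a_i b_i),

which performs well on structurally homogeneous activity classes and
poorly on heterogeneous ones. `siamscreen` implements a learned
alternative: twin weight-shared rectifier encoders embed both
fingerprints, two fixed distance layers compare the embeddings
element-wise — Manhattan `d = |e_A − e_B|` and exponential Manhattan
`E = exp(−|e_A − e_B|)` — a fusion layer concatenates them, and a
trainable head ends in a sigmoid unit scoring pair similarity in (0, 1).
Training uses binary cross-entropy with RMSprop on balanced same-class /
different-class molecule pairs.

Around the model, the package provides the field's full evaluation
protocol:

* **Screening** — ten random reference structures per class, MAX group
  fusion, top-1%/5% recall, recall tables with mean rows and best-cell
  ("shaded") counts; transcriptions of the published MDDR/MUV/DUD
  benchmark tables ship as data (`benchmark_recall_table()`).
* **Node pruning** — signal-to-noise ratio `|μ|/σ` of each incoming
  weight column, global bottom-k masking, and recall sweeps across
  pruning ratios.
* **Concordance** — tie-corrected Kendall W across activity classes,
  with chi-square significance and mean-rank method ordering.
* **Synthetic libraries** — a calibrated generator emulating the
  benchmark class structure (active counts, decoy background, intra-class
  diversity within ±0.02 of target) so the whole pipeline runs without
  licensed data.

## Worked example

The end-to-end pipeline — generate a library, train, screen, prune,
rank — runs from one call:

```r
library(siamscreen)
res <- run_pipeline(out_dir = "demo", seed = 42)
res$tables$top1
#> # A tibble: 3 × 3
#>   class_label   TAN   MLP
#>   <chr>       <dbl> <dbl>
#> 1 class1         62    62
#> 2 class2         62    62
#> 3 class3         24    62
#> Mean:   TAN=49.33  MLP=62.00
#> Shaded: TAN=2  MLP=3
```

The default configuration builds three 60-active classes over 3000
decoys at fingerprint width 256 — one homogeneous class (diversity
0.35), one intermediate (0.20), one heterogeneous (0.12). The top-1%
recall table above shows the characteristic result: on homogeneous
classes the learned model matches the Tanimoto baseline (both retrieve
every active that fits in the top-1% slice, 62%), while on the
heterogeneous class the baseline collapses to 24% and the Siamese model
still retrieves 62%.

The pruning sweep shows recall holding as low-SNR nodes are removed:

```r
tidyr::pivot_wider(res$sweep, names_from = class_label, values_from = recall)
#> # A tibble: 6 × 4
#>   ratio class1 class2 class3
#> 1   0       62     62     62
#> 2   0.1     62     62     62
#> 3   0.2     62     62     56
#> 4   0.4     62     62     30
#> 5   0.6     56     56     10
#> 6   0.8      4      2      2
```

Individual stages are exported (`generate_library()`,
`select_queries()`, `sample_pairs()`, `train_siamese()`,
`score_library()`, `top_percent_recall()`, `prune()`, `kendall_w()`),
results have `tidy()`/`glance()` methods and `autoplot()` figures, and a
thin command-line front end lives at `inst/cli/siamscreen.R`
(`simulate`, `run-all`, `concordance` subcommands).

Concordance analysis of a published benchmark table:

```r
res <- kendall_w(benchmark_recall_table("ds1", pct = 1))
glance(res)
#> # A tibble: 1 × 6
#>       W chi_square    df   p_value     m     n
#> 1 0.593       26.1     4 0.0000301    11     5
```

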