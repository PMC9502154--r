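# cellframe

Single-cell RNA-seq data lives in hierarchical containers: sparse assay
matrices (features × cells), per-cell annotations, and low-dimensional
embeddings, each in its own slot. That layout is efficient for algorithms
but awkward for the exploratory work that dominates an analysis — filtering
cells on QC metrics, joining sample-level metadata, faceting by cluster,
subsampling per donor. `cellframe` presents such a container as **one tidy
table with one row per cell** and adapts the grammar-of-data verbs
(`mutate`, `filter`, `select`, joins, `nest`, …) to operate on it, while
the sparse container stays intact underneath.

The package is aimed at analysts who think in data-grammar pipelines but
need their object to remain a valid expression container for downstream
numerical methods.

## The core idea: verb dispatch

Every visible column has a class: the **key** column `.cell` (the cell
identifier), **editable** cell-metadata columns, and **view-only** columns
backed by reductions (`PC1`, `UMAP1`, …). Each verb materializes the view,
applies the ordinary tabular operation, and then *dispatches* on the
result:

* it returns a container-backed `TidyView` iff the operation (i) kept the
  `.cell` column, (ii) did not duplicate cells, and (iii) did not alter a
  view-only column;
* otherwise it returns a plain tibble, with a structured demotion warning.

Summary-style verbs (`summarise`, `count`, `distinct`, `pull`,
`pivot_longer`) return plain tables or arrays by design. Writing to a
view-only column is an error; reading one (e.g. `arrange(v, PC1)`) is
always allowed.

Beyond the verbs, the package provides transcript joining
(`join_features`, wide or long), per-group nested analysis
(`nest_cells` / `map_nested` / `unnest_cells`), QC metrics, library-size
log-normalization, min–max rescaling, multi-gene signature scores
(rescaled positive sum minus rescaled negative sum, bounded in [−1, 1]),
variance-ranked variable features, a deterministic PCA embedding, polygon
gating, MatrixMarket (10x triplet) I/O, and a negative-binomial synthetic
PBMC-like generator so every feature is testable offline.

## Worked example

```r
library(cellframe)

cc <- simulate_cells(sim_params(n_cells = 1000, seed = 1))
v  <- as_tidy(cc) |> compute_qc() |> log_normalize() |> run_pca(n_dims = 10)
print(v, n = 4)
#> # A Cell-table abstraction: 1000 × 16
#> # Features = 500 | Active assay=RNA | Assays=RNA
#> # .cell<key> | sample<edit> | true_type<edit> | total_count<edit> | ...
#> # A tibble: 4 × 16
#>   .cell sample true_type total_count n_detected mito_fraction   PC1   PC2
#> 1 cell… sampl… type_1           2045        288        0.0220 -1.37  5.48
#> 2 cell… sampl… type_3           1342        259        0.0261 -5.99 -3.89
#> ...
```

The header counts cells × visible columns and reports the feature count
and assays; `<key>/<edit>/<view>` mark the column classes. Score the
planted cell type with a positive/negative marker signature and summarize
per type:

```r
fm  <- backend(v)$feature_meta
pos <- fm$feature[!is.na(fm$marker_of) & fm$marker_of == "type_1"]
neg <- fm$feature[!is.na(fm$marker_of) & fm$marker_of == "type_2"]
v   <- signature_score(v, positive = pos, negative = neg, slot = "data")
summarise(group_by(v, true_type), mean_score = mean(signature_score), n = dplyr::n())
#>   true_type mean_score     n
#> 1 type_1        0.517    316
#> 2 type_2       -0.450    352
#> 3 type_3        0.0224   332
```

`type_1` — the type whose markers form the positive set — scores highest;
`type_2` (the negative set) lowest. Balanced subsampling across samples is
one pipeline:

```r
bal <- v |>
  add_count(sample, name = "tot_cells") |>
  mutate(min_cells = min(tot_cells)) |>
  group_by(sample) |>
  sample_cells(min_cells, seed = 1)
count(bal, sample)
#>   sample       n
#> 1 sample_1   499
#> 2 sample_2   499
```

Both samples end up with exactly the smaller sample's size (499 here).
Cells in an embedding region are selected with a fixed polygon instead of
an interactive gate:

```r
g <- gate_polygon(v, "PC1", "PC2", "0,0 10,0 10,10 0,10", out_column = "in_gate")
filter(g, in_gate)   # still a container-backed view
```

## Command line

```sh
exec/cellframe simulate --n-cells 500 --seed 1 --out /tmp/sim
exec/cellframe describe /tmp/sim
exec/cellframe score /tmp/sim --positive gene1,gene2 --negative gene11 --out /tmp/scored
exec/cellframe gate /tmp/scored --x PC1 --y PC2 --polygon "0,0 10,0 10,10 0,10" --out /tmp/gated
```

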