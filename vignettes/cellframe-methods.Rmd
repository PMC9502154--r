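---
title: "cellframe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellframe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellframe)
```

## The abstraction and its dispatch rule

A single-cell experiment is stored as a `CellContainer`: named assays
(each a features × cells sparse matrix with a raw `counts` slot and
optionally a normalized `data` slot), a per-cell metadata table, a
per-feature metadata table, and named reductions (cells × dims embedding
matrices). Matrices are stored features × cells — the orientation of 10x
triplet files — so disk round trips are bit-exact; only the abstraction is
cell-major.

`as_tidy()` presents the container as a table with one row per cell.
Columns fall into three classes:

* **key** — exactly one column, `.cell`, holding the cell identifier. The
  leading dot avoids collisions with user metadata.
* **editable** — the cell-metadata columns. Verbs may create, overwrite,
  rename and delete these.
* **view-only** — reduction dimensions. They are derived data: readable
  (you can sort or gate on `PC1`) but not writable.

Every adapted verb follows the same template: materialize the visible
table, apply the ordinary dplyr/tidyr operation, and *dispatch* on the
result. The result is promoted back to a container-backed view iff

1. the `.cell` column is still present with unmodified values drawn from
   the origin's cells,
2. no cell is duplicated, and
3. no view-only column's values changed.

Otherwise the result is returned as a plain tibble together with a
structured demotion warning (verb + violated rule, emitted once per
call). Demotion is a value, never an error: a duplicated-cell table is a
perfectly good table, it just cannot be a container. Two asymmetries are
deliberate:

* `mutate(v, PC1 = 0)` raises a read-only error instead of silently
  demoting — "view only" implies write protection, and silent demotion on
  an assignment is almost always a bug in the caller's pipeline.
* `select()` without a view-only column merely *hides* it; the backing
  reduction is kept. Hiding is a display concern, deletion is not possible
  for derived data.

Duplication is representable only after demotion: at container level,
`subset_cells()` and `bind_cells()` treat repeated cell ids as errors.
Sampling with replacement always returns a plain table, even when a
particular draw contains no duplicates — the return *kind* of a verb is a
function of the operation, not of the randomness.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `scale_total` (`log_normalize`) | 10 000 | counts-per-10k, the convention shared by the major toolkits; the signature score is invariant to it (min–max rescaling removes scale and offset) |
| `to` (`rescale_minmax`, `signature_score`) | `c(0, 1)` | makes a positive-minus-negative score land in [−1, 1] |
| `mito_pattern` (`compute_qc`) | `"MT-"` | human gene-symbol prefix for mitochondrial genes |
| `k` (`variable_features`) | 2000 | customary highly-variable-gene count; truncated with a warning beyond the feature count |
| `n_dims` (`run_pca`) | 10 | enough to separate a handful of cell types; must not exceed min(cells, features) |
| label separator (`options(cellframe.label_sep = )`) | `""` | `"PC1"`/`"UMAP1"` spelling; set `"_"` for the `"UMAP_1"` spelling — both appear in the wild and the package treats the choice as configuration |
| `flavor` (`display_header`) | `"Cell"` | first header line reads `# A Cell-table abstraction: N × M` |

## The synthetic generator: what a green test establishes

`simulate_cells()` emulates a small PBMC-like droplet experiment. Counts
are negative binomial with mean

```
mu[f, c] = base_mean[f] * lib[c] * boost[f, c]
```

* `base_mean` — gamma-distributed baselines (shape 0.5) scaled so a
  library-factor-1 cell expects `total_mean = 2000` counts; markers are
  pinned at the average non-marker baseline so the marker boost is
  interpretable as a pure fold change.
* `lib` — per-cell log-normal library-size factor (`sdlog = 0.35`,
  roughly the spread seen in filtered droplet data).
* `boost` — `2^marker_log2fc` (default 8×) for the 10 marker genes of the
  cell's type, 1 elsewhere. Three types, equal proportions, two samples
  assigned uniformly.
* 10 `MT-` genes share 5% of the expected library, giving realistic
  mitochondrial fractions.
* dispersion: NB `size = 1` (variance = μ + μ²), typical of UMI counts at
  this depth.

Ground truth (`true_type`, `sample`, `marker_of`, `is_mito`) is recorded
so tests can assert against the generator's *own stated model* — e.g.
that the realized marker fold change is within 15% of `2^marker_log2fc`
at n = 2000, or that a signature built from planted markers ranks the
planted type highest.

What the generator does **not** emulate: doublets and empty droplets,
ambient RNA, batch effects between samples, gene–gene correlation beyond
the type structure, cell-cycle phase, or realistic mean–variance trends
across genes. A green case-study test therefore establishes that the
*machinery* (scoring, balancing, gating, dispatch) is correct under a
known signal, not that the defaults are tuned for any particular real
dataset. All randomness flows through explicit seeds; the generator is a
pure function of its parameter object.

## Numerical choices

* **Zero-range rescale.** `rescale_minmax(c(5,5,5))` returns the midpoint
  of `to`. Any affine choice is defensible; the midpoint matches the
  convention of the scaling utilities this mirrors and keeps constant
  signatures at score 0.
* **PCA sign.** Each component is flipped so its largest-magnitude
  feature loading is positive; with base `svd()` and no stochastic
  initialization the embedding is bit-reproducible. Variance-ranked
  feature selection breaks ties by input feature order (stable
  `order()`).
* **Polygon boundary.** Points exactly on an edge or vertex are inside
  (even–odd ray casting with an explicit collinearity test), so a gate's
  cell count is reproducible; degenerate polygons (< 3 vertices or zero
  area) are rejected. The test suite checks agreement with an independent
  winding-number implementation on 10⁴ random points, which holds for
  simple polygons.
* **Degenerate inputs.** Zero-total cells stay all-zero under
  normalization and have `mito_fraction = 0` (guarded division); 0-cell
  views are valid and display as `0 × M`; an all-constant matrix ranks
  features in input order.
* **Non-scalar aggregations.** Current dplyr errors on multi-row
  `summarise()` results; the adapter rethrows this as the package's
  aggregation-error class so callers see one stable condition type.

## Open design points and how they were settled

* **Wide `join_features` stays container-backed.** Adding per-feature
  columns duplicates no cell and touches no key, and real pipelines pipe
  the wide result straight into `mutate()`; the long shape, which
  replicates cells by construction, is always a plain table.
* **Right joins.** Rows with no backing cell cannot be container-backed;
  any unmatched right row demotes the whole result rather than inventing
  placeholder cells.
* **Reductions survive feature-space changes** (they are cell-wise);
  concatenation keeps a reduction only when both datasets carry it with
  identical dimension labels, and always drops normalized `data` slots —
  normalizations fitted per dataset are not mergeable.
* **`NA` group keys** form their own nesting group rather than being
  dropped: silently losing cells during a nest/unnest round trip would
  violate the partition invariant.

## Limitations

No UMAP, graph clustering, differential expression, cell-cycle scoring or
reference-based cell typing — those belong to the upstream toolkits this
package abstracts over; the PCA here is a deterministic stand-in
embedding. Assays are limited to `counts`/`data` slots (no scaled slot),
single modality, in-memory matrices. The expression interface of
`mutate`/`filter` is vectorized tidy evaluation over visible columns;
arbitrary row-wise callbacks are out of scope so the dense relational
oracle in the tests can evaluate the same expressions identically.

There are no numeric acceptance targets: the quantities reported in the
motivating study (50 706 cells, 24 clusters, cluster percentages,
classification discordance, code-size ratios) all depend on seven
external accessions and upstream clustering/classification tools.
Acceptance is property-based — dispatch-rule exactness, equivalence with
a dense relational oracle, round-trip identities, the synthetic case
study, closed-form checks and the display contract — implemented in
`tests/testthat/test-acceptance.R` and re-run from scratch by
`scripts/acceptance.R`.
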