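#' Per-cell quality-control metrics
#'
#' Adds three editable metadata columns computed from the counts slot of
#' the active assay: `total_count` (library size), `n_detected` (features
#' with a positive count) and `mito_fraction` (share of counts from
#' features whose id starts with `mito_pattern`; 0 for an all-zero cell).
#'
#' @param view A `TidyView`.
#' @param mito_pattern Feature-id prefix marking mitochondrial genes
#'   (default `"MT-"`, the human gene-symbol convention).
#' @return A `TidyView` with the QC columns.
#' @export
compute_qc <- function(view, mito_pattern = "MT-") {
  stopifnot(inherits(view, "TidyView"))
  cc <- view$backend
  counts <- get_slot(cc, slot = "counts")
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  a <- get_assay(cc)
  is_mito <- startsWith(a$feature_ids, mito_pattern)
  mito <- if (any(is_mito)) Matrix::colSums(counts[is_mito, , drop = FALSE]) else numeric(length(total))
  frac <- ifelse(total > 0, mito / total, 0)
  for (nm in c("total_count", "n_detected", "mito_fraction")) {
    if (!nm %in% view$col_order) view$col_order <- c(view$col_order, nm)
  }
  cc <- set_cell_meta_column(cc, "total_count", unname(total))
  cc <- set_cell_meta_column(cc, "n_detected", unname(as.numeric(detected)))
  cc <- set_cell_meta_column(cc, "mito_fraction", unname(frac))
  view$backend <- cc
  view
}

#' Library-size log-normalization
#'
#' Writes the `"data"` slot of the active assay:
#' `log(1 + count * scale_total / total_count)` per entry, the standard
#' counts-per-`scale_total` log transform. Cells with zero total stay
#' all-zero; the sparsity pattern is preserved.
#'
#' @param view A `TidyView`.
#' @param scale_total Target library size (default 10000).
#' @return A `TidyView` whose backend gained a `"data"` slot.
#' @export
log_normalize <- function(view, scale_total = 10000) {
  stopifnot(inherits(view, "TidyView"))
  cc <- view$backend
  view$backend <- log_normalize_container(cc, scale_total)
  view
}

log_normalize_container <- function(cc, scale_total = 10000) {
  counts <- get_slot(cc, slot = "counts")
  total <- Matrix::colSums(counts)
  data <- counts
  if (length(data@x)) {
    percol <- rep.int(total, diff(data@p))
    data@x <- log1p(data@x * scale_total / percol)
  }
  set_slot(cc, "data", data)
}

#' Min-max rescaling
#'
#' Linearly maps `values` so that the minimum lands on `to[1]` and the
#' maximum on `to[2]`. Zero-range input maps to the midpoint of `to`.
#'
#' @param values Finite numeric vector (non-empty).
#' @param to Output range `c(low, high)`, `low < high`.
#' @return Numeric vector of the same length.
#' @examples
#' rescale_minmax(c(2, 4, 6))          # 0, 0.5, 1
#' rescale_minmax(c(5, 5, 5))          # midpoint rule: 0.5, 0.5, 0.5
#' @export
rescale_minmax <- function(values, to = c(0, 1)) {
  if (length(values) == 0) err_empty_input("cannot rescale an empty vector")
  stopifnot(length(to) == 2, to[1] < to[2])
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep((to[1] + to[2]) / 2, length(values)))
  (values - rng[1]) / (rng[2] - rng[1]) * (to[2] - to[1]) + to[1]
}

#' Multi-gene signature score
#'
#' Per cell: the min-max-rescaled sum of the positive features' slot values
#' minus the rescaled sum of the negative features' (0 when the negative
#' set is empty). With `to = c(0, 1)` scores lie in `[-1, 1]`. The score is
#' invariant under positive affine transforms of the per-cell sums.
#'
#' @param view A `TidyView`.
#' @param positive,negative Character vectors of feature ids.
#' @param assay Assay name; default the active assay.
#' @param slot Slot; defaults to `"data"` when present, else `"counts"`.
#' @param to Rescale range (default `c(0, 1)`).
#' @param out_column Name of the score column (default `"signature_score"`).
#' @return A `TidyView` with the score as an editable column.
#' @export
signature_score <- function(view, positive, negative = character(),
                            assay = NULL, slot = NULL, to = c(0, 1),
                            out_column = "signature_score") {
  stopifnot(inherits(view, "TidyView"))
  if (length(positive) + length(negative) == 0) err_param("empty signature")
  cc <- view$backend
  a <- get_assay(cc, assay)
  if (is.null(slot)) slot <- if ("data" %in% names(a$slots)) "data" else "counts"
  m <- a$slots[[slot]]
  if (is.null(m)) err_name(sprintf("assay '%s' has no slot '%s'", a$name, slot))
  missing <- setdiff(c(positive, negative), a$feature_ids)
  if (length(missing)) {
    err_feature(sprintf("feature(s) not found: %s", paste(missing, collapse = ", ")),
                missing = missing)
  }
  sum_rows <- function(ids) {
    if (!length(ids)) return(NULL)
    as.numeric(Matrix::colSums(m[match(ids, a$feature_ids), , drop = FALSE]))
  }
  pos <- sum_rows(positive)
  neg <- sum_rows(negative)
  score <- if (is.null(pos)) 0 else rescale_minmax(pos, to)
  if (!is.null(neg)) score <- score - rescale_minmax(neg, to)
  cc <- set_cell_meta_column(cc, out_column, score)
  view$backend <- cc
  if (!out_column %in% view$col_order) view$col_order <- c(view$col_order, out_column)
  view
}

feature_variances <- function(m) {
  # var over cells per feature, computed on the sparse structure:
  # var = (sum x^2 - n * mean^2) / (n - 1)
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  sums <- Matrix::rowSums(m)
  sq <- Matrix::rowSums(m^2)
  (sq - sums^2 / n) / (n - 1)
}

#' Variance-ranked variable features
#'
#' Features ranked by descending variance of the normalized `"data"` slot
#' across cells (computed with [log_normalize()] defaults when absent),
#' ties broken by input feature order. A deliberately simple stand-in for
#' mean-variance-stabilized selection.
#'
#' @param container A `CellContainer` (or `TidyView`).
#' @param k Number of features to return; larger than the feature count is
#'   truncated with a warning.
#' @return Character vector of the top-`k` feature ids.
#' @export
variable_features <- function(container, k = 2000) {
  if (inherits(container, "TidyView")) container <- container$backend
  a <- get_assay(container)
  if (!"data" %in% names(a$slots)) {
    container <- log_normalize_container(container)
    a <- get_assay(container)
  }
  if (k > length(a$feature_ids)) {
    warn_cellframe(sprintf("k = %d exceeds %d features; truncated", k, length(a$feature_ids)))
    k <- length(a$feature_ids)
  }
  v <- feature_variances(a$slots$data)
  a$feature_ids[order(-v)[seq_len(k)]]
}

#' Deterministic PCA embedding
#'
#' Truncated SVD of the per-feature-centered `"data"` slot (computed with
#' [log_normalize()] defaults when absent), restricted to `use_features`
#' (default: top-2000 variable features). The embedding is stored as
#' reduction `"pc"`. Sign convention: each component's largest-magnitude
#' feature loading is positive, so results are bit-reproducible.
#'
#' @param container A `CellContainer` (or `TidyView`; the same kind is
#'   returned).
#' @param n_dims Number of components; at most `min(n_cells, n_features)`.
#' @param use_features Optional feature-id subset.
#' @return The input with reduction `"pc"` attached.
#' @export
run_pca <- function(container, n_dims = 10, use_features = NULL) {
  is_view <- inherits(container, "TidyView")
  cc <- if (is_view) container$backend else container
  a <- get_assay(cc)
  if (!"data" %in% names(a$slots)) {
    cc <- log_normalize_container(cc)
    a <- get_assay(cc)
  }
  if (is.null(use_features)) {
    use_features <- variable_features(cc, k = min(2000, length(a$feature_ids)))
  }
  missing <- setdiff(use_features, a$feature_ids)
  if (length(missing)) err_feature("unknown feature(s) in use_features", missing = missing)
  x <- t(as.matrix(a$slots$data[match(use_features, a$feature_ids), , drop = FALSE]))
  if (n_dims > min(nrow(x), ncol(x))) {
    err_shape(sprintf("n_dims = %d exceeds min(n_cells, n_features) = %d",
                      n_dims, min(nrow(x), ncol(x))))
  }
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_dims, nv = n_dims)
  u <- sv$u; v <- sv$v
  for (j in seq_len(n_dims)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(sv$d[seq_len(n_dims)], n_dims)
  cc <- add_reduction(cc, "pc", scores)
  if (is_view) {
    container$backend <- cc
    container$col_order <- union(container$col_order, reduction_labels(cc))
    container
  } else {
    cc
  }
}

point_in_polygon <- function(px, py, vx, vy) {
  # even-odd ray casting; points on an edge or vertex count as inside
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: collinear and within the segment's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) & px <= pmax(xi, xj) &
              py >= pmin(yi, yj) & py <= pmax(yi, yj)
    on_edge <- on_edge | (cross == 0 & within)
    crosses <- ((yi > py) != (yj > py)) &
               (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

polygon_area2 <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  sum(vx[j] * vy - vx * vy[j])
}

#' Polygon gating of cells in a 2-D embedding
#'
#' A programmatic replacement for interactive gate drawing: tests each
#' cell's (x, y) coordinates against a fixed polygon (even-odd ray
#' casting; boundary points count as inside, so gate counts are
#' reproducible) and writes the result as a logical editable column.
#'
#' @param view A `TidyView`.
#' @param x_column,y_column Visible numeric columns (view-only reduction
#'   columns may be read).
#' @param polygon A two-column matrix / data frame of vertices (>= 3,
#'   non-degenerate), or a string `"x1,y1 x2,y2 ..."`.
#' @param out_column Name of the logical gate column (default `"gated"`).
#' @return A `TidyView` with the gate column.
#' @export
gate_polygon <- function(view, x_column, y_column, polygon, out_column = "gated") {
  stopifnot(inherits(view, "TidyView"))
  for (nm in c(x_column, y_column)) {
    if (!nm %in% visible_columns(view)) err_name(sprintf("unknown column '%s'", nm))
  }
  poly <- parse_polygon(polygon)
  if (nrow(poly) < 3 || abs(polygon_area2(poly[, 1], poly[, 2])) == 0) {
    err_polygon("polygon must have >= 3 vertices and non-zero area")
  }
  tbl <- materialize(view)
  gated <- point_in_polygon(as.numeric(tbl[[x_column]]), as.numeric(tbl[[y_column]]),
                            poly[, 1], poly[, 2])
  view$backend <- set_cell_meta_column(view$backend, out_column, gated)
  if (!out_column %in% view$col_order) view$col_order <- c(view$col_order, out_column)
  view
}

parse_polygon <- function(polygon) {
  if (is.character(polygon) && length(polygon) == 1) {
    pairs <- strsplit(trimws(polygon), "\\s+")[[1]]
    xy <- lapply(strsplit(pairs, ","), as.numeric)
    if (any(vapply(xy, length, 1L) != 2) || anyNA(unlist(xy))) {
      err_polygon("polygon string must be \"x1,y1 x2,y2 ...\"")
    }
    polygon <- do.call(rbind, xy)
  }
  poly <- as.matrix(polygon)
  if (ncol(poly) != 2 || anyNA(poly)) err_polygon("polygon must be vertices x 2 numeric")
  poly
}
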