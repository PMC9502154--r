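# Fixtures are built in code; no files on disk.

# A 4-cell fixture mirroring the published example table: editable
# metadata columns, one PC and one UMAP reduction dimension.
table1_fixture <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 1, 4, 5, 2),
    j = c(1, 1, 2, 3, 3, 4, 4),
    x = c(2, 1, 5, 3, 1, 4, 2),
    dims = c(5, 4)
  )
  cc <- new_container(
    counts, paste0("g", 1:5), paste0("cell_", 1:4),
    cell_meta = tibble::tibble(
      `Total count` = c(10456, 2088, 11309, 8791),
      `Total transcripts` = c(450, 400, 699, 423),
      Cluster = c(1L, 2L, 5L, 1L),
      `Cell type` = c("T cell", "B cell", "Monocyte", "Monocyte")
    )
  )
  cc <- add_reduction(cc, "pc", matrix(c(-1.23, 0.98, 5.55, -5.42), ncol = 1))
  add_reduction(cc, "umap", matrix(c(-3.47, -1.59, 1.26, -4.42), ncol = 1))
}

# Randomized container: n cells, sparse counts, two metadata columns and a
# 2-dim reduction. Used by the property/oracle tests.
random_container <- function(seed, n = 50, n_feat = 20) {
  withr::with_seed(seed, {
    dense <- matrix(rpois(n_feat * n, 1.5), n_feat, n)
    cc <- new_container(
      Matrix::Matrix(dense, sparse = TRUE),
      paste0("g", seq_len(n_feat)),
      sprintf("c%03d", seq_len(n)),
      cell_meta = tibble::tibble(
        sample = sample(c("A", "B", "C"), n, replace = TRUE),
        score = round(rnorm(n), 3),
        grp = sample(c("x", "y"), n, replace = TRUE)
      )
    )
    add_reduction(cc, "pc", matrix(round(rnorm(2 * n), 3), ncol = 2))
  })
}

# Independent winding-number point-in-polygon oracle (signed-angle sum),
# unrelated to the ray-casting implementation under test.
winding_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vx[i] - px; ay <- vy[i] - py
    bx <- vx[j] - px; by <- vy[j] - py
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(total) > pi  # winding number != 0
}

expect_view <- function(x) expect_s3_class(x, "TidyView")
expect_plain <- function(x) {
  expect_false(inherits(x, "TidyView"))
  expect_s3_class(x, "tbl_df")
}

# order-insensitive equality of two materialized cell tables, keyed by .cell
expect_same_cells <- function(a, b) {
  expect_setequal(a$.cell, b$.cell)
  expect_setequal(names(a), names(b))
  a <- a[order(a$.cell), sort(names(a))]
  b <- b[order(b$.cell), sort(names(b))]
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
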