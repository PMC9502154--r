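v1 <- function() as_tidy(table1_fixture())

test_that("mutate writes editable columns and guards key / view-only ones", {
  out <- mutate(v1(), double = 2 * `Total count`)
  expect_view(out)
  expect_equal(materialize(out)$double, c(20912, 4176, 22618, 17582))
  expect_warning(out2 <- mutate(v1(), .cell = "x"), class = "cellframe_demotion")
  expect_plain(out2)
  expect_error(mutate(v1(), PC1 = 0), class = "cellframe_readonly_column_error")
  expect_error(mutate(v1(), y = nonexistent + 1), class = "cellframe_name_error")
})

test_that("grouped mutate broadcasts aggregates within groups", {
  out <- v1() |>
    group_by(`Cell type`) |>
    mutate(min_count = min(`Total count`))
  expect_view(out)
  expect_equal(materialize(out)$min_count, c(10456, 2088, 8791, 8791))
  expect_equal(group_vars(ungroup(out)), character())
})

test_that("rename keeps the backend for editable columns only", {
  out <- rename(v1(), cluster_id = Cluster)
  expect_view(out)
  expect_true("cluster_id" %in% names(backend(out)$cell_meta))
  expect_false("Cluster" %in% visible_columns(out))
  expect_warning(out2 <- rename(v1(), barcode = .cell), class = "cellframe_demotion")
  expect_plain(out2)
  expect_error(rename(v1(), PC1 = Cluster), class = "cellframe_name_collision_error")
})

test_that("select keeps the view iff .cell is kept, hiding not deleting", {
  out <- select(v1(), .cell, Cluster)
  expect_view(out)
  expect_equal(visible_columns(out), c(".cell", "Cluster"))
  expect_true("Total count" %in% names(backend(out)$cell_meta))
  expect_warning(out2 <- select(v1(), Cluster), class = "cellframe_demotion")
  expect_plain(out2)
  expect_error(select(v1(), nope), class = "cellframe_name_error")
})

test_that("filter subsets cells preserving order", {
  out <- filter(v1(), `Total count` > 5000)
  expect_view(out)
  expect_equal(cell_ids(backend(out)), paste0("cell_", c(1, 3, 4)))
  expect_equal(cell_ids(backend(filter(v1(), TRUE))), paste0("cell_", 1:4))
  none <- filter(v1(), FALSE)
  expect_view(none)
  expect_equal(n_cells(backend(none)), 0)
  expect_match(display_header(none)[1], "0 × 7")
  expect_error(filter(v1(), nope > 1), class = "cellframe_name_error")
})

test_that("slice honors order, errors out of range, demotes duplicates", {
  out <- slice(v1(), 2)
  expect_view(out)
  expect_equal(cell_ids(backend(out)), "cell_2")
  expect_warning(out2 <- slice(v1(), c(1, 1)), class = "cellframe_demotion")
  expect_plain(out2)
  expect_error(slice(v1(), 5), class = "cellframe_index_error")
  expect_equal(cell_ids(backend(slice(v1(), c(3, 1)))), c("cell_3", "cell_1"))
})

test_that("arrange sorts stably and may read view-only columns", {
  out <- arrange(v1(), `Total count`)
  expect_view(out)
  expect_equal(cell_ids(backend(out)), c("cell_2", "cell_4", "cell_1", "cell_3"))
  # stability: Cluster has a tie (cell_1, cell_4) broken by prior order
  expect_equal(cell_ids(backend(arrange(v1(), Cluster))),
               c("cell_1", "cell_4", "cell_2", "cell_3"))
  expect_view(arrange(v1(), PC1))
})

test_that("sample_cells is seeded, per-group, and demotes with replacement", {
  out <- sample_cells(v1(), n = 2, seed = 7)
  expect_view(out)
  expect_equal(n_cells(backend(out)), 2)
  expect_identical(cell_ids(backend(sample_cells(v1(), n = 2, seed = 7))),
                   cell_ids(backend(out)))
  expect_warning(rep_out <- sample_cells(v1(), n = 3, replace = TRUE, seed = 1),
                 class = "cellframe_demotion")
  expect_plain(rep_out)
  expect_error(sample_cells(v1(), n = 9, seed = 1), class = "cellframe_sample_size_error")
  expect_error(sample_cells(v1(), n = 2, frac = 0.5, seed = 1), class = "cellframe_param_error")

  cc <- random_container(11, n = 15)
  g <- group_by(as_tidy(cc), sample)
  sizes <- table(materialize(g)$sample)
  n_min <- min(sizes)
  out2 <- sample_cells(g, n = n_min, seed = 3)
  expect_view(out2)
  expect_true(all(table(materialize(out2)$sample) == n_min))
})

test_that("count / add_count follow the blue/green split", {
  cc <- random_container(4, n = 5)
  v <- as_tidy(cc)
  tb <- count(v, sample)
  expect_plain(tb)
  expect_equal(sum(tb$n), 5)
  out <- add_count(v, sample, name = "tot_cells")
  expect_view(out)
  tbl <- materialize(out)
  expect_equal(tbl$tot_cells, as.vector(table(tbl$sample)[tbl$sample]))
  expect_error(add_count(out, sample, name = "tot_cells"),
               class = "cellframe_name_collision_error")
  none <- filter(v, FALSE)
  expect_equal(nrow(count(none, sample)), 0)
})

test_that("summarise and distinct always return plain tables", {
  tb <- summarise(v1(), m = mean(`Total count`))
  expect_plain(tb)
  expect_equal(tb$m, 8161)
  by_type <- summarise(group_by(v1(), `Cell type`), m = mean(`Total count`))
  expect_equal(nrow(by_type), 3)
  expect_error(summarise(v1(), m = range(`Total count`)),
               class = "cellframe_aggregation_error")
  d <- distinct(v1(), `Cell type`)
  expect_plain(d)
  expect_equal(d$`Cell type`, c("T cell", "B cell", "Monocyte"))
  expect_equal(nrow(distinct(v1(), .cell)), 4)
})

test_that("pull returns bare arrays", {
  expect_equal(pull(v1(), .cell), paste0("cell_", 1:4))
  expect_equal(pull(v1(), PC1), c(-1.23, 0.98, 5.55, -5.42))
  expect_error(pull(v1(), nope), class = "cellframe_name_error")
})

test_that("join_metadata promotes unique-match joins and demotes the rest", {
  cc <- random_container(5, n = 6)
  v <- as_tidy(cc)
  lookup <- tibble::tibble(sample = c("A", "B", "C"), condition = c("ctl", "trt", "ctl"))
  out <- join_metadata(v, lookup, by = "sample", mode = "left")
  expect_view(out)
  expect_equal(materialize(out)$condition,
               lookup$condition[match(materialize(v)$sample, lookup$sample)])

  dup_lookup <- lookup[c(1, 1, 2, 3), ]
  expect_warning(out2 <- join_metadata(v, dup_lookup, by = "sample", mode = "left"),
                 class = "cellframe_demotion")
  expect_plain(out2)

  partial <- lookup[lookup$sample != materialize(v)$sample[[1]], ]
  out3 <- join_metadata(v, partial, by = "sample", mode = "inner")
  expect_view(out3)
  expect_lt(n_cells(backend(out3)), 6)
  # relational oracle on the densified table
  expect_equal(as.data.frame(materialize(out3)),
               as.data.frame(dplyr::inner_join(materialize(v), partial, by = "sample")))

  extra <- dplyr::bind_rows(lookup, tibble::tibble(sample = "Z", condition = "trt"))
  expect_warning(out4 <- join_metadata(v, extra, by = "sample", mode = "right"),
                 class = "cellframe_demotion")
  expect_plain(out4)
  expect_error(join_metadata(v, lookup, by = character()), class = "cellframe_join_key_error")
})

test_that("bind_cells concatenates with union or intersect feature policies", {
  m1 <- Matrix::Matrix(matrix(1:6, 2, 3), sparse = TRUE)   # g1, g2 x 3 cells
  m2 <- Matrix::Matrix(matrix(7:10, 2, 2), sparse = TRUE)  # g2, g3 x 2 cells
  a <- new_container(m1, c("g1", "g2"), c("c1", "c2", "c3"))
  b <- new_container(m2, c("g2", "g3"), c("d1", "d2"))
  out <- bind_cells(as_tidy(a), as_tidy(b), feature_policy = "union")
  expect_view(out)
  cc <- backend(out)
  expect_equal(n_cells(cc), 5)
  expect_equal(get_assay(cc)$feature_ids, c("g1", "g2", "g3"))
  dense <- as.matrix(get_slot(cc))
  # zero-fill oracle on densified blocks
  oracle <- matrix(0, 3, 5, dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3", "d1", "d2")))
  oracle[1:2, 1:3] <- as.matrix(m1)
  oracle[2:3, 4:5] <- as.matrix(m2)
  expect_equal(dense, oracle)
  inter <- backend(bind_cells(a, b, feature_policy = "intersect"))
  expect_equal(get_assay(inter)$feature_ids, "g2")
  expect_error(bind_cells(a, a), class = "cellframe_duplication_error")
  expect_view(bind_cells(a, a, make_unique = TRUE))
})

test_that("bind_cells drops unmergeable data slots and unshared reductions", {
  a <- random_container(6, n = 4)
  b <- relabeled <- random_container(7, n = 3)
  b$cell_ids <- paste0("x", b$cell_ids)
  b <- subset_cells(b, b$cell_ids)  # no-op aside from consistency
  va <- log_normalize(as_tidy(a))
  expect_warning(out <- bind_cells(va, as_tidy(b)), class = "cellframe_warning")
  expect_false("data" %in% names(get_assay(backend(out))$slots))
  expect_true("pc" %in% names(backend(out)$reductions))
})

test_that("separate / unite / extract operate on editable columns only", {
  cc <- new_container(Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 2)),
                      "g1", c("c1", "c2"),
                      cell_meta = tibble::tibble(sample_rep = c("S1_a", "S2_b")))
  v <- as_tidy(cc)
  out <- separate(v, sample_rep, into = c("sample", "rep"), sep = "_")
  expect_view(out)
  expect_equal(materialize(out)$sample, c("S1", "S2"))
  back <- unite(out, "sample_rep", sample, rep, sep = "-")
  expect_view(back)
  expect_equal(materialize(back)$sample_rep, c("S1-a", "S2-b"))
  ex <- extract(v, sample_rep, into = "snum", regex = "S([0-9]+)_", remove = FALSE)
  expect_view(ex)
  expect_equal(materialize(ex)$snum, c("1", "2"))
  expect_error(extract(v, sample_rep, into = "x", regex = "S[0-9]+"),
               class = "cellframe_pattern_error")
  t1 <- v1()
  expect_error(separate(t1, PC1, into = c("a", "b")), class = "cellframe_readonly_column_error")
  expect_error(unite(t1, "k", .cell, Cluster), class = "cellframe_readonly_column_error")
})

test_that("pivot_longer always returns a plain long table", {
  v <- v1()
  long <- pivot_longer(v, cols = c(`Total count`, `Total transcripts`, Cluster))
  expect_plain(long)
  expect_equal(nrow(long), 4 * 3)
  # reshape oracle: (cell, name) -> value preserved pairwise
  tbl <- materialize(v)
  for (i in seq_len(nrow(long))) {
    expect_equal(long$value[[i]], tbl[[long$name[[i]]]][[match(long$.cell[[i]], tbl$.cell)]])
  }
  expect_equal(nrow(pivot_longer(v, cols = Cluster)), 4)
})

test_that("no verb mutates its input view's backend", {
  v <- v1()
  before <- backend(v)
  invisible(mutate(v, z = 1))
  invisible(filter(v, Cluster == 1))
  invisible(arrange(v, PC1))
  invisible(suppressWarnings(slice(v, c(1, 1))))
  invisible(sample_cells(v, n = 2, seed = 1))
  expect_identical(backend(v), before)
})

test_that("filter composes and grouped sampling caps at group size", {
  for (seed in 1:10) {
    v <- as_tidy(random_container(seed))
    fused <- filter(v, score > 0 & grp == "x")
    chained <- filter(filter(v, score > 0), grp == "x")
    expect_identical(materialize(fused), materialize(chained))
    g <- group_by(v, sample)
    sizes <- table(materialize(v)$sample)
    n_req <- 3
    out <- sample_cells(g, n = min(n_req, min(sizes)), seed = seed)
    expect_true(all(table(materialize(out)$sample) == min(n_req, min(sizes))))
  }
})
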