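#' @import rlang
#' @importFrom dplyr mutate rename select filter slice arrange group_by
#'   ungroup group_vars count add_count summarise summarize distinct pull
#'   left_join inner_join right_join bind_rows
#' @importFrom tidyr separate unite extract pivot_longer
NULL

# Materialize with the view's grouping applied, so grouped verbs
# (mutate-with-aggregates, summarise, count) see dplyr groups.
grouped_tbl <- function(view) {
  tbl <- materialize(view)
  if (length(view$groups)) dplyr::group_by(tbl, !!!syms(view$groups)) else tbl
}

# dplyr raises plain evaluation errors for unknown columns; rethrow them as
# the package's name error so callers can rely on one condition class.
with_name_errors <- function(expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "cellframe_error")) stop(e)
    err_name(conditionMessage(e))
  })
}

check_readonly_targets <- function(view, targets, verb) {
  ro <- intersect(targets, viewonly_columns(view))
  if (length(ro)) {
    err_readonly(sprintf("`%s()` cannot modify view-only column(s): %s",
                         verb, paste(ro, collapse = ", ")))
  }
}

#' Grammar-of-data verbs on a tidy view
#'
#' Each verb materializes the view, applies the ordinary tabular operation,
#' and passes the result through [dispatch()]: the return value is a
#' container-backed `TidyView` when the operation neither duplicates cells
#' nor breaks the `.cell` key column, and a plain tibble (with a demotion
#' warning) otherwise. `summarise()`, `count()`, `distinct()`, `pull()` and
#' `pivot_longer()` return plain tables or arrays by design. Assigning to a
#' view-only (reduction) column raises a read-only error; reading one is
#' always allowed.
#'
#' @param .data,x,data A `TidyView`.
#' @param ... Verb arguments, as in dplyr/tidyr.
#' @name verbs
NULL

#' @rdname verbs
#' @export
mutate.TidyView <- function(.data, ...) {
  dots <- enquos(..., .named = TRUE)
  check_readonly_targets(.data, names(dots), "mutate")
  result <- with_name_errors(dplyr::ungroup(dplyr::mutate(grouped_tbl(.data), !!!dots)))
  dispatch_result(result, .data, "mutate")
}

#' @rdname verbs
#' @export
rename.TidyView <- function(.data, ...) {
  dots <- enquos(...)
  new <- names(dots)
  old <- vapply(dots, as_name, character(1))
  unknown <- setdiff(old, visible_columns(.data))
  if (length(unknown)) err_name(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  clash <- intersect(new, setdiff(all_columns(.data), old))
  if (length(clash)) err_collision(sprintf("column(s) %s already exist", paste(clash, collapse = ", ")))
  breaking <- old %in% c(".cell", viewonly_columns(.data))
  if (any(breaking)) {
    result <- dplyr::rename(materialize(.data), !!!dots)
    return(dispatch_result(result, .data, "rename"))
  }
  cc <- .data$backend
  names(cc$cell_meta)[match(old, names(cc$cell_meta))] <- new
  .data$backend <- cc
  .data$col_order[match(old, .data$col_order)] <- new
  .data$groups[.data$groups %in% old] <- new[match(.data$groups[.data$groups %in% old], old)]
  .data
}

#' @rdname verbs
#' @export
select.TidyView <- function(.data, ...) {
  result <- with_name_errors(dplyr::select(materialize(.data), ...))
  dispatch_result(result, .data, "select")
}

#' @rdname verbs
#' @export
filter.TidyView <- function(.data, ..., .preserve = FALSE) {
  result <- with_name_errors(dplyr::ungroup(dplyr::filter(grouped_tbl(.data), ...)))
  dispatch_result(result, .data, "filter")
}

#' @rdname verbs
#' @param positions 1-based cell positions; out-of-range is an error,
#'   duplicated positions demote (cell duplication).
#' @export
slice.TidyView <- function(.data, positions, ...) {
  if (missing(positions)) positions <- integer()
  pos <- c(positions, unlist(list(...)))
  n <- n_cells(.data$backend)
  if (length(pos) && (any(pos < 1) || any(pos > n) || any(pos != trunc(pos)))) {
    err_index(sprintf("positions must be integers in [1, %d]", n))
  }
  result <- materialize(.data)[pos, , drop = FALSE]
  dispatch_result(result, .data, "slice")
}

#' @rdname verbs
#' @export
arrange.TidyView <- function(.data, ...) {
  result <- with_name_errors(dplyr::arrange(materialize(.data), ...))
  dispatch_result(result, .data, "arrange")
}

#' @rdname verbs
#' @param .add Add to existing grouping instead of replacing it.
#' @export
group_by.TidyView <- function(.data, ..., .add = FALSE) {
  cols <- vapply(enquos(...), as_name, character(1))
  unknown <- setdiff(cols, visible_columns(.data))
  if (length(unknown)) err_name(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  .data$groups <- if (.add) union(.data$groups, cols) else cols
  .data
}

#' @rdname verbs
#' @export
ungroup.TidyView <- function(x, ...) {
  x$groups <- character()
  x
}

#' @rdname verbs
#' @param name Name of the count column.
#' @export
count.TidyView <- function(x, ..., name = "n") {
  with_name_errors(dplyr::count(grouped_tbl(x), ..., name = name))
}

#' @rdname verbs
#' @export
add_count.TidyView <- function(x, ..., name = "n") {
  if (name %in% all_columns(x)) {
    err_collision(sprintf("count column '%s' already exists", name))
  }
  result <- with_name_errors(
    dplyr::ungroup(dplyr::add_count(grouped_tbl(x), ..., name = name))
  )
  dispatch_result(result, x, "add_count")
}

#' @rdname verbs
#' @export
summarise.TidyView <- function(.data, ...) {
  tbl <- grouped_tbl(.data)
  n_groups <- if (length(.data$groups)) nrow(dplyr::distinct(dplyr::ungroup(tbl)[.data$groups])) else 1L
  result <- tryCatch(
    withCallingHandlers(
      dplyr::summarise(tbl, ..., .groups = "drop"),
      # dplyr warns (deprecation) before returning a multi-row result; the
      # size check below turns that case into the aggregation error
      lifecycle_warning_deprecated = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) {
      if (inherits(e, "cellframe_error")) stop(e)
      if (grepl("size", conditionMessage(e))) {
        err_aggregation("aggregations must reduce each group to one value")
      }
      err_name(conditionMessage(e))
    }
  )
  if (nrow(result) > n_groups && n_cells(.data$backend) > 0) {
    err_aggregation("aggregations must reduce each group to one value")
  }
  result
}

#' @rdname verbs
#' @export
summarize.TidyView <- summarise.TidyView

#' @rdname verbs
#' @export
distinct.TidyView <- function(.data, ...) {
  with_name_errors(dplyr::distinct(materialize(.data), ...))
}

#' @rdname verbs
#' @param var Column to extract.
#' @export
pull.TidyView <- function(.data, var, ...) {
  with_name_errors(dplyr::pull(materialize(.data), {{ var }}))
}

#' Sample cells, optionally per group
#'
#' Samples `n` cells (or a fraction `frac`) from the view, per group when a
#' grouping is set with `group_by()`. Sampling without replacement returns a
#' container-backed view; with replacement the result may duplicate cells
#' and is therefore a plain tibble. `n` may be a bare column name (e.g. a
#' per-group minimum computed with `mutate()`), in which case its first
#' value within each group is used — this supports the balanced
#' subsampling recipe `add_count() |> mutate(min_cells = min(tot_cells)) |>
#' group_by(sample) |> sample_cells(min_cells, seed = s)`.
#'
#' @param view A `TidyView`.
#' @param n Number of cells per group (scalar, or bare column name).
#' @param frac Fraction of each group in (0, 1]; give exactly one of
#'   `n`/`frac`.
#' @param replace Sample with replacement (result is a plain tibble).
#' @param seed Integer seed; all randomness flows through it (the global
#'   RNG state is untouched).
#' @return A `TidyView`, or a plain tibble when `replace = TRUE`.
#' @export
sample_cells <- function(view, n = NULL, frac = NULL, replace = FALSE, seed) {
  stopifnot(inherits(view, "TidyView"))
  n_quo <- enquo(n)
  has_n <- !quo_is_null(n_quo)
  if (has_n == !is.null(frac)) err_param("give exactly one of `n` or `frac`")
  if (!is.null(frac) && (frac <= 0 || frac > 1)) err_param("`frac` must be in (0, 1]")
  tbl <- materialize(view)
  groups <- view$groups
  key <- if (length(groups)) interaction(tbl[groups], drop = TRUE, lex.order = FALSE) else rep(1L, nrow(tbl))
  idx_by_group <- split(seq_len(nrow(tbl)), key)
  # keep groups in first-occurrence order
  idx_by_group <- idx_by_group[order(vapply(idx_by_group, min, 1L))]
  picked <- withr::with_seed(seed, {
    unlist(lapply(idx_by_group, function(idx) {
      size <- if (has_n) {
        v <- eval_tidy(n_quo, data = tbl[idx, , drop = FALSE])
        as.integer(v[[1]])
      } else {
        as.integer(round(frac * length(idx)))
      }
      if (!replace && size > length(idx)) {
        err_sample_size(sprintf("cannot sample %d from a group of %d without replacement",
                                size, length(idx)))
      }
      idx[sample.int(length(idx), size, replace = replace)]
    }), use.names = FALSE)
  })
  result <- tbl[picked, , drop = FALSE]
  if (replace) {
    # possible duplication: always a plain table, even if this draw had none
    warn_demotion("sample_cells", "sampling with replacement may duplicate cells")
    attr(result, "demotion") <- list(verb = "sample_cells",
                                     rule = "sampling with replacement may duplicate cells")
    return(result)
  }
  dispatch_result(result, view, "sample_cells")
}

#' Join an external metadata table onto the cells
#'
#' A relational join between the materialized view and an ordinary table.
#' Left/inner joins with at most one match per cell return a
#' container-backed view gaining the other table's columns; a join that
#' duplicates cells (many-to-many match) or produces rows with no backing
#' cell (right-join unmatched rows) demotes to a plain tibble.
#'
#' @param view A `TidyView`.
#' @param other A data frame.
#' @param by Character vector of join columns (non-empty).
#' @param mode One of `"left"`, `"inner"`, `"right"`.
#' @return A `TidyView` or a plain tibble.
#' @export
join_metadata <- function(view, other, by, mode = c("left", "inner", "right")) {
  mode <- match.arg(mode)
  if (length(by) == 0) err_join_key("`by` must name at least one column")
  other <- tibble::as_tibble(other)
  clash <- intersect(names(other), viewonly_columns(view))
  if (length(clash)) {
    err_collision(sprintf("`other` uses view-only column name(s): %s", paste(clash, collapse = ", ")))
  }
  joinfn <- switch(mode, left = dplyr::left_join, inner = dplyr::inner_join,
                   right = dplyr::right_join)
  result <- with_name_errors(
    joinfn(materialize(view), other, by = by, relationship = "many-to-many")
  )
  if (anyNA(result$.cell)) {
    # rows with no backing cell cannot be container-backed
    warn_demotion(paste0(mode, "_join"), "rows without a backing cell were created")
    attr(result, "demotion") <- list(verb = paste0(mode, "_join"),
                                     rule = "rows without a backing cell were created")
    return(result)
  }
  dispatch_result(result, view, paste0(mode, "_join"))
}

expand_feature_rows <- function(m, old_ids, new_ids) {
  s <- Matrix::summary(m)
  Matrix::sparseMatrix(i = match(old_ids, new_ids)[s$i], j = s$j, x = s$x,
                       dims = c(length(new_ids), ncol(m)))
}

#' Concatenate two datasets cell-wise
#'
#' Combines two views (or containers) into one container-backed view. The
#' counts slot is combined over the union of features (zero-filling
#' features absent from one dataset) or their intersection. Cell metadata
#' columns are unioned with missing values set to `NA`. Reductions are kept
#' only when present in both datasets with identical dimension labels;
#' normalized `"data"` slots are dropped (normalization is not mergeable
#' across datasets) — both with a warning.
#'
#' @param a,b `TidyView`s or `CellContainer`s with disjoint cell ids.
#' @param feature_policy `"union"` (default, zero-fill) or `"intersect"`.
#' @param make_unique Append a dataset suffix to overlapping cell ids
#'   instead of raising a duplication error.
#' @return A `TidyView`.
#' @export
bind_cells <- function(a, b, feature_policy = c("union", "intersect"),
                       make_unique = FALSE) {
  feature_policy <- match.arg(feature_policy)
  ca <- if (inherits(a, "TidyView")) a$backend else a
  cb <- if (inherits(b, "TidyView")) b$backend else b
  overlap <- intersect(ca$cell_ids, cb$cell_ids)
  if (length(overlap)) {
    if (!make_unique) {
      err_duplication(sprintf("overlapping cell id(s): %s", paste(utils::head(overlap, 5), collapse = ", ")))
    }
    ca <- relabel_cells(ca, paste0(ca$cell_ids, "_1"))
    cb <- relabel_cells(cb, paste0(cb$cell_ids, "_2"))
  }
  common_assays <- intersect(names(ca$assays), names(cb$assays))
  dropped_assays <- setdiff(union(names(ca$assays), names(cb$assays)), common_assays)
  if (length(dropped_assays)) {
    warn_cellframe(sprintf("assay(s) %s present in only one dataset were dropped",
                           paste(dropped_assays, collapse = ", ")))
  }
  if (!length(common_assays)) err_name("no assay in common")
  cells <- c(ca$cell_ids, cb$cell_ids)
  assays <- list()
  for (an in common_assays) {
    fa <- ca$assays[[an]]$feature_ids
    fb <- cb$assays[[an]]$feature_ids
    feats <- if (feature_policy == "union") union(fa, fb) else intersect(fa, fb)
    if (any(c("data" %in% names(ca$assays[[an]]$slots), "data" %in% names(cb$assays[[an]]$slots)))) {
      warn_cellframe(sprintf("normalized 'data' slot of assay '%s' dropped on concatenation", an))
    }
    ma <- ca$assays[[an]]$slots$counts
    mb <- cb$assays[[an]]$slots$counts
    if (feature_policy == "intersect") {
      ma <- ma[match(feats, fa), , drop = FALSE]
      mb <- mb[match(feats, fb), , drop = FALSE]
      counts <- cbind(ma, mb)
    } else {
      counts <- cbind(expand_feature_rows(ma, fa, feats), expand_feature_rows(mb, fb, feats))
    }
    dimnames(counts) <- list(feats, cells)
    assays[[an]] <- structure(
      list(name = an, feature_ids = feats, slots = list(counts = as_sparse(counts))),
      class = "Assay"
    )
  }
  meta <- dplyr::bind_rows(ca$cell_meta, cb$cell_meta)
  reductions <- list()
  for (rn in intersect(names(ca$reductions), names(cb$reductions))) {
    ra <- ca$reductions[[rn]]; rb <- cb$reductions[[rn]]
    if (identical(ra$dim_labels, rb$dim_labels)) {
      emb <- rbind(ra$embedding, rb$embedding)
      rownames(emb) <- cells
      reductions[[rn]] <- list(embedding = emb, dim_labels = ra$dim_labels)
    }
  }
  dropped_red <- setdiff(union(names(ca$reductions), names(cb$reductions)), names(reductions))
  if (length(dropped_red)) {
    warn_cellframe(sprintf("reduction(s) %s not shared (or label mismatch) were dropped",
                           paste(dropped_red, collapse = ", ")))
  }
  active <- if (ca$active_assay %in% common_assays) ca$active_assay else common_assays[[1]]
  cc <- structure(list(
    cell_ids = cells, assays = assays, active_assay = active,
    cell_meta = meta,
    feature_meta = tibble::tibble(feature = assays[[active]]$feature_ids),
    reductions = reductions
  ), class = "CellContainer")
  as_tidy(cc)
}

relabel_cells <- function(cc, new_ids) {
  cc$cell_ids <- new_ids
  cc$assays <- lapply(cc$assays, function(a) {
    a$slots <- lapply(a$slots, function(m) { colnames(m) <- new_ids; m })
    a
  })
  cc$reductions <- lapply(cc$reductions, function(r) {
    rownames(r$embedding) <- new_ids
    r
  })
  cc
}

n_capture_groups <- function(pattern) {
  m <- gregexpr("\\((?!\\?)", pattern, perl = TRUE)[[1]]
  sum(m > 0)
}

#' @rdname verbs
#' @param col,into,sep,regex,remove String-manipulation arguments as in
#'   tidyr; targets must be editable metadata columns.
#' @export
separate.TidyView <- function(data, col, into, sep = "[^[:alnum:]]+",
                              remove = TRUE, ...) {
  col_nm <- as_name(enquo(col))
  if (!col_nm %in% visible_columns(data)) err_name(sprintf("unknown column '%s'", col_nm))
  if (col_nm %in% c(".cell", viewonly_columns(data))) {
    err_readonly("separate() targets editable metadata columns only")
  }
  result <- tidyr::separate(materialize(data), col = !!col_nm, into = into,
                            sep = sep, remove = remove, ...)
  dispatch_result(result, data, "separate")
}

#' @rdname verbs
#' @export
unite.TidyView <- function(data, col, ..., sep = "_", remove = TRUE, na.rm = FALSE) {
  srcs <- vapply(enquos(...), as_name, character(1))
  unknown <- setdiff(srcs, visible_columns(data))
  if (length(unknown)) err_name(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  bad <- intersect(srcs, c(".cell", viewonly_columns(data)))
  if (length(bad)) err_readonly("unite() targets editable metadata columns only")
  result <- tidyr::unite(materialize(data), col = {{ col }}, !!!syms(srcs),
                         sep = sep, remove = remove, na.rm = na.rm)
  dispatch_result(result, data, "unite")
}

#' @rdname verbs
#' @export
extract.TidyView <- function(data, col, into, regex = "([[:alnum:]]+)",
                             remove = TRUE, ...) {
  col_nm <- as_name(enquo(col))
  if (!col_nm %in% visible_columns(data)) err_name(sprintf("unknown column '%s'", col_nm))
  if (col_nm %in% c(".cell", viewonly_columns(data))) {
    err_readonly("extract() targets editable metadata columns only")
  }
  if (n_capture_groups(regex) < 1) err_pattern("`regex` must contain at least one capture group")
  result <- tidyr::extract(materialize(data), col = !!col_nm, into = into,
                           regex = regex, remove = remove, ...)
  dispatch_result(result, data, "extract")
}

#' @rdname verbs
#' @param cols,names_to,values_to Reshaping arguments as in tidyr.
#' @export
pivot_longer.TidyView <- function(data, cols, names_to = "name",
                                  values_to = "value", ...) {
  with_name_errors(
    tidyr::pivot_longer(materialize(data), cols = {{ cols }},
                        names_to = names_to, values_to = values_to, ...)
  )
}
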