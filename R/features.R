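#' Add transcript abundance to the cell table
#'
#' Transcript information is absent from the tidy view by default and added
#' on request. With `shape = "wide"` one editable column per feature is
#' added (values taken from the chosen assay slot) and the result stays
#' container-backed — no cell duplication occurs. With `shape = "long"` the
#' result is a plain tibble with one row per cell x feature, holding the
#' existing visible columns plus `.feature`, `.abundance` and `.assay`.
#'
#' @param view A `TidyView`.
#' @param features Character vector of feature ids (all must exist in the
#'   assay; the error lists any missing ids).
#' @param shape `"wide"` or `"long"`.
#' @param assay Assay name; default the active assay.
#' @param slot Slot name; defaults to `"data"` when present, else `"counts"`.
#' @return A `TidyView` (wide) or a tibble (long).
#' @export
join_features <- function(view, features, shape = c("wide", "long"),
                          assay = NULL, slot = NULL) {
  stopifnot(inherits(view, "TidyView"))
  shape <- match.arg(shape)
  cc <- view$backend
  a <- get_assay(cc, assay)
  if (is.null(slot)) slot <- if ("data" %in% names(a$slots)) "data" else "counts"
  if (!slot %in% names(a$slots)) err_name(sprintf("assay '%s' has no slot '%s'", a$name, slot))
  missing <- setdiff(features, a$feature_ids)
  if (length(missing)) {
    err_feature(sprintf("feature(s) not found: %s", paste(missing, collapse = ", ")),
                missing = missing)
  }
  m <- a$slots[[slot]][match(features, a$feature_ids), , drop = FALSE]
  if (shape == "wide") {
    clash <- intersect(features, all_columns(view))
    if (length(clash)) {
      err_collision(sprintf("feature column(s) collide with existing columns: %s",
                            paste(clash, collapse = ", ")))
    }
    for (k in seq_along(features)) {
      cc <- set_cell_meta_column(cc, features[[k]], as.numeric(m[k, ]))
    }
    view$backend <- cc
    view$col_order <- c(view$col_order, features)
    return(view)
  }
  tbl <- materialize(view)
  k <- length(features)
  idx <- rep(seq_len(nrow(tbl)), each = k)
  long <- tbl[idx, , drop = FALSE]
  long$.feature <- rep(features, times = nrow(tbl))
  long$.abundance <- as.numeric(as.matrix(m))  # column-major: features fastest
  long$.assay <- a$name
  tibble::as_tibble(long)
}

#' Nest the cells into per-group sub-containers
#'
#' Splits the view into one sub-container per observed combination of the
#' `by` columns (first-occurrence order), carrying full assays and
#' reductions. The result is a `NestedTable`: the group key columns plus a
#' `data` list-column of `CellContainer`s. `NA` group keys form their own
#' group. Per-group results computed with [map_nested()] become additional
#' columns; [unnest_cells()] reassembles the cells.
#'
#' @param view A `TidyView`.
#' @param by Character vector of editable column names (non-empty).
#' @return A `NestedTable`.
#' @export
nest_cells <- function(view, by) {
  stopifnot(inherits(view, "TidyView"))
  if (length(by) == 0) err_group_key("`by` must name at least one column")
  unknown <- setdiff(by, visible_columns(view))
  if (length(unknown)) err_name(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  bad <- intersect(by, c(".cell", viewonly_columns(view)))
  if (length(bad)) err_group_key("nesting keys must be editable metadata columns")
  tbl <- materialize(view)
  key <- do.call(paste, c(lapply(tbl[by], function(x) ifelse(is.na(x), "\r<NA>", as.character(x))),
                          sep = "\r"))
  first <- !duplicated(key)
  keys <- tbl[first, by, drop = FALSE]
  containers <- lapply(key[first], function(k) {
    subset_cells(view$backend, tbl$.cell[key == k])
  })
  out <- keys
  out$data <- containers
  structure(out, class = c("NestedTable", class(tibble::as_tibble(keys))),
            group_columns = by)
}

#' @export
print.NestedTable <- function(x, ...) {
  cat(sprintf("# A nested cell table: %d group(s) × %d column(s)\n", nrow(x), ncol(x)))
  show <- as.data.frame(x[setdiff(names(x), "data")])
  show$data <- vapply(x$data, function(cc) sprintf("<CellContainer: %d cells>", n_cells(cc)), character(1))
  print(show)
  invisible(x)
}

#' Apply a function to each nested sub-container
#'
#' @param nested A `NestedTable`.
#' @param fn Function taking a `CellContainer`.
#' @param out_column Name of the result column. Scalar results are
#'   simplified to an atomic column; anything else becomes a list-column.
#' @return The `NestedTable` with the new column, group order preserved.
#' @export
map_nested <- function(nested, fn, out_column) {
  stopifnot(inherits(nested, "NestedTable"))
  by <- attr(nested, "group_columns")
  res <- vector("list", nrow(nested))
  for (i in seq_len(nrow(nested))) {
    res[[i]] <- withCallingHandlers(
      tryCatch(fn(nested$data[[i]]), error = function(e) {
        key <- paste(sprintf("%s=%s", by, as.character(nested[i, by, drop = TRUE])), collapse = ", ")
        rlang::abort(sprintf("map_nested failed for group (%s): %s", key, conditionMessage(e)),
                     class = "cellframe_map_error", parent = e)
      })
    )
  }
  scalar <- all(vapply(res, function(r) is.atomic(r) && length(r) == 1L, logical(1)))
  nested[[out_column]] <- if (scalar) unlist(res, use.names = FALSE) else res
  nested
}

#' Reassemble nested groups into one view
#'
#' Concatenates the nested containers (union feature policy) and broadcasts
#' the group key columns back as editable metadata. The inverse of
#' [nest_cells()] up to row order.
#'
#' @param nested A `NestedTable`.
#' @return A `TidyView`.
#' @export
unnest_cells <- function(nested) {
  stopifnot(inherits(nested, "NestedTable"))
  by <- attr(nested, "group_columns")
  containers <- nested$data
  ids <- unlist(lapply(containers, cell_ids), use.names = FALSE)
  if (anyDuplicated(ids)) err_duplication("nested groups share cell ids")
  for (i in seq_along(containers)) {
    for (col in by) {
      containers[[i]] <- set_cell_meta_column(
        containers[[i]], col,
        rep(nested[[col]][[i]], n_cells(containers[[i]]))
      )
    }
  }
  view <- as_tidy(containers[[1]])
  for (i in seq_along(containers)[-1]) {
    view <- bind_cells(view, containers[[i]], feature_policy = "union")
  }
  view
}
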