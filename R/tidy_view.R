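#' Tidy view over a cell container
#'
#' `as_tidy()` wraps a [CellContainer][new_container] in a one-row-per-cell
#' tabular abstraction. The first column is always the key column `.cell`
#' (the cell identifier); cell-metadata columns are editable; reduction
#' dimension columns are view only. Transcript abundance is absent by
#' default and added on request with [join_features()].
#'
#' @param container A `CellContainer`.
#' @return A `TidyView`.
#' @export
as_tidy <- function(container) {
  stopifnot(inherits(container, "CellContainer"))
  new_view(container,
           col_order = c(".cell", names(container$cell_meta), reduction_labels(container)))
}

new_view <- function(backend, col_order, groups = character()) {
  stopifnot(".cell" %in% col_order)
  v <- list(backend = backend, col_order = col_order, groups = groups)
  class(v) <- "TidyView"
  v
}

#' @rdname as_tidy
#' @param view A `TidyView`.
#' @export
backend <- function(view) {
  stopifnot(inherits(view, "TidyView"))
  view$backend
}

#' @export
group_vars.TidyView <- function(x) x$groups

all_columns <- function(view) {
  c(".cell", names(view$backend$cell_meta), reduction_labels(view$backend))
}

visible_columns <- function(view) view$col_order

viewonly_columns <- function(view) reduction_labels(view$backend)

#' Realize the visible table
#'
#' Returns the fully materialized tibble behind a view: `.cell`, then the
#' visible metadata and reduction columns, values bit-equal to the backend.
#'
#' @param view A `TidyView`.
#' @return A tibble (plain table, no backend).
#' @export
materialize <- function(view) {
  cc <- view$backend
  red <- reduction_column_values(cc)
  cols <- lapply(view$col_order, function(nm) {
    if (nm == ".cell") cc$cell_ids
    else if (nm %in% names(cc$cell_meta)) cc$cell_meta[[nm]]
    else red[[nm]]
  })
  names(cols) <- view$col_order
  tibble::as_tibble(cols)
}

reduction_column_values <- function(cc) {
  out <- list()
  for (r in cc$reductions) {
    for (j in seq_along(r$dim_labels)) {
      out[[r$dim_labels[[j]]]] <- unname(r$embedding[, j])
    }
  }
  out
}

#' Classify a visible column
#'
#' `.cell` is the key column; reduction dimensions are view only; every
#' cell-metadata column is editable.
#'
#' @param view A `TidyView`.
#' @param name A visible column name.
#' @return One of `"key"`, `"editable"`, `"view_only"`.
#' @export
classify_column <- function(view, name) {
  if (!name %in% visible_columns(view)) {
    err_name(sprintf("unknown column '%s'", name))
  }
  if (name == ".cell") return("key")
  if (name %in% viewonly_columns(view)) return("view_only")
  "editable"
}

#' Display header lines
#'
#' Two text lines summarizing the abstraction, in the format
#' `# A <flavor>-table abstraction: <cells> x <visible columns>` and
#' `# Features = <n> | Active assay=<name> | Assays=<comma list>`.
#'
#' @param view A `TidyView`.
#' @param flavor Flavor string for the first line; package-wide default via
#'   `options(cellframe.flavor = ...)`.
#' @return Character vector of two lines.
#' @export
display_header <- function(view, flavor = getOption("cellframe.flavor", "Cell")) {
  cc <- view$backend
  c(
    sprintf("# A %s-table abstraction: %d × %d",
            flavor, n_cells(cc), length(visible_columns(view))),
    sprintf("# Features = %d | Active assay=%s | Assays=%s",
            n_features(cc), cc$active_assay,
            paste(names(cc$assays), collapse = ", "))
  )
}

#' Hide columns from the display
#'
#' Hiding is a display concern: the backing metadata or reduction is kept.
#' The key column `.cell` cannot be hidden.
#'
#' @param view A `TidyView`.
#' @param columns Character vector of visible column names.
#' @return A `TidyView`.
#' @export
hide_columns <- function(view, columns) {
  unknown <- setdiff(columns, visible_columns(view))
  if (length(unknown)) err_name(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  if (".cell" %in% columns) err_reserved("the key column '.cell' cannot be hidden")
  view$col_order <- setdiff(view$col_order, columns)
  view$groups <- intersect(view$groups, view$col_order)
  view
}

#' Decide the return kind of a verb result
#'
#' A tabular verb result is promoted back to a container-backed `TidyView`
#' iff (i) the key column `.cell` is present, (ii) its values are a
#' duplicate-free subset of the origin's cell ids, and (iii) no view-only
#' column was altered. Otherwise the result is returned unchanged as a
#' plain tibble and a structured demotion warning is emitted. Demotion is a
#' value, never an error.
#'
#' @param result A tibble produced by a verb applied to the materialized view.
#' @param origin The origin `TidyView` (or `CellContainer`).
#' @param verb Verb name used in the demotion warning.
#' @return A `TidyView` or a plain tibble.
#' @export
dispatch <- function(result, origin, verb = "dispatch") {
  if (inherits(origin, "CellContainer")) origin <- as_tidy(origin)
  dispatch_result(tibble::as_tibble(result), origin, verb)
}

dispatch_result <- function(result, view, verb) {
  cc <- view$backend
  demote <- function(rule) {
    warn_demotion(verb, rule)
    attr(result, "demotion") <- list(verb = verb, rule = rule)
    result
  }
  if (!".cell" %in% names(result)) {
    return(demote("the key column '.cell' was excluded, modified or renamed"))
  }
  cells <- result$.cell
  if (anyDuplicated(cells)) {
    return(demote("the operation leads to cell duplication"))
  }
  if (!all(cells %in% cc$cell_ids)) {
    return(demote("the key column '.cell' was excluded, modified or renamed"))
  }
  ro <- intersect(names(result), viewonly_columns(view))
  if (length(ro)) {
    idx <- match(cells, cc$cell_ids)
    red <- reduction_column_values(cc)
    for (nm in ro) {
      if (!identical(unname(as.vector(result[[nm]])), unname(red[[nm]][idx]))) {
        return(demote(sprintf("view-only column '%s' was altered", nm)))
      }
    }
  }
  new_cc <- subset_cells(cc, as.character(cells))
  editable <- setdiff(names(result), c(".cell", viewonly_columns(view)))
  for (nm in editable) new_cc$cell_meta[[nm]] <- result[[nm]]
  new_view(new_cc,
           col_order = names(result),
           groups = intersect(view$groups, names(result)))
}

#' @export
print.TidyView <- function(x, n = 10, ...) {
  writeLines(display_header(x))
  tbl <- materialize(x)
  cls <- vapply(visible_columns(x), function(nm) classify_column(x, nm), character(1))
  tag <- c(key = "<key>", editable = "<edit>", view_only = "<view>")[cls]
  writeLines(paste0("# ", paste(sprintf("%s%s", visible_columns(x), tag), collapse = " | ")))
  if (length(x$groups)) writeLines(paste0("# Groups: ", paste(x$groups, collapse = ", ")))
  print(utils::head(tbl, n))
  invisible(x)
}
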