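#' @importFrom methods as is
#' @importFrom stats var setNames rnbinom rgamma rlnorm
NULL

as_sparse <- function(m) {
  if (is(m, "CsparseMatrix") && is(m, "generalMatrix") && is(m, "dMatrix")) return(m)
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Create a single-cell expression container
#'
#' The container is the hierarchical, machine-facing side of the package:
#' sparse assay matrices stored features x cells (matching 10x triplet
#' files), a per-cell metadata table, a per-feature metadata table, and
#' named low-dimensional embeddings ("reductions"). The human-facing side
#' is the tidy view created by [as_tidy()].
#'
#' @param counts Sparse (or dense) matrix of non-negative integer counts,
#'   features in rows, cells in columns.
#' @param feature_ids Character vector of unique feature identifiers, one
#'   per row of `counts`.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column of `counts`.
#' @param cell_meta Optional data frame of per-cell annotations, one row per
#'   cell in `cell_ids` order.
#' @param assay_name Name of the created assay (default `"RNA"`).
#' @return A `CellContainer`.
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(2, 5), dims = c(3, 2))
#' cc <- new_container(m, c("g1", "g2", "g3"), c("c1", "c2"))
#' n_cells(cc)
#' @export
new_container <- function(counts, feature_ids, cell_ids, cell_meta = NULL,
                          assay_name = "RNA") {
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(feature_ids)) err_identifier("duplicate feature ids")
  if (anyDuplicated(cell_ids)) err_identifier("duplicate cell ids")
  counts <- as_sparse(counts)
  if (nrow(counts) != length(feature_ids) || ncol(counts) != length(cell_ids)) {
    err_shape(sprintf(
      "counts is %d x %d but %d feature ids and %d cell ids were given",
      nrow(counts), ncol(counts), length(feature_ids), length(cell_ids)
    ))
  }
  check_counts_slot(counts)
  dimnames(counts) <- list(feature_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(.rows = length(cell_ids))
  } else {
    cell_meta <- tibble::as_tibble(cell_meta)
    if (nrow(cell_meta) != length(cell_ids)) {
      err_shape("cell_meta must have one row per cell")
    }
    if (".cell" %in% names(cell_meta)) err_reserved("'.cell' is a reserved column name")
  }
  assay <- list(name = assay_name, feature_ids = feature_ids,
                slots = list(counts = counts))
  class(assay) <- "Assay"
  cc <- list(
    cell_ids = cell_ids,
    assays = setNames(list(assay), assay_name),
    active_assay = assay_name,
    cell_meta = cell_meta,
    feature_meta = tibble::tibble(feature = feature_ids),
    reductions = list()
  )
  class(cc) <- "CellContainer"
  cc
}

check_counts_slot <- function(m) {
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != trunc(x)))) {
    err_shape("counts slot must hold non-negative integers")
  }
  invisible(TRUE)
}

#' Container dimensions and accessors
#'
#' @param container A `CellContainer`.
#' @return `n_cells()` / `n_features()` return integers; `cell_ids()` the
#'   cell identifiers; `get_slot()` a sparse features x cells matrix.
#' @export
n_cells <- function(container) length(container$cell_ids)

#' @rdname n_cells
#' @param assay Assay name; default the active assay.
#' @export
n_features <- function(container, assay = NULL) {
  length(get_assay(container, assay)$feature_ids)
}

#' @rdname n_cells
#' @export
cell_ids <- function(container) container$cell_ids

get_assay <- function(container, assay = NULL) {
  assay <- assay %||% container$active_assay
  if (!assay %in% names(container$assays)) {
    err_name(sprintf("unknown assay '%s'", assay))
  }
  container$assays[[assay]]
}

#' @rdname n_cells
#' @param slot Slot name, `"counts"` or `"data"`.
#' @export
get_slot <- function(container, assay = NULL, slot = "counts") {
  a <- get_assay(container, assay)
  if (!slot %in% names(a$slots)) {
    err_name(sprintf("assay '%s' has no slot '%s'", a$name, slot))
  }
  a$slots[[slot]]
}

set_slot <- function(container, slot, value, assay = NULL) {
  assay <- assay %||% container$active_assay
  a <- get_assay(container, assay)
  if (!slot %in% c("counts", "data")) err_name("slot must be 'counts' or 'data'")
  stopifnot(nrow(value) == length(a$feature_ids), ncol(value) == n_cells(container))
  container$assays[[assay]]$slots[[slot]] <- value
  container
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a container to a set of cells
#'
#' Every assay slot, metadata row and reduction row is restricted to `keep`,
#' in `keep` order. The feature space is unchanged. Duplication is forbidden
#' at container level: a duplicated id in `keep` is an error, mirroring the
#' rule that duplicated cells only exist in demoted plain tables.
#'
#' @param container A `CellContainer`.
#' @param keep Character vector of cell ids to retain, in the desired order.
#' @return A `CellContainer` over the `keep` cells.
#' @export
subset_cells <- function(container, keep) {
  keep <- as.character(keep)
  if (anyDuplicated(keep)) err_duplication("duplicated cell id in `keep`")
  idx <- match(keep, container$cell_ids)
  if (anyNA(idx)) {
    err_identifier(sprintf(
      "unknown cell id(s): %s", paste(keep[is.na(idx)], collapse = ", ")
    ))
  }
  container$cell_ids <- keep
  container$assays <- lapply(container$assays, function(a) {
    a$slots <- lapply(a$slots, function(m) m[, idx, drop = FALSE])
    a
  })
  container$cell_meta <- container$cell_meta[idx, , drop = FALSE]
  container$reductions <- lapply(container$reductions, function(r) {
    r$embedding <- r$embedding[idx, , drop = FALSE]
    r
  })
  container
}

#' Write or overwrite a cell-metadata column
#'
#' @param container A `CellContainer`.
#' @param name Column name; `".cell"` and reduction dimension labels are
#'   reserved.
#' @param values Vector of length `n_cells(container)`.
#' @return The updated container (value semantics; the input is untouched).
#' @export
set_cell_meta_column <- function(container, name, values) {
  if (identical(name, ".cell")) err_reserved("'.cell' is the reserved key column")
  if (name %in% reduction_labels(container)) {
    err_reserved(sprintf("'%s' is a view-only reduction column", name))
  }
  if (length(values) != n_cells(container)) {
    err_shape(sprintf("%d values for %d cells", length(values), n_cells(container)))
  }
  container$cell_meta[[name]] <- values
  container
}

#' Add an assay to a container
#'
#' @param container A `CellContainer`.
#' @param name New assay name.
#' @param counts Sparse matrix of non-negative integers, features x cells.
#' @param feature_ids Feature ids for the new assay (default: row names of
#'   `counts`, else the active assay's ids when dimensions match).
#' @param set_active Make the new assay the active one.
#' @return The updated container.
#' @export
add_assay <- function(container, name, counts, feature_ids = NULL,
                      set_active = FALSE) {
  if (name %in% names(container$assays)) {
    err_collision(sprintf("assay '%s' already exists", name))
  }
  counts <- as_sparse(counts)
  if (is.null(feature_ids)) {
    feature_ids <- rownames(counts) %||%
      (if (nrow(counts) == n_features(container)) get_assay(container)$feature_ids
       else err_identifier("feature_ids required"))
  }
  if (anyDuplicated(feature_ids)) err_identifier("duplicate feature ids")
  if (nrow(counts) != length(feature_ids) || ncol(counts) != n_cells(container)) {
    err_shape("counts must be length(feature_ids) x n_cells")
  }
  check_counts_slot(counts)
  dimnames(counts) <- list(feature_ids, container$cell_ids)
  container$assays[[name]] <- structure(
    list(name = name, feature_ids = as.character(feature_ids),
         slots = list(counts = counts)),
    class = "Assay"
  )
  if (set_active) container$active_assay <- name
  container
}

reduction_labels <- function(container) {
  unlist(lapply(container$reductions, function(r) r$dim_labels), use.names = FALSE) %||% character()
}

#' Attach a dimensionality reduction
#'
#' Reductions (cells x dims matrices such as PCA or UMAP coordinates) are
#' exposed in the tidy view as view-only columns. Default dimension labels
#' are the upper-cased reduction name plus a 1-based index, with an optional
#' separator (`"PC1"` by default, `"PC_1"` with `sep = "_"`).
#'
#' @param container A `CellContainer`.
#' @param name Reduction name (e.g. `"pc"`, `"umap"`).
#' @param embedding Numeric matrix, cells x dims, rows in cell order.
#' @param dim_labels Optional character vector of dimension labels.
#' @param sep Separator between label stem and index when `dim_labels` is
#'   defaulted; set the package-wide default with
#'   `options(cellframe.label_sep = "_")`.
#' @return The updated container.
#' @export
add_reduction <- function(container, name, embedding, dim_labels = NULL,
                          sep = getOption("cellframe.label_sep", "")) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != n_cells(container)) {
    err_shape(sprintf("embedding has %d rows for %d cells", nrow(embedding), n_cells(container)))
  }
  d <- ncol(embedding)
  if (is.null(dim_labels)) {
    dim_labels <- paste0(toupper(name), sep, seq_len(d))
  }
  if (length(dim_labels) != d) err_shape("one label per embedding dimension required")
  if (anyDuplicated(dim_labels)) err_identifier("duplicate dimension labels")
  clash <- intersect(dim_labels, c(names(container$cell_meta), reduction_labels(container)))
  if (length(clash)) {
    err_collision(sprintf("label(s) %s collide with existing columns", paste(clash, collapse = ", ")))
  }
  dimnames(embedding) <- list(container$cell_ids, dim_labels)
  container$reductions[[name]] <- list(embedding = embedding, dim_labels = dim_labels)
  container
}

#' @export
print.CellContainer <- function(x, ...) {
  cat(sprintf(
    "CellContainer: %d features x %d cells | assays: %s (active: %s) | reductions: %s\n",
    n_features(x), n_cells(x), paste(names(x$assays), collapse = ", "),
    x$active_assay,
    if (length(x$reductions)) paste(names(x$reductions), collapse = ", ") else "none"
  ))
  invisible(x)
}
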