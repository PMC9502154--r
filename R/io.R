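#' Read a 10x-style triplet directory
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate, features x cells,
#' integer counts), `features.tsv` (id, optionally name and type) and
#' `barcodes.tsv` (one cell id per line). An optional `cell_meta.csv`
#' (first column `.cell` or matching the barcodes) and CSV files under
#' `reductions/` are attached when present.
#'
#' @param path Directory path.
#' @return A `CellContainer`.
#' @export
read_mtx_dir <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  feats <- file.path(path, "features.tsv")
  bcs <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feats, bcs)) {
    if (!file.exists(f)) err_format(sprintf("missing file: %s", f))
  }
  m <- tryCatch(Matrix::readMM(mtx), error = function(e) err_format(conditionMessage(e)))
  m <- as_sparse(m)
  if (length(m@x) && any(m@x != trunc(m@x))) err_format("matrix.mtx holds non-integer values")
  feature_tab <- utils::read.delim(feats, header = FALSE, sep = "\t",
                                   colClasses = "character")
  barcodes <- readLines(bcs)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(feature_tab) != nrow(m)) {
    err_format(sprintf("matrix has %d rows but features.tsv has %d lines",
                       nrow(m), nrow(feature_tab)))
  }
  if (length(barcodes) != ncol(m)) {
    err_format(sprintf("matrix has %d columns but barcodes.tsv has %d lines",
                       ncol(m), length(barcodes)))
  }
  meta <- NULL
  meta_path <- file.path(path, "cell_meta.csv")
  if (file.exists(meta_path)) {
    tab <- read_table_csv(meta_path)
    key <- if (".cell" %in% names(tab)) ".cell" else names(tab)[[1]]
    idx <- match(barcodes, tab[[key]])
    if (anyNA(idx)) err_format("cell_meta.csv does not cover all barcodes")
    meta <- tab[idx, setdiff(names(tab), key), drop = FALSE]
  }
  cc <- new_container(m, feature_tab[[1]], barcodes, cell_meta = meta)
  if (ncol(feature_tab) >= 2) cc$feature_meta$name <- feature_tab[[2]]
  red_dir <- file.path(path, "reductions")
  if (dir.exists(red_dir)) {
    for (f in sort(list.files(red_dir, pattern = "\\.csv$", full.names = TRUE))) {
      tab <- read_table_csv(f)
      key <- if (".cell" %in% names(tab)) ".cell" else names(tab)[[1]]
      idx <- match(barcodes, tab[[key]])
      if (anyNA(idx)) err_format(sprintf("%s does not cover all barcodes", f))
      emb <- as.matrix(tab[idx, setdiff(names(tab), key), drop = FALSE])
      cc <- add_reduction(cc, sub("\\.csv$", "", basename(f)), emb,
                          dim_labels = colnames(emb))
    }
  }
  cc
}

#' Write a container as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (header
#' `%%MatrixMarket matrix coordinate integer general`, entries sorted
#' column-major), `features.tsv`, `barcodes.tsv`, `cell_meta.csv` (first
#' column `.cell`) when metadata exists, and one CSV per reduction under
#' `reductions/`.
#'
#' @param container A `CellContainer` (or `TidyView`).
#' @param path Output directory.
#' @param overwrite Overwrite a non-empty existing directory.
#' @export
write_mtx_dir <- function(container, path, overwrite = FALSE) {
  if (inherits(container, "TidyView")) container <- container$backend
  if (dir.exists(path) && length(list.files(path)) && !overwrite) {
    err_file_exists(sprintf("'%s' exists and overwrite = FALSE", path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- get_slot(container, slot = "counts")
  s <- Matrix::summary(m)  # dgCMatrix triplets come out column-major sorted
  con <- file(file.path(path, "matrix.mtx"), "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(s)), con)
  if (nrow(s)) {
    writeLines(sprintf("%d %d %d", s$i, s$j, as.integer(s$x)), con)
  }
  close(con)
  a <- get_assay(container)
  feat <- container$feature_meta
  feat_lines <- if ("name" %in% names(feat)) {
    paste(a$feature_ids, feat$name[match(a$feature_ids, feat$feature)], sep = "\t")
  } else {
    paste(a$feature_ids, a$feature_ids, sep = "\t")
  }
  writeLines(feat_lines, file.path(path, "features.tsv"))
  writeLines(container$cell_ids, file.path(path, "barcodes.tsv"))
  if (ncol(container$cell_meta)) {
    meta <- dplyr::bind_cols(tibble::tibble(.cell = container$cell_ids),
                             container$cell_meta)
    write_table_csv(meta, file.path(path, "cell_meta.csv"))
  }
  if (length(container$reductions)) {
    dir.create(file.path(path, "reductions"), showWarnings = FALSE)
    for (rn in names(container$reductions)) {
      r <- container$reductions[[rn]]
      tab <- tibble::as_tibble(r$embedding)
      names(tab) <- r$dim_labels
      tab <- dplyr::bind_cols(tibble::tibble(.cell = container$cell_ids), tab)
      write_table_csv(tab, file.path(path, "reductions", paste0(rn, ".csv")))
    }
  }
  invisible(path)
}

#' Read / write a plain CSV table
#'
#' RFC-4180-style CSV with a header row. Empty fields are `NA` (the null
#' encoding); text, numeric and logical columns round-trip losslessly.
#' Ragged rows are a format error.
#'
#' @param path File path.
#' @return `read_table_csv()` returns a tibble.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) err_format(sprintf("no such file: %s", path))
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1) err_format(sprintf("ragged rows in %s", path))
  tab <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                         stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' @rdname read_table_csv
#' @param table A data frame.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}
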