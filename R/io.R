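tsv_write <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
}

tsv_read <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Write a cell dataset as MatrixMarket counts plus TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells sparse counts), `genes.tsv`,
#' `cells.tsv` (with donor, site, and mitochondrial-fraction columns), and
#' `truth.tsv` (`cell_id`, `true_cluster`, `true_time`) when ground truth is
#' present.
#'
#' @param data A `cell_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(data$counts, file.path(dir, "matrix.mtx"))
  tsv_write(data$gene_meta, file.path(dir, "genes.tsv"))
  cell_cols <- intersect(c("cell_id", "donor", "site", "mito_fraction"),
                         names(data$cell_meta))
  tsv_write(data$cell_meta[cell_cols], file.path(dir, "cells.tsv"))
  if (all(c("true_cluster", "true_time") %in% names(data$cell_meta))) {
    tsv_write(data$cell_meta[c("cell_id", "true_cluster", "true_time")],
              file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' Read a cell dataset written by [write_cell_dataset()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`, and
#'   optionally `truth.tsv`.
#' @return A `cell_dataset`.
#' @export
read_cell_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- tsv_read(file.path(dir, "genes.tsv"))
  cells <- tsv_read(file.path(dir, "cells.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    truth <- tsv_read(truth_path,
                      col_types = readr::cols(true_cluster = readr::col_character()))
    cells <- left_join(cells, truth, by = "cell_id")
  }
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  new_cell_dataset(counts, gene_meta = genes, cell_meta = cells)
}

#' Write / read a bulk reference matrix as TSV
#'
#' One row per sample: `sample_id`, `subtype`, then one column per gene.
#'
#' @param reference A `reference_matrix`.
#' @param path TSV path.
#' @return `path` invisibly ([write_reference_matrix()]); a
#'   `reference_matrix` ([read_reference_matrix()]).
#' @export
write_reference_matrix <- function(reference, path) {
  df <- dplyr::bind_cols(
    tibble(sample_id = reference$sample_ids, subtype = reference$subtype),
    as_tibble(as.data.frame(reference$expr)))
  tsv_write(df, path)
  invisible(path)
}

#' @rdname write_reference_matrix
#' @export
read_reference_matrix <- function(path) {
  df <- tsv_read(path)
  expr <- as.matrix(df[, setdiff(names(df), c("sample_id", "subtype"))])
  rownames(expr) <- df$sample_id
  new_reference_matrix(expr, df$subtype)
}

#' Signature I/O: two-column TSV and GMT gene-set files
#'
#' Signatures round-trip through a two-column TSV (`gene_id`, `weight`).
#' GMT files carry one gene set per line (`name`, description, genes);
#' [read_gmt()] returns a named list of gene vectors, from which paired
#' `<name>_up` / `<name>_down` sets can be turned into +/-1 signatures with
#' [signature_from_genelist()].
#'
#' @param signature A `signature`.
#' @param path File path.
#' @param name Signature name on reading.
#' @return See details.
#' @export
write_signature <- function(signature, path) {
  tsv_write(tibble(gene_id = names(signature$weights),
                   weight = unname(signature$weights)), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, name = basename(path)) {
  df <- tsv_read(path)
  new_signature(setNames(df$weight, df$gene_id), name)
}

#' @rdname write_signature
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname write_signature
#' @param sets Named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
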