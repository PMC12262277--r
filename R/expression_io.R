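#' Microregion expression matrices
#'
#' Container for digital-spatial-profiling counts: a microregions x genes
#' matrix of non-negative values plus per-microregion metadata (specimen,
#' local progression stage, segment, batch). Rows of `values` are named by
#' microregion id and columns by gene id.
#'
#' @param values numeric MR x gene matrix, rownames = microregion ids.
#' @param metadata data.frame with columns `mr_id`, `specimen_id`, `stage`,
#'   `segment`; optional `batch`.
#' @param gene_ids optional character vector overriding `colnames(values)`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata, gene_ids = colnames(values)) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression_matrix: negative values", call. = FALSE)
  }
  req <- c("mr_id", "specimen_id", "stage", "segment")
  missing <- setdiff(req, names(metadata))
  if (length(missing) > 0) {
    stop("expression_matrix: metadata missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(metadata$stage) || anyNA(metadata$specimen_id)) {
    stop("expression_matrix: stage and specimen_id metadata must be complete",
         call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- as.character(metadata$mr_id)
  if (nrow(values) != nrow(metadata)) {
    stop("expression_matrix: values/metadata dimension mismatch", call. = FALSE)
  }
  unmatched <- setdiff(rownames(values), metadata$mr_id)
  if (length(unmatched) > 0) {
    stop("expression_matrix: microregion id(s) without metadata: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  metadata <- metadata[match(rownames(values), metadata$mr_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.null(gene_ids)) colnames(values) <- gene_ids
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("gene%04d", seq_len(ncol(values)))
  }
  structure(list(values = values, metadata = metadata,
                 gene_ids = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d microregions x %d genes, %d specimens>\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$metadata$specimen_id))))
  invisible(x)
}

#' Read a microregion expression matrix
#'
#' Counts may be a dense CSV (rows = microregions, first column or rownames =
#' microregion id) or a MatrixMarket `.mtx` file accompanied by
#' `<stem>_rows.txt` (microregion ids) and `<stem>_cols.txt` (gene ids).
#' Metadata is a TSV keyed by `mr_id`; every counts row must have a metadata
#' row.
#'
#' @param counts_path path to CSV or MTX counts.
#' @param metadata_path path to the metadata TSV.
#' @return an [expression_matrix].
#' @export
read_expression_matrix <- function(counts_path, metadata_path) {
  for (p in c(counts_path, metadata_path)) {
    if (!file.exists(p)) stop("read_expression_matrix: file not found: ", p, call. = FALSE)
  }
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    stem <- sub("\\.mtx$", "", counts_path)
    rownames(m) <- readLines(paste0(stem, "_rows.txt"))
    colnames(m) <- readLines(paste0(stem, "_cols.txt"))
  } else {
    raw <- utils::read.csv(counts_path, check.names = FALSE)
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
  }
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  missing_md <- setdiff(rownames(m), md$mr_id)
  if (length(missing_md) > 0) {
    stop("read_expression_matrix: counts rows without metadata: ",
         paste(missing_md, collapse = ", "), call. = FALSE)
  }
  expression_matrix(m, md[match(rownames(m), md$mr_id), , drop = FALSE])
}

#' Write an expression matrix
#'
#' Writes counts (CSV or MTX with `_rows.txt`/`_cols.txt` sidecars, chosen by
#' the `counts_path` extension) and the metadata TSV.
#'
#' @param em an [expression_matrix].
#' @param counts_path output counts path (`.csv` or `.mtx`).
#' @param metadata_path output metadata TSV path.
#' @return `counts_path`, invisibly.
#' @export
write_expression_matrix <- function(em, counts_path, metadata_path) {
  if (grepl("\\.mtx$", counts_path)) {
    Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), counts_path)
    stem <- sub("\\.mtx$", "", counts_path)
    writeLines(rownames(em$values), paste0(stem, "_rows.txt"))
    writeLines(colnames(em$values), paste0(stem, "_cols.txt"))
  } else {
    out <- data.frame(mr_id = rownames(em$values), em$values,
                      check.names = FALSE)
    utils::write.csv(out, counts_path, row.names = FALSE)
  }
  utils::write.table(em$metadata, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}
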