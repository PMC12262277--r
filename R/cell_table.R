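#' Single-cell feature tables
#'
#' A `cell_table` is a plain `data.frame` carrying one row per segmented cell:
#' an integer `cell_id` (unique within `specimen_id`), micron-scale centroid
#' coordinates `x` and `y`, one numeric column of raw mean intensity per
#' marker, and optional derived columns — rescaled intensities (suffix
#' `_scaled`, values in \[0, 1\]), a `phenotype` label, a `tumor_state` label,
#' and a `region_id`. All spatial statistics in the package consume this
#' container.
#'
#' @param df data.frame with at least `cell_id`, `specimen_id`, `x`, `y` and
#'   one marker column.
#' @return `df` validated and classed as `cell_table`.
#' @export
cell_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df)
  required <- c("cell_id", "specimen_id", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cell_table: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("cell_table: non-finite coordinates", call. = FALSE)
  }
  if (anyDuplicated(df[, c("specimen_id", "cell_id")])) {
    stop("cell_table: cell_id not unique within specimen_id", call. = FALSE)
  }
  markers <- cell_markers(df)
  if (length(markers) == 0) {
    stop("cell_table: no marker intensity column found", call. = FALSE)
  }
  for (m in markers) {
    v <- df[[m]]
    if (!is.numeric(v)) stop("cell_table: non-numeric intensity column ", m, call. = FALSE)
    if (any(v < 0, na.rm = TRUE)) stop("cell_table: negative raw intensity in ", m, call. = FALSE)
  }
  scaled <- grep("_scaled$", names(df), value = TRUE)
  for (s in scaled) {
    v <- df[[s]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
      stop("cell_table: rescaled intensities outside [0,1] in ", s, call. = FALSE)
    }
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

reserved_cell_columns <- c("cell_id", "specimen_id", "x", "y", "phenotype",
                           "tumor_state", "region_id", "band", "rcn", "rcng",
                           "distance_to_epidermis", "local_entropy")

#' Marker columns of a cell table
#'
#' Marker columns are inferred structurally: numeric columns that are neither
#' reserved bookkeeping columns nor `_scaled` derivatives.
#'
#' @param cells a `cell_table` (or compatible data.frame).
#' @return character vector of raw marker column names.
#' @export
cell_markers <- function(cells) {
  cand <- setdiff(names(cells), reserved_cell_columns)
  cand <- cand[!grepl("_scaled$", cand)]
  cand[vapply(cells[cand], is.numeric, logical(1))]
}

#' Read a single-cell feature table from CSV
#'
#' Reads an MCMICRO-style quantification table (columns `CellID`,
#' `X_centroid`, `Y_centroid`, one column per marker, optional `Specimen`)
#' and converts centroid coordinates to microns at the boundary: internally
#' the package always works in microns.
#'
#' @param path CSV file path.
#' @param pixel_size microns per pixel, used when `units = "pixels"`.
#' @param units `"pixels"` (default; coordinates are multiplied by
#'   `pixel_size`) or `"microns"` (taken as-is).
#' @param specimen_id specimen label used when the file has no `Specimen`
#'   column.
#' @return a [cell_table].
#' @export
read_cell_table <- function(path, pixel_size, units = c("pixels", "microns"),
                            specimen_id = "specimen1") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("read_cell_table: file not found: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e)
                    stop("read_cell_table: empty or unreadable file: ", path,
                         call. = FALSE))
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("read_cell_table: empty file: ", path, call. = FALSE)
  }
  required <- c("CellID", "X_centroid", "Y_centroid")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("read_cell_table: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (units == "pixels") {
    if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0) {
      stop("read_cell_table: pixel_size (microns per pixel) is mandatory for pixel inputs",
           call. = FALSE)
    }
    scale <- pixel_size
  } else {
    scale <- 1
  }
  meta_cols <- c(required, "Specimen", "phenotype", "tumor_state", "region_id")
  marker_cols <- setdiff(names(raw), meta_cols)
  for (m in setdiff(marker_cols, grep("_scaled$", marker_cols, value = TRUE))) {
    v <- raw[[m]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("read_cell_table: non-numeric intensity in column ", m,
           " at row ", bad, call. = FALSE)
    }
  }
  out <- data.frame(
    cell_id = as.integer(raw$CellID),
    specimen_id = if ("Specimen" %in% names(raw)) as.character(raw$Specimen) else specimen_id,
    x = raw$X_centroid * scale,
    y = raw$Y_centroid * scale,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, raw[marker_cols])
  for (opt in c("phenotype", "tumor_state", "region_id")) {
    if (opt %in% names(raw)) out[[opt]] <- as.character(raw[[opt]])
  }
  cell_table(out)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: coordinates are written in microns under
#' `X_centroid`/`Y_centroid` (so round-tripping uses `units = "microns"`).
#'
#' @param cells a [cell_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  out <- as.data.frame(cells)
  names(out)[names(out) == "cell_id"] <- "CellID"
  names(out)[names(out) == "specimen_id"] <- "Specimen"
  names(out)[names(out) == "x"] <- "X_centroid"
  names(out)[names(out) == "y"] <- "Y_centroid"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
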