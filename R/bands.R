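#' Distance from each cell to the epidermis reference geometry
#'
#' Euclidean distance from each cell centroid to the nearest point of the
#' reference polyline or polygon outline; cells inside a reference polygon
#' get distance 0.
#'
#' @param cells a [cell_table].
#' @param reference the epidermis [region_annotation] (role
#'   `epidermis_reference`), or any region annotation.
#' @return numeric vector of distances in microns.
#' @export
distance_to_epidermis <- function(cells, reference) {
  if (missing(reference) || is.null(reference)) {
    stop("distance_to_epidermis: reference geometry required", call. = FALSE)
  }
  stopifnot(inherits(reference, "region_annotation"))
  v <- reference$geometry
  n <- nrow(v)
  segs <- if (reference$geom_type == "polygon") {
    cbind(v, v[c(2:n, 1), , drop = FALSE])
  } else {
    cbind(v[-n, , drop = FALSE], v[-1, , drop = FALSE])
  }
  px <- cells$x; py <- cells$y
  d2 <- rep(Inf, length(px))
  for (s in seq_len(nrow(segs))) {
    ax <- segs[s, 1]; ay <- segs[s, 2]; bx <- segs[s, 3]; by <- segs[s, 4]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    d2 <- pmin(d2, (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
  }
  d <- sqrt(d2)
  if (reference$geom_type == "polygon") {
    d[points_in_region(cells, reference)] <- 0
  }
  d
}

#' Assign invasion bands by distance from the epidermis
#'
#' Bands are fixed-thickness, half-open depth intervals
#' `[k * band_width, (k+1) * band_width)`: `band = floor(d / band_width)`,
#' so a cell exactly on a band boundary belongs to the deeper band. Every
#' cell with finite distance gets exactly one band, so band sizes sum to the
#' cell count.
#'
#' @param distances non-negative distances in microns
#'   (from [distance_to_epidermis()]).
#' @param band_width band thickness in microns (default 200, i.e. 0.2 mm).
#' @return data.frame with `distance` and integer `band` (0-based).
#' @export
assign_bands <- function(distances, band_width = 200) {
  if (!is.numeric(band_width) || band_width <= 0) {
    stop("assign_bands: band_width must be > 0", call. = FALSE)
  }
  if (any(distances < 0, na.rm = TRUE)) {
    stop("assign_bands: negative distance", call. = FALSE)
  }
  data.frame(distance = distances,
             band = as.integer(floor(distances / band_width)))
}

#' Spatial entropy per (region, band)
#'
#' Splits each annotated region into disjoint invasion-band subsections and
#' computes [spatial_entropy()] within each non-empty subsection holding at
#' least `min_cells` attribute-bearing cells; smaller subsections are
#' reported as not-computable.
#'
#' @param cells a [cell_table].
#' @param bands [assign_bands()] output for the same cells (row-aligned).
#' @param regions list of [region_annotation] polygons.
#' @param attribute entropy attribute column (default `"tumor_state"`).
#' @param alpha display scale.
#' @param min_cells minimum cells per subsection (default 3).
#' @return data.frame keyed by (`region_id`, `band`) with `n_cells`, `H`,
#'   `status`.
#' @export
entropy_by_band <- function(cells, bands, regions, attribute = "tumor_state",
                            alpha = 1, min_cells = 3) {
  stopifnot(nrow(bands) == nrow(cells))
  cells$band <- bands$band
  regions <- Filter(function(r) r$geom_type == "polygon", regions)
  rows <- list()
  for (rg in regions) {
    inside <- points_in_region(cells, rg)
    sub <- cells[inside & !is.na(cells[[attribute]]), , drop = FALSE]
    if (nrow(sub) == 0) next
    for (b in sort(unique(sub$band))) {
      sb <- sub[sub$band == b, , drop = FALSE]
      if (nrow(sb) < min_cells) {
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = rg$region_id, band = b, n_cells = nrow(sb),
          H = NA_real_, status = "not-computable", stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch(
        spatial_entropy(build_delaunay_graph(sb, attribute), alpha),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = rg$region_id, band = b, n_cells = nrow(sb),
        H = if (is.null(res)) NA_real_ else res$H,
        status = if (is.null(res)) "not-computable" else "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
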