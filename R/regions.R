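#' Region annotations
#'
#' A `region_annotation` describes one annotated geometry on the section:
#' a pathologist-drawn histologic region or microregion (simple polygon) or
#' the epidermis reference geometry (polygon or polyline). Stages follow the
#' local-progression vocabulary: normal skin (N), precursor (P), melanoma in
#' situ (MIS), radial growth phase (RGP), vertical growth phase (VGP).
#'
#' @param region_id character id.
#' @param geometry numeric n x 2 matrix of vertices, micron coordinates.
#'   Polygons may repeat the first vertex last; the closing vertex is dropped.
#' @param stage one of `r paste(stage_vocabulary, collapse=", ")`, or `NA` for
#'   reference geometries.
#' @param role `"histologic_region"`, `"microregion"` or
#'   `"epidermis_reference"`.
#' @param geom_type `"polygon"` or `"polyline"` (polyline only for the
#'   epidermis reference).
#' @param til_status optional `"brisk"`, `"non-brisk"` or `"absent"`.
#' @return object of class `region_annotation`.
#' @export
region_annotation <- function(region_id, geometry, stage = NA_character_,
                              role = "histologic_region",
                              geom_type = "polygon", til_status = NA_character_) {
  geometry <- as.matrix(geometry)
  stopifnot(ncol(geometry) == 2, is.numeric(geometry))
  role <- match.arg(role, c("histologic_region", "microregion", "epidermis_reference"))
  geom_type <- match.arg(geom_type, c("polygon", "polyline"))
  if (geom_type == "polyline" && role != "epidermis_reference") {
    stop("region_annotation: polyline geometry only allowed for epidermis_reference",
         call. = FALSE)
  }
  if (geom_type == "polygon") {
    if (nrow(geometry) >= 2 &&
        isTRUE(all(geometry[1, ] == geometry[nrow(geometry), ]))) {
      geometry <- geometry[-nrow(geometry), , drop = FALSE]
    }
    if (nrow(geometry) < 3) stop("region_annotation: polygon needs >= 3 vertices", call. = FALSE)
    if (!is_simple_polygon(geometry)) {
      stop("region_annotation: self-intersecting polygon in region ", region_id,
           call. = FALSE)
    }
  }
  if (!is.na(stage) && !(stage %in% stage_vocabulary)) {
    stop("region_annotation: unknown stage '", stage, "' (expected one of ",
         paste(stage_vocabulary, collapse = ", "), ")", call. = FALSE)
  }
  if (is.na(stage) && role != "epidermis_reference") {
    stop("region_annotation: stage required for role ", role, call. = FALSE)
  }
  structure(list(region_id = as.character(region_id), geometry = geometry,
                 stage = stage, role = role, geom_type = geom_type,
                 til_status = til_status),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation %s: %s %s, %d vertices, stage %s>\n",
              x$region_id, x$role, x$geom_type, nrow(x$geometry),
              ifelse(is.na(x$stage), "-", x$stage)))
  invisible(x)
}

#' @rdname region_annotation
#' @format NULL
#' @export
stage_vocabulary <- c("N", "P", "MIS", "RGP", "VGP")

# Simple-polygon test: no two non-adjacent edges may intersect.
# O(n^2) segment pairs; annotation polygons are small.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Read region annotations from GeoJSON
#'
#' Expects a FeatureCollection whose features carry `region_id`, `stage`,
#' `role` (and optionally `til_status`) properties, with Polygon or LineString
#' geometries in the same micron frame as the cell tables.
#'
#' @param path GeoJSON file path.
#' @return list of [region_annotation] objects.
#' @export
read_region_annotations <- function(path) {
  if (!file.exists(path)) stop("read_region_annotations: file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("read_region_annotations: not a GeoJSON FeatureCollection", call. = FALSE)
  }
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    props <- f$properties
    gtype <- f$geometry$type
    if (gtype == "Polygon") {
      ring <- f$geometry$coordinates[[1]]
      coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      geom_type <- "polygon"
    } else if (gtype == "LineString") {
      coords <- do.call(rbind, lapply(f$geometry$coordinates, function(p) c(p[[1]], p[[2]])))
      geom_type <- "polyline"
    } else {
      stop("read_region_annotations: unsupported geometry type ", gtype, call. = FALSE)
    }
    region_annotation(
      region_id = props$region_id %||% sprintf("region%03d", i),
      geometry = coords,
      stage = props$stage %||% NA_character_,
      role = props$role %||% "histologic_region",
      geom_type = geom_type,
      til_status = props$til_status %||% NA_character_
    )
  })
}

#' Write region annotations to GeoJSON
#'
#' @param regions list of [region_annotation] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_annotations <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    if (r$geom_type == "polygon") {
      ring <- rbind(r$geometry, r$geometry[1, ])
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(ring)),
                                             function(i) as.list(unname(ring[i, ])))))
    } else {
      geom <- list(type = "LineString",
                   coordinates = lapply(seq_len(nrow(r$geometry)),
                                        function(i) as.list(unname(r$geometry[i, ]))))
    }
    props <- list(region_id = r$region_id, role = r$role)
    if (!is.na(r$stage)) props$stage <- r$stage
    if (!is.na(r$til_status)) props$til_status <- r$til_status
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Point-in-region membership
#'
#' Boundary-inclusive point-in-polygon test: a centroid lying exactly on the
#' polygon edge or a vertex belongs to the region.
#'
#' @param cells a [cell_table] (uses columns `x`, `y`).
#' @param region a polygon [region_annotation].
#' @return logical vector, one entry per cell.
#' @export
points_in_region <- function(cells, region) {
  stopifnot(inherits(region, "region_annotation"))
  if (region$geom_type != "polygon") {
    stop("points_in_region: region geometry is not a polygon", call. = FALSE)
  }
  code <- sp::point.in.polygon(cells$x, cells$y,
                               region$geometry[, 1], region$geometry[, 2])
  code > 0
}
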