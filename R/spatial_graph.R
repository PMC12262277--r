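#' Delaunay spatial graphs
#'
#' A `spatial_graph` is the Delaunay neighbor graph on a designated cell
#' subset: nodes are cells with coordinates and one categorical attribute
#' (the label entropy is computed over, e.g. the tumor differentiation
#' state), edges are the Delaunay triangulation edges weighted by Euclidean
#' distance in microns. Optionally, edges longer than `max_edge` are pruned
#' after triangulation (the graph may then disconnect; pruning guards against
#' biologically meaningless long edges across stromal gaps when
#' triangulating tumor cells only).
#'
#' @param cells a [cell_table] subset (>= 3 cells, not all collinear).
#' @param attribute name of the label column used as the node attribute.
#' @param max_edge optional maximum edge length in microns (default `NULL`,
#'   no pruning).
#' @return object of class `spatial_graph`: list with `nodes` (data.frame
#'   `cell_id`, `x`, `y`, `attr`), `edges` (data.frame `i`, `j`, `weight`
#'   with node indices `i < j`), `degree`, and `attribute`.
#' @export
build_delaunay_graph <- function(cells, attribute, max_edge = NULL) {
  if (nrow(cells) < 3) {
    stop("build_delaunay_graph: need at least 3 cells", call. = FALSE)
  }
  if (!attribute %in% names(cells)) {
    stop("build_delaunay_graph: attribute column '", attribute, "' not found",
         call. = FALSE)
  }
  x <- cells$x; y <- cells$y
  if (anyDuplicated(cbind(x, y))) {
    warning("build_delaunay_graph: duplicate coordinates perturbed by 1e-6 um")
    dup <- duplicated(cbind(x, y))
    x[dup] <- x[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
    y[dup] <- y[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
  }
  # collinearity: all cross products of consecutive spans vanish
  if (all(abs((x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])) < 1e-9 *
          max(1, diff(range(x)), diff(range(y))))) {
    stop("build_delaunay_graph: all cells are collinear", call. = FALSE)
  }
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  e <- dd$delsgs
  i <- pmin(e$ind1, e$ind2); j <- pmax(e$ind1, e$ind2)
  w <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  keep <- if (is.null(max_edge)) rep(TRUE, length(w)) else w <= max_edge
  edges <- data.frame(i = i[keep], j = j[keep], weight = w[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  n <- length(x)
  degree <- tabulate(c(edges$i, edges$j), nbins = n)
  structure(list(
    nodes = data.frame(cell_id = cells$cell_id, x = x, y = y,
                       attr = as.character(cells[[attribute]]),
                       stringsAsFactors = FALSE),
    edges = edges, degree = degree, attribute = attribute),
    class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph: %d nodes, %d edges, attribute '%s'>\n",
              nrow(x$nodes), nrow(x$edges), x$attribute))
  invisible(x)
}

#' Export a spatial graph edge list
#'
#' @param graph a `spatial_graph`.
#' @param path output TSV path (columns source, target, weight as cell ids).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  out <- data.frame(source = graph$nodes$cell_id[graph$edges$i],
                    target = graph$nodes$cell_id[graph$edges$j],
                    weight = graph$edges$weight)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fixed-radius neighbor lists
#'
#' For every cell, the indices of all other cells within Euclidean distance
#' `r` (inclusive, `d <= r`; the focal cell is excluded). Exact grid-binning
#' scan: cells are bucketed on an `r`-spaced grid and only the 3x3 bucket
#' neighborhood is compared.
#'
#' @param cells a [cell_table] (or any data.frame with `x`, `y`).
#' @param r radius in microns (> 0).
#' @return list of integer vectors (row indices into `cells`), one per cell.
#' @export
radius_neighbors <- function(cells, r) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    stop("radius_neighbors: r must be a single positive number", call. = FALSE)
  }
  x <- cells$x; y <- cells$y
  n <- length(x)
  out <- vector("list", n)
  if (n == 0) return(out)
  gx <- floor(x / r); gy <- floor(y / r)
  key <- paste0(gx, ",", gy)
  buckets <- split(seq_len(n), key)
  r2 <- r * r
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      b <- buckets[[paste0(gx[i] + di, ",", gy[i] + dj)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    nb <- cand[d2 <= r2]
    out[[i]] <- sort(nb[nb != i])
  }
  out
}
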