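#' Per-cell local Shannon entropy
#'
#' For each cell, the Shannon entropy (bits) of the attribute frequencies
#' among its Delaunay neighbors, the focal cell excluded by default: with
#' neighbor attribute frequencies `f_t`, entropy is `-sum(f_t * log2(f_t))`.
#' Values lie in `[0, log2(L)]` for `L` attributes. Isolated nodes (possible
#' only after `max_edge` pruning) get entropy 0 and are flagged.
#'
#' @param graph a [build_delaunay_graph()] result.
#' @param include_focal include the focal cell's own attribute in the
#'   neighborhood distribution (default `FALSE`).
#' @return data.frame with `cell_id`, `entropy` (bits), `degree`, `isolated`.
#' @export
local_shannon_entropy <- function(graph, include_focal = FALSE) {
  stopifnot(inherits(graph, "spatial_graph"))
  attr_v <- graph$nodes$attr
  if (anyNA(attr_v)) {
    stop("local_shannon_entropy: missing attribute on one or more nodes",
         call. = FALSE)
  }
  n <- nrow(graph$nodes)
  lev <- sort(unique(attr_v))
  code <- match(attr_v, lev)
  # neighbor attribute counts via one pass over the edge list
  counts <- matrix(0L, n, length(lev))
  ei <- graph$edges$i; ej <- graph$edges$j
  for (t in seq_along(lev)) {
    counts[, t] <- tabulate(c(ei[code[ej] == t], ej[code[ei] == t]), nbins = n)
  }
  if (include_focal) {
    counts[cbind(seq_len(n), code)] <- counts[cbind(seq_len(n), code)] + 1L
  }
  tot <- rowSums(counts)
  f <- counts / pmax(tot, 1L)
  plogp <- ifelse(f > 0, f * log2(f), 0)
  h <- -rowSums(plogp)
  h[tot == 0] <- 0
  data.frame(cell_id = graph$nodes$cell_id, entropy = h,
             degree = graph$degree, isolated = tot == 0)
}

#' Region-level spatial entropy
#'
#' Shannon entropy of the attribute composition, weighted per attribute by an
#' intermixing prefactor measured on the Delaunay graph. For cell `i` with
#' attribute `l`, the intermixing strength `M_il` is the number of its
#' Delaunay neighbors carrying a different attribute, and `D_il` is the sum
#' of Euclidean edge lengths to those heterotypic neighbors. With `Mbar_l`
#' and `Dbar_l` the means of `M_il` and `D_il` over the `n_l` cells of
#' attribute `l`, and `p_l = n_l / N` the attribute probability in the
#' analyzed cell set, the statistic is
#'
#'   `H = -alpha * sum_l (Mbar_l / Dbar_l) * p_l * log2(p_l)`
#'
#' so that the prefactor grows with intermixing and shrinks with the distance
#' between heterotypic neighbors (units: bits per micron at `alpha = 1`). An
#' attribute whose members have no heterotypic neighbors contributes 0 (the
#' `Mbar -> 0` limit). The sum is negated so `H >= 0`; the raw signed value
#' is also returned. `alpha` is a pure display scale and never affects
#' comparisons.
#'
#' @param graph a [build_delaunay_graph()] result on the region's cells.
#' @param alpha positive scaling factor (default 1).
#' @return object of class `entropy_result`: list with `H`, `H_signed`,
#'   `alpha`, `L`, `n_cells`, and a per-attribute `components` data.frame
#'   (`attribute`, `n_l`, `p_l`, `M_bar`, `D_bar`, `term`).
#' @export
spatial_entropy <- function(graph, alpha = 1) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("spatial_entropy: alpha must be > 0", call. = FALSE)
  }
  attr_v <- graph$nodes$attr
  n <- length(attr_v)
  if (n == 0) stop("spatial_entropy: empty graph", call. = FALSE)
  if (anyNA(attr_v)) {
    stop("spatial_entropy: missing attribute on one or more nodes", call. = FALSE)
  }
  ei <- graph$edges$i; ej <- graph$edges$j; w <- graph$edges$weight
  hetero <- attr_v[ei] != attr_v[ej]
  M_i <- tabulate(c(ei[hetero], ej[hetero]), nbins = n)
  D_i <- numeric(n)
  if (any(hetero)) {
    sums <- rowsum(c(w[hetero], w[hetero]), c(ei[hetero], ej[hetero]))
    D_i[as.integer(rownames(sums))] <- sums[, 1]
  }
  lev <- sort(unique(attr_v))
  n_l <- as.vector(table(factor(attr_v, levels = lev)))
  M_bar <- as.vector(tapply(M_i, factor(attr_v, levels = lev), mean))
  D_bar <- as.vector(tapply(D_i, factor(attr_v, levels = lev), mean))
  p_l <- n_l / n
  ratio <- ifelse(M_bar > 0, M_bar / D_bar, 0)
  term <- ratio * p_l * log2(p_l)       # <= 0
  H_signed <- alpha * sum(term)
  structure(list(
    H = -H_signed, H_signed = H_signed, alpha = alpha,
    L = length(lev), n_cells = n,
    components = data.frame(attribute = lev, n_l = n_l, p_l = p_l,
                            M_bar = M_bar, D_bar = D_bar, term = term,
                            stringsAsFactors = FALSE)),
    class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result: H = %.6g (alpha = %g, L = %d, n = %d)>\n",
              x$H, x$alpha, x$L, x$n_cells))
  invisible(x)
}

#' Spatial entropy per annotated region
#'
#' For each polygon region, selects the cells inside it (boundary-inclusive)
#' that carry a non-missing value of `attribute` (for tumor-state entropy
#' this restricts the graph to tumor cells), builds a fresh Delaunay graph,
#' and computes [spatial_entropy()]. Regions with fewer than `min_cells`
#' eligible cells (or with degenerate geometry for triangulation) are
#' reported with status `"not-computable"`.
#'
#' @param cells a [cell_table].
#' @param regions list of [region_annotation] polygons (reference geometries
#'   are skipped).
#' @param attribute label column for the entropy attribute
#'   (default `"tumor_state"`).
#' @param alpha display scale (default 1).
#' @param min_cells minimum eligible cells (default 3).
#' @param max_edge optional Delaunay edge pruning in microns.
#' @return data.frame with one row per region: `region_id`, `stage`,
#'   `n_cells`, `L`, `H`, `status`; the full `entropy_result` objects are
#'   attached as the `"results"` attribute, keyed by region id.
#' @export
entropy_by_region <- function(cells, regions, attribute = "tumor_state",
                              alpha = 1, min_cells = 3, max_edge = NULL) {
  regions <- Filter(function(r) r$geom_type == "polygon", regions)
  results <- list()
  rows <- lapply(regions, function(rg) {
    inside <- points_in_region(cells, rg)
    sub <- cells[inside & !is.na(cells[[attribute]]), , drop = FALSE]
    if (nrow(sub) < min_cells) {
      return(data.frame(region_id = rg$region_id, stage = rg$stage,
                        n_cells = nrow(sub), L = NA_integer_, H = NA_real_,
                        status = "not-computable", stringsAsFactors = FALSE))
    }
    res <- tryCatch(
      spatial_entropy(build_delaunay_graph(sub, attribute, max_edge), alpha),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(region_id = rg$region_id, stage = rg$stage,
                        n_cells = nrow(sub), L = NA_integer_, H = NA_real_,
                        status = "not-computable", stringsAsFactors = FALSE))
    }
    results[[rg$region_id]] <<- res
    data.frame(region_id = rg$region_id, stage = rg$stage,
               n_cells = res$n_cells, L = res$L, H = res$H, status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Compare two groups of entropy values
#'
#' `test = "rank_sum"`: two-sided Mann-Whitney U rank test (exact null when
#' both groups have at most 8 untied observations, normal approximation with
#' continuity and tie correction otherwise). `test = "variance"`: Levene's
#' test on absolute deviations from the group means (`center = mean`, the
#' classical Levene form).
#'
#' @param values_a,values_b numeric samples.
#' @param test `"rank_sum"` or `"variance"`.
#' @param alternative passed to the rank test (default `"two.sided"`).
#' @return list with `statistic`, `p_value`, `method`, `status`
#'   (`"ok"` or `"degenerate"`).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("rank_sum", "variance"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = test, status = "degenerate"))
  }
  if (test == "rank_sum") {
    if (length(a) < 3 || length(b) < 3) {
      stop("compare_groups: rank_sum needs >= 3 values per group", call. = FALSE)
    }
    exact <- min(length(a), length(b)) <= 8 && !any(duplicated(pooled))
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                              exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "Mann-Whitney U", status = "ok")
  } else {
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lv <- car::leveneTest(pooled, g, center = mean)
    stat <- lv[1, "F value"]
    if (!is.finite(stat)) {
      return(list(statistic = NA_real_, p_value = NA_real_,
                  method = "Levene", status = "degenerate"))
    }
    list(statistic = stat, p_value = lv[1, "Pr(>F)"],
         method = "Levene (center = mean)", status = "ok")
  }
}
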