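#' Neighborhood composition matrix
#'
#' For every phenotyped cell, counts each phenotype among its neighbors
#' within radius `r` microns (Euclidean, focal cell excluded) and derives
#' row frequencies. Cells with zero neighbors are flagged as isolated; their
#' frequency rows are undefined and they are excluded from RCN clustering.
#'
#' @param cells a [cell_table] with a `phenotype` column.
#' @param r neighborhood radius in microns (default 15, the paper-scale
#'   radius of 50 pixels at 0.3 um/px).
#' @param phenotypes optional fixed phenotype vocabulary (columns); defaults
#'   to the sorted observed labels.
#' @return object of class `neighborhood_matrix`: list with `counts`
#'   (cells x phenotypes integer matrix), `freq` (row frequencies, `NA` rows
#'   for isolated cells), `isolated` (logical), `cell_id`, `r`.
#' @export
neighborhood_composition <- function(cells, r = 15, phenotypes = NULL) {
  if (!"phenotype" %in% names(cells)) {
    stop("neighborhood_composition: no phenotype column", call. = FALSE)
  }
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  nb <- radius_neighbors(cells, r)
  code <- match(cells$phenotype, phenotypes)
  n <- nrow(cells)
  counts <- matrix(0L, n, length(phenotypes),
                   dimnames = list(NULL, phenotypes))
  for (i in seq_len(n)) {
    if (length(nb[[i]]) > 0) {
      counts[i, ] <- tabulate(code[nb[[i]]], nbins = length(phenotypes))
    }
  }
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot > 0, tot, NA_real_)
  structure(list(counts = counts, freq = freq, isolated = tot == 0,
                 cell_id = cells$cell_id, r = r),
            class = "neighborhood_matrix")
}

#' @export
print.neighborhood_matrix <- function(x, ...) {
  cat(sprintf("<neighborhood_matrix: %d cells x %d phenotypes, r = %g um, %d isolated>\n",
              nrow(x$counts), ncol(x$counts), x$r, sum(x$isolated)))
  invisible(x)
}

#' Cluster neighborhood compositions into recurrent cellular neighborhoods
#'
#' k-means on the frequency rows of non-isolated cells (compositions, not
#' counts, so cell density does not dominate), with `nstart` restarts under a
#' fixed seed; the best-inertia fit is kept, so results are deterministic
#' given the seed.
#'
#' @param matrix a [neighborhood_composition()] result.
#' @param k number of RCNs (the reference analysis used k = 25).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return object of class `rcn_model`: list with `k`, `centroids`
#'   (k x phenotype matrix), `labels` (per cell, `NA` for isolated cells),
#'   `inertia` (total within-cluster sum of squares), `seed`, `cell_id`,
#'   and `rcng_map`/`g` (filled by [group_rcns()]).
#' @export
cluster_rcn <- function(matrix, k = 25, seed = 1L, nstart = 10) {
  stopifnot(inherits(matrix, "neighborhood_matrix"))
  rows <- matrix$freq[!matrix$isolated, , drop = FALSE]
  n_distinct <- nrow(unique(rows))
  if (k < 1 || k > n_distinct) {
    stop("cluster_rcn: k must be between 1 and the number of distinct ",
         "composition rows (", n_distinct, ")", call. = FALSE)
  }
  set.seed(seed)
  km <- stats::kmeans(rows, centers = k, nstart = nstart, iter.max = 100)
  labels <- rep(NA_integer_, nrow(matrix$freq))
  labels[!matrix$isolated] <- km$cluster
  structure(list(k = k, centroids = km$centers, labels = labels,
                 inertia = km$tot.withinss, seed = seed,
                 cell_id = matrix$cell_id, rcng_map = NULL, g = NULL),
            class = "rcn_model")
}

#' Elbow-based choice of the RCN cluster count
#'
#' Fits k-means over `k_range`, records the inertia (total within-cluster
#' sum of squares) per k, and returns the elbow: the k maximizing the
#' perpendicular distance from the inertia curve to the chord joining its
#' endpoints. A curve that ever fails to decrease yields status
#' `"no elbow"`.
#'
#' @param matrix a [neighborhood_composition()] result.
#' @param k_range increasing integer vector of at least 3 candidate k.
#' @param seed,nstart passed to [cluster_rcn()].
#' @return list with `k` (recommended, or `NA`), `status`, and the
#'   `curve` data.frame (`k`, `inertia`, `distance`).
#' @export
select_k_elbow <- function(matrix, k_range = 1:10, seed = 1L, nstart = 10) {
  if (length(k_range) < 3 || is.unsorted(k_range, strictly = TRUE)) {
    stop("select_k_elbow: k_range must be >= 3 strictly increasing values",
         call. = FALSE)
  }
  inertia <- vapply(k_range, function(k)
    cluster_rcn(matrix, k = k, seed = seed, nstart = nstart)$inertia,
    numeric(1))
  p1 <- c(k_range[1], inertia[1])
  p2 <- c(k_range[length(k_range)], inertia[length(inertia)])
  v <- p2 - p1
  dist <- abs(v[2] * (k_range - p1[1]) - v[1] * (inertia - p1[2])) /
    sqrt(sum(v^2))
  curve <- data.frame(k = k_range, inertia = inertia, distance = dist)
  if (any(diff(inertia) > 0)) {
    return(list(k = NA_integer_, status = "no elbow", curve = curve))
  }
  list(k = k_range[which.max(dist)], status = "ok", curve = curve)
}

#' Group RCNs into RCN groups (RCNGs)
#'
#' Agglomerative clustering (average linkage on correlation distance
#' `1 - cor`) of the k RCN centroids, cut into `g` groups (the reference
#' analysis used g = 11). RCNG ids are renumbered in order of first
#' appearance along the RCN index. The map can be overridden manually by
#' assigning `model$rcng_map` directly.
#'
#' @param model an [cluster_rcn()] result.
#' @param g number of RCNGs, `1 <= g <= k`.
#' @return the model with `rcng_map` (integer vector over 1..k) and `g` set.
#' @export
group_rcns <- function(model, g = 11) {
  stopifnot(inherits(model, "rcn_model"))
  if (g < 1 || g > model$k) {
    stop("group_rcns: g must be between 1 and k = ", model$k, call. = FALSE)
  }
  if (g == model$k) {
    model$rcng_map <- seq_len(model$k)
  } else {
    cc <- suppressWarnings(stats::cor(t(model$centroids)))
    cc[!is.finite(cc)] <- 0    # constant centroid rows: no correlation signal
    d <- stats::as.dist(1 - cc)
    cut <- stats::cutree(stats::hclust(d, method = "average"), k = g)
    model$rcng_map <- as.integer(factor(cut, levels = unique(cut)))
  }
  model$g <- g
  model
}

#' Attach RCN / RCNG labels to a cell table
#'
#' @param cells the [cell_table] the neighborhood matrix was built from
#'   (same row order).
#' @param model an [cluster_rcn()] result (optionally after [group_rcns()]).
#' @return the cell table with `rcn` (and `rcng`, if grouped) columns.
#' @export
label_rcn <- function(cells, model) {
  stopifnot(inherits(model, "rcn_model"), nrow(cells) == length(model$labels))
  cells$rcn <- model$labels
  if (!is.null(model$rcng_map)) {
    cells$rcng <- ifelse(is.na(model$labels), NA_integer_,
                         model$rcng_map[model$labels])
  }
  cell_table(cells)
}

#' RCNG abundance per region, with group comparisons
#'
#' Computes per-region RCNG proportion vectors (rows sum to 1) and, when a
#' two-level grouping of regions is supplied, a per-RCNG two-sided rank-sum
#' comparison of proportions between the groups with Benjamini-Hochberg
#' adjustment.
#'
#' @param cells a [cell_table] with `rcng` (or `rcn`) and `region_id` columns.
#' @param label `"rcng"` (default) or `"rcn"`.
#' @param region_groups optional named vector mapping region ids to two group
#'   labels.
#' @return list with `proportions` (region x RCNG matrix) and `comparisons`
#'   (data.frame, `NULL` without `region_groups`).
#' @export
rcn_abundance <- function(cells, label = "rcng", region_groups = NULL) {
  if (!label %in% names(cells) || !"region_id" %in% names(cells)) {
    stop("rcn_abundance: need '", label, "' and 'region_id' columns", call. = FALSE)
  }
  keep <- !is.na(cells[[label]]) & !is.na(cells$region_id)
  tab <- table(cells$region_id[keep], cells[[label]][keep])
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  comparisons <- NULL
  if (!is.null(region_groups)) {
    grp <- region_groups[rownames(prop)]
    lv <- unique(stats::na.omit(grp))
    if (length(lv) != 2) {
      stop("rcn_abundance: region_groups must define exactly 2 groups", call. = FALSE)
    }
    comparisons <- do.call(rbind, lapply(colnames(prop), function(cl) {
      a <- prop[which(grp == lv[1]), cl]; b <- prop[which(grp == lv[2]), cl]
      ct <- compare_groups(a, b, test = "rank_sum")
      data.frame(label = cl, group_a = lv[1], group_b = lv[2],
                 mean_a = mean(a), mean_b = mean(b),
                 statistic = ct$statistic, p_value = ct$p_value,
                 stringsAsFactors = FALSE)
    }))
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, "BH")
  }
  list(proportions = prop, comparisons = comparisons)
}
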