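#' Comparative proximity profile around two focal tumor states
#'
#' For every focal cell of each of two tumor states (e.g. MART1+ vs MART1-
#' SOX10+ tumor cells), counts the phenotypes of all cells lying within
#' radius `r` microns. Counts are aggregated to per-group mean compositions
#' within each region (or specimen), and each phenotype is compared between
#' the two focal states by a two-sided rank-sum test on the per-region
#' means, with Benjamini-Hochberg adjustment across phenotypes. Focal cells
#' with empty neighborhoods contribute zero count vectors.
#'
#' @param cells a [cell_table] with `phenotype`, `tumor_state` and a grouping
#'   column (`region_id` by default).
#' @param state_a,state_b focal tumor states to compare.
#' @param r radius in microns (default 15).
#' @param group_col aggregation column (default `"region_id"`).
#' @return object of class `proximity_profile`: list with `per_cell`
#'   (focal cell counts), `per_group` (group x phenotype mean compositions
#'   per state), and `comparisons` (per-phenotype test table, or `NULL` when
#'   either state has no cells — status `"not-computable"`).
#' @export
proximity_profile <- function(cells, state_a, state_b, r = 15,
                              group_col = "region_id") {
  for (col in c("phenotype", "tumor_state", group_col)) {
    if (!col %in% names(cells)) {
      stop("proximity_profile: missing column ", col, call. = FALSE)
    }
  }
  phenotypes <- sort(unique(cells$phenotype))
  nb <- radius_neighbors(cells, r)
  code <- match(cells$phenotype, phenotypes)
  focal <- which(!is.na(cells$tumor_state) &
                   cells$tumor_state %in% c(state_a, state_b))
  counts <- matrix(0L, length(focal), length(phenotypes),
                   dimnames = list(NULL, phenotypes))
  for (k in seq_along(focal)) {
    i <- focal[k]
    if (length(nb[[i]]) > 0) {
      counts[k, ] <- tabulate(code[nb[[i]]], nbins = length(phenotypes))
    }
  }
  per_cell <- data.frame(cell_id = cells$cell_id[focal],
                         state = cells$tumor_state[focal],
                         group = cells[[group_col]][focal],
                         counts, check.names = FALSE,
                         stringsAsFactors = FALSE)

  status <- "ok"
  if (!any(per_cell$state == state_a) || !any(per_cell$state == state_b)) {
    status <- "not-computable"
  }
  agg <- function(st) {
    sub <- per_cell[per_cell$state == st & !is.na(per_cell$group), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    m <- apply(sub[, phenotypes, drop = FALSE], 2,
               function(v) tapply(v, sub$group, mean))
    matrix(m, ncol = length(phenotypes),
           dimnames = list(sort(unique(sub$group)), phenotypes))
  }
  per_group <- list(agg(state_a), agg(state_b))
  names(per_group) <- c(state_a, state_b)

  comparisons <- NULL
  if (status == "ok" && !is.null(per_group[[1]]) && !is.null(per_group[[2]]) &&
      nrow(per_group[[1]]) >= 3 && nrow(per_group[[2]]) >= 3) {
    comparisons <- do.call(rbind, lapply(phenotypes, function(ph) {
      ct <- tryCatch(compare_groups(per_group[[1]][, ph], per_group[[2]][, ph],
                                    test = "rank_sum"),
                     error = function(e) list(statistic = NA_real_,
                                              p_value = NA_real_))
      data.frame(phenotype = ph,
                 mean_a = mean(per_group[[1]][, ph]),
                 mean_b = mean(per_group[[2]][, ph]),
                 statistic = ct$statistic, p_value = ct$p_value,
                 stringsAsFactors = FALSE)
    }))
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, "BH")
  }
  structure(list(state_a = state_a, state_b = state_b, r = r,
                 per_cell = per_cell, per_group = per_group,
                 comparisons = comparisons, status = status),
            class = "proximity_profile")
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat(sprintf("<proximity_profile: %s vs %s, r = %g um, %d focal cells, %s>\n",
              x$state_a, x$state_b, x$r, nrow(x$per_cell), x$status))
  invisible(x)
}

#' Mean nearest-neighbor distances between cell types
#'
#' For each ordered type pair (A, B), the mean over all cells of type A of
#' the distance to the nearest cell of type B (the focal cell itself is
#' excluded when A = B). Pairs involving an absent type, or A = B with a
#' single cell, are reported as not-computable (`NA`).
#'
#' @param cells a [cell_table] with a `phenotype` column.
#' @param types character vector of types to query (default: all observed).
#' @return data.frame with `type_a`, `type_b`, `mean_distance`, `n_focal`,
#'   `status`.
#' @export
nearest_neighbor_distances <- function(cells, types = NULL) {
  if (!"phenotype" %in% names(cells)) {
    stop("nearest_neighbor_distances: no phenotype column", call. = FALSE)
  }
  if (is.null(types)) types <- sort(unique(cells$phenotype))
  idx <- lapply(types, function(t) which(cells$phenotype == t))
  names(idx) <- types
  rows <- list()
  for (a in types) for (b in types) {
    ia <- idx[[a]]; ib <- idx[[b]]
    computable <- length(ia) >= 1 && length(ib) >= 1 &&
      !(a == b && length(ia) < 2)
    if (!computable) {
      rows[[length(rows) + 1L]] <- data.frame(
        type_a = a, type_b = b, mean_distance = NA_real_,
        n_focal = length(ia), status = "not-computable",
        stringsAsFactors = FALSE)
      next
    }
    d <- vapply(ia, function(i) {
      tb <- if (a == b) setdiff(ib, i) else ib
      sqrt(min((cells$x[tb] - cells$x[i])^2 + (cells$y[tb] - cells$y[i])^2))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      type_a = a, type_b = b, mean_distance = mean(d),
      n_focal = length(ia), status = "ok", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
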