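#' Preprocess an expression matrix for SOM training
#'
#' log10(x + 1) transform, quantile normalization across microregions (each
#' sample's sorted values are replaced by the mean sorted profile, ties
#' averaged; `limma::normalizeQuantiles`), then gene-wise centering by
#' subtracting each gene's mean log expression across samples. Genes with
#' zero variance after transform are retained (centering zeroes them) and
#' flagged.
#'
#' @param em an [expression_matrix] (counts >= 0) or plain MR x gene matrix.
#' @return list with `values` (normalized MR x gene matrix), `flat_genes`
#'   (logical flag per gene), and the metadata carried through (`NULL` for
#'   plain matrices).
#' @export
preprocess_expression <- function(em) {
  values <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (any(values < 0)) stop("preprocess_expression: negative counts", call. = FALSE)
  lg <- log10(values + 1)                       # MR x gene
  qn <- t(limma::normalizeQuantiles(t(lg)))     # samples are columns in limma
  dimnames(qn) <- dimnames(lg)
  centered <- sweep(qn, 2, colMeans(qn))
  flat <- apply(lg, 2, function(v) stats::var(v) == 0)
  list(values = centered, flat_genes = flat,
       metadata = if (inherits(em, "expression_matrix")) em$metadata else NULL)
}

#' Train a self-organizing map over gene expression profiles
#'
#' Batch SOM with genes as observations and samples (microregions) as the
#' feature space, on a rectangular `grid` of units. Each unit's codebook
#' vector is a metagene: the shared expression profile of the genes mapped
#' to it, so a `30 x 30` grid yields 900 metagenes. Initialization spans the
#' first two principal components of the gene profiles (deterministic up to
#' PC sign, which is fixed by convention), and each batch epoch updates every
#' unit as the neighborhood-weighted mean of the gene profiles, with a
#' Gaussian neighborhood whose radius decays linearly from half the larger
#' grid side to 1. Training is fully deterministic; `seed` is recorded for
#' provenance only.
#'
#' @param x normalized genes x samples matrix ([preprocess_expression()]
#'   output must be transposed: `t(pre$values)`), or the
#'   `preprocess_expression` result itself (transposed internally).
#' @param grid c(rows, cols) of the map (default c(30, 30)).
#' @param epochs batch epochs (default 20).
#' @param seed recorded provenance seed.
#' @return object of class `som_model`: list with `grid`, `codebook`
#'   (units x samples; row `u` is metagene `u`, units in row-major grid
#'   order), `unit_coords`, `bmu` (best-matching unit per gene),
#'   `qe_trace` (mean quantization error per epoch), `sample_ids`,
#'   `gene_ids`, `seed`.
#' @export
train_som <- function(x, grid = c(30, 30), epochs = 20, seed = 1L) {
  if (is.list(x) && !is.null(x$values)) x <- t(x$values)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("train_som: need at least 2 samples", call. = FALSE)
  n_units <- prod(grid)
  if (nrow(x) < 2 * n_units) {
    warning("train_som: fewer than 2 genes per unit (", nrow(x), " genes, ",
            n_units, " units)")
  }
  rows <- grid[1]; cols <- grid[2]
  gi <- rep(seq_len(rows), each = cols)
  gj <- rep(seq_len(cols), times = rows)
  unit_coords <- cbind(row = gi, col = gj)

  # PCA-plane initialization (deterministic; PC signs fixed by convention)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = 2)
  flip <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  v1 <- flip(sv$v[, 1]); v2 <- if (ncol(sv$v) > 1) flip(sv$v[, 2]) else 0 * v1
  s1 <- sv$d[1] / sqrt(max(1, nrow(x) - 1))
  s2 <- if (length(sv$d) > 1) sv$d[2] / sqrt(max(1, nrow(x) - 1)) else 0
  a1 <- if (rows > 1) (gi - (rows + 1) / 2) / ((rows - 1) / 2) else rep(0, n_units)
  a2 <- if (cols > 1) (gj - (cols + 1) / 2) / ((cols - 1) / 2) else rep(0, n_units)
  codebook <- matrix(mu, n_units, ncol(x), byrow = TRUE) +
    2 * s1 * outer(a1, v1) + 2 * s2 * outer(a2, v2)

  gene_norm2 <- rowSums(x^2)
  qe_trace <- numeric(epochs)
  r0 <- max(rows, cols) / 2
  radii <- if (epochs > 1) seq(r0, 1, length.out = epochs) else 1
  grid_d2 <- outer(gi, gi, "-")^2 + outer(gj, gj, "-")^2

  for (ep in seq_len(epochs)) {
    # squared distance of each gene to each unit
    d2 <- outer(gene_norm2, rowSums(codebook^2), "+") - 2 * x %*% t(codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qe_trace[ep] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(x)), bmu)], 0)))
    h <- exp(-grid_d2 / (2 * radii[ep]^2))     # units x units
    wsum <- h[, bmu, drop = FALSE]             # units x genes
    denom <- rowSums(wsum)
    codebook <- (wsum %*% x) / denom
  }
  d2 <- outer(gene_norm2, rowSums(codebook^2), "+") - 2 * x %*% t(codebook)
  bmu <- max.col(-d2, ties.method = "first")

  structure(list(grid = grid, codebook = codebook, unit_coords = unit_coords,
                 bmu = bmu, qe_trace = qe_trace,
                 sample_ids = colnames(x) %||% sprintf("s%d", seq_len(ncol(x))),
                 gene_ids = rownames(x) %||% sprintf("g%d", seq_len(nrow(x))),
                 seed = seed),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model: %d x %d grid (%d metagenes), %d genes, %d samples>\n",
              x$grid[1], x$grid[2], nrow(x$codebook),
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Number of metagenes of a SOM model
#' @param model a `som_model`.
#' @return integer, equal to the grid area.
#' @export
n_metagenes <- function(model) nrow(model$codebook)

#' SOM portraits
#'
#' `sample_portrait` renders one sample's metagene values as a grid matrix:
#' `portrait[u] = codebook[u, sample]`. `group_portrait` is the element-wise
#' mean over a set of samples; `difference_portrait` the element-wise
#' difference of two portraits.
#'
#' @param model a [train_som()] result.
#' @param sample sample id or index.
#' @return rows x cols numeric matrix.
#' @export
sample_portrait <- function(model, sample) {
  j <- if (is.character(sample)) match(sample, model$sample_ids) else sample
  if (is.na(j) || j < 1 || j > length(model$sample_ids)) {
    stop("sample_portrait: unknown sample", call. = FALSE)
  }
  matrix(model$codebook[, j], model$grid[1], model$grid[2], byrow = TRUE)
}

#' @rdname sample_portrait
#' @param samples vector of sample ids or indices (non-empty).
#' @export
group_portrait <- function(model, samples) {
  if (length(samples) == 0) {
    stop("group_portrait: empty sample group", call. = FALSE)
  }
  Reduce(`+`, lapply(samples, function(s) sample_portrait(model, s))) /
    length(samples)
}

#' @rdname sample_portrait
#' @param p1,p2 portraits (matrices of identical dimension).
#' @export
difference_portrait <- function(p1, p2) {
  stopifnot(all(dim(p1) == dim(p2)))
  p1 - p2
}

#' Overexpression cluster areas on the SOM grid
#'
#' Units are flagged overexpressed per sample by a min-max scaled threshold
#' (default 0.95), under one of two scalings:
#'
#' * `scale = "profile"`: each metagene profile is scaled over samples, so a
#'   unit is flagged in the samples near its own maximum (a metagene with a
#'   unique maximum sample is flagged exactly there; constant profiles are
#'   never flagged). Every non-constant unit is flagged for some sample, so
#'   this scaling characterizes *when* a unit is hot, not *which* units are.
#' * `scale = "portrait"` (recommended for cluster detection): each sample's
#'   portrait is scaled over units, so the flag marks approximately the top
#'   5 percent of the map for that sample.
#'
#' Connected components (4-connectivity) over the union of flagged units
#' define the cluster areas.
#'
#' @param model a [train_som()] result.
#' @param threshold min-max threshold in (0, 1).
#' @param scale `"profile"` (over samples, per unit) or `"portrait"`
#'   (over units, per sample).
#' @return object of class `cluster_areas`: list with `flags`
#'   (units x samples logical), `cluster_id` (per unit, `NA` if unflagged),
#'   `n_clusters`, `members` (list of unit index vectors),
#'   `cluster_samples` (per cluster, number of member-unit flags per
#'   sample), `threshold`.
#' @export
overexpression_clusters <- function(model, threshold = 0.95,
                                    scale = c("profile", "portrait")) {
  if (!(threshold > 0 && threshold < 1)) {
    stop("overexpression_clusters: threshold must be in (0, 1)", call. = FALSE)
  }
  scale <- match.arg(scale)
  cb <- model$codebook
  if (scale == "profile") {
    rng <- apply(cb, 1, range)
    span <- rng[2, ] - rng[1, ]
    scaled <- (cb - rng[1, ]) / ifelse(span > 0, span, Inf)  # constant -> 0
  } else {
    rng <- apply(cb, 2, range)
    span <- rng[2, ] - rng[1, ]
    scaled <- sweep(sweep(cb, 2, rng[1, ]), 2, ifelse(span > 0, span, Inf), "/")
  }
  flags <- scaled >= threshold
  flagged <- which(rowSums(flags) > 0)

  cluster_id <- rep(NA_integer_, nrow(cb))
  members <- list()
  if (length(flagged) > 0) {
    rows <- model$grid[1]; cols <- model$grid[2]
    ur <- model$unit_coords[, 1]; uc <- model$unit_coords[, 2]
    in_set <- logical(nrow(cb)); in_set[flagged] <- TRUE
    unit_at <- matrix(seq_len(nrow(cb))[order(ur, uc)], rows, cols, byrow = TRUE)
    visited <- logical(nrow(cb))
    cid <- 0L
    for (u0 in flagged) {
      if (visited[u0]) next
      cid <- cid + 1L
      queue <- u0; visited[u0] <- TRUE; comp <- integer(0)
      while (length(queue) > 0) {
        u <- queue[1]; queue <- queue[-1]
        comp <- c(comp, u)
        r <- ur[u]; c <- uc[u]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- r + d[1]; cc <- c + d[2]
          if (rr >= 1 && rr <= rows && cc >= 1 && cc <= cols) {
            v <- unit_at[rr, cc]
            if (in_set[v] && !visited[v]) {
              visited[v] <- TRUE
              queue <- c(queue, v)
            }
          }
        }
      }
      comp <- sort(comp)
      members[[cid]] <- comp
      cluster_id[comp] <- cid
    }
  }
  cluster_samples <- lapply(members, function(m)
    colSums(flags[m, , drop = FALSE]))
  structure(list(flags = flags, cluster_id = cluster_id,
                 n_clusters = length(members), members = members,
                 cluster_samples = cluster_samples, threshold = threshold),
            class = "cluster_areas")
}

#' @export
print.cluster_areas <- function(x, ...) {
  cat(sprintf("<cluster_areas: %d clusters over %d flagged units (threshold %g)>\n",
              x$n_clusters, sum(!is.na(x$cluster_id)), x$threshold))
  invisible(x)
}
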