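# Independent oracles used across the suite. Each is a deliberately naive
# implementation (triple loops, exhaustive enumeration) kept separate from
# the package code paths it checks.

make_cells <- function(x, y, label = NULL, specimen = "S1") {
  df <- data.frame(cell_id = seq_along(x), specimen_id = specimen,
                   x = x, y = y, M1 = 1, stringsAsFactors = FALSE)
  if (!is.null(label)) df$state <- as.character(label)
  cell_table(df)
}

# triple-loop transcription of the region-level spatial entropy definition
oracle_spatial_entropy <- function(graph, alpha = 1) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  nbrs <- lapply(seq_len(n), function(i)
    c(graph$edges$j[graph$edges$i == i], graph$edges$i[graph$edges$j == i]))
  H <- 0
  for (l in sort(unique(nodes$attr))) {
    members <- which(nodes$attr == l)
    M <- numeric(length(members)); D <- numeric(length(members))
    for (mi in seq_along(members)) {
      i <- members[mi]
      for (j in nbrs[[i]]) {
        if (nodes$attr[j] != l) {
          M[mi] <- M[mi] + 1
          D[mi] <- D[mi] + sqrt((nodes$x[i] - nodes$x[j])^2 +
                                  (nodes$y[i] - nodes$y[j])^2)
        }
      }
    }
    p <- length(members) / n
    if (mean(M) > 0) H <- H - alpha * (mean(M) / mean(D)) * p * log2(p)
  }
  H
}

brute_radius_neighbors <- function(cells, r) {
  n <- nrow(cells)
  lapply(seq_len(n), function(i) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    sort(setdiff(which(d <= r), i))
  })
}

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ax - ux)^2 + (ay - uy)^2)
}

# exhaustive Delaunay edge construction: a triangle belongs to the
# triangulation iff its circumcircle contains no other point
brute_delaunay_edges <- function(x, y, tol = 1e-9) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcircle(x[i], y[i], x[j], y[j], x[k], y[k])
    if (is.null(cc)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - cc$x)^2 + (y[others] - cc$y)^2
    if (all(d2 > cc$r2 + tol)) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# canonical Prufer decode (smallest-label leaf first)
prufer_to_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(NA_integer_, n - 1, 2)
  for (k in seq_along(pr)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, pr[k])
    degree[leaf] <- 0L
    degree[pr[k]] <- degree[pr[k]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# exhaustive minimum over all labelled spanning trees (Cayley enumeration)
brute_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (row in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(as.integer(seqs[row, ]), n)
    best <- min(best, sum(d[e]))
  }
  best
}

# exact one-sided Mann-Whitney p by enumeration of all rank assignments
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_stat <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_stat(seq_len(n))
  combos <- utils::combn(length(pooled), n)
  mean(apply(combos, 2, u_stat) <= obs)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# three spatially separated planted neighborhood archetypes:
# pure tumor, tumor/T-cell interface, pure stroma
make_planted_neighborhoods <- function(seed = 1, n_per = 120) {
  set.seed(seed)
  block <- function(x0, types) {
    g <- expand.grid(x = seq(0, 100, length.out = 11),
                     y = seq(0, 100, length.out = ceiling(n_per / 11)))
    g <- g[seq_len(n_per), ]
    data.frame(x = x0 + g$x + runif(n_per, -2, 2),
               y = g$y + runif(n_per, -2, 2),
               phenotype = rep_len(types, n_per),
               stringsAsFactors = FALSE)
  }
  d <- rbind(cbind(block(0, "tumor"), truth = "pure_tumor"),
             cbind(block(500, c("tumor", "T cell")), truth = "interface"),
             cbind(block(1000, "stromal"), truth = "stroma"))
  d$cell_id <- seq_len(nrow(d))
  d$specimen_id <- "S1"
  d$M1 <- 1
  cell_table(d)
}
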