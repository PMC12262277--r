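#' Correlation spanning tree over microregions
#'
#' Pairwise Pearson correlation `r` between per-microregion metagene
#' expression profiles defines a distance `1 - r`; the correlation spanning
#' tree is the minimum spanning tree under that distance, so strongly
#' correlated microregions end up adjacent. Kruskal's algorithm with edges
#' ordered by (weight, then lexicographic node-id pair) makes the tree
#' deterministic under ties. A constant profile has undefined correlations
#' and is a contract error naming the node.
#'
#' @param profiles numeric matrix with one column per microregion (e.g. the
#'   SOM codebook, metagenes x microregions) and column names as node ids.
#' @return object of class `correlation_tree`: list with `nodes` (ids),
#'   `edges` (data.frame `from`, `to`, `weight`, `correlation`), `degree`
#'   (named), and `total_weight`.
#' @export
correlation_spanning_tree <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) {
    stop("correlation_spanning_tree: need >= 2 microregions", call. = FALSE)
  }
  ids <- colnames(profiles) %||% sprintf("node%03d", seq_len(ncol(profiles)))
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    stop("correlation_spanning_tree: constant profile for node(s): ",
         paste(ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  cc <- stats::cor(profiles)
  n <- ncol(profiles)
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  ed <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   weight = 1 - cc[pairs])
  # lexicographic tie-break on node ids
  ord <- order(ed$weight, ids[ed$i], ids[ed$j])
  ed <- ed[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  take <- logical(nrow(ed))
  got <- 0L
  for (k in seq_len(nrow(ed))) {
    ra <- find(ed$i[k]); rb <- find(ed$j[k])
    if (ra != rb) {
      parent[ra] <- rb
      take[k] <- TRUE
      got <- got + 1L
      if (got == n - 1L) break
    }
  }
  ed <- ed[take, , drop = FALSE]
  edges <- data.frame(from = ids[ed$i], to = ids[ed$j], weight = ed$weight,
                      correlation = 1 - ed$weight, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  degree <- table(factor(c(edges$from, edges$to), levels = ids))
  structure(list(nodes = ids, edges = edges,
                 degree = stats::setNames(as.integer(degree), ids),
                 total_weight = sum(edges$weight)),
            class = "correlation_tree")
}

#' @export
print.correlation_tree <- function(x, ...) {
  cat(sprintf("<correlation_tree: %d nodes, %d edges, total weight %.4f>\n",
              length(x$nodes), nrow(x$edges), x$total_weight))
  invisible(x)
}

#' Decompose a correlation spanning tree into branches
#'
#' Branch points are nodes of degree >= 3; removing them splits the tree
#' into maximal paths (branches) between branch points and leaves. Nodes are
#' labelled by branch id (branch points get label 0, `"branchpoint"`); a
#' tree without branch points (a path) is a single branch. Branch ids are
#' ordered by the lexicographically smallest member node, so labels are
#' deterministic. A manual override map (node -> branch id) is accepted and
#' applied after the automatic labelling.
#'
#' @param tree a [correlation_spanning_tree()] result.
#' @param override optional named vector of manual branch assignments.
#' @return data.frame with `node`, `branch` (integer, 0 = branch point) and
#'   `is_branch_point`.
#' @export
decompose_branches <- function(tree, override = NULL) {
  stopifnot(inherits(tree, "correlation_tree"))
  ids <- tree$nodes
  bp <- names(tree$degree)[tree$degree >= 3]
  branch <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  if (length(bp) == 0) {
    branch[] <- 1L
  } else {
    branch[bp] <- 0L
    # connected components of the tree minus branch points
    keep <- !(tree$edges$from %in% bp | tree$edges$to %in% bp)
    adj <- split(
      c(tree$edges$to[keep], tree$edges$from[keep]),
      factor(c(tree$edges$from[keep], tree$edges$to[keep]), levels = ids))
    bid <- 0L
    for (start in sort(setdiff(ids, bp))) {
      if (!is.na(branch[start])) next
      bid <- bid + 1L
      queue <- start
      branch[start] <- bid
      while (length(queue) > 0) {
        u <- queue[1]; queue <- queue[-1]
        for (v in adj[[u]]) {
          if (is.na(branch[v])) {
            branch[v] <- bid
            queue <- c(queue, v)
          }
        }
      }
    }
  }
  if (!is.null(override)) branch[names(override)] <- override
  data.frame(node = ids, branch = unname(branch[ids]),
             is_branch_point = ids %in% bp, stringsAsFactors = FALSE)
}
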