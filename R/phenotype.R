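#' Gate sets
#'
#' One gate per (specimen, marker): the intensity threshold `gate` separating
#' marker-negative from marker-positive cells, plus the anchors `min`/`max`
#' used by the piecewise-linear rescaling. Anchors are typically robust
#' percentiles of the observed intensities (see [true_gate_set()]) rather
#' than raw extrema.
#'
#' @param df data.frame with columns `specimen_id`, `marker`, `gate`, `min`,
#'   `max` satisfying `min <= gate <= max`.
#' @return the validated data.frame, classed `gate_set`.
#' @export
gate_set <- function(df) {
  req <- c("specimen_id", "marker", "gate", "min", "max")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("gate_set: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("specimen_id", "marker")])) {
    stop("gate_set: duplicate (specimen, marker) pair", call. = FALSE)
  }
  bad <- which(!(df$min <= df$gate & df$gate <= df$max))
  if (length(bad) > 0) {
    stop("gate_set: min <= gate <= max violated for ",
         paste(df$marker[bad], collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("gate_set", class(df)))
  df
}

#' Read / write gate files
#'
#' Gate files are TSV with columns `specimen_id`, `marker`, `gate`, `min`,
#' `max`.
#'
#' @param path TSV path.
#' @return [gate_set] (read) or `path` invisibly (write).
#' @export
read_gate_set <- function(path) {
  gate_set(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_gate_set
#' @param gates a [gate_set].
#' @export
write_gate_set <- function(gates, path) {
  utils::write.table(gates, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rescale raw intensities to the unit interval around a gate
#'
#' Piecewise-linear map sending `[min, gate]` to `[0, 0.5]` and
#' `[gate, max]` to `[0.5, 1]`, clipping below `min` to 0 and above `max`
#' to 1. The gate maps exactly to 0.5, so after rescaling, values strictly
#' above 0.5 identify cells expressing the marker. Monotone non-decreasing by
#' construction. A constant channel (`min == max`) maps everything to 0 and
#' records a degenerate-channel warning.
#'
#' @param values numeric vector of raw intensities.
#' @param gate,min,max gate and anchor values (`min <= gate <= max`).
#' @return numeric vector in \[0, 1\].
#' @export
rescale_by_gate <- function(values, gate, min, max) {
  stopifnot(is.numeric(values), length(gate) == 1, length(min) == 1,
            length(max) == 1)
  if (!(min <= gate && gate <= max)) {
    stop("rescale_by_gate: need min <= gate <= max", call. = FALSE)
  }
  if (min == max) {
    warning("rescale_by_gate: degenerate channel (min == max); all values map to 0")
    return(rep(0, length(values)))
  }
  v <- pmin(pmax(values, min), max)
  lo <- gate > min & v <= gate
  out <- numeric(length(v))
  if (gate > min) out[lo] <- 0.5 * (v[lo] - min) / (gate - min)
  if (gate < max) {
    out[!lo] <- 0.5 + 0.5 * (v[!lo] - gate) / (max - gate)
  } else {
    out[!lo] <- 0.5
  }
  out
}

#' Rescale all gated markers of a cell table
#'
#' Applies [rescale_by_gate()] per (specimen, marker) and appends
#' `<marker>_scaled` columns. Markers without a gate entry are left
#' unscaled.
#'
#' @param cells a [cell_table].
#' @param gates a [gate_set].
#' @return the cell table with `_scaled` columns added.
#' @export
rescale_cells <- function(cells, gates) {
  gates <- gate_set(gates)
  for (i in seq_len(nrow(gates))) {
    m <- gates$marker[i]
    if (!m %in% names(cells)) {
      stop("rescale_cells: gated marker ", m, " not in cell table", call. = FALSE)
    }
    sel <- cells$specimen_id == gates$specimen_id[i]
    col <- paste0(m, "_scaled")
    if (!col %in% names(cells)) cells[[col]] <- NA_real_
    cells[[col]][sel] <- rescale_by_gate(cells[[m]][sel], gates$gate[i],
                                         gates$min[i], gates$max[i])
  }
  cell_table(cells)
}

#' Phenotype hierarchies
#'
#' An ordered rule table for hierarchical gating: each rule names required
#' positive markers (rescaled value strictly above 0.5) and required negative
#' markers (at or below 0.5), and a parent rule whose requirements it
#' inherits. Cells are assigned the deepest matching rule; cells matching no
#' rule are `"unclassified"`. Exactly 0.5 counts as negative.
#'
#' @param rules data.frame with columns `label`, `positive`, `negative`
#'   (comma-separated marker names, `""` for none), `parent` (`"root"` for
#'   top-level rules).
#' @return the validated rule table, classed `phenotype_hierarchy`.
#' @export
phenotype_hierarchy <- function(rules) {
  req <- c("label", "positive", "negative", "parent")
  missing <- setdiff(req, names(rules))
  if (length(missing) > 0) {
    stop("phenotype_hierarchy: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rules$label)) {
    stop("phenotype_hierarchy: duplicate labels", call. = FALSE)
  }
  unknown <- setdiff(rules$parent, c("root", rules$label))
  if (length(unknown) > 0) {
    stop("phenotype_hierarchy: unknown parent(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # depth computation doubles as acyclicity / reachability check
  depth <- rep(NA_integer_, nrow(rules)); names(depth) <- rules$label
  for (iter in seq_len(nrow(rules) + 1L)) {
    for (i in seq_len(nrow(rules))) {
      p <- rules$parent[i]
      if (p == "root") depth[i] <- 1L
      else if (!is.na(depth[p])) depth[i] <- depth[p] + 1L
    }
    if (!anyNA(depth)) break
  }
  if (anyNA(depth)) {
    stop("phenotype_hierarchy: cyclic or unreachable rule(s): ",
         paste(rules$label[is.na(depth)], collapse = ", "), call. = FALSE)
  }
  rules$depth <- as.integer(depth)
  class(rules) <- unique(c("phenotype_hierarchy", class(rules)))
  rules
}

#' Default phenotype hierarchy for the simulated marker panel
#'
#' Lineage gating over the 11-marker panel: SOX10 for melanocytes/tumor,
#' CD45 for immune cells (CD3 T cells split into CD8 and FOXP3 regulatory
#' subsets, CD11C myeloid), panCK keratinocytes, CD31 endothelium. All-
#' negative cells (dermal stroma) remain `"unclassified"`.
#'
#' @return a [phenotype_hierarchy].
#' @export
default_phenotype_hierarchy <- function() {
  phenotype_hierarchy(data.frame(
    label    = c("tumor", "immune", "keratinocyte", "endothelial",
                 "T cell", "CD8 T cell", "Treg", "myeloid"),
    positive = c("SOX10", "CD45", "panCK", "CD31",
                 "CD3", "CD8A", "FOXP3", "CD11C"),
    negative = c("CD45", "SOX10", "SOX10,CD45", "SOX10,CD45,panCK",
                 "", "FOXP3", "", "CD3"),
    parent   = c("root", "root", "root", "root",
                 "immune", "T cell", "T cell", "immune"),
    stringsAsFactors = FALSE))
}

split_markers <- function(s) {
  if (is.na(s) || s == "") character(0) else trimws(strsplit(s, ",")[[1]])
}

#' Call cell phenotypes by hierarchical gating
#'
#' Binarizes each rescaled marker at 0.5 (strictly above = positive) and
#' assigns each cell the deepest hierarchy rule whose inherited
#' positive/negative requirements all hold; ties at equal depth go to the
#' earlier rule. Unmatched cells are labelled `"unclassified"`.
#'
#' @param cells a [cell_table] with `_scaled` columns for every marker the
#'   hierarchy references.
#' @param hierarchy a [phenotype_hierarchy]
#'   (default [default_phenotype_hierarchy()]).
#' @return the cell table with a `phenotype` column.
#' @export
call_phenotypes <- function(cells, hierarchy = default_phenotype_hierarchy()) {
  stopifnot(inherits(hierarchy, "phenotype_hierarchy"))
  all_markers <- unique(unlist(lapply(
    c(hierarchy$positive, hierarchy$negative), split_markers)))
  scaled_cols <- paste0(all_markers, "_scaled")
  absent <- scaled_cols[!scaled_cols %in% names(cells)]
  if (length(absent) > 0) {
    stop("call_phenotypes: hierarchy references marker(s) without rescaled data: ",
         paste(sub("_scaled$", "", absent), collapse = ", "), call. = FALSE)
  }
  pos <- sapply(all_markers, function(m) cells[[paste0(m, "_scaled")]] > 0.5)
  pos <- matrix(pos, nrow = nrow(cells), dimnames = list(NULL, all_markers))

  requirements <- function(label) {
    p <- character(0); n <- character(0)
    while (label != "root") {
      i <- match(label, hierarchy$label)
      p <- c(p, split_markers(hierarchy$positive[i]))
      n <- c(n, split_markers(hierarchy$negative[i]))
      label <- hierarchy$parent[i]
    }
    list(pos = unique(p), neg = unique(n))
  }

  labels <- rep("unclassified", nrow(cells))
  best_depth <- rep(0L, nrow(cells))
  for (i in order(hierarchy$depth)) {
    rq <- requirements(hierarchy$label[i])
    ok <- rep(TRUE, nrow(cells))
    for (m in rq$pos) ok <- ok & pos[, m]
    for (m in rq$neg) ok <- ok & !pos[, m]
    take <- ok & hierarchy$depth[i] > best_depth
    labels[take] <- hierarchy$label[i]
    best_depth[take] <- hierarchy$depth[i]
  }
  cells$phenotype <- labels
  cell_table(cells)
}

#' Default tumor differentiation state map
#'
#' Total map from the binarized (MART1, SOX9, NGFR) staining pattern of a
#' SOX10+ tumor cell to a differentiation state: MART1+ cells without SOX9 or
#' NGFR are melanocytic; MART1+ cells co-expressing SOX9 and/or NGFR are
#' transitional; MART1- SOX9+ cells are mesenchymal; MART1- NGFR+ cells are
#' neural-crest-like. The triple-negative combination is biologically
#' undefined by these markers and maps to `"undetermined"`. The map is a
#' plain data.frame, so alternative readings of the state taxonomy can be
#' supplied.
#'
#' @return data.frame with logical columns `MART1`, `SOX9`, `NGFR` and a
#'   `state` column covering all 8 combinations.
#' @export
default_tumor_state_map <- function() {
  data.frame(
    MART1 = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
    SOX9  = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
    NGFR  = c(FALSE, FALSE, TRUE,  TRUE,  FALSE, TRUE,  TRUE,  FALSE),
    state = c("melanocytic", "transitional", "transitional", "transitional",
              "mesenchymal", "NC-like", "NC-like", "undetermined"),
    stringsAsFactors = FALSE)
}

#' Assign tumor differentiation states
#'
#' Looks up each SOX10+ tumor cell's binarized (MART1, SOX9, NGFR) pattern in
#' the state map. The input must already be restricted to tumor cells
#' (phenotype `tumor_label`); passing other cells is a contract error.
#'
#' @param cells a [cell_table] of tumor cells with `MART1_scaled`,
#'   `SOX9_scaled`, `NGFR_scaled` columns.
#' @param state_map state lookup table (default [default_tumor_state_map()]).
#' @param tumor_label phenotype label identifying tumor cells.
#' @return the cell table with a `tumor_state` column.
#' @export
assign_tumor_states <- function(cells, state_map = default_tumor_state_map(),
                                tumor_label = "tumor") {
  if (!"phenotype" %in% names(cells) || any(cells$phenotype != tumor_label)) {
    stop("assign_tumor_states: input must contain only cells with phenotype '",
         tumor_label, "'", call. = FALSE)
  }
  need <- c("MART1_scaled", "SOX9_scaled", "NGFR_scaled")
  absent <- setdiff(need, names(cells))
  if (length(absent) > 0) {
    stop("assign_tumor_states: missing rescaled column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(unique(state_map[, c("MART1", "SOX9", "NGFR")])) != 8) {
    stop("assign_tumor_states: state map must cover all 8 sign combinations",
         call. = FALSE)
  }
  key <- paste(cells$MART1_scaled > 0.5, cells$SOX9_scaled > 0.5,
               cells$NGFR_scaled > 0.5)
  map_key <- paste(state_map$MART1, state_map$SOX9, state_map$NGFR)
  cells$tumor_state <- state_map$state[match(key, map_key)]
  cell_table(cells)
}
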