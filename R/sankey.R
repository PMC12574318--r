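## Sankey graph model: layers are positions on a configurable rank ladder
## (leading letter of the Kraken rank code), flow width is clade read count.
## An unfiltered graph keeps every report row — on-ladder rows as nodes,
## everything else in a verbatim side table — so the source report can be
## reconstructed exactly, which is the model's own validation.

.SYNTHETIC_ROOT <- ".synthetic_root"

.nodeCols <- c("nodeId", "taxid", "name", "rankCode", "layer", "proportion",
               "cladeReads", "taxonReads", "parentNodeId", "rowIndex",
               "depth", "percentText", "extra")

.canonicalNodes <- function(nd) {
  out <- data.frame(
    nodeId       = as.character(nd$nodeId),
    taxid        = as.integer(nd$taxid),
    name         = as.character(nd$name),
    rankCode     = as.character(nd$rankCode),
    layer        = as.integer(nd$layer),
    proportion   = as.numeric(nd$proportion),
    cladeReads   = as.numeric(nd$cladeReads),
    taxonReads   = as.numeric(nd$taxonReads),
    parentNodeId = as.character(nd$parentNodeId),
    rowIndex     = as.integer(nd$rowIndex),
    depth        = as.integer(nd$depth),
    percentText  = as.character(nd$percentText),
    extra        = as.character(nd$extra),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.emptyNodes <- function() .canonicalNodes(data.frame(
  nodeId = character(0), taxid = integer(0), name = character(0),
  rankCode = character(0), layer = integer(0), proportion = numeric(0),
  cladeReads = numeric(0), taxonReads = numeric(0),
  parentNodeId = character(0), rowIndex = integer(0), depth = integer(0),
  percentText = character(0), extra = character(0)))

.canonicalLinks <- function(lk) {
  out <- data.frame(sourceNodeId = as.character(lk$sourceNodeId),
                    targetNodeId = as.character(lk$targetNodeId),
                    value = as.numeric(lk$value), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.emptyLinks <- function() .canonicalLinks(data.frame(
  sourceNodeId = character(0), targetNodeId = character(0),
  value = numeric(0)))

.canonicalOffLadder <- function(r) {
  out <- data.frame(
    percentText = as.character(r$percentText), percent = as.numeric(r$percent),
    cladeReads = as.numeric(r$cladeReads), taxonReads = as.numeric(r$taxonReads),
    rankCode = as.character(r$rankCode), taxid = as.integer(r$taxid),
    name = as.character(r$name), depth = as.integer(r$depth),
    rowIndex = as.integer(r$rowIndex), extra = as.character(r$extra),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.linksFromParents <- function(nodes) {
  has <- !is.na(nodes$parentNodeId)
  .canonicalLinks(data.frame(sourceNodeId = nodes$parentNodeId[has],
                             targetNodeId = nodes$nodeId[has],
                             value = nodes$cladeReads[has]))
}

#' Build the Sankey graph of a taxonomy report
#'
#' Every report row whose rank code's leading letter sits on `rankLadder`
#' becomes a node at that ladder layer; its parent is the nearest on-ladder
#' report-tree ancestor at a strictly smaller layer (rows skipping
#' intermediate ranks link across layers). A row with no such ancestor that is
#' not itself at the first ladder layer hangs off a synthetic root node. Rows
#' at off-ladder ranks (including the "unclassified" pseudo-row) are kept in a
#' verbatim side table so [reconstructReport()] can rebuild the report. No
#' filtering is applied here.
#'
#' @param report a [KrakenReport-class].
#' @param rankLadder ordered character vector of rank codes; default the
#'   canonical eight-rank ladder D, K, P, C, O, F, G, S.
#' @return an unfiltered [SankeyGraph-class].
#' @export
buildSankey <- function(report,
                        rankLadder = c("D", "K", "P", "C", "O", "F", "G", "S")) {
  stopifnot(is(report, "KrakenReport"), length(rankLadder) >= 1L)
  rows <- report@rows
  n <- nrow(rows)
  layer <- match(substr(rows$rankCode, 1L, 1L), rankLadder) - 1L
  isNode <- !is.na(layer)
  parentId <- rep(NA_character_, n)
  needSynthetic <- FALSE
  ## chainStack[[d + 1]]: on-ladder ancestors (nodeId, layer) along the path
  ## to the current row's parent at depth d - 1
  chainStack <- list(list())
  for (i in seq_len(n)) {
    d <- rows$depth[i]
    chain <- if (d + 1L <= length(chainStack)) chainStack[[d + 1L]] else
      stop("inconsistent indentation at row ", rows$rowIndex[i])
    newChain <- chain
    if (isNode[i]) {
      if (length(chain)) {
        ls <- vapply(chain, `[[`, 0L, 2L)
        ok <- which(ls < layer[i])
        if (length(ok)) parentId[i] <- chain[[max(ok)]][[1L]]
      }
      if (is.na(parentId[i]) && layer[i] > 0L) {
        parentId[i] <- .SYNTHETIC_ROOT
        needSynthetic <- TRUE
      }
      newChain <- c(chain, list(list(as.character(rows$taxid[i]), layer[i])))
    }
    chainStack <- c(chainStack[seq_len(d + 1L)], list(newChain))
  }

  nd <- rows[isNode, , drop = FALSE]
  nodes <- .canonicalNodes(data.frame(
    nodeId = as.character(nd$taxid), taxid = nd$taxid, name = nd$name,
    rankCode = nd$rankCode, layer = layer[isNode], proportion = nd$percent,
    cladeReads = nd$cladeReads, taxonReads = nd$taxonReads,
    parentNodeId = parentId[isNode], rowIndex = nd$rowIndex,
    depth = nd$depth, percentText = nd$percentText, extra = nd$extra,
    stringsAsFactors = FALSE))
  if (needSynthetic)
    nodes <- rbind(nodes, .canonicalNodes(data.frame(
      nodeId = .SYNTHETIC_ROOT, taxid = NA_integer_, name = "root",
      rankCode = "", layer = -1L, proportion = NA_real_,
      cladeReads = NA_real_, taxonReads = NA_real_,
      parentNodeId = NA_character_, rowIndex = NA_integer_,
      depth = NA_integer_, percentText = NA_character_,
      extra = NA_character_)))
  off <- .canonicalOffLadder(rows[!isNode, , drop = FALSE])
  new("SankeyGraph", nodes = nodes, links = .linksFromParents(nodes),
      rankLadder = as.character(rankLadder),
      totalReads = report@totalReads, offLadderRows = off,
      filters = sankeyFilters(), filtered = FALSE)
}

#' @describeIn applyFilters Threshold, rank and top-N filtering. Nodes
#'   survive when `proportion >= minProportion`, `cladeReads >=
#'   minCladeReads` and their rank's leading letter is in `ranksShown`
#'   (empty = all); then, per layer, only the `maxTaxaPerRank` nodes with
#'   the largest clade read counts remain (ties: smaller taxid). Descendants
#'   of removed nodes re-attach to their nearest surviving ancestor, each
#'   link still carrying the descendant's clade read count. The result is no
#'   longer reconstructible.
#' @param .exempt internal: nodeIds kept regardless of the filters (the
#'   subtree root).
setMethod("applyFilters", c("SankeyGraph", "SankeyFilters"),
          function(graph, filters, .exempt = character(0)) {
  nd <- graph@nodes
  real <- !is.na(nd$taxid)
  ranks <- if (length(filters@ranksShown)) filters@ranksShown else
    graph@rankLadder
  pass <- real &
    nd$proportion >= filters@minProportion &
    nd$cladeReads >= filters@minCladeReads &
    substr(nd$rankCode, 1L, 1L) %in% substr(ranks, 1L, 1L)
  exempt <- nd$nodeId %in% .exempt
  keep <- (pass | exempt) & real
  ## per-layer cap on what passed the thresholds (exempt nodes don't count)
  if (is.finite(filters@maxTaxaPerRank)) {
    capIdx <- which(keep & !exempt)
    for (ly in unique(nd$layer[capIdx])) {
      at <- capIdx[nd$layer[capIdx] == ly]
      if (length(at) > filters@maxTaxaPerRank) {
        ord <- at[order(-nd$cladeReads[at], nd$taxid[at])]
        keep[ord[-seq_len(filters@maxTaxaPerRank)]] <- FALSE
      }
    }
  }
  survivors <- nd$nodeId[keep]
  parentMap <- setNames(nd$parentNodeId, nd$nodeId)
  reattach <- function(nid) {
    p <- parentMap[[nid]]
    while (!is.na(p) && p != .SYNTHETIC_ROOT && !(p %in% survivors))
      p <- parentMap[[p]]
    p
  }
  out <- nd[keep, , drop = FALSE]
  out$parentNodeId <- vapply(out$nodeId, reattach, "")
  if (.SYNTHETIC_ROOT %in% out$parentNodeId)
    out <- rbind(out, nd[nd$nodeId == .SYNTHETIC_ROOT, , drop = FALSE])
  out <- .canonicalNodes(out)
  new("SankeyGraph", nodes = out, links = .linksFromParents(out),
      rankLadder = graph@rankLadder, totalReads = graph@totalReads,
      offLadderRows = .canonicalOffLadder(
        graph@offLadderRows[0, , drop = FALSE]),
      filters = filters, filtered = TRUE)
})

#' Re-root a Sankey graph at a taxon
#'
#' The chosen node becomes the sole top-layer node; its descendants are
#' gathered recursively and the given filters applied to them (the root
#' itself is always kept). Layers are re-based so the new root is layer 0;
#' proportions stay relative to the original total read count.
#'
#' @param graph a [SankeyGraph-class] (typically unfiltered).
#' @param taxid taxid of the new root; must have a node in `graph`.
#' @param filters a [SankeyFilters-class]; identity by default.
#' @return a filtered [SankeyGraph-class] rooted at `taxid`.
#' @export
sankeySubtree <- function(graph, taxid, filters = sankeyFilters()) {
  nd <- graph@nodes
  rootAt <- which(!is.na(nd$taxid) & nd$taxid == as.integer(taxid))
  if (length(rootAt) != 1L)
    stop("no Sankey node for taxid ", taxid)
  rootNid <- nd$nodeId[rootAt]
  kids <- split(nd$nodeId, nd$parentNodeId)
  closure <- character(0)
  frontier <- rootNid
  while (length(frontier)) {
    closure <- c(closure, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  sub <- nd[nd$nodeId %in% closure, , drop = FALSE]
  sub$layer <- sub$layer - nd$layer[rootAt]
  sub$parentNodeId[sub$nodeId == rootNid] <- NA_character_
  g <- new("SankeyGraph", nodes = .canonicalNodes(sub),
           links = .linksFromParents(sub),
           rankLadder = graph@rankLadder, totalReads = graph@totalReads,
           offLadderRows = .canonicalOffLadder(
             graph@offLadderRows[0, , drop = FALSE]),
           filters = filters, filtered = TRUE)
  applyFilters(g, filters, .exempt = rootNid)
}

## ---- JSON serialization ("taxoview-json/1") --------------------------

.filtersToList <- function(f) {
  list(min_proportion_percent = f@minProportion,
       min_clade_reads = f@minCladeReads,
       max_taxa_per_rank = if (is.finite(f@maxTaxaPerRank))
         f@maxTaxaPerRank else NULL,
       ranks_shown = as.list(f@ranksShown))
}

.filtersFromList <- function(x) {
  sankeyFilters(
    minProportion = x$min_proportion_percent %||% 0,
    minCladeReads = x$min_clade_reads %||% 0,
    maxTaxaPerRank = if (is.null(x$max_taxa_per_rank)) Inf else
      x$max_taxa_per_rank,
    ranksShown = unlist(x$ranks_shown) %||% character(0))
}

#' Serialize a Sankey graph to JSON
#'
#' Deterministic "taxoview-json/1" document: stable key order, nodes ordered
#' by original row index (synthetic root last), all reconstruction fields
#' (row index, depth, verbatim percent text, taxon reads, extra columns)
#' included, plus the off-ladder side table. `sankeyFromJSON(sankeyToJSON(g))`
#' reproduces `g` exactly.
#'
#' @param graph a [SankeyGraph-class].
#' @param path optional output file.
#' @return the JSON text (a `json` object), invisibly when `path` is given.
#' @export
sankeyToJSON <- function(graph, path = NULL) {
  nd <- graph@nodes
  nd <- nd[order(is.na(nd$rowIndex), nd$rowIndex), , drop = FALSE]
  names(nd) <- c("node_id", "taxid", "name", "rank_code", "layer",
                 "proportion", "clade_reads", "taxon_reads",
                 "parent_node_id", "row_index", "depth", "percent_text",
                 "extra")
  lk <- graph@links
  names(lk) <- c("source_node_id", "target_node_id", "value")
  off <- graph@offLadderRows
  names(off) <- c("percent_text", "percent", "clade_reads", "taxon_reads",
                  "rank_code", "taxid", "name", "depth", "row_index", "extra")
  doc <- list(schema = "taxoview-json/1",
              rank_ladder = as.list(graph@rankLadder),
              total_reads = graph@totalReads,
              filtered = graph@filtered,
              filters_applied = .filtersToList(graph@filters),
              nodes = nd, links = lk, off_ladder_rows = off)
  js <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}

#' Parse a "taxoview-json/1" document back into a Sankey graph
#'
#' @param x JSON text, a parsed list, or the path of a JSON file.
#' @return a [SankeyGraph-class].
#' @export
sankeyFromJSON <- function(x) {
  doc <- if (is.list(x)) x else {
    txt <- if (length(x) == 1L && !grepl("^\\s*\\{", x) && file.exists(x))
      paste(readLines(x), collapse = "\n") else paste(x, collapse = "\n")
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  if (!identical(doc$schema, "taxoview-json/1"))
    stop("unsupported or missing schema (expected taxoview-json/1)")
  nd <- doc$nodes
  nodes <- if (is.data.frame(nd) && nrow(nd)) .canonicalNodes(data.frame(
    nodeId = nd$node_id, taxid = nd$taxid, name = nd$name,
    rankCode = nd$rank_code, layer = nd$layer, proportion = nd$proportion,
    cladeReads = nd$clade_reads, taxonReads = nd$taxon_reads,
    parentNodeId = nd$parent_node_id, rowIndex = nd$row_index,
    depth = nd$depth, percentText = nd$percent_text, extra = nd$extra,
    stringsAsFactors = FALSE)) else .emptyNodes()
  lk <- doc$links
  links <- if (is.data.frame(lk) && nrow(lk)) .canonicalLinks(data.frame(
    sourceNodeId = lk$source_node_id, targetNodeId = lk$target_node_id,
    value = lk$value, stringsAsFactors = FALSE)) else .emptyLinks()
  off <- doc$off_ladder_rows
  offRows <- if (is.data.frame(off) && nrow(off)) .canonicalOffLadder(
    data.frame(percentText = off$percent_text, percent = off$percent,
               cladeReads = off$clade_reads, taxonReads = off$taxon_reads,
               rankCode = off$rank_code, taxid = off$taxid, name = off$name,
               depth = off$depth, rowIndex = off$row_index,
               extra = off$extra, stringsAsFactors = FALSE)) else
    .canonicalOffLadder(data.frame(
      percentText = character(0), percent = numeric(0),
      cladeReads = numeric(0), taxonReads = numeric(0),
      rankCode = character(0), taxid = integer(0), name = character(0),
      depth = integer(0), rowIndex = integer(0), extra = character(0)))
  new("SankeyGraph", nodes = nodes, links = links,
      rankLadder = unlist(doc$rank_ladder) %||% character(0),
      totalReads = as.numeric(doc$total_reads),
      offLadderRows = offRows,
      filters = .filtersFromList(doc$filters_applied),
      filtered = isTRUE(doc$filtered))
}

#' Reconstruct the source report from a Sankey document
#'
#' The model's validation step: merges the on-ladder nodes with the
#' off-ladder side table, orders by original row index, restores indentation
#' and verbatim percent text, and re-validates. Succeeds only on documents of
#' unfiltered graphs — filtering leaves row-index gaps, which raise a
#' completeness error.
#'
#' @param x a [SankeyGraph-class], JSON text, parsed list or JSON file path.
#' @return the reconstructed [KrakenReport-class].
#' @export
reconstructReport <- function(x) {
  graph <- if (is(x, "SankeyGraph")) x else sankeyFromJSON(x)
  nd <- graph@nodes
  nd <- nd[!is.na(nd$rowIndex), , drop = FALSE]
  fromNodes <- data.frame(
    percentText = nd$percentText, percent = nd$proportion,
    cladeReads = nd$cladeReads, taxonReads = nd$taxonReads,
    rankCode = nd$rankCode, taxid = nd$taxid, name = nd$name,
    depth = nd$depth, rowIndex = nd$rowIndex, extra = nd$extra,
    stringsAsFactors = FALSE)
  rows <- rbind(fromNodes, graph@offLadderRows[, names(fromNodes)])
  rows <- rows[order(rows$rowIndex), , drop = FALSE]
  if (!identical(as.integer(rows$rowIndex), seq_len(nrow(rows))))
    stop("reconstruction-completeness error: row_index gaps ",
         "(document built from a filtered graph?)")
  KrakenReport(rows, totalReads = graph@totalReads)
}

#' @rdname sankeyNodes
setMethod("sankeyNodes", "SankeyGraph", function(x) x@nodes)

#' @rdname sankeyLinks
setMethod("sankeyLinks", "SankeyGraph", function(x) x@links)
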