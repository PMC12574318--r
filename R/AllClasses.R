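## Central S4 containers. Validity methods enforce the structural invariants
## each downstream operation relies on; constructors coerce to canonical
## column types so that serialization round trips compare `identical`.

#' TaxonomyTree: taxid-keyed parent/child structure
#'
#' Holds one taxonomy as a node table (`taxid`, `parent`, `rank`, `name`) plus
#' the root taxid. The graph must be a tree: taxids unique, every parent
#' present, the root (and only the root) its own parent, and all parent chains
#' terminating at the root. Rank strings are stored verbatim — NCBI, GTDB and
#' ICTV dumps disagree on rank vocabulary and normalization is a display
#' concern.
#'
#' @slot nodes data.frame with integer `taxid`, integer `parent`, character
#'   `rank`, character `name`.
#' @slot rootTaxid integer scalar, the root node's taxid.
#' @aliases TaxonomyTree-class
#' @exportClass TaxonomyTree
setClass("TaxonomyTree",
         representation(nodes = "data.frame", rootTaxid = "integer"))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  req <- c("taxid", "parent", "rank", "name")
  if (!all(req %in% names(nd)))
    return("nodes must have columns taxid, parent, rank, name")
  if (nrow(nd) == 0L) return("tree must contain at least the root node")
  if (anyDuplicated(nd$taxid)) return("duplicate taxid in tree")
  if (any(nd$taxid <= 0L)) return("taxids must be positive")
  if (length(object@rootTaxid) != 1L || !(object@rootTaxid %in% nd$taxid))
    return("rootTaxid must name a node in the tree")
  selfPar <- nd$taxid[nd$parent == nd$taxid]
  if (!identical(sort(selfPar), object@rootTaxid))
    return("exactly one node (the root) may be its own parent")
  missingPar <- setdiff(nd$parent, nd$taxid)
  if (length(missingPar))
    return(paste0("orphan parent reference(s): ",
                  paste(missingPar, collapse = ", ")))
  ## acyclicity: chase parents; every chain must reach the root within n steps
  pidx <- match(nd$parent, nd$taxid)
  cur <- seq_len(nrow(nd))
  for (step in seq_len(nrow(nd))) {
    atRoot <- nd$taxid[cur] == object@rootTaxid
    if (all(atRoot)) return(TRUE)
    cur <- ifelse(atRoot, cur, pidx[cur])
  }
  "cycle detected in parent links"
})

#' @describeIn TaxonomyTree-class Constructor; coerces column types and
#'   validates.
#' @param nodes data.frame of nodes (taxid, parent, rank, name).
#' @param rootTaxid root taxid; located automatically (the self-parent row)
#'   when `NULL`.
#' @export
TaxonomyTree <- function(nodes, rootTaxid = NULL) {
  nodes <- data.frame(taxid  = as.integer(nodes$taxid),
                      parent = as.integer(nodes$parent),
                      rank   = as.character(nodes$rank),
                      name   = as.character(nodes$name),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  if (is.null(rootTaxid)) {
    rootTaxid <- nodes$taxid[nodes$parent == nodes$taxid]
    if (length(rootTaxid) != 1L)
      stop("cannot locate a unique root (self-parent) node")
  }
  new("TaxonomyTree", nodes = nodes, rootTaxid = as.integer(rootTaxid))
}

#' @describeIn TaxonomyTree-class Compact display.
#' @param object a `TaxonomyTree`.
#' @export
setMethod("show", "TaxonomyTree", function(object) {
  cat("TaxonomyTree with", nrow(object@nodes), "nodes; root taxid",
      object@rootTaxid, "\n")
  rk <- table(object@nodes$rank)
  cat("  ranks:", paste0(names(rk), " (", as.integer(rk), ")",
                         collapse = ", "), "\n")
})

#' KrakenReport: a parsed Kraken-format taxonomy report
#'
#' Rows are stored exactly as read — `percentText` verbatim, counts, rank
#' code, taxid, un-indented name, indentation depth, original row index and
#' any extra trailing columns — so that [writeReport()] reproduces the file
#' byte-for-byte. Validity enforces the conservation law
#' `clade_reads = taxon_reads + sum(children clade_reads)` on every row and
#' the printed-percent consistency `|percent - 100*clade/total| <= 0.01`.
#'
#' @slot rows data.frame with columns percentText, percent, cladeReads,
#'   taxonReads, rankCode, taxid, name, depth, rowIndex, extra.
#' @slot totalReads numeric scalar: unclassified clade reads + root clade
#'   reads.
#' @aliases KrakenReport-class
#' @exportClass KrakenReport
setClass("KrakenReport",
         representation(rows = "data.frame", totalReads = "numeric"))

setValidity("KrakenReport", function(object) {
  msg <- tryCatch({
    .validateReportRows(object@rows, object@totalReads)
    TRUE
  }, error = function(e) conditionMessage(e))
  msg
})

#' @describeIn KrakenReport-class Constructor. `rows` must carry at least
#'   cladeReads, taxonReads, rankCode, taxid, name and depth; percent text,
#'   row indices and totals are synthesized when absent (percent formatted to
#'   two decimals, half away from zero).
#' @param rows report row data.frame.
#' @param totalReads total read count; computed from the depth-0 rows when
#'   `NULL`.
#' @export
KrakenReport <- function(rows, totalReads = NULL) {
  rows <- .normalizeReportRows(rows, totalReads)
  if (is.null(totalReads))
    totalReads <- sum(rows$cladeReads[rows$depth == 0L])
  new("KrakenReport", rows = rows, totalReads = as.numeric(totalReads))
}

#' @describeIn KrakenReport-class Compact display.
#' @param object a `KrakenReport`.
#' @export
setMethod("show", "KrakenReport", function(object) {
  cat("KrakenReport:", nrow(object@rows), "rows,", object@totalReads,
      "total reads\n")
  if (nrow(object@rows)) {
    top <- utils::head(object@rows, 5L)
    cat(paste0("  ", top$percentText, "\t", top$cladeReads, "\t",
               top$rankCode, "\t", top$taxid, "\t",
               strrep("  ", top$depth), top$name, collapse = "\n"), "\n")
    if (nrow(object@rows) > 5L) cat("  ...\n")
  }
})

#' SankeyFilters: filter specification for Sankey graphs
#'
#' Conjunction of a minimum clade proportion (percent of total reads), a
#' minimum clade read count, a per-rank cap on the number of taxa (most
#' abundant kept, ties broken by smaller taxid) and the set of rank codes to
#' display. Thresholds are applied first, the per-rank cap second.
#'
#' @slot minProportion numeric >= 0, percent of total reads.
#' @slot minCladeReads numeric >= 0.
#' @slot maxTaxaPerRank positive numeric, `Inf` = unlimited.
#' @slot ranksShown character; empty = all ladder ranks.
#' @aliases SankeyFilters-class
#' @exportClass SankeyFilters
setClass("SankeyFilters",
         representation(minProportion = "numeric", minCladeReads = "numeric",
                        maxTaxaPerRank = "numeric", ranksShown = "character"))

setValidity("SankeyFilters", function(object) {
  if (length(object@minProportion) != 1L || !is.finite(object@minProportion) ||
      object@minProportion < 0)
    return("minProportion must be a finite non-negative scalar")
  if (length(object@minCladeReads) != 1L || !is.finite(object@minCladeReads) ||
      object@minCladeReads < 0)
    return("minCladeReads must be a finite non-negative scalar")
  if (length(object@maxTaxaPerRank) != 1L || object@maxTaxaPerRank < 1)
    return("maxTaxaPerRank must be >= 1 (Inf for unlimited)")
  TRUE
})

#' @describeIn SankeyFilters-class Constructor with identity-filter defaults.
#' @param minProportion,minCladeReads,maxTaxaPerRank,ranksShown see slots.
#' @export
sankeyFilters <- function(minProportion = 0, minCladeReads = 0,
                          maxTaxaPerRank = Inf, ranksShown = character(0)) {
  new("SankeyFilters", minProportion = as.numeric(minProportion),
      minCladeReads = as.numeric(minCladeReads),
      maxTaxaPerRank = as.numeric(maxTaxaPerRank),
      ranksShown = as.character(ranksShown))
}

#' @describeIn SankeyFilters-class Compact display.
#' @param object a `SankeyFilters`.
#' @export
setMethod("show", "SankeyFilters", function(object) {
  cat("SankeyFilters: minProportion=", object@minProportion,
      "%, minCladeReads=", object@minCladeReads,
      ", maxTaxaPerRank=", object@maxTaxaPerRank,
      ", ranksShown=", if (length(object@ranksShown))
        paste(object@ranksShown, collapse = ",") else "<all>", "\n", sep = "")
})

#' SankeyGraph: layered Sankey view of a taxonomy report
#'
#' Nodes are report rows whose rank code's leading letter is on the configured
#' rank ladder; the layer is the ladder index. Each node's parent is its
#' nearest on-ladder report-tree ancestor at a strictly smaller layer, and
#' each link carries the target node's clade read count. Off-ladder rows are
#' retained verbatim in a side table so an unfiltered graph reconstructs its
#' source report exactly.
#'
#' @slot nodes data.frame: nodeId, taxid, name, rankCode, layer, proportion,
#'   cladeReads, taxonReads, parentNodeId, rowIndex, depth, percentText,
#'   extra. The synthetic root (if present) has `NA` taxid and layer -1.
#' @slot links data.frame: sourceNodeId, targetNodeId, value.
#' @slot rankLadder character, ordered rank codes.
#' @slot totalReads numeric scalar.
#' @slot offLadderRows data.frame of report rows not on the ladder.
#' @slot filters the [SankeyFilters-class] applied, or identity filters.
#' @slot filtered logical: `TRUE` once [applyFilters()] or [sankeySubtree()]
#'   has run (such graphs are no longer reconstructible).
#' @aliases SankeyGraph-class
#' @exportClass SankeyGraph
setClass("SankeyGraph",
         representation(nodes = "data.frame", links = "data.frame",
                        rankLadder = "character", totalReads = "numeric",
                        offLadderRows = "data.frame", filters = "SankeyFilters",
                        filtered = "logical"))

setValidity("SankeyGraph", function(object) {
  nd <- object@nodes; lk <- object@links
  if (nrow(lk)) {
    if (!all(lk$sourceNodeId %in% nd$nodeId) ||
        !all(lk$targetNodeId %in% nd$nodeId))
      return("link endpoint missing from node table")
    sl <- nd$layer[match(lk$sourceNodeId, nd$nodeId)]
    tl <- nd$layer[match(lk$targetNodeId, nd$nodeId)]
    if (any(sl >= tl)) return("link source layer must be below target layer")
    tv <- nd$cladeReads[match(lk$targetNodeId, nd$nodeId)]
    if (any(lk$value != tv))
      return("link value must equal target node clade reads")
  }
  if (anyDuplicated(nd$nodeId)) return("duplicate nodeId")
  par <- nd$parentNodeId
  bad <- !is.na(par) & !(par %in% nd$nodeId)
  if (any(bad)) return("parentNodeId missing from node table")
  TRUE
})

#' @describeIn SankeyGraph-class Compact display.
#' @param object a `SankeyGraph`.
#' @export
setMethod("show", "SankeyGraph", function(object) {
  cat("SankeyGraph:", nrow(object@nodes), "nodes,", nrow(object@links),
      "links; ladder", paste(object@rankLadder, collapse = ">"),
      "; total reads", object@totalReads,
      if (object@filtered) "(filtered)" else "(unfiltered)", "\n")
})

#' KmerList: sorted, deduplicated list of (k-mer key, species taxid) records
#'
#' The database primitive behind incremental updates: records sorted
#' ascending by (key, species taxid) with no duplicate pair. Keys are 2-bit
#' DNA encodings held exactly in doubles (k <= 26).
#'
#' @slot keys numeric vector of k-mer keys.
#' @slot taxids integer vector of species taxids, parallel to `keys`.
#' @slot k integer, the k-mer length the keys encode.
#' @aliases KmerList-class
#' @exportClass KmerList
setClass("KmerList",
         representation(keys = "numeric", taxids = "integer", k = "integer"))

setValidity("KmerList", function(object) {
  n <- length(object@keys)
  if (length(object@taxids) != n) return("keys and taxids lengths differ")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    return("k must be a positive integer scalar")
  if (object@k > 26L) return("k must be <= 26 (exact 2-bit keys in doubles)")
  if (n == 0L) return(TRUE)
  if (any(is.na(object@keys)) || any(object@keys < 0) ||
      any(object@keys != floor(object@keys)))
    return("keys must be non-negative integers")
  if (any(is.na(object@taxids)) || any(object@taxids <= 0L))
    return("taxids must be positive")
  if (n > 1L) {
    dk <- diff(object@keys)
    if (any(dk < 0)) return("keys not sorted ascending")
    same <- dk == 0
    if (any(same & diff(object@taxids) < 0L))
      return("taxids not sorted within equal keys")
    if (any(same & diff(object@taxids) == 0L))
      return("duplicate (key, taxid) record")
  }
  TRUE
})

#' @describeIn KmerList-class Constructor; sorts and deduplicates the given
#'   records.
#' @param keys numeric k-mer keys.
#' @param taxids integer species taxids.
#' @param k k-mer length.
#' @export
KmerList <- function(keys = numeric(0), taxids = integer(0), k) {
  keys <- as.numeric(keys); taxids <- as.integer(taxids)
  o <- order(keys, taxids)
  keys <- keys[o]; taxids <- taxids[o]
  dup <- if (length(keys) > 1L)
    c(FALSE, diff(keys) == 0 & diff(taxids) == 0L) else
    logical(length(keys))
  new("KmerList", keys = keys[!dup], taxids = taxids[!dup],
      k = as.integer(k))
}

#' @describeIn KmerList-class Compact display.
#' @param object a `KmerList`.
#' @export
setMethod("show", "KmerList", function(object) {
  cat("KmerList: ", length(object@keys), " records, k=", object@k, ", ",
      length(unique(object@taxids)), " species\n", sep = "")
})

#' @describeIn KmerList-class Number of records.
#' @param x a `KmerList`.
#' @export
setMethod("length", "KmerList", function(x) length(x@keys))
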