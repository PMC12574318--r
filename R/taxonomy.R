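## NCBI taxdump dialect: fields separated by "\t|\t", lines terminated "\t|".
## Only the columns needed are read (nodes: taxid, parent, rank; names: name
## rows of class "scientific name"); everything else is ignored.

.splitDumpLines <- function(lines) {
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Load an NCBI-style taxonomy dump
#'
#' Reads `nodes.dmp` (taxid, parent taxid, rank) and `names.dmp` (scientific
#' names only) into a [TaxonomyTree-class]. Nodes without a scientific name
#' get an empty name. Merged-id files are deliberately not consulted: a taxid
#' unknown to the dump fails lookup loudly downstream.
#'
#' @param nodesPath path to nodes.dmp.
#' @param namesPath path to names.dmp.
#' @return a [TaxonomyTree-class].
#' @export
loadTaxonomyDump <- function(nodesPath, namesPath) {
  nl <- readLines(nodesPath)
  parts <- .splitDumpLines(nl)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed nodes.dmp row at line ", bad[1L],
         ": fewer than 3 fields")
  taxidTxt  <- vapply(parts, `[[`, "", 1L)
  parentTxt <- vapply(parts, `[[`, "", 2L)
  rank      <- vapply(parts, `[[`, "", 3L)
  badInt <- which(!grepl("^[0-9]+$", taxidTxt) | !grepl("^[0-9]+$", parentTxt))
  if (length(badInt))
    stop("malformed nodes.dmp row at line ", badInt[1L],
         ": non-integer taxid or parent")
  taxid <- as.integer(taxidTxt); parent <- as.integer(parentTxt)

  orphan <- setdiff(parent, taxid)
  if (length(orphan))
    stop("orphan parent taxid(s) in nodes.dmp: ",
         paste(orphan, collapse = ", "))

  ml <- readLines(namesPath)
  nparts <- .splitDumpLines(ml)
  nbad <- which(lengths(nparts) < 4L)
  if (length(nbad))
    stop("malformed names.dmp row at line ", nbad[1L],
         ": fewer than 4 fields")
  nmTaxid <- vapply(nparts, `[[`, "", 1L)
  nmName  <- vapply(nparts, `[[`, "", 2L)
  nmClass <- vapply(nparts, `[[`, "", 4L)
  sci <- nmClass == "scientific name"
  nameMap <- setNames(nmName[sci], nmTaxid[sci])
  name <- nameMap[as.character(taxid)]
  name[is.na(name)] <- ""

  TaxonomyTree(data.frame(taxid = taxid, parent = parent, rank = rank,
                          name = unname(name), stringsAsFactors = FALSE))
}

#' Write a taxonomy as NCBI-style dump files
#'
#' Inverse of [loadTaxonomyDump()] for the columns this package reads; used
#' by the fixture generators and the k-mer database snapshot.
#'
#' @param tree a [TaxonomyTree-class].
#' @param nodesPath,namesPath output paths.
#' @return invisibly, the two paths.
#' @export
writeTaxonomyDump <- function(tree, nodesPath, namesPath) {
  nd <- tree@nodes
  writeLines(paste0(nd$taxid, "\t|\t", nd$parent, "\t|\t", nd$rank, "\t|"),
             nodesPath, useBytes = TRUE)
  writeLines(paste0(nd$taxid, "\t|\t", nd$name, "\t|\t\t|\tscientific name\t|"),
             namesPath, useBytes = TRUE)
  invisible(c(nodesPath, namesPath))
}

#' @rdname descendants
setMethod("descendants", "TaxonomyTree", function(tree, taxid) {
  nd <- tree@nodes
  taxid <- as.integer(taxid)
  if (length(taxid) != 1L || is.na(taxid) || !(taxid %in% nd$taxid))
    stop("unknown taxid: ", taxid)
  notRoot <- nd$taxid != tree@rootTaxid
  kids <- split(nd$taxid[notRoot], nd$parent[notRoot])
  out <- integer(0)
  frontier <- taxid
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
  }
  sort(out)
})

#' Build a taxonomy tree from report rows
#'
#' Recovers the hierarchy a Kraken-format report encodes through indentation:
#' each row's parent is the nearest preceding row at a smaller depth. The
#' "unclassified" pseudo-row (taxid 0) sits outside the hierarchy and is never
#' inserted. Rank codes are stored verbatim as the node rank.
#'
#' @param x a [KrakenReport-class] or a report-row data.frame.
#' @return a [TaxonomyTree-class].
#' @export
treeFromReport <- function(x) {
  rows <- if (is(x, "KrakenReport")) x@rows else x
  keep <- rows$taxid != 0L
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) stop("report contains no taxa")
  n <- nrow(rows)
  parent <- integer(n)
  stackTax <- integer(0)  # stackTax[d + 1] = taxid at depth d on current path
  for (i in seq_len(n)) {
    d <- rows$depth[i]
    if (i == 1L) {
      if (d != 0L)
        stop("first taxon row must be at depth 0 (row ", rows$rowIndex[i], ")")
      parent[i] <- rows$taxid[i]
    } else {
      if (d == 0L)
        stop("second root row at depth 0 (row ", rows$rowIndex[i], ")")
      if (d > length(stackTax))
        stop("indentation jump > 1 at row ", rows$rowIndex[i])
      parent[i] <- stackTax[d]
    }
    stackTax <- c(stackTax[seq_len(d)], rows$taxid[i])
  }
  TaxonomyTree(data.frame(taxid = rows$taxid, parent = parent,
                          rank = rows$rankCode, name = rows$name,
                          stringsAsFactors = FALSE),
               rootTaxid = rows$taxid[1L])
}

#' @rdname taxonomyNodes
setMethod("taxonomyNodes", "TaxonomyTree", function(x) x@nodes)

#' @rdname rootTaxid
setMethod("rootTaxid", "TaxonomyTree", function(x) x@rootTaxid)
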