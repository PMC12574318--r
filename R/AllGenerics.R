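#' Taxids of the clade rooted at a taxon
#'
#' Returns the taxon itself plus every node reachable by child links — the set
#' used both for taxon-specific read extraction and for subtree views.
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxid taxid present in the tree (error otherwise).
#' @return sorted integer vector of taxids.
#' @examples
#' tr <- TaxonomyTree(data.frame(taxid = c(1, 2, 3), parent = c(1, 1, 2),
#'                               rank = c("no rank", "genus", "species"),
#'                               name = c("root", "G", "S")))
#' descendants(tr, 2)  # 2 3
#' @export
setGeneric("descendants", function(tree, taxid) standardGeneric("descendants"))

#' Restrict a Sankey graph with thresholds and a per-rank cap
#'
#' @param graph a [SankeyGraph-class].
#' @param filters a [SankeyFilters-class].
#' @param ... further arguments for methods.
#' @return a filtered [SankeyGraph-class].
#' @export
setGeneric("applyFilters",
           function(graph, filters, ...) standardGeneric("applyFilters"))

## Accessors ------------------------------------------------------------

#' Report rows accessor
#' @param x a [KrakenReport-class] (or an object carrying report rows).
#' @return data.frame of report rows.
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))

#' Total read count accessor
#' @param x a [KrakenReport-class] or [SankeyGraph-class].
#' @return numeric scalar.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Sankey node table accessor
#' @param x a [SankeyGraph-class].
#' @return data.frame of nodes.
#' @export
setGeneric("sankeyNodes", function(x) standardGeneric("sankeyNodes"))

#' Sankey link table accessor
#' @param x a [SankeyGraph-class].
#' @return data.frame of links.
#' @export
setGeneric("sankeyLinks", function(x) standardGeneric("sankeyLinks"))

#' Taxonomy node table accessor
#' @param x a [TaxonomyTree-class].
#' @return data.frame of taxonomy nodes.
#' @export
setGeneric("taxonomyNodes", function(x) standardGeneric("taxonomyNodes"))

#' Root taxid accessor
#' @param x a [TaxonomyTree-class].
#' @return integer scalar.
#' @export
setGeneric("rootTaxid", function(x) standardGeneric("rootTaxid"))

#' K-mer record table accessor
#' @param x a [KmerList-class].
#' @return data.frame with columns kmerKey, speciesTaxid.
#' @export
setGeneric("kmerRecords", function(x) standardGeneric("kmerRecords"))
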