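## Kraken-format report: >= 6 tab-separated columns — percent, clade reads,
## taxon reads, rank code, taxid, name indented two spaces per level. Extra
## trailing columns are tolerated and carried opaquely so rewriting is
## byte-faithful.

## two decimals, half away from zero (kraken-report convention)
.fmtPercent <- function(p) {
  p[!is.finite(p)] <- 0
  sprintf("%.2f", floor(p * 100 + 0.5 + 1e-9) / 100)
}

.fmtCount <- function(x) sprintf("%.0f", x)

## Canonical row table; synthesizes percentText / percent / rowIndex / extra
## when absent (programmatic construction, e.g. fixtures).
.normalizeReportRows <- function(rows, totalReads = NULL) {
  req <- c("cladeReads", "taxonReads", "rankCode", "taxid", "name", "depth")
  miss <- setdiff(req, names(rows))
  if (length(miss))
    stop("report rows missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(rows)
  out <- data.frame(
    percentText = if ("percentText" %in% names(rows))
      as.character(rows$percentText) else rep(NA_character_, n),
    percent    = if ("percent" %in% names(rows))
      as.numeric(rows$percent) else rep(NA_real_, n),
    cladeReads = as.numeric(rows$cladeReads),
    taxonReads = as.numeric(rows$taxonReads),
    rankCode   = as.character(rows$rankCode),
    taxid      = as.integer(rows$taxid),
    name       = as.character(rows$name),
    depth      = as.integer(rows$depth),
    rowIndex   = if ("rowIndex" %in% names(rows))
      as.integer(rows$rowIndex) else seq_len(n),
    extra      = if ("extra" %in% names(rows))
      as.character(rows$extra) else rep(NA_character_, n),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (anyNA(out$percent)) {
    if (is.null(totalReads)) totalReads <- sum(out$cladeReads[out$depth == 0L])
    p <- if (totalReads > 0) 100 * out$cladeReads / totalReads else
      rep(0, n)
    out$percent[is.na(out$percent)] <- p[is.na(out$percent)]
  }
  na <- is.na(out$percentText)
  out$percentText[na] <- .fmtPercent(out$percent[na])
  out
}

## Full structural validation: types, ranges, depth discipline, conservation
## (clade = taxon + sum of immediate children's clades) and printed-percent
## consistency. Stops with an informative error; returns the parent row index
## vector invisibly.
.validateReportRows <- function(rows, totalReads) {
  n <- nrow(rows)
  if (n == 0L) return(invisible(integer(0)))
  if (any(rows$cladeReads < 0) || any(rows$taxonReads < 0))
    stop("negative read count at row ",
         rows$rowIndex[which(rows$cladeReads < 0 | rows$taxonReads < 0)[1L]])
  bad <- which(rows$cladeReads < rows$taxonReads)
  if (length(bad))
    stop("clade_reads < taxon_reads for taxid ", rows$taxid[bad[1L]],
         " (row ", rows$rowIndex[bad[1L]], ")")
  if (any(rows$percent < -1e-9 | rows$percent > 100 + 1e-9))
    stop("percent outside [0, 100] at row ",
         rows$rowIndex[which(rows$percent < -1e-9 |
                               rows$percent > 100 + 1e-9)[1L]])
  d0 <- which(rows$depth == 0L)
  if (length(which(rows$taxid[d0] != 0L)) > 1L)
    stop("more than one root row at depth 0")
  if (any(rows$depth > 0L & rows$taxid == 0L))
    stop("unclassified row (taxid 0) must be at depth 0")

  ## conservation via an indentation stack over taxon rows
  parentOf <- rep(NA_integer_, n)      # index of parent row
  stackIdx <- integer(0)
  for (i in seq_len(n)) {
    if (rows$taxid[i] == 0L) next      # unclassified: outside the hierarchy
    d <- rows$depth[i]
    if (d > length(stackIdx))
      stop("indentation jump > 1 at row ", rows$rowIndex[i])
    if (d > 0L) parentOf[i] <- stackIdx[d]
    stackIdx <- c(stackIdx[seq_len(d)], i)
  }
  childSum <- rep(0, n)
  hasPar <- !is.na(parentOf)
  if (any(hasPar)) {
    agg <- tapply(rows$cladeReads[hasPar], parentOf[hasPar], sum)
    childSum[as.integer(names(agg))] <- as.numeric(agg)
  }
  taxonRows <- rows$taxid != 0L
  viol <- which(taxonRows &
                  rows$cladeReads != rows$taxonReads + childSum)
  if (length(viol))
    stop("conservation violated for taxid ", rows$taxid[viol[1L]],
         ": clade_reads ", rows$cladeReads[viol[1L]], " != taxon_reads ",
         rows$taxonReads[viol[1L]], " + children ", childSum[viol[1L]])

  if (totalReads > 0) {
    expect <- 100 * rows$cladeReads / totalReads
    off <- which(abs(rows$percent - expect) > 0.01 + 1e-9)
    if (length(off))
      stop("percent column inconsistent with clade_reads/total for taxid ",
           rows$taxid[off[1L]])
  }
  invisible(parentOf)
}

#' Read a Kraken-format taxonomy report
#'
#' Parses, validates (count sanity, indentation discipline, the conservation
#' law clade = taxon + sum of children, printed-percent consistency) and
#' returns a [KrakenReport-class]. Extra trailing columns are preserved
#' opaquely; [writeReport()] reproduces the file byte-for-byte.
#'
#' @param path report file path.
#' @return a [KrakenReport-class].
#' @export
readReport <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(new("KrakenReport", rows = .normalizeReportRows(
      data.frame(cladeReads = numeric(0), taxonReads = numeric(0),
                 rankCode = character(0), taxid = integer(0),
                 name = character(0), depth = integer(0))),
      totalReads = 0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 6L)
  if (length(short))
    stop("line ", short[1L], ": fewer than 6 tab-separated columns")
  col <- function(i) vapply(parts, `[[`, "", i)
  percentText <- col(1L); cladeTxt <- col(2L); taxonTxt <- col(3L)
  rankCode <- col(4L); taxidTxt <- col(5L); nameField <- col(6L)
  extra <- vapply(parts, function(p)
    if (length(p) > 6L) paste(p[-(1:6)], collapse = "\t") else NA_character_,
    "")

  badCnt <- which(!grepl("^[0-9]+$", cladeTxt) | !grepl("^[0-9]+$", taxonTxt))
  if (length(badCnt))
    stop("line ", badCnt[1L], ": non-integer or negative read count")
  badTax <- which(!grepl("^[0-9]+$", taxidTxt))
  if (length(badTax))
    stop("line ", badTax[1L], ": non-integer taxid")
  percent <- suppressWarnings(as.numeric(percentText))
  if (anyNA(percent))
    stop("line ", which(is.na(percent))[1L], ": non-numeric percent")

  indent <- attr(regexpr("^ *", nameField), "match.length")
  odd <- which(indent %% 2L != 0L)
  if (length(odd))
    stop("line ", odd[1L], ": odd indentation (not a multiple of 2 spaces)")
  rows <- data.frame(percentText = percentText, percent = percent,
                     cladeReads = as.numeric(cladeTxt),
                     taxonReads = as.numeric(taxonTxt),
                     rankCode = rankCode, taxid = as.integer(taxidTxt),
                     name = substring(nameField, indent + 1L),
                     depth = as.integer(indent %/% 2L),
                     rowIndex = seq_along(lines), extra = extra,
                     stringsAsFactors = FALSE)
  totalReads <- sum(rows$cladeReads[rows$depth == 0L])
  new("KrakenReport", rows = rows, totalReads = totalReads)
}

#' Write a Kraken-format taxonomy report
#'
#' Emits rows in original row order with the percent column verbatim
#' (`percentText`) and names indented two spaces per depth level, so that
#' `readReport(writeReport(r))` is the identity and the rewritten file is
#' byte-identical to its source.
#'
#' @param report a [KrakenReport-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  r <- report@rows[order(report@rows$rowIndex), , drop = FALSE]
  lines <- paste(r$percentText, .fmtCount(r$cladeReads),
                 .fmtCount(r$taxonReads), r$rankCode, r$taxid,
                 paste0(strrep("  ", r$depth), r$name), sep = "\t")
  hasExtra <- !is.na(r$extra)
  lines[hasExtra] <- paste(lines[hasExtra], r$extra[hasExtra], sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter report rows by rank code
#'
#' Keeps rows whose rank code's leading letter is in `ranks` (so Kraken's
#' digit-suffixed codes such as "S1" follow their base rank), preserving the
#' original order — the operation behind the rank filter of the result table.
#'
#' @param report a [KrakenReport-class].
#' @param ranks character vector of single-letter rank codes, e.g.
#'   `c("P", "C")`.
#' @return data.frame of the matching rows.
#' @export
filterRowsByRank <- function(report, ranks) {
  rows <- report@rows
  rows[substr(rows$rankCode, 1L, 1L) %in% ranks, , drop = FALSE]
}

#' @rdname reportRows
setMethod("reportRows", "KrakenReport", function(x) x@rows)

#' @rdname totalReads
setMethod("totalReads", "KrakenReport", function(x) x@totalReads)

#' @rdname totalReads
setMethod("totalReads", "SankeyGraph", function(x) x@totalReads)
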