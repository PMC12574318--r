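## Taxon-specific read extraction. Read identity is positional: the i-th
## classification line describes the i-th read (pair), so extraction collects
## line numbers of matching classifications and copies those records verbatim
## — format, multi-line FASTA layout and gzip compression all mirror the
## input. Read ids are used only for diagnostics.

#' Read a per-read classification file
#'
#' TSV dialect: column 1 = classified flag (0/1), column 2 = read id,
#' column 3 = assigned taxid (0 when unclassified); extra columns ignored.
#' One line per read — per pair in paired mode — in read-file order.
#'
#' @param path classification file path.
#' @return data.frame with isClassified (logical), readId, taxid,
#'   lineNumber.
#' @export
readClassifications <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(isClassified = logical(0), readId = character(0),
                      taxid = integer(0), lineNumber = integer(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("classification line ", short[1L], ": fewer than 3 columns")
  flagTxt <- vapply(parts, `[[`, "", 1L)
  readId <- vapply(parts, `[[`, "", 2L)
  taxidTxt <- vapply(parts, `[[`, "", 3L)
  badFlag <- which(!flagTxt %in% c("0", "1"))
  if (length(badFlag))
    stop("classification line ", badFlag[1L],
         ": classified flag must be 0 or 1")
  badTax <- which(!grepl("^[0-9]+$", taxidTxt))
  if (length(badTax))
    stop("classification line ", badTax[1L], ": non-integer taxid")
  flag <- flagTxt == "1"
  taxid <- as.integer(taxidTxt)
  mismatch <- which(flag != (taxid != 0L))
  if (length(mismatch))
    stop("classification line ", mismatch[1L],
         ": classified flag and taxid disagree (taxid 0 iff unclassified)")
  data.frame(isClassified = flag, readId = readId, taxid = taxid,
             lineNumber = seq_along(lines), stringsAsFactors = FALSE)
}

#' Line numbers of reads classified under a taxon or its descendants
#'
#' @param records data.frame from [readClassifications()].
#' @param tree a [TaxonomyTree-class].
#' @param target taxid present in the tree.
#' @return ascending integer vector of matching line numbers.
#' @export
matchingLines <- function(records, tree, target) {
  clade <- descendants(tree, target)
  sort(records$lineNumber[records$taxid %in% clade])
}

## ---- verbatim FASTA/FASTQ record handling ----------------------------

## Splits a read file into per-record character vectors of its original
## lines. FASTQ records are 4-line; FASTA records start at '>' and may be
## multi-line.
.readSeqRecords <- function(path) {
  gz <- .isGzFile(path)
  con <- if (gz) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L)
    return(list(records = list(), format = "empty", gz = gz))
  first <- substr(lines[1L], 1L, 1L)
  if (first == "@") {
    if (length(lines) %% 4L != 0L)
      stop("FASTQ file ", path, ": line count not a multiple of 4")
    grp <- rep(seq_len(length(lines) %/% 4L), each = 4L)
    list(records = split(lines, grp), format = "fastq", gz = gz)
  } else if (first == ">") {
    starts <- grepl("^>", lines)
    grp <- cumsum(starts)
    if (grp[1L] == 0L) stop("FASTA file ", path, ": leading junk before '>'")
    list(records = split(lines, grp), format = "fasta", gz = gz)
  } else {
    stop("cannot detect read format of ", path,
         " (first character neither '@' nor '>')")
  }
}

.writeSeqRecords <- function(records, path, gz) {
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(records))
    writeLines(unlist(records, use.names = FALSE), con, useBytes = TRUE)
  invisible(path)
}

## output path mirroring the input's extension and compression
.extractOutPath <- function(inPath, outPrefix, mate = 0L) {
  base <- basename(inPath)
  gz <- grepl("\\.gz$", base, ignore.case = TRUE)
  if (gz) base <- sub("\\.gz$", "", base, ignore.case = TRUE)
  ext <- tools::file_ext(base)
  if (ext == "") ext <- "fa"
  paste0(outPrefix, if (mate > 0L) paste0("_", mate), ".", ext,
         if (gz) ".gz")
}

#' Extract reads by classification line number
#'
#' Copies the records at the given (1-based) line numbers from one read file
#' — or from both mates of a pair — to new files, verbatim and in original
#' order. Output format and gzip compression mirror the input; in paired
#' mode, line `i` selects the i-th pair and both mates are written to
#' mate-specific outputs.
#'
#' @param reads path of the read file (FASTA/FASTQ, optionally gzipped).
#' @param lines ascending integer vector of record ordinals to extract.
#' @param outPrefix output path prefix.
#' @param reads2 optional mate-2 file for paired-end data.
#' @return list with `matchedLineNumbers`, `readsWritten` (named per output
#'   file) and `files`.
#' @export
extractReads <- function(reads, lines, outPrefix, reads2 = NULL) {
  lines <- as.integer(lines)
  if (is.unsorted(lines, strictly = TRUE))
    stop("line numbers must be strictly increasing")
  paired <- !is.null(reads2)
  r1 <- .readSeqRecords(reads)
  n1 <- length(r1$records)
  if (length(lines) && max(lines) > n1)
    stop("classification/read file mismatch: line ", max(lines),
         " requested but ", reads, " has ", n1, " records")
  if (paired) {
    r2 <- .readSeqRecords(reads2)
    if (length(r2$records) != n1)
      stop("pairing error: ", reads, " has ", n1, " records but ", reads2,
           " has ", length(r2$records))
  }
  out1 <- .extractOutPath(reads, outPrefix, mate = if (paired) 1L else 0L)
  .writeSeqRecords(r1$records[lines], out1, r1$gz)
  files <- out1
  counts <- setNames(length(lines), out1)
  if (paired) {
    out2 <- .extractOutPath(reads2, outPrefix, mate = 2L)
    .writeSeqRecords(r2$records[lines], out2, r2$gz)
    files <- c(files, out2)
    counts <- c(counts, setNames(length(lines), out2))
  }
  list(matchedLineNumbers = lines, readsWritten = counts, files = files)
}

#' One-call taxon-specific extraction
#'
#' Convenience wrapper: scans the classification file, selects reads
#' classified under `taxid` or its descendants, and extracts them.
#'
#' @param classifications classification TSV path.
#' @param tree a [TaxonomyTree-class].
#' @param taxid target taxid.
#' @param reads,reads2 read file(s).
#' @param outPrefix output path prefix.
#' @return as [extractReads()].
#' @export
extractTaxon <- function(classifications, tree, taxid, reads, outPrefix,
                         reads2 = NULL) {
  records <- readClassifications(classifications)
  lines <- matchingLines(records, tree, taxid)
  extractReads(reads, lines, outPrefix, reads2 = reads2)
}
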