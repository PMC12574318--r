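## Incremental k-mer database model. A database is a sorted, species-
## deduplicated list of (k-mer key, species taxid) records plus a taxonomy
## snapshot; updating it merges the sorted list built from new sequences into
## the existing one without ever touching the original genome files. Keys
## are plain 2-bit DNA encodings (A=0, C=1, G=2, T=3) at fixed k — the merge
## is encoding-agnostic, so correctness transfers to richer key types.

.BASE_CODES <- c(A = 0, C = 1, G = 2, T = 3)

## rolling 2-bit encoding of all k-windows of one sequence; windows touching
## a non-ACGT character are skipped
.encodeWindows <- function(seq, k) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  codes <- unname(.BASE_CODES[chars])
  if (L < k)
    return(list(key = numeric(0), valid = logical(0), codes = codes,
                nwin = 0L))
  nwin <- L - k + 1L
  key <- numeric(nwin)
  valid <- rep(TRUE, nwin)
  for (j in 0:(k - 1L)) {
    cj <- codes[(1L + j):(nwin + j)]
    bad <- is.na(cj)
    valid <- valid & !bad
    cj[bad] <- 0
    key <- key * 4 + cj
  }
  list(key = key, valid = valid, codes = codes, nwin = nwin)
}

#' Build a sorted k-mer list from sequences
#'
#' Encodes every k-length window of each sequence as a 2-bit integer key
#' (windows containing a non-ACGT character are skipped), tags it with the
#' record's species taxid, sorts ascending by (key, taxid) and removes
#' duplicate (key, taxid) pairs. With `canonical = TRUE` each window is
#' replaced by the smaller of its forward and reverse-complement keys.
#'
#' @param sequences character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param taxids integer species taxids, one per sequence (recycled if
#'   length 1).
#' @param k k-mer length, 1..26 (default 12).
#' @param canonical canonicalize strand? Default `FALSE` (forward only).
#' @return a [KmerList-class].
#' @export
buildKmerList <- function(sequences, taxids, k = 12L, canonical = FALSE) {
  k <- as.integer(k)
  if (k < 1L || k > 26L) stop("k must be in 1..26")
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  taxids <- as.integer(rep_len(taxids, length(sequences)))
  keys <- vector("list", length(sequences))
  taxs <- vector("list", length(sequences))
  for (s in seq_along(sequences)) {
    enc <- .encodeWindows(sequences[[s]], k)
    if (length(enc$key) == 0L) next
    kk <- enc$key[enc$valid]
    if (canonical && length(kk)) {
      rcCodes <- rev(3 - enc$codes)
      nwin <- enc$nwin
      rcKeyAll <- numeric(nwin)
      for (j in 0:(k - 1L)) {
        cj <- rcCodes[(1L + j):(nwin + j)]
        cj[is.na(cj)] <- 0
        rcKeyAll <- rcKeyAll * 4 + cj
      }
      ## window i on the forward strand is window nwin - i + 1 in the
      ## reversed complement
      rcKey <- rev(rcKeyAll)[enc$valid]
      kk <- pmin(kk, rcKey)
    }
    keys[[s]] <- kk
    taxs[[s]] <- rep(taxids[s], length(kk))
  }
  KmerList(unlist(keys) %||% numeric(0),
           unlist(taxs) %||% integer(0), k = k)
}

#' Merge two sorted k-mer lists
#'
#' Single-pass streaming two-way merge: the output is sorted, records
#' identical in (key, species taxid) collapse to one, and equal keys from
#' different species are all retained. The concatenation of the inputs is
#' never materialized; unsorted input is detected during the pass and
#' reported with its record position.
#'
#' @param existing,incoming [KmerList-class] objects with equal `k`.
#' @return the merged [KmerList-class].
#' @export
mergeKmerLists <- function(existing, incoming) {
  stopifnot(is(existing, "KmerList"), is(incoming, "KmerList"))
  if (existing@k != incoming@k)
    stop("cannot merge k-mer lists with different k (",
         existing@k, " vs ", incoming@k, ")")
  m <- .mergeKmerRuns(existing@keys, existing@taxids,
                      incoming@keys, incoming@taxids)
  new("KmerList", keys = m$keys, taxids = m$taxids, k = existing@k)
}

#' @rdname kmerRecords
setMethod("kmerRecords", "KmerList", function(x)
  data.frame(kmerKey = x@keys, speciesTaxid = x@taxids,
             stringsAsFactors = FALSE))

## ---- on-disk formats -------------------------------------------------

## binary: little-endian fixed-width records — 8-byte unsigned key stored as
## two 4-byte halves (low, high), then 4-byte taxid — plus a JSON sidecar
## header carrying k, record count and format version.

.KMER_FORMAT_VERSION <- 1L

.u32ToInt <- function(x) as.integer(x - ifelse(x >= 2^31, 2^32, 0))
.intToU32 <- function(x) {
  x <- as.numeric(x)
  x + ifelse(x < 0, 2^32, 0)
}

#' Write a k-mer list to disk
#'
#' `format = "bin"`: little-endian fixed-width records (8-byte unsigned key,
#' 4-byte taxid) with a JSON sidecar header at `<path>.json` recording k,
#' count and version. `format = "tsv"`: two-column debug text
#' (kmer_key, species_taxid) with a header line.
#'
#' @param x a [KmerList-class].
#' @param path output path.
#' @param format "bin" (default) or "tsv".
#' @return invisibly, `path`.
#' @export
writeKmerList <- function(x, path, format = c("bin", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(c("kmer_key\tspecies_taxid",
                 sprintf("%.0f\t%d", x@keys, x@taxids)), path,
               useBytes = TRUE)
    return(invisible(path))
  }
  lo <- .u32ToInt(x@keys %% 2^32)
  hi <- .u32ToInt(x@keys %/% 2^32)
  n <- length(x@keys)
  buf <- integer(3L * n)
  if (n) {
    buf[seq(1L, by = 3L, length.out = n)] <- lo
    buf[seq(2L, by = 3L, length.out = n)] <- hi
    buf[seq(3L, by = 3L, length.out = n)] <- x@taxids
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(buf, con, size = 4L, endian = "little")
  jsonlite::write_json(list(format = "taxokit-kmerlist",
                            version = .KMER_FORMAT_VERSION,
                            k = x@k, count = n),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a k-mer list from disk
#'
#' @param path path written by [writeKmerList()].
#' @param format "bin" (default) or "tsv".
#' @param k k-mer length; required for "tsv", read from the sidecar for
#'   "bin".
#' @return a [KmerList-class].
#' @export
readKmerList <- function(path, format = c("bin", "tsv"), k = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(k)) stop("k is required when reading the TSV format")
    tab <- read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("numeric", "integer"))
    return(new("KmerList", keys = tab$kmer_key,
               taxids = as.integer(tab$species_taxid), k = as.integer(k)))
  }
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$format, "taxokit-kmerlist"))
    stop("not a taxokit k-mer list: ", path)
  n <- as.integer(hdr$count)
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "integer", n = 3L * n, size = 4L, endian = "little")
  if (length(buf) != 3L * n)
    stop("truncated k-mer list: expected ", n, " records in ", path)
  lo <- .intToU32(buf[seq(1L, by = 3L, length.out = n)])
  hi <- .intToU32(buf[seq(2L, by = 3L, length.out = n)])
  new("KmerList", keys = hi * 2^32 + lo,
      taxids = buf[seq(3L, by = 3L, length.out = n)],
      k = as.integer(hdr$k))
}

## ---- database directory ----------------------------------------------

#' Write a k-mer database directory
#'
#' Layout: `kmers.bin` (+ `kmers.bin.json` header) and a taxonomy snapshot
#' as `nodes.dmp` / `names.dmp`.
#'
#' @param dir database directory (created if needed).
#' @param kmers a [KmerList-class].
#' @param taxonomy a [TaxonomyTree-class].
#' @return invisibly, `dir`.
#' @export
writeKmerDb <- function(dir, kmers, taxonomy) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeKmerList(kmers, file.path(dir, "kmers.bin"))
  writeTaxonomyDump(taxonomy, file.path(dir, "nodes.dmp"),
                    file.path(dir, "names.dmp"))
  invisible(dir)
}

#' Read a k-mer database directory
#'
#' @param dir directory written by [writeKmerDb()].
#' @return list with elements `kmers` ([KmerList-class]) and `taxonomy`
#'   ([TaxonomyTree-class]).
#' @export
readKmerDb <- function(dir) {
  list(kmers = readKmerList(file.path(dir, "kmers.bin")),
       taxonomy = loadTaxonomyDump(file.path(dir, "nodes.dmp"),
                                   file.path(dir, "names.dmp")))
}

.insertNewTaxa <- function(tree, newTaxa) {
  nd <- tree@nodes
  for (i in seq_len(nrow(newTaxa))) {
    tid <- as.integer(newTaxa$taxid[i])
    par <- as.integer(newTaxa$parent[i])
    at <- match(tid, nd$taxid)
    if (!is.na(at)) {
      if (nd$rank[at] != newTaxa$rank[i] || nd$name[at] != newTaxa$name[i])
        stop("taxid ", tid, " already present with different rank/name")
      next
    }
    if (!(par %in% nd$taxid))
      stop("new taxon ", tid, " names unknown parent ", par)
    nd <- rbind(nd, data.frame(taxid = tid, parent = par,
                               rank = as.character(newTaxa$rank[i]),
                               name = as.character(newTaxa$name[i]),
                               stringsAsFactors = FALSE))
  }
  TaxonomyTree(nd, rootTaxid = tree@rootTaxid)
}

#' Incrementally update a k-mer database with new sequences
#'
#' Builds a sorted k-mer list from the new sequences (the original database
#' sequences are never consulted), merges it into the existing list with
#' species-level deduplication, optionally extends the taxonomy with new
#' taxa, and writes the updated database.
#'
#' @param dbDir existing database directory ([writeKmerDb()] layout).
#' @param fasta path of a FASTA file with the new sequences.
#' @param taxidMap two-column TSV path or data.frame mapping sequence id
#'   (first whitespace token of the FASTA header) to species taxid.
#' @param newTaxa optional data.frame / TSV path with columns taxid, parent,
#'   rank, name to insert into the taxonomy.
#' @param outDir output directory; defaults to updating `dbDir` in place.
#' @param canonical passed to [buildKmerList()].
#' @return invisibly, the output directory.
#' @export
updateDatabase <- function(dbDir, fasta, taxidMap, newTaxa = NULL,
                           outDir = dbDir, canonical = FALSE) {
  db <- readKmerDb(dbDir)
  taxonomy <- db$taxonomy
  if (!is.null(newTaxa)) {
    if (is.character(newTaxa))
      newTaxa <- read.table(newTaxa, header = FALSE, sep = "\t",
                            col.names = c("taxid", "parent", "rank", "name"),
                            colClasses = c("integer", "integer",
                                           "character", "character"))
    taxonomy <- .insertNewTaxa(taxonomy, newTaxa)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.character(taxidMap))
    taxidMap <- read.table(taxidMap, header = FALSE, sep = "\t",
                           col.names = c("id", "taxid"),
                           colClasses = c("character", "integer"))
  tax <- taxidMap$taxid[match(ids, taxidMap$id)]
  if (anyNA(tax))
    stop("no taxid mapping for sequence(s): ",
         paste(utils::head(ids[is.na(tax)], 3L), collapse = ", "))
  unknown <- setdiff(tax, taxonomy@nodes$taxid)
  if (length(unknown))
    stop("species taxid(s) absent from the taxonomy: ",
         paste(unknown, collapse = ", "),
         " (add them via newTaxa)")
  incoming <- buildKmerList(as.character(seqs), tax, k = db$kmers@k,
                            canonical = canonical)
  merged <- mergeKmerLists(db$kmers, incoming)
  writeKmerDb(outDir, merged, taxonomy)
  invisible(outDir)
}
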