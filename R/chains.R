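## Assembly of co-linear k-mer match chains. A match is a (query codon
## position, diagonal) pair with two integer scores: `fullScore`, the score
## of the match taken alone, and `extScore`, the score contributed by the one
## additional codon when the match extends a consecutive predecessor.
## Two matches are consecutive exactly when the second sits one codon to the
## right on the same diagonal. Coordinates are codon-indexed, 0-based,
## closed intervals.
##
## Two implementations are provided: the reference graph + depth-first-search
## method (two scans: build the digraph of consecutive pairs, then search the
## best path from every source node) and the replacement single-pass
## algorithm that connects each match at position n+1 to the best-scoring
## consecutive chain ending at n, carrying the chain start forward. Their
## outputs are required to be identical.

#' Construct and validate a match list
#'
#' @param queryPos non-negative integer codon positions on the read.
#' @param diagonal integer diagonals (query position minus subject
#'   position; equal diagonals mean co-linear placement).
#' @param fullScore integer score of each match taken alone.
#' @param extScore integer score of the one codon a match adds when it
#'   extends a consecutive predecessor; `fullScore >= extScore >= 0`.
#' @return data.frame sorted by `queryPos`, unique on (queryPos, diagonal).
#' @export
matchList <- function(queryPos, diagonal, fullScore, extScore) {
  m <- data.frame(queryPos = as.integer(queryPos),
                  diagonal = as.integer(diagonal),
                  fullScore = as.integer(fullScore),
                  extScore = as.integer(extScore))
  m <- m[order(m$queryPos), , drop = FALSE]
  rownames(m) <- NULL
  .validateMatchList(m)
  m
}

.validateMatchList <- function(m) {
  if (nrow(m) == 0L) return(invisible(m))
  if (is.unsorted(m$queryPos))
    stop("match list not sorted by query position")
  if (any(m$queryPos < 0L)) stop("negative query position")
  if (any(m$extScore < 0L) || any(m$fullScore < m$extScore))
    stop("scores must satisfy fullScore >= extScore >= 0")
  if (anyDuplicated(m[, c("queryPos", "diagonal")]))
    stop("duplicate (queryPos, diagonal) match")
  invisible(m)
}

#' Are two matches consecutive?
#'
#' True iff `b` is one codon to the right of `a` on the same diagonal.
#'
#' @param a,b single matches (one-row data.frames or lists with `queryPos`
#'   and `diagonal`).
#' @return logical scalar.
#' @export
consecutiveMatches <- function(a, b) {
  isTRUE(b$queryPos == a$queryPos + 1L && b$diagonal == a$diagonal)
}

.sortChains <- function(ch) {
  ch <- ch[order(-ch$score, ch$startPos, ch$endPos), , drop = FALSE]
  rownames(ch) <- NULL
  ch
}

.emptyChains <- function() data.frame(startPos = integer(0),
                                      endPos = integer(0),
                                      score = integer(0))

#' Reference chain assembly: digraph + depth-first search
#'
#' The prior method, kept as the correctness oracle: one scan builds a
#' directed graph with matches as nodes and edges linking consecutive ones;
#' a second scan runs a depth-first search from every source node (no
#' incoming edge) and reports the highest-scoring path to a terminal node.
#' A path scores its first match's `fullScore` plus the `extScore` of every
#' subsequent match.
#'
#' @param matches a match list ([matchList()]), sorted by query position.
#' @return data.frame of chains (startPos, endPos, score), sorted by score
#'   descending (ties: smaller start, then end).
#' @export
assembleChainsOracle <- function(matches) {
  m <- .validateMatchList(matches)
  n <- nrow(m)
  if (n == 0L) return(.emptyChains())
  ## scan 1: adjacency of consecutive pairs
  key <- paste(m$queryPos, m$diagonal)
  succKey <- paste(m$queryPos + 1L, m$diagonal)
  succ <- lapply(succKey, function(k) which(key == k))
  hasPred <- logical(n)
  for (i in seq_len(n)) hasPred[succ[[i]]] <- TRUE
  ## scan 2: DFS from each source, best path to a terminal
  best <- vector("list", n)
  dfs <- function(i, score, start) {
    nxt <- succ[[i]]
    if (length(nxt) == 0L) {
      cand <- c(start, m$queryPos[i], score)
      if (is.null(best[[src]]) || score > best[[src]][3L] ||
          (score == best[[src]][3L] && m$queryPos[i] < best[[src]][2L]))
        best[[src]] <<- cand
      return(invisible(NULL))
    }
    for (j in nxt) dfs(j, score + m$extScore[j], start)
  }
  src <- 0L
  for (i in which(!hasPred)) {
    src <- i
    dfs(i, m$fullScore[i], m$queryPos[i])
  }
  keep <- !vapply(best, is.null, TRUE)
  ch <- do.call(rbind, best[keep])
  .sortChains(data.frame(startPos = as.integer(ch[, 1L]),
                         endPos = as.integer(ch[, 2L]),
                         score = as.integer(ch[, 3L])))
}

#' Single-pass chain assembly
#'
#' The cache-friendly replacement: scans the sorted match list once,
#' maintaining per diagonal the best open chain ending at the previous query
#' position. A match with a consecutive predecessor takes the predecessor
#' chain's score plus its own `extScore` and inherits the chain's start
#' position; a match without one opens a new chain at its own `fullScore`.
#' Chains with no consecutive successor terminate and are emitted. The
#' output is identical — same (start, end, score) multiset — to
#' [assembleChainsOracle()].
#'
#' @param matches a match list ([matchList()]), sorted by query position
#'   (error otherwise).
#' @param countVisits when `TRUE`, attach the number of match inspections as
#'   attribute `"visits"` (equals the list length: each match is visited
#'   once).
#' @return data.frame of chains (startPos, endPos, score), sorted by score
#'   descending (ties: smaller start, then end).
#' @export
assembleChains <- function(matches, countVisits = FALSE) {
  m <- .validateMatchList(matches)
  n <- nrow(m)
  if (n == 0L) {
    out <- .emptyChains()
    if (countVisits) attr(out, "visits") <- 0L
    return(out)
  }
  ## open chains keyed by diagonal: start, score, end position
  openDiag <- integer(0); openStart <- integer(0)
  openScore <- integer(0); openEnd <- integer(0)
  outStart <- integer(0); outEnd <- integer(0); outScore <- integer(0)
  emit <- function(sel) {
    outStart <<- c(outStart, openStart[sel])
    outEnd <<- c(outEnd, openEnd[sel])
    outScore <<- c(outScore, openScore[sel])
  }
  visits <- 0L
  i <- 1L
  while (i <= n) {
    q <- m$queryPos[i]
    ## chains that can no longer be extended (end < q - 1) terminate
    dead <- openEnd < q - 1L
    if (any(dead)) {
      emit(dead)
      openDiag <- openDiag[!dead]; openStart <- openStart[!dead]
      openScore <- openScore[!dead]; openEnd <- openEnd[!dead]
    }
    ## all matches at position q
    j <- i
    while (j <= n && m$queryPos[j] == q) j <- j + 1L
    idx <- i:(j - 1L)
    visits <- visits + length(idx)
    extended <- logical(length(openDiag))
    newDiag <- m$diagonal[idx]
    newStart <- integer(length(idx)); newScore <- integer(length(idx))
    for (t in seq_along(idx)) {
      at <- match(newDiag[t], openDiag)
      if (!is.na(at) && openEnd[at] == q - 1L) {
        newScore[t] <- openScore[at] + m$extScore[idx[t]]
        newStart[t] <- openStart[at]
        extended[at] <- TRUE
      } else {
        newScore[t] <- m$fullScore[idx[t]]
        newStart[t] <- q
      }
    }
    ## chains ending at q - 1 with no successor at q terminate
    stale <- !extended & openEnd == q - 1L
    if (any(stale)) emit(stale)
    keepOpen <- !stale & !extended
    openDiag <- c(openDiag[keepOpen], newDiag)
    openStart <- c(openStart[keepOpen], newStart)
    openScore <- c(openScore[keepOpen], newScore)
    openEnd <- c(openEnd[keepOpen], rep(q, length(idx)))
    i <- j
  }
  if (length(openDiag)) emit(rep(TRUE, length(openDiag)))
  out <- .sortChains(data.frame(startPos = outStart, endPos = outEnd,
                                score = outScore))
  if (countVisits) attr(out, "visits") <- visits
  out
}

#' Select the highest-scoring non-overlapping chains
#'
#' Sorts chains by score descending (ties: smaller start, then smaller end)
#' and greedily accepts each chain whose closed codon interval
#' `[startPos, endPos]` does not overlap an already-accepted one — the
#' selection that maximizes the score of the covered read region.
#'
#' @param chains data.frame of chains (startPos, endPos, score).
#' @return accepted chains, in acceptance order.
#' @export
selectBestChains <- function(chains) {
  if (nrow(chains) == 0L) return(.emptyChains())
  ch <- .sortChains(chains)
  accS <- integer(0); accE <- integer(0)
  keep <- logical(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    if (!any(ch$startPos[i] <= accE & ch$endPos[i] >= accS)) {
      keep[i] <- TRUE
      accS <- c(accS, ch$startPos[i]); accE <- c(accE, ch$endPos[i])
    }
  }
  out <- ch[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- debug TSV formats ------------------------------------------------

#' Read / write match-list debug TSV
#'
#' Four columns: query_pos, diagonal, full_score, ext_score (with header).
#'
#' @param path TSV path.
#' @return [readMatchList()]: a match list data.frame.
#' @export
readMatchList <- function(path) {
  if (length(readLines(path)) <= 1L)
    return(matchList(integer(0), integer(0), integer(0), integer(0)))
  tab <- read.table(path, header = FALSE, skip = 1L, sep = "\t",
                    col.names = c("queryPos", "diagonal", "fullScore",
                                  "extScore"),
                    colClasses = "integer")
  matchList(tab$queryPos, tab$diagonal, tab$fullScore, tab$extScore)
}

#' @rdname readMatchList
#' @param matches a match list to write.
#' @export
writeMatchList <- function(matches, path) {
  writeLines(c("query_pos\tdiagonal\tfull_score\text_score",
               sprintf("%d\t%d\t%d\t%d", matches$queryPos,
                       matches$diagonal, matches$fullScore,
                       matches$extScore)), path, useBytes = TRUE)
  invisible(path)
}
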