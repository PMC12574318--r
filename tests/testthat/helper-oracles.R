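# Independent brute-force reference implementations. These deliberately
# share no code with the package internals: closures are computed by
# iterated edge expansion, chain scores by exhaustive path enumeration over
# an explicitly constructed edge list, merges by sort-then-deduplicate of
# the concatenation.

# transitive closure (taxon + all descendants) over an edge table
bruteDescendants <- function(edges, taxid) {
  out <- taxid
  repeat {
    more <- edges$taxid[edges$parent %in% out &
                          !(edges$taxid %in% out) &
                          edges$taxid != edges$parent]
    if (length(more) == 0L) break
    out <- c(out, more)
  }
  sort(out)
}

# all maximal paths in the consecutive-match digraph, best score per source
bruteChainEnum <- function(m) {
  n <- nrow(m)
  if (n == 0L)
    return(data.frame(startPos = integer(0), endPos = integer(0),
                      score = integer(0)))
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (m$queryPos[j] == m$queryPos[i] + 1L &&
        m$diagonal[j] == m$diagonal[i]) edge[i, j] <- TRUE
  sources <- which(colSums(edge) == 0L)
  res <- list()
  for (s in sources) {
    best <- NULL
    stack <- list(list(node = s, score = m$fullScore[s]))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nxt <- which(edge[top$node, ])
      if (length(nxt) == 0L) {
        cand <- c(m$queryPos[s], m$queryPos[top$node], top$score)
        if (is.null(best) || cand[3L] > best[3L] ||
            (cand[3L] == best[3L] && cand[2L] < best[2L])) best <- cand
      } else {
        for (j in nxt)
          stack[[length(stack) + 1L]] <-
            list(node = j, score = top$score + m$extScore[j])
      }
    }
    res[[length(res) + 1L]] <- best
  }
  ch <- do.call(rbind, res)
  ch <- data.frame(startPos = as.integer(ch[, 1L]),
                   endPos = as.integer(ch[, 2L]),
                   score = as.integer(ch[, 3L]))
  ch <- ch[order(-ch$score, ch$startPos, ch$endPos), , drop = FALSE]
  rownames(ch) <- NULL
  ch
}

# sort + species-level dedup of the concatenation of two k-mer lists
bruteMerge <- function(a, b) {
  k <- c(a@keys, b@keys); t <- c(a@taxids, b@taxids)
  o <- order(k, t)
  k <- k[o]; t <- t[o]
  dup <- c(FALSE, diff(k) == 0 & diff(t) == 0L)
  data.frame(kmerKey = k[!dup], speciesTaxid = t[!dup])
}

# enumerate-sort-dedup k-mer oracle over raw string windows
bruteKmers <- function(seqs, taxids, k) {
  recs <- list()
  for (s in seq_along(seqs)) {
    x <- toupper(seqs[[s]])
    L <- nchar(x)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      w <- substr(x, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      code <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T")) - 1
      recs[[length(recs) + 1L]] <- c(sum(code * 4^((k - 1):0)), taxids[s])
    }
  }
  if (length(recs) == 0L)
    return(data.frame(kmerKey = numeric(0), speciesTaxid = integer(0)))
  m <- do.call(rbind, recs)
  m <- unique(m[order(m[, 1], m[, 2]), , drop = FALSE])
  data.frame(kmerKey = unname(m[, 1]),
             speciesTaxid = as.integer(m[, 2]), row.names = NULL)
}

# greedy best-scoring non-overlapping chain selection, recomputed afresh
bruteSelect <- function(ch) {
  ch <- ch[order(-ch$score, ch$startPos, ch$endPos), , drop = FALSE]
  rownames(ch) <- NULL
  taken <- list()
  keep <- logical(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    clash <- FALSE
    for (iv in taken)
      if (ch$startPos[i] <= iv[2] && ch$endPos[i] >= iv[1]) clash <- TRUE
    if (!clash) {
      keep[i] <- TRUE
      taken[[length(taken) + 1L]] <- c(ch$startPos[i], ch$endPos[i])
    }
  }
  out <- ch[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

fileBytes <- function(path) readBin(path, "raw", file.size(path))

expect_files_identical <- function(a, b) {
  expect_identical(fileBytes(a), fileBytes(b))
}
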