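## Deterministic synthetic-data generators. Every generator draws from its
## own PRNG stream seeded from (spec seed, generator name), so adding a
## generator never perturbs the output of existing ones: the same spec and
## seed always reproduce byte-identical artifacts.

.RANK_NAMES <- c(D = "superkingdom", K = "kingdom", P = "phylum",
                 C = "class", O = "order", F = "family", G = "genus",
                 S = "species")

#' Fixture specification
#'
#' One object stating the simulated world: taxonomy size and rank ladder,
#' read count and length, pairing, the leaf abundance model and the
#' unclassified fraction. Defaults describe a modest shotgun metagenome:
#' 200 taxa on the canonical eight-rank ladder, 1000 reads of 150 bp,
#' log-normal leaf abundances (meanlog 0, sdlog 1 — the heavy-tailed shape
#' typical of microbial communities) and 10% unclassified reads.
#'
#' @param seed integer master seed.
#' @param nTaxa number of taxonomy nodes including the root.
#' @param rankLadder ordered rank codes, depth 1 of the tree mapping to the
#'   first code.
#' @param nReads number of reads (pairs, when `paired`).
#' @param readLength read length in bp.
#' @param paired generate paired-end reads?
#' @param abundance list: `model` one of "uniform", "geometric" (with `p`),
#'   "lognormal" (with `meanlog`, `sdlog`).
#' @param unclassifiedFraction fraction of reads left unclassified, in
#'   \[0, 1\].
#' @return a validated spec (list of class `"taxokit_fixture_spec"`).
#' @export
fixtureSpec <- function(seed = 42L, nTaxa = 200L,
                        rankLadder = c("D", "K", "P", "C", "O", "F", "G", "S"),
                        nReads = 1000L, readLength = 150L, paired = FALSE,
                        abundance = list(model = "lognormal", meanlog = 0,
                                         sdlog = 1),
                        unclassifiedFraction = 0.1) {
  stopifnot(nTaxa >= 1L, nReads >= 0L, readLength >= 1L,
            unclassifiedFraction >= 0, unclassifiedFraction <= 1,
            length(rankLadder) >= 1L,
            abundance$model %in% c("uniform", "geometric", "lognormal"))
  structure(list(seed = as.integer(seed), nTaxa = as.integer(nTaxa),
                 rankLadder = as.character(rankLadder),
                 nReads = as.integer(nReads),
                 readLength = as.integer(readLength),
                 paired = isTRUE(paired), abundance = abundance,
                 unclassifiedFraction = unclassifiedFraction),
            class = "taxokit_fixture_spec")
}

#' Generate a random taxonomy respecting the rank ladder
#'
#' Root (taxid 1, rank "no rank") plus `nTaxa - 1` nodes, each attached to a
#' random existing node above the deepest rank; a node at tree depth d gets
#' the rank name of the d-th ladder code. Optionally writes NCBI-style dump
#' files plus a machine-readable adjacency ground truth.
#'
#' @param spec a [fixtureSpec()].
#' @param dir optional output directory for nodes.dmp / names.dmp /
#'   ground_truth.tsv.
#' @return list: `tree` ([TaxonomyTree-class]), `groundTruth` (data.frame
#'   taxid, parent, depth, rankCode), `files` (paths or NULL).
#' @export
makeTaxonomy <- function(spec, dir = NULL) {
  set.seed(.seedFor(spec$seed, "taxonomy"))
  ladder <- spec$rankLadder
  n <- spec$nTaxa
  taxid <- seq_len(n)
  parent <- integer(n); depth <- integer(n)
  parent[1L] <- 1L; depth[1L] <- 0L
  for (i in seq_len(n)[-1L]) {
    eligible <- which(depth[seq_len(i - 1L)] < length(ladder))
    p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    parent[i] <- taxid[p]
    depth[i] <- depth[p] + 1L
  }
  rankCode <- c("R", ladder)[depth + 1L]
  rankName <- ifelse(depth == 0L, "no rank",
                     unname(.RANK_NAMES[rankCode]))
  rankName[is.na(rankName)] <- rankCode[is.na(rankName)]
  name <- ifelse(depth == 0L, "root",
                 paste0(tolower(rankName), "_", taxid))
  tree <- TaxonomyTree(data.frame(taxid = taxid, parent = parent,
                                  rank = rankName, name = name,
                                  stringsAsFactors = FALSE))
  gt <- data.frame(taxid = taxid, parent = parent, depth = depth,
                   rankCode = rankCode, stringsAsFactors = FALSE)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(nodes = file.path(dir, "nodes.dmp"),
               names = file.path(dir, "names.dmp"),
               groundTruth = file.path(dir, "ground_truth.tsv"))
    writeTaxonomyDump(tree, files[["nodes"]], files[["names"]])
    write.table(gt, files[["groundTruth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(tree = tree, groundTruth = gt, files = files)
}

.leafWeights <- function(spec, nLeaves) {
  ab <- spec$abundance
  switch(ab$model,
         uniform = rep(1 / nLeaves, nLeaves),
         geometric = {
           p <- ab$p %||% 0.3
           w <- p * (1 - p)^(seq_len(nLeaves) - 1L)
           w / sum(w)
         },
         lognormal = {
           w <- rlnorm(nLeaves, ab$meanlog %||% 0, ab$sdlog %||% 1)
           w / sum(w)
         })
}

.randomReads <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

## Kraken-style report rows from per-node direct counts: DFS preorder,
## children ordered by clade reads descending (ties: taxid), only taxa with
## clade reads > 0 except the root, "unclassified" pseudo-row first.
.reportFromCounts <- function(gt, taxonReads, unclassified) {
  n <- nrow(gt)
  clade <- as.numeric(taxonReads)
  for (i in order(gt$depth, decreasing = TRUE)) {
    if (gt$depth[i] > 0L) {
      p <- match(gt$parent[i], gt$taxid)
      clade[p] <- clade[p] + clade[i]
    }
  }
  total <- unclassified + clade[1L]
  kids <- split(seq_len(n)[-1L], gt$parent[-1L])
  rowsIdx <- integer(0)
  visit <- function(i) {
    rowsIdx <<- c(rowsIdx, i)
    ch <- kids[[as.character(gt$taxid[i])]]
    ch <- ch[clade[ch] > 0]
    for (j in ch[order(-clade[ch], gt$taxid[ch])]) visit(j)
  }
  visit(1L)
  rows <- data.frame(
    cladeReads = c(unclassified, clade[rowsIdx]),
    taxonReads = c(unclassified, taxonReads[rowsIdx]),
    rankCode = c("U", gt$rankCode[rowsIdx]),
    taxid = c(0L, gt$taxid[rowsIdx]),
    name = c("unclassified",
             ifelse(gt$depth[rowsIdx] == 0L, "root",
                    paste0("x_", gt$taxid[rowsIdx]))),
    depth = c(0L, gt$depth[rowsIdx]),
    stringsAsFactors = FALSE)
  KrakenReport(rows, totalReads = total)
}

#' Generate a mutually consistent profile: report, classifications, reads
#'
#' Classified reads are drawn from the taxonomy's leaves under the spec's
#' abundance model; a `unclassifiedFraction` share stays unclassified. The
#' classification file's i-th line describes the i-th read (pair), and the
#' report is aggregated bottom-up so the conservation law holds exactly.
#'
#' @param spec a [fixtureSpec()].
#' @param taxonomy result of [makeTaxonomy()] (list with tree and
#'   groundTruth); generated from `spec` when `NULL`.
#' @param dir optional output directory: writes report.tsv,
#'   classifications.tsv and reads as FASTQ (gzipped when `gzip = TRUE`).
#' @param gzip write gzipped read files?
#' @return list: `report` ([KrakenReport-class]), `classifications`
#'   (data.frame as [readClassifications()]), `reads` (character vector, or
#'   list of two for paired), `assignments` (integer taxid per read, 0 =
#'   unclassified), `tree`, `files`.
#' @export
makeProfile <- function(spec, taxonomy = NULL, dir = NULL, gzip = FALSE) {
  if (is.null(taxonomy)) taxonomy <- makeTaxonomy(spec)
  set.seed(.seedFor(spec$seed, "profile"))
  gt <- taxonomy$groundTruth
  tree <- taxonomy$tree
  leaves <- setdiff(gt$taxid, gt$parent[gt$depth > 0L])
  n <- spec$nReads
  unc <- runif(n) < spec$unclassifiedFraction
  assignments <- integer(n)
  if (any(!unc)) {
    w <- .leafWeights(spec, length(leaves))
    assignments[!unc] <- if (length(leaves) == 1L) leaves else
      sample(leaves, sum(!unc), replace = TRUE, prob = w)
  }
  taxonReads <- tabulate(match(assignments, gt$taxid), nbins = nrow(gt))

  nameMap <- setNames(tree@nodes$name, tree@nodes$taxid)
  report <- local({
    rep0 <- .reportFromCounts(gt, taxonReads, sum(unc))
    rows <- rep0@rows
    named <- rows$taxid != 0L
    rows$name[named] <- unname(nameMap[as.character(rows$taxid[named])])
    KrakenReport(rows, totalReads = rep0@totalReads)
  })

  readIds <- sprintf("read_%06d", seq_len(n))
  classifications <- data.frame(
    isClassified = !unc, readId = readIds, taxid = assignments,
    lineNumber = seq_len(n), stringsAsFactors = FALSE)
  mkFastq <- function(suffix) {
    seqs <- .randomReads(n, spec$readLength)
    as.vector(rbind(paste0("@", readIds, suffix), seqs, "+",
                    strrep("I", spec$readLength)))
  }
  reads <- if (spec$paired) list(r1 = mkFastq("/1"), r2 = mkFastq("/2"))
           else list(r1 = mkFastq(""))

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fq.gz" else ".fq"
    files <- c(report = file.path(dir, "report.tsv"),
               classifications = file.path(dir, "classifications.tsv"))
    writeReport(report, files[["report"]])
    writeLines(paste(as.integer(classifications$isClassified),
                     classifications$readId, classifications$taxid,
                     sep = "\t"),
               files[["classifications"]], useBytes = TRUE)
    for (m in seq_along(reads)) {
      p <- file.path(dir, paste0("reads_", m, ext))
      con <- if (gzip) gzfile(p, "wt") else file(p, "wt")
      writeLines(reads[[m]], con, useBytes = TRUE)
      close(con)
      files <- c(files, setNames(p, paste0("reads", m)))
    }
  }
  list(report = report, classifications = classifications, reads = reads,
       assignments = assignments, tree = tree, files = files)
}

#' Generate a match list with planted chains and isolated noise
#'
#' Plants `plantedChains` runs of consecutive matches on shared diagonals
#' (length 2-5 codons) and fills up to `n` total matches with isolated noise
#' matches that are guaranteed not to touch a planted chain or each other on
#' any diagonal, so the planted (start, end, score) triples appear verbatim
#' in any correct assembler's output.
#'
#' @param seed integer seed.
#' @param n total number of matches.
#' @param nDiagonals number of distinct diagonals to draw from.
#' @param plantedChains number of chains to plant (trimmed when `n` is too
#'   small).
#' @param maxScore upper bound for `fullScore` draws.
#' @return list: `matches` (a [matchList()]), `planted` (data.frame
#'   startPos, endPos, score).
#' @export
makeMatches <- function(seed, n = 30L, nDiagonals = 4L, plantedChains = 2L,
                        maxScore = 16L) {
  set.seed(.seedFor(seed, "matches"))
  maxQ <- max(20L, 4L * n)
  occupied <- character(0)   # "q d" cells blocked for further placement
  qp <- integer(0); dg <- integer(0); fs <- integer(0); es <- integer(0)
  planted <- .emptyChains()
  blockCell <- function(q, d) paste(c(q - 1L, q, q + 1L), d)
  left <- n
  for (ch in seq_len(plantedChains)) {
    len <- sample(2:5, 1L)
    if (len > left) break
    placed <- FALSE
    for (try in 1:50) {
      d <- sample.int(nDiagonals, 1L)
      q0 <- sample.int(maxQ - len, 1L)
      cells <- paste(q0:(q0 + len - 1L), d)
      if (!any(cells %in% occupied)) { placed <- TRUE; break }
    }
    if (!placed) next
    full <- sample.int(maxScore, len, replace = TRUE)
    ext <- vapply(full, function(f) sample.int(f + 1L, 1L) - 1L, 0L)
    qp <- c(qp, q0:(q0 + len - 1L)); dg <- c(dg, rep(d, len))
    fs <- c(fs, full); es <- c(es, ext)
    occupied <- c(occupied,
                  unlist(lapply(q0:(q0 + len - 1L), blockCell, d = d)))
    planted <- rbind(planted,
                     data.frame(startPos = q0, endPos = q0 + len - 1L,
                                score = full[1L] + sum(ext[-1L])))
    left <- left - len
  }
  while (left > 0L) {
    for (try in 1:200) {
      d <- sample.int(nDiagonals, 1L)
      q <- sample.int(maxQ, 1L)
      if (!(paste(q, d) %in% occupied)) break
    }
    if (paste(q, d) %in% occupied) break
    full <- sample.int(maxScore, 1L)
    qp <- c(qp, q); dg <- c(dg, d)
    fs <- c(fs, full); es <- c(es, sample.int(full + 1L, 1L) - 1L)
    occupied <- c(occupied, blockCell(q, d))
    left <- left - 1L
  }
  list(matches = matchList(qp, dg, fs, es), planted = planted)
}
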