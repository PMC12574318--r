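simpleReport <- function() {
  KrakenReport(data.frame(
    cladeReads = c(2, 8, 8, 5), taxonReads = c(2, 0, 3, 5),
    rankCode = c("U", "R", "D", "P"), taxid = c(0L, 1L, 2L, 3L),
    name = c("unclassified", "root", "Bacteria", "Proteobacteria"),
    depth = c(0L, 0L, 1L, 2L)))
}

test_that("ladder placement and cross-layer links follow the ancestor rule", {
  g <- buildSankey(simpleReport(), c("D", "P"))
  nd <- sankeyNodes(g)
  expect_identical(nd$taxid, c(2L, 3L))
  expect_identical(nd$layer, c(0L, 1L))
  lk <- sankeyLinks(g)
  expect_identical(nrow(lk), 1L)
  expect_identical(lk$value, 5)  # Proteobacteria clade reads

  # genus directly under phylum: link spans layers on the full ladder
  r <- KrakenReport(data.frame(
    cladeReads = c(6, 6, 6), taxonReads = c(0, 0, 6),
    rankCode = c("R", "P", "G"), taxid = 1:3,
    name = c("root", "phy", "gen"), depth = 0:2))
  g2 <- buildSankey(r, c("P", "C", "O", "F", "G"))
  lk2 <- sankeyLinks(g2)
  expect_identical(lk2$sourceNodeId, "2")
  expect_identical(lk2$targetNodeId, "3")
  nd2 <- sankeyNodes(g2)
  expect_identical(nd2$layer[nd2$taxid == 3L], 4L)
})

test_that("per-layer clade sums never exceed the total read count", {
  prof <- makeProfile(fixtureSpec(seed = 17, nTaxa = 200, nReads = 1000))
  g <- buildSankey(prof$report)
  nd <- sankeyNodes(g)
  for (ly in unique(nd$layer[!is.na(nd$taxid)])) {
    expect_lte(sum(nd$cladeReads[nd$layer == ly & !is.na(nd$taxid)]),
               totalReads(g))
  }
})

test_that("a row with no on-ladder ancestor hangs off the synthetic root", {
  r <- KrakenReport(data.frame(
    cladeReads = c(4, 4), taxonReads = c(0, 4),
    rankCode = c("R", "G"), taxid = 1:2,
    name = c("root", "genus"), depth = 0:1))
  g <- buildSankey(r, c("P", "G"))
  nd <- sankeyNodes(g)
  expect_true(any(is.na(nd$taxid)))  # synthetic root present
  expect_identical(nd$parentNodeId[nd$taxid == 2L & !is.na(nd$taxid)],
                   ".synthetic_root")
  # and the graph still reconstructs its source report
  expect_equal(reconstructReport(sankeyToJSON(g)), r)
})

test_that("threshold filters drop nodes; identity filters are a no-op", {
  prof <- makeProfile(fixtureSpec(seed = 29, nTaxa = 120, nReads = 600))
  g <- buildSankey(prof$report)
  gf <- applyFilters(g, sankeyFilters(minProportion = 5))
  expect_true(all(sankeyNodes(gf)$proportion >= 5, na.rm = TRUE))
  # a node at 4% vanishes under a 5% threshold
  nd <- sankeyNodes(g)
  low <- nd$nodeId[!is.na(nd$taxid) & nd$proportion < 5]
  expect_false(any(low %in% sankeyNodes(gf)$nodeId))

  gid <- applyFilters(g, sankeyFilters())
  expect_equal(sankeyNodes(gid)[, c("nodeId", "parentNodeId", "cladeReads")],
               nd[!is.na(nd$taxid), c("nodeId", "parentNodeId", "cladeReads")],
               ignore_attr = TRUE)
})

test_that("top-N keeps the most abundant taxa, ties to the smaller taxid", {
  r <- KrakenReport(data.frame(
    cladeReads = c(120, 50, 30, 30, 10), taxonReads = c(0, 50, 30, 30, 10),
    rankCode = c("R", "P", "P", "P", "P"), taxid = c(1L, 20L, 40L, 30L, 50L),
    name = c("root", "a", "b", "c", "d"), depth = c(0L, 1L, 1L, 1L, 1L)))
  g <- buildSankey(r, c("P"))
  gf <- applyFilters(g, sankeyFilters(maxTaxaPerRank = 2))
  kept <- sankeyNodes(gf)$taxid
  # clade 50 always in; of the tied 30s the smaller taxid (30) survives
  expect_setequal(kept, c(20L, 30L))

  # enumerate every 2-subset: the chosen one maximizes clade reads with the
  # smaller-taxid tie rule
  cand <- utils::combn(c(20L, 40L, 30L, 50L), 2, simplify = FALSE)
  score <- vapply(cand, function(s) {
    cl <- c(`20` = 50, `40` = 30, `30` = 30, `50` = 10)[as.character(s)]
    sum(cl) * 1000 - sum(s)  # abundance first, then smaller taxids
  }, 0)
  expect_setequal(kept, cand[[which.max(score)]])
})

test_that("descendants of removed nodes re-attach with value preserved", {
  # root(R) -> D -> P -> G ; filter out the P layer
  r <- KrakenReport(data.frame(
    cladeReads = c(9, 9, 9, 9), taxonReads = c(0, 0, 0, 9),
    rankCode = c("R", "D", "P", "G"), taxid = 1:4,
    name = c("root", "dom", "phy", "gen"), depth = 0:3))
  g <- buildSankey(r, c("D", "P", "G"))
  gf <- applyFilters(g, sankeyFilters(ranksShown = c("D", "G")))
  nd <- sankeyNodes(gf)
  expect_setequal(nd$taxid[!is.na(nd$taxid)], c(2L, 4L))
  expect_identical(nd$parentNodeId[nd$taxid == 4L & !is.na(nd$taxid)], "2")
  lk <- sankeyLinks(gf)
  expect_identical(lk$value, 9)  # still the descendant's clade reads
})

test_that("filter monotonicity: stricter filters never add nodes", {
  prof <- makeProfile(fixtureSpec(seed = 41, nTaxa = 150, nReads = 800))
  g <- buildSankey(prof$report)
  set.seed(77)
  for (i in 1:30) {
    p <- runif(1, 0, 10); c0 <- sample(0:50, 1); n0 <- sample(1:10, 1)
    a <- applyFilters(g, sankeyFilters(p, c0, n0))
    b <- applyFilters(g, sankeyFilters(p + runif(1, 0, 5),
                                       c0 + sample(0:20, 1),
                                       max(1, n0 - sample(0:3, 1))))
    expect_lte(nrow(sankeyNodes(b)), nrow(sankeyNodes(a)))
  }
})

test_that("subtree re-roots, re-bases layers and honors filters", {
  prof <- makeProfile(fixtureSpec(seed = 53, nTaxa = 100, nReads = 500))
  # put the root row itself on the ladder so the graph has one top node
  g <- buildSankey(prof$report,
                   c("R", "D", "K", "P", "C", "O", "F", "G", "S"))
  nd <- sankeyNodes(g)

  # at the top node: identical node set, layers re-based
  top <- nd[which.min(nd$layer), ]
  s <- sankeySubtree(g, top$taxid)
  expect_setequal(sankeyNodes(s)$nodeId, nd$nodeId[!is.na(nd$taxid)])
  expect_identical(min(sankeyNodes(s)$layer), 0L)
  expect_identical(sankeyNodes(s)$layer,
                   nd$layer[match(sankeyNodes(s)$nodeId, nd$nodeId)])

  # at a leaf: single node, no links
  leafId <- setdiff(nd$nodeId, sankeyLinks(g)$sourceNodeId)[1L]
  leaf <- nd[nd$nodeId == leafId, ]
  sl <- sankeySubtree(g, leaf$taxid)
  expect_identical(nrow(sankeyNodes(sl)), 1L)
  expect_identical(nrow(sankeyLinks(sl)), 0L)

  # random internal nodes: node set equals brute-force closure over parents
  internal <- intersect(nd$nodeId, sankeyLinks(g)$sourceNodeId)
  set.seed(8)
  for (nid in sample(internal, min(5, length(internal)))) {
    s2 <- sankeySubtree(g, nd$taxid[nd$nodeId == nid])
    closure <- nid
    repeat {
      more <- nd$nodeId[nd$parentNodeId %in% closure &
                          !(nd$nodeId %in% closure)]
      if (!length(more)) break
      closure <- c(closure, more)
    }
    expect_setequal(sankeyNodes(s2)$nodeId, closure)
    # proportions stay relative to the original total
    expect_identical(sankeyNodes(s2)$proportion,
                     nd$proportion[match(sankeyNodes(s2)$nodeId, nd$nodeId)])
  }
  expect_error(sankeySubtree(g, 999999L), "no Sankey node")
})

test_that("JSON serialization is deterministic and exactly invertible", {
  prof <- makeProfile(fixtureSpec(seed = 61, nTaxa = 90, nReads = 400))
  g <- buildSankey(prof$report)
  js1 <- sankeyToJSON(g); js2 <- sankeyToJSON(g)
  expect_identical(as.character(js1), as.character(js2))
  g2 <- sankeyFromJSON(js1)
  expect_equal(g2, g)

  # empty report -> empty arrays, still schema-valid
  f <- tempfile(); writeLines(character(0), f)
  emptyG <- buildSankey(readReport(f))
  doc <- jsonlite::fromJSON(sankeyToJSON(emptyG))
  expect_identical(doc$schema, "taxoview-json/1")
  expect_length(doc$nodes, 0)
  expect_equal(sankeyFromJSON(sankeyToJSON(emptyG)), emptyG)
})

test_that("reconstruction is exact for unfiltered graphs and refuses gaps", {
  r <- simpleReport()
  expect_equal(reconstructReport(sankeyToJSON(buildSankey(r))), r)

  prof <- makeProfile(fixtureSpec(seed = 67, nTaxa = 200, nReads = 900))
  f1 <- tempfile(); writeReport(prof$report, f1)
  for (ladder in list(c("D", "K", "P", "C", "O", "F", "G", "S"),
                      c("D", "P", "G"), c("S"))) {
    g <- buildSankey(prof$report, ladder)
    r2 <- reconstructReport(sankeyToJSON(g))
    f2 <- tempfile(); writeReport(r2, f2)
    expect_files_identical(f1, f2)
    unlink(f2)
  }

  gf <- applyFilters(buildSankey(prof$report), sankeyFilters(minCladeReads = 5))
  expect_error(reconstructReport(gf), "completeness")
})
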