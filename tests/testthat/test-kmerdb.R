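test_that("window encoding, N handling and species dedup are correct", {
  expect_identical(kmerRecords(buildKmerList("ACGT", 9, k = 4)),
                   data.frame(kmerKey = 27, speciesTaxid = 9L))
  expect_identical(length(buildKmerList("AAAA", 9, k = 2)), 1L)  # dedup
  # windows touching N are skipped
  kl <- buildKmerList("ACNGT", 5, k = 2)
  expect_identical(kmerRecords(kl)$kmerKey,
                   sort(c(1, 11)))  # AC and GT only
  # k longer than every sequence: empty, not an error
  expect_identical(length(buildKmerList("ACG", 5, k = 7)), 0L)
  expect_error(buildKmerList("ACG", 5, k = 30), "26")
})

test_that("list building equals the enumerate-sort-dedup oracle", {
  set.seed(12)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 1000, TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""), "")
  taxids <- c(7L, 7L, 11L, 13L)
  for (k in c(3L, 12L))
    expect_identical(kmerRecords(buildKmerList(seqs, taxids, k = k)),
                     bruteKmers(seqs, taxids, k))
})

test_that("canonical encoding takes the smaller strand key", {
  # AC (key 1) vs revcomp GT (key 11): canonical keeps 1; for GT itself the
  # revcomp is AC so both windows map to the same canonical key
  kl <- buildKmerList("ACGT", 3, k = 2, canonical = TRUE)
  expect_identical(unique(kl@keys %in% c(1, 6)), TRUE)  # AC=1, CG=6
  # cross-check against Biostrings reverseComplement on random 30-mers
  set.seed(3)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(buildKmerList(s, 1, k = 8, canonical = TRUE)@keys,
                     buildKmerList(rc, 1, k = 8, canonical = TRUE)@keys)
  }
})

test_that("merge behavior on the species-dedup boundary cases", {
  a <- KmerList(5, 1L, k = 12); b <- KmerList(5, 1L, k = 12)
  m <- mergeKmerLists(a, b)  # same k-mer, same species -> one record
  expect_identical(kmerRecords(m), data.frame(kmerKey = 5, speciesTaxid = 1L))
  b2 <- KmerList(5, 2L, k = 12)  # same k-mer, different species -> both
  expect_identical(kmerRecords(mergeKmerLists(a, b2)),
                   data.frame(kmerKey = c(5, 5), speciesTaxid = c(1L, 2L)))
  expect_error(mergeKmerLists(a, KmerList(5, 1L, k = 11)), "different k")
})

test_that("streaming merge equals sort+dedup of the concatenation", {
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(0:5000, 1); n2 <- sample(0:5000, 1)
    a <- KmerList(sample(0:20000, n1, TRUE), sample(1:30, n1, TRUE), k = 12)
    b <- KmerList(sample(0:20000, n2, TRUE), sample(1:30, n2, TRUE), k = 12)
    expect_identical(kmerRecords(mergeKmerLists(a, b)), bruteMerge(a, b))
  }
})

test_that("unsorted input is detected during the pass, with a position", {
  a <- KmerList(c(3, 9), c(1L, 1L), k = 12)
  a@keys <- c(9, 3)  # corrupt past the constructor, as a damaged file would
  b <- KmerList(numeric(0), integer(0), k = 12)
  expect_error(mergeKmerLists(a, b), "unsorted.*record 2")
})

test_that("merge is associative, commutative, and size-bounded", {
  set.seed(31)
  mk <- function(n) KmerList(sample(0:3000, n, TRUE),
                             sample(1:10, n, TRUE), k = 12)
  for (i in 1:5) {
    a <- mk(800); b <- mk(800); c <- mk(800)
    ab_c <- mergeKmerLists(mergeKmerLists(a, b), c)
    a_bc <- mergeKmerLists(a, mergeKmerLists(b, c))
    ba <- mergeKmerLists(b, a)
    expect_identical(kmerRecords(ab_c), kmerRecords(a_bc))
    expect_identical(kmerRecords(mergeKmerLists(a, b)), kmerRecords(ba))
    expect_lte(length(mergeKmerLists(a, b)), length(a) + length(b))
  }
  # equality iff no shared (key, taxid)
  a <- KmerList(c(1, 2), c(1L, 1L), k = 12)
  b <- KmerList(c(3, 4), c(1L, 1L), k = 12)
  expect_identical(length(mergeKmerLists(a, b)), 4L)
})

test_that("binary and TSV round trips are exact", {
  set.seed(41)
  # include keys above 2^32 to exercise the two-halves encoding
  keys <- sort(sample(c(0:1000, 2^32 + 0:1000, 4^26 - 1), 500))
  kl <- KmerList(keys, sample(1:99, 500, TRUE), k = 26)
  p <- tempfile()
  writeKmerList(kl, p)
  expect_identical(kmerRecords(readKmerList(p)), kmerRecords(kl))
  expect_identical(readKmerList(p)@k, 26L)
  pt <- tempfile()
  writeKmerList(kl, pt, format = "tsv")
  expect_identical(kmerRecords(readKmerList(pt, format = "tsv", k = 26)),
                   kmerRecords(kl))
})

test_that("updateDatabase: identity, idempotence and rebuild equivalence", {
  d <- withr::local_tempdir()
  tree <- TaxonomyTree(data.frame(
    taxid = c(1L, 2L, 3L), parent = c(1L, 1L, 1L),
    rank = c("no rank", "species", "species"),
    name = c("root", "sp2", "sp3")))
  set.seed(51)
  g1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  g2 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  writeKmerDb(d, buildKmerList(c(g1, g2), c(2L, 3L), k = 12), tree)
  h0 <- fileBytes(file.path(d, "kmers.bin"))

  # zero new sequences: unchanged
  fa0 <- tempfile(fileext = ".fa"); file.create(fa0)
  mp0 <- tempfile(); file.create(mp0)
  updateDatabase(d, fa0, data.frame(id = character(0), taxid = integer(0)))
  expect_identical(fileBytes(file.path(d, "kmers.bin")), h0)

  # update with itself: dedup makes it idempotent
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", g1, ">s2", g2), fa)
  mp <- tempfile(); writeLines(c("s1\t2", "s2\t3"), mp)
  updateDatabase(d, fa, mp)
  expect_identical(fileBytes(file.path(d, "kmers.bin")), h0)

  # disjoint new genome + new taxon == building from the union from scratch
  g3 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  fa3 <- tempfile(fileext = ".fa"); writeLines(c(">s3", g3), fa3)
  mp3 <- tempfile(); writeLines("s3\t4", mp3)
  expect_error(updateDatabase(d, fa3, mp3), "absent from the taxonomy")
  updateDatabase(d, fa3, mp3,
                 newTaxa = data.frame(taxid = 4L, parent = 1L,
                                      rank = "species", name = "sp4"))
  scratch <- buildKmerList(c(g1, g2, g3), c(2L, 3L, 4L), k = 12)
  expect_identical(kmerRecords(readKmerDb(d)$kmers), kmerRecords(scratch))
  expect_true(4L %in% taxonomyNodes(readKmerDb(d)$taxonomy)$taxid)

  # conflicting re-insertion of an existing taxid
  expect_error(
    updateDatabase(d, fa3, mp3,
                   newTaxa = data.frame(taxid = 4L, parent = 1L,
                                        rank = "genus", name = "zzz")),
    "different rank/name")
  # unknown parent
  expect_error(
    updateDatabase(d, fa3, mp3,
                   newTaxa = data.frame(taxid = 9L, parent = 77L,
                                        rank = "species", name = "x")),
    "unknown parent")
})

test_that("update order does not matter", {
  set.seed(61)
  tree <- TaxonomyTree(data.frame(
    taxid = 1:3, parent = c(1L, 1L, 1L),
    rank = c("no rank", "species", "species"),
    name = c("root", "a", "b")))
  base <- buildKmerList(
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), 2L,
    k = 12)
  gA <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  gB <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  apply2 <- function(order) {
    d <- tempfile(); writeKmerDb(d, base, tree)
    for (nm in order) {
      fa <- tempfile(fileext = ".fa")
      writeLines(c(paste0(">", nm), if (nm == "A") gA else gB), fa)
      updateDatabase(d, fa, data.frame(id = nm,
                                       taxid = if (nm == "A") 2L else 3L))
    }
    kmerRecords(readKmerDb(d)$kmers)
  }
  expect_identical(apply2(c("A", "B")), apply2(c("B", "A")))
})
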