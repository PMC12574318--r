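test_that("consecutiveness is one codon right on the same diagonal", {
  m <- function(q, d) list(queryPos = q, diagonal = d)
  expect_true(consecutiveMatches(m(3, 2), m(4, 2)))
  expect_false(consecutiveMatches(m(3, 2), m(5, 2)))  # gap
  expect_false(consecutiveMatches(m(3, 2), m(4, 1)))  # diagonal shift
})

test_that("match list preconditions are enforced", {
  expect_error(matchList(0, 0, 1, 2), "fullScore >= extScore")
  expect_error(matchList(c(0, 0), c(1, 1), c(5, 5), c(0, 0)), "duplicate")
  unsorted <- data.frame(queryPos = c(5L, 1L), diagonal = c(0L, 0L),
                         fullScore = c(2L, 2L), extScore = c(1L, 1L))
  expect_error(assembleChains(unsorted), "not sorted")
})

test_that("oracle handles singleton and the hand-computed two-match chain", {
  one <- matchList(4, 2, 7, 3)
  expect_identical(assembleChainsOracle(one),
                   data.frame(startPos = 4L, endPos = 4L, score = 7L))
  two <- matchList(c(0, 1), c(0, 0), c(8, 8), c(1, 2))
  # single path: 8 (full of first) + 2 (ext of second) = 10
  expect_identical(assembleChainsOracle(two),
                   data.frame(startPos = 0L, endPos = 1L, score = 10L))
})

test_that("oracle equals exhaustive all-paths enumeration (<= 12 matches)", {
  set.seed(19)
  for (i in 1:150) {
    fx <- makeMatches(1000 + i, n = sample(0:12, 1),
                      nDiagonals = sample(1:3, 1),
                      plantedChains = sample(0:2, 1))
    expect_identical(assembleChainsOracle(fx$matches),
                     bruteChainEnum(fx$matches))
  }
})

test_that("single pass reproduces the oracle on spec examples", {
  empty <- matchList(integer(0), integer(0), integer(0), integer(0))
  expect_identical(nrow(assembleChains(empty)), 0L)
  m <- matchList(c(0, 1, 1), c(0, 0, 3), c(8, 8, 8), c(1, 2, 5))
  got <- assembleChains(m)
  expect_identical(got, data.frame(startPos = c(0L, 1L),
                                   endPos = c(1L, 1L),
                                   score = c(10L, 8L)))
  expect_identical(got, assembleChainsOracle(m))
})

test_that("single pass equals the oracle on random and adversarial inputs", {
  set.seed(29)
  for (i in 1:300) {
    fx <- makeMatches(2000 + i, n = sample(0:30, 1),
                      nDiagonals = sample(1:4, 1),
                      plantedChains = sample(0:3, 1))
    expect_identical(assembleChains(fx$matches),
                     assembleChainsOracle(fx$matches))
  }
  # one long chain spanning 40 positions
  long <- matchList(0:39, rep(0L, 40), rep(2L, 40), rep(1L, 40))
  expect_identical(assembleChains(long), assembleChainsOracle(long))
  expect_identical(assembleChains(long)$score, 2L + 39L)
  # many parallel diagonals at the same positions
  par <- matchList(rep(0:9, each = 4), rep(1:4, 10),
                   rep(3L, 40), rep(1L, 40))
  expect_identical(assembleChains(par), assembleChainsOracle(par))
  # all scores tied at zero extension
  tie <- matchList(c(0:3, 0:3), c(rep(1L, 4), rep(2L, 4)),
                   rep(5L, 8), rep(0L, 8))
  expect_identical(assembleChains(tie), assembleChainsOracle(tie))
})

test_that("each match is inspected exactly once in the single pass", {
  for (seed in c(1, 5, 9)) {
    fx <- makeMatches(seed, n = 30, nDiagonals = 4, plantedChains = 3)
    out <- assembleChains(fx$matches, countVisits = TRUE)
    expect_identical(attr(out, "visits"), nrow(fx$matches))
  }
})

test_that("extending a chain never lowers its score; count bounds hold", {
  set.seed(39)
  for (i in 1:50) {
    fx <- makeMatches(3000 + i, n = 12, nDiagonals = 1, plantedChains = 2)
    m <- fx$matches
    if (nrow(m) == 0L) next
    ch <- assembleChains(m)
    expect_lte(nrow(ch), nrow(m))
    expect_lte(sum(ch$endPos - ch$startPos + 1L), nrow(m))
    # append one consecutive match to the tail of the right-most chain
    q <- max(m$queryPos); d <- m$diagonal[1L]
    old <- ch[ch$endPos == q, ]
    m2 <- matchList(c(m$queryPos, q + 1L), c(m$diagonal, d),
                    c(m$fullScore, 4L), c(m$extScore, 2L))
    ch2 <- assembleChains(m2)
    grown <- ch2[ch2$startPos == old$startPos & ch2$endPos == q + 1L, ]
    expect_identical(nrow(grown), 1L)
    expect_identical(grown$score, old$score + 2L)
    expect_gte(grown$score, old$score)
  }
})

test_that("best-chain selection is greedy by score over disjoint intervals", {
  disjoint <- data.frame(startPos = c(0L, 10L), endPos = c(5L, 12L),
                         score = c(3L, 9L))
  expect_identical(nrow(selectBestChains(disjoint)), 2L)
  overlap <- data.frame(startPos = c(0L, 0L), endPos = c(5L, 5L),
                        score = c(10L, 8L))
  expect_identical(selectBestChains(overlap)$score, 10L)
  set.seed(49)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    s <- sample(0:30, n, TRUE)
    ch <- data.frame(startPos = s, endPos = s + sample(0:6, n, TRUE),
                     score = sample(1:20, n, TRUE))
    expect_identical(selectBestChains(ch), bruteSelect(ch))
  }
})

test_that("match-list TSV round trip", {
  fx <- makeMatches(5, n = 15, nDiagonals = 3, plantedChains = 2)
  f <- tempfile()
  writeMatchList(fx$matches, f)
  expect_identical(readMatchList(f), fx$matches)
})
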