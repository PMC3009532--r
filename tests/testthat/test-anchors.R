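# Anchor extraction: multiplicity classes, top-k selection, self-chain
# filtering and bridged composition.

simpleChain <- function(id, score, tStart, tEnd, qStart,
                        tName = "chrT", qName = paste0("chrQ", id),
                        qStrand = "+", tSize = 100000, qSize = 100000) {
  w <- tEnd - tStart
  list(score = score, tName = tName, tSize = tSize, tStart = tStart,
       tEnd = tEnd, qName = qName, qSize = qSize, qStrand = qStrand,
       qStart = qStart, qEnd = qStart + w, id = id,
       blocks = cbind(w, 0, 0))
}

chainSetOf <- function(...) {
  f <- tempfile(fileext = ".chain")
  writeChainFile(f, list(...))
  readChains(f)
}

test_that("a single chain yields only gray 1-to-1 anchors", {
  cs <- chainSetOf(simpleChain("1", 900, 1000, 2000, 5000))
  anc <- anchorsForRegion(GRanges("chrT", IRanges(1, 10000)), cs)
  expect_true(all(anc$multiplicity == "one_to_one"))
  expect_true(all(anc$color == "gray"))
  expect_equal(sum(width(anc)), 1000)
})

test_that("overlapping chains give blue 1-to-2 anchors on the shared span", {
  cs <- chainSetOf(simpleChain("a", 900, 1000, 2000, 5000),
                   simpleChain("b", 800, 1500, 2500, 7000))
  anc <- anchorsForRegion(GRanges("chrT", IRanges(1, 10000)), cs)
  shared <- anc[anc$multiplicity == "one_to_two"]
  expect_setequal(unique(shared$chain_id), c("a", "b"))
  expect_true(all(start(shared) >= 1501 & end(shared) <= 2000))
  expect_true(all(shared$color == "blue"))
  solo <- anc[anc$multiplicity == "one_to_one"]
  expect_true(all(countOverlaps(granges(solo), granges(shared)) == 0))
})

test_that("more than maxAnchorLoci chains are cut to the top scorers", {
  cs <- chainSetOf(simpleChain("a", 900, 1000, 2000, 5000),
                   simpleChain("b", 800, 1000, 2000, 7000),
                   simpleChain("c", 700, 1000, 2000, 9000))
  anc <- anchorsForRegion(GRanges("chrT", IRanges(1, 10000)), cs)
  expect_setequal(unique(anc$chain_id), c("a", "b"))
  expect_true(all(anc$multiplicity == "one_to_two"))
})

test_that("per-base multiplicity equals the brute-force oracle", {
  set.seed(515)
  for (rep in 1:12) {
    nCh <- sample(2:5, 1)
    specs <- lapply(seq_len(nCh), function(i) {
      s <- randomChainSpec(letters[i], tName = "chrT", tSize = 2000L,
                           qName = sprintf("chrQ%d", i), qSize = 5000L,
                           qStrand = sample(c("+", "-"), 1),
                           score = sample(100:999, 1))
      s
    })
    f <- tempfile(fileext = ".chain")
    writeChainFile(f, lapply(specs, function(s) s[setdiff(names(s), "bm")]))
    cs <- readChains(f)
    region <- GRanges("chrT", IRanges(1, 2000))
    anc <- anchorsForRegion(region, cs)
    got <- anchorsToBaseMap(anc, 1, 2000)
    chainsSpec <- lapply(specs, function(s)
      list(id = s$id, score = s$score, bm = s$bm, tName = s$tName))
    want <- oracleMultiplicity("chrT", 1, 2000, chainsSpec, 2)
    # the oracle footprint tie-break counts whole-region coverage; ours does
    # too, so kept chain sets must agree base by base
    expect_equal(got$ids, want)
    # multiplicity flag agrees with the per-base chain count
    for (k in seq_along(anc)) {
      nCov <- lengths(want[start(anc)[k]:end(anc)[k]])
      if (anc$multiplicity[k] == "one_to_one") expect_true(all(nCov == 1))
      else expect_true(all(nCov >= 2))
    }
    # no reference base carries more than maxLoci chains
    expect_true(all(lengths(got$ids) <= 2))
  }
})

test_that("anchor output is invariant to chain input order", {
  set.seed(626)
  specs <- lapply(1:4, function(i)
    randomChainSpec(letters[i], tName = "chrT", tSize = 2000L,
                    qName = sprintf("chrQ%d", i), qSize = 5000L,
                    score = sample(100:999, 1)))
  region <- GRanges("chrT", IRanges(1, 2000))
  f1 <- tempfile(); f2 <- tempfile()
  writeChainFile(f1, lapply(specs, function(s) s[setdiff(names(s), "bm")]))
  writeChainFile(f2, lapply(rev(specs),
                            function(s) s[setdiff(names(s), "bm")]))
  a1 <- anchorsForRegion(region, readChains(f1))
  a2 <- anchorsForRegion(region, readChains(f2))
  o1 <- order(start(a1), a1$chain_id); o2 <- order(start(a2), a2$chain_id)
  expect_equal(granges(a1)[o1], granges(a2)[o2])
  expect_equal(a1$chain_id[o1], a2$chain_id[o2])
  expect_equal(a1$multiplicity[o1], a2$multiplicity[o2])
})

test_that("self-chain anchors discard trivial identity alignments", {
  paralog <- simpleChain("p", 900, 0, 1000, 5000, tName = "chr2",
                         qName = "chr7")
  trivial <- simpleChain("t", 99999, 0, 1000, 0, tName = "chr2",
                         qName = "chr2")
  tandem <- simpleChain("d", 800, 0, 1000, 1000, tName = "chr2",
                        qName = "chr2")
  region <- GRanges("chr2", IRanges(1, 1000))
  # paralogous locus on another sequence is kept
  a1 <- selfAnchors(region, chainSetOf(paralog, trivial))
  expect_setequal(unique(a1$chain_id), "p")
  # tandem duplication on the same sequence is kept
  a2 <- selfAnchors(region, chainSetOf(tandem, trivial))
  expect_setequal(unique(a2$chain_id), "d")
  # an identity chain alone yields nothing
  expect_length(selfAnchors(region, chainSetOf(trivial)), 0)
})

test_that("bridge composition intersects the two alignments in A", {
  # A[0,100) -> B[0,100) and A[50,150) -> C[200,300):
  # expected anchor B[50,100) <-> C[200,250)
  ab <- simpleChain("ab", 900, 0, 100, 0, tName = "chrA", qName = "chrB")
  ac <- simpleChain("ac", 800, 50, 150, 200, tName = "chrA", qName = "chrC")
  anc <- bridgeAnchors(chainSetOf(ab), chainSetOf(ac),
                       GRanges("chrB", IRanges(1, 100)))
  expect_length(anc, 1)
  expect_equal(c(start(anc), end(anc)), c(51, 100))
  expect_equal(c(start(anc$target), end(anc$target)), c(201, 250))
  expect_equal(anc$orientation, "same")
  expect_equal(anc$score, 800)

  # disjoint A footprints give nothing
  ac2 <- simpleChain("ac", 800, 5000, 5100, 200, tName = "chrA",
                     qName = "chrC")
  expect_length(bridgeAnchors(chainSetOf(ab), chainSetOf(ac2),
                              GRanges("chrB", IRanges(1, 100))), 0)
})

test_that("opposite times opposite composes to same orientation", {
  ab <- simpleChain("ab", 900, 0, 100, 500, tName = "chrA", qName = "chrB",
                    qStrand = "-")
  ac <- simpleChain("ac", 800, 0, 100, 700, tName = "chrA", qName = "chrC",
                    qStrand = "-")
  bRegion <- GRanges("chrB", IRanges(1, 100000))
  anc <- bridgeAnchors(chainSetOf(ab), chainSetOf(ac), bRegion)
  expect_true(length(anc) >= 1)
  expect_true(all(anc$orientation == "same"))
  # and same x opposite composes to opposite
  ac2 <- simpleChain("ac", 800, 0, 100, 700, tName = "chrA", qName = "chrC")
  anc2 <- bridgeAnchors(chainSetOf(ab), chainSetOf(ac2), bRegion)
  expect_true(all(anc2$orientation == "opposite"))
})

test_that("bridging a chain set with itself reproduces the identity", {
  set.seed(737)
  spec <- randomChainSpec("x", tName = "chrA", qName = "chrB")
  cs <- chainSetOf(spec[setdiff(names(spec), "bm")])
  bl <- blocksOf(cs)
  region <- GRanges("chrB", IRanges(min(bl$q_start), max(bl$q_end)))
  anc <- bridgeAnchors(cs, cs, region, minWidth = 1L)
  expect_true(length(anc) >= 1)
  expect_equal(granges(anc$target), granges(anc))
  expect_true(all(anc$orientation == "same"))
})

test_that("bridge composition equals the per-base oracle", {
  set.seed(848)
  for (rep in 1:6) {
    sAB <- randomChainSpec("ab", tName = "chrA", tSize = 10000L,
                           qName = "chrB", score = 900)
    sAC <- randomChainSpec("ac", tName = "chrA", tSize = 10000L,
                           qName = "chrC", score = 700)
    csAB <- chainSetOf(sAB[setdiff(names(sAB), "bm")])
    csAC <- chainSetOf(sAC[setdiff(names(sAC), "bm")])
    region <- GRanges("chrB", IRanges(1, 10000))
    anc <- bridgeAnchors(csAB, csAC, region, minWidth = 1L)
    got <- rep(NA_integer_, 10000)
    for (k in seq_along(anc))
      for (p in start(anc)[k]:end(anc)[k])
        got[p] <- mapAnchorPosition(anc[k], p) - 1L
    want <- oracleBridgeMap(sAB$bm, sAC$bm, 1, 10000)
    expect_equal(got, want)
  }
})

test_that("narrow composed anchors are dropped by the width filter", {
  ab <- simpleChain("ab", 900, 0, 100, 0, tName = "chrA", qName = "chrB")
  ac <- simpleChain("ac", 800, 95, 150, 200, tName = "chrA", qName = "chrC")
  region <- GRanges("chrB", IRanges(1, 100))
  # overlap in A is 5 bp: kept at minWidth 1, dropped at the default 10
  expect_length(bridgeAnchors(chainSetOf(ab), chainSetOf(ac), region,
                              minWidth = 1L), 1)
  expect_length(bridgeAnchors(chainSetOf(ab), chainSetOf(ac), region), 0)
})
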