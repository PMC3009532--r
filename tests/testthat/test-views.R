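# The three comparison views, shared/turnover TSS annotation, exon
# conservation and serialization.

# two-assembly fixture: one ref gene with TSSes 1000 and 5000 (+ strand), a
# same-orientation chain shifting everything by +4000, and a homologous gene
viewFixture <- function() {
  gmR <- makeGeneModels(list(cbind(c(1000, 2001), c(1500, 2600)),
                             cbind(c(5000, 6001), c(5500, 6600))),
                        "+", seq = "chrR", geneId = "GR")
  gmT <- makeGeneModels(list(cbind(c(5000, 6001), c(5500, 6600)),
                             cbind(c(9000, 10001), c(9500, 10600))),
                        "+", seq = "chrQ", geneId = "GT")
  ch <- list(score = 950, tName = "chrR", tSize = 100000, tStart = 0,
             tEnd = 20000, qName = "chrQ", qSize = 100000, qStart = 4000,
             qEnd = 24000, qStrand = "+", id = "1",
             blocks = cbind(20000, 0, 0))
  f <- tempfile(fileext = ".chain")
  writeChainFile(f, list(ch))
  list(gmR = gmR, gmT = gmT, cs = readChains(f))
}

test_that("promoter view spans the union of promoter regions", {
  fx <- viewFixture()
  v <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT, chains = fx$cs)
  expect_equal(c(start(v@ref@region), end(v@ref@region)), c(500, 5499))
  expect_equal(c(start(v@target@region), end(v@target@region)),
               c(4500, 9499))
  expect_equal(v@annotations$promoterCentersRef, c(1000L, 5000L))
  expect_true(length(v@anchors) >= 1)
  # anchors stay inside both regions
  expect_true(all(start(v@anchors) >= 500 & end(v@anchors) <= 5499))
  tgt <- v@anchors$target
  expect_true(all(start(tgt) >= 4500 & end(tgt) <= 9499))
})

test_that("a view without alignment is valid and anchor-free", {
  fx <- viewFixture()
  v <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT, chains = NULL)
  expect_length(v@anchors, 0)
  doc <- serializeView(v, "json")
  expect_true(jsonlite::validate(doc))
})

test_that("six isoforms with four distinct TSSes report four centers", {
  exs <- lapply(c(1000, 1000, 3000, 3000, 7000, 9000), function(s)
    cbind(c(s, s + 2001), c(s + 300, s + 2300)))
  gm <- makeGeneModels(exs, "+", seq = "chrR", geneId = "GR")
  fx <- viewFixture()
  v <- buildPromoterView("GR", "GT", gm, fx$gmT, chains = fx$cs)
  expect_length(v@annotations$promoterCentersRef, 4)
})

test_that("shared TSS detection follows the mapped-distance rule", {
  fx <- viewFixture()
  # ref TC at 1000 maps to 5000; target TC at 5040 is within tolerance 100
  tcR <- tagClustersFromPositions("chrR", 1000L, "+", 30L)
  tcT <- tagClustersFromPositions("chrQ", 5040L, "+", 20L)
  v <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT, tcR, tcT,
                         chains = fx$cs)
  st <- v@annotations$sharedTss
  expect_equal(nrow(st), 1)
  expect_equal(st$mapped_distance, 40)
  # outside tolerance: turnover on both sides
  tcT2 <- tagClustersFromPositions("chrQ", 5200L, "+", 20L)
  v2 <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT, tcR, tcT2,
                          chains = fx$cs)
  expect_equal(nrow(v2@annotations$sharedTss), 0)
  expect_equal(v2@annotations$turnoverRef, 1L)
  expect_equal(v2@annotations$turnoverTarget, 1L)
  # strand-inconsistent target TC is never shared
  tcT3 <- tagClustersFromPositions("chrQ", 5040L, "-", 20L)
  v3 <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT, tcR, tcT3,
                          chains = fx$cs)
  expect_equal(nrow(v3@annotations$sharedTss), 0)
})

test_that("shared pairs and turnover partition the TC sets", {
  set.seed(55)
  b <- simulateHomologousLoci(55, dupMode = "ortholog",
                              tssTurnoverProb = 0.4)
  tcR <- clusterTags(b$cageRef); tcT <- clusterTags(b$cageTarget)
  for (g in geneIds(b$gmRef)[1:3]) {
    v <- buildPromoterView(g, paste0(g, "o"), b$gmRef, b$gmTarget, tcR, tcT,
                           chains = b$chains)
    st <- v@annotations$sharedTss
    nR <- length(v@ref@tagClusters); nT <- length(v@target@tagClusters)
    expect_setequal(c(st$ref_tc, v@annotations$turnoverRef), seq_len(nR))
    expect_setequal(c(st$target_tc, v@annotations$turnoverTarget),
                    seq_len(nT))
    if (nrow(st))
      expect_true(all(st$mapped_distance <=
                        v@params$sharedTssTolerance))
  }
})

test_that("swapping the loci yields the mirror view", {
  set.seed(66)
  b <- simulateHomologousLoci(66, dupMode = "ortholog",
                              tssTurnoverProb = 0.3)
  tcR <- clusterTags(b$cageRef); tcT <- clusterTags(b$cageTarget)
  for (g in geneIds(b$gmRef)[1:3]) {
    v <- buildPromoterView(g, paste0(g, "o"), b$gmRef, b$gmTarget, tcR, tcT,
                           chains = b$chains)
    m <- buildPromoterView(paste0(g, "o"), g, b$gmTarget, b$gmRef, tcT, tcR,
                           chains = b$chains)
    a <- v@annotations$sharedTss
    bb <- m@annotations$sharedTss
    expect_equal(nrow(a), nrow(bb))
    expect_setequal(paste(a$ref_pos, a$target_pos),
                    paste(bb$target_pos, bb$ref_pos))
  }
})

test_that("gene-structure views pad transcripts and score exon coverage", {
  fx <- viewFixture()
  v <- buildGeneStructureView("GR", "GT", fx$gmR, fx$gmT, chains = fx$cs)
  sp <- txSpans(fx$gmR)
  expect_equal(start(v@ref@region), min(start(sp)) - 500)
  expect_equal(end(v@ref@region), max(end(sp)) + 500)
  ec <- v@annotations$exonConservation
  # the fixture chain covers everything: fully conserved exons
  expect_true(all(ec$fraction == 1))
  expect_setequal(unique(ec$side), c("ref", "target"))
})

test_that("exon conservation is the anchored fraction of each exon", {
  exons <- GRanges("chrR", IRanges(c(1, 101), c(100, 200)), strand = "+")
  full <- GRanges("chrR", IRanges(1, 200))
  expect_equal(exonConservation(exons, full)$fraction, c(1, 1))
  half <- GRanges("chrR", IRanges(1, 50))
  expect_equal(exonConservation(exons, half)$fraction, c(0.5, 0))
  expect_equal(exonConservation(exons, GRanges())$fraction, c(0, 0))
  # monotone non-decreasing as anchors are added
  set.seed(77)
  added <- GRanges()
  prev <- c(0, 0)
  for (i in 1:6) {
    s <- sample(1:190, 1)
    added <- c(added, GRanges("chrR", IRanges(s, s + sample(5:40, 1))))
    cur <- exonConservation(exons, added)$fraction
    expect_true(all(cur >= prev - 1e-12))
    expect_true(all(cur >= 0 & cur <= 1))
    prev <- cur
  }
})

test_that("fractional exon conservation is recovered from exonic indels", {
  b <- simulateHomologousLoci(31, dupMode = "ortholog", tssTurnoverProb = 0,
                              exonIndels = TRUE)
  tr <- b$truth$exonConservation
  degraded <- tr[tr$fraction < 1, ]
  skipIfNone <- nrow(degraded) > 0
  expect_true(skipIfNone)  # seed chosen arbitrarily; layout guarantees some
  for (g in unique(sub("\\.t\\d+$", "", degraded$tx_id))) {
    v <- buildGeneStructureView(g, paste0(g, "o"), b$gmRef, b$gmTarget,
                                chains = b$chains)
    ec <- v@annotations$exonConservation
    ec <- ec[ec$side == "ref", ]
    want <- tr[sub("\\.t\\d+$", "", tr$tx_id) == g, ]
    got <- merge(ec, want, by = c("tx_id", "exon_index"))
    expect_equal(got$fraction.x, got$fraction.y, tolerance = 1e-12)
  }
})

test_that("neighborhood views link homologous neighbors with order flags", {
  set.seed(88)
  b <- simulateHomologousLoci(88, dupMode = "ortholog")
  g <- geneIds(b$gmRef)[3]
  v <- buildNeighborhoodView(g, paste0(g, "o"), b$gmRef, b$gmTarget,
                             b$homology)
  # the simulated locus sits near the origin, so the 2 Mb window is
  # left-clipped at base 1; the right edge is midpoint + 1 Mb
  box <- geneSpans(subsetGenes(b$gmRef, geneIds = g))
  mid0 <- (start(box) - 1L + end(box)) %/% 2L
  expect_equal(start(v@ref@region), 1)
  expect_equal(end(v@ref@region), mid0 + 1000000L)
  nl <- v@annotations$neighborLinks
  # every simulated gene is an ortholog neighbor inside the 2 Mb window
  expect_equal(nrow(nl), length(geneIds(b$gmRef)))
  expect_true(all(nl$strands_agree))
  expect_true(v@annotations$conservedOrder)
  expect_true(all(v@anchors$color == "gene"))

  # no homologs among neighbors: only the query pair is linked
  emptyHom <- b$homology[0, ]
  v2 <- buildNeighborhoodView(g, paste0(g, "o"), b$gmRef, b$gmTarget,
                              emptyHom)
  expect_equal(nrow(v2@annotations$neighborLinks), 1)
  expect_equal(v2@annotations$neighborLinks$relation, "query")
})

test_that("scrambled target gene order clears the conserved-order flag", {
  gmR <- GeneModels(
    do.call(c, lapply(1:3, function(i) exonsByTx(
      makeGeneModels(list(cbind(i * 10000, i * 10000 + 500)), "+",
                     seq = "chrR", geneId = paste0("r", i))))),
    DataFrame(tx_id = paste0("r", 1:3, ".t1"), gene_id = paste0("r", 1:3)))
  # target order reversed relative to ref is still collinear (inversion);
  # a genuine scramble breaks monotonicity
  ordT <- c(2, 1, 3)
  gmT <- GeneModels(
    do.call(c, lapply(1:3, function(i) exonsByTx(
      makeGeneModels(list(cbind(ordT[i] * 10000, ordT[i] * 10000 + 500)),
                     "+", seq = "chrQ", geneId = paste0("t", i))))),
    DataFrame(tx_id = paste0("t", 1:3, ".t1"), gene_id = paste0("t", 1:3)))
  hom <- data.frame(gene_a = paste0("r", 1:3), species_a = "A",
                    gene_b = paste0("t", 1:3), species_b = "B",
                    relation = "ortholog", ancestor_taxon = "X",
                    confidence = NA)
  v <- buildNeighborhoodView("r1", "t1", gmR, gmT, hom)
  expect_equal(nrow(v@annotations$neighborLinks), 3)
  expect_false(v@annotations$conservedOrder)
})

test_that("JSON serialization round-trips every coordinate exactly", {
  set.seed(99)
  b <- simulateHomologousLoci(99, dupMode = "ortholog")
  tcR <- clusterTags(b$cageRef); tcT <- clusterTags(b$cageTarget)
  g <- geneIds(b$gmRef)[2]
  v <- buildPromoterView(g, paste0(g, "o"), b$gmRef, b$gmTarget, tcR, tcT,
                         chains = b$chains)
  f <- tempfile(fileext = ".json")
  serializeView(v, "json", f)
  v2 <- readViewJSON(f)
  expect_equal(granges(v2@ref@region), granges(v@ref@region))
  expect_equal(granges(v2@target@region), granges(v@target@region))
  expect_equal(granges(v2@anchors), granges(v@anchors))
  expect_equal(granges(v2@anchors$target), granges(v@anchors$target))
  expect_equal(v2@ref@tagClusters$repPos, v@ref@tagClusters$repPos)
  expect_equal(v2@ref@tagClusters$tpm, v@ref@tagClusters$tpm)
  for (tx in names(exonsByTx(v@ref@genes)))
    expect_equal(ranges(exonsByTx(v2@ref@genes)[[tx]]),
                 ranges(exonsByTx(v@ref@genes)[[tx]]))
  # serializing the reconstruction reproduces the document byte for byte
  expect_identical(serializeView(v2, "json"), serializeView(v, "json"))
  expect_error(serializeView(v, "pdf"))
})

test_that("zero-anchor views serialize to valid JSON with empty anchors", {
  fx <- viewFixture()
  v <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT)
  doc <- serializeView(v, "json")
  parsed <- jsonlite::fromJSON(doc)
  expect_length(parsed$anchors, 0)
})

test_that("SVG output is well-formed XML with anchor ribbons and TC bars", {
  fx <- viewFixture()
  tcR <- tagClustersFromPositions("chrR", c(1000L, 5000L), "+", c(30L, 10L))
  tcT <- tagClustersFromPositions("chrQ", 5000L, "+", 20L)
  v <- buildPromoterView("GR", "GT", fx$gmR, fx$gmT, tcR, tcT,
                         chains = fx$cs)
  svg <- serializeView(v, "svg")
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_true(length(xml2::xml_find_all(doc, ".//*[local-name()='polygon']"))
              >= 1)
  expect_true(length(xml2::xml_find_all(doc, ".//*[local-name()='rect']"))
              >= 3)
})

test_that("unknown genes fail with near-miss suggestions", {
  fx <- viewFixture()
  expect_error(buildPromoterView("GQ", "GT", fx$gmR, fx$gmT),
               "did you mean")
})

test_that("the fixture view reproduces the golden JSON byte for byte", {
  golden <- system.file("extdata", "golden_promoter_view.json",
                        package = "homolocus")
  b <- simulateHomologousLoci(424242, dupMode = "ortholog",
                              tssTurnoverProb = 0.3)
  tcR <- clusterTags(b$cageRef); tcT <- clusterTags(b$cageTarget)
  g <- geneIds(b$gmRef)[1]
  v <- buildPromoterView(g, paste0(g, "o"), b$gmRef, b$gmTarget, tcR, tcT,
                         chains = b$chains,
                         assemblies = c(ref = "genomeA",
                                        target = "genomeB"))
  expect_identical(strsplit(serializeView(v, "json"), "\n")[[1]],
                   readLines(golden))
})
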