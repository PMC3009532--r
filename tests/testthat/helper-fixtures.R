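# Small fixture builders used across the tests.  Everything is generated in
# code; chain files are written from raw numbers so that tests control the
# exact bytes the parser sees.

# chains: list of list(score, tName, tSize, tStart, tEnd, qName, qSize,
#                      qStrand, qStart, qEnd, id, blocks = matrix with
#                      columns size, dt, dq (dt/dq ignored on last row))
writeChainFile <- function(path, chains) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", ch$score, ch$tName, ch$tSize, "+",
                     ch$tStart, ch$tEnd, ch$qName, ch$qSize, ch$qStrand,
                     ch$qStart, ch$qEnd, ch$id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L)
      writeLines(paste(b[-n, 1], b[-n, 2], b[-n, 3]), con)
    writeLines(c(as.character(b[n, 1]), ""), con)
  }
  invisible(path)
}

# a random consistent chain on a <=10 kb genome; returns the raw spec plus
# its oracle base map
randomChainSpec <- function(id, tName = "chrT", tSize = 10000L,
                            qName = "chrQ", qSize = 10000L,
                            qStrand = "+", score = 1000) {
  nb <- sample(1:5, 1)
  sizes <- sample(20:200, nb, replace = TRUE)
  dts <- c(sample(0:100, nb - 1, replace = TRUE), 0L)
  dqs <- c(sample(0:100, nb - 1, replace = TRUE), 0L)
  tSpan <- sum(sizes + dts)
  qSpan <- sum(sizes + dqs)
  tStart <- sample(0:(tSize - tSpan), 1)
  qStart <- sample(0:(qSize - qSpan), 1)
  list(score = score, tName = tName, tSize = tSize, tStart = tStart,
       tEnd = tStart + tSpan, qName = qName, qSize = qSize,
       qStrand = qStrand, qStart = qStart, qEnd = qStart + qSpan, id = id,
       blocks = cbind(sizes, dts, dqs),
       bm = oracleBaseMap(tStart, sizes, dts, dqs, qStart, qStrand, qSize))
}

# random CAGE tags as a CageLibrary (spans 1-25 bp)
randomTagLibrary <- function(n, seqs = c("chr1", "chr2"), span = 3000L) {
  st <- sample(seq_len(span), n, replace = TRUE)
  w <- sample(1:25, n, replace = TRUE)
  str <- sample(c("+", "-"), n, replace = TRUE)
  gr <- GRanges(sample(seqs, n, replace = TRUE), IRanges(st, width = w),
                strand = str,
                count = sample(1:9, n, replace = TRUE))
  gr$fivePrime <- ifelse(str == "-", end(gr), start(gr))
  CageLibrary(gr)
}

# minimal GeneModels: one gene, transcripts given as list of exon matrices
# (columns start, end), one strand
makeGeneModels <- function(txExons, strand = "+", seq = "chr1",
                           geneId = "G1", txIds = NULL) {
  if (is.null(txIds)) txIds <- paste0(geneId, ".t", seq_along(txExons))
  exl <- lapply(txExons, function(m)
    GRanges(seq, IRanges(m[, 1], m[, 2]), strand = strand))
  GeneModels(stats::setNames(GRangesList(exl), txIds),
             DataFrame(tx_id = txIds, gene_id = rep(geneId,
                                                    length(txIds))))
}

tagClustersFromPositions <- function(seqname, pos, strand, counts,
                                     librarySize = NULL) {
  gr <- GRanges(seqname, IRanges(pos, width = 1L), strand = strand,
                count = counts, fivePrime = pos)
  clusterTags(CageLibrary(gr, librarySize))
}
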