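## Synthetic fixture generation: self-consistent gene models, chain
## alignments, CAGE libraries and homology tables for a pair of homologous
## loci, with the planted ground truth (shared/turnover TSSes, anchor
## segments, WGD pairs, exon conservation) recorded alongside.
##
## The construction works on an "ancestral" locus layout; descendant loci are
## the ancestor shifted by a constant offset plus random indels, which become
## the gaps of the emitted chains.  Indels avoid a protected pad around every
## TSS and (by default) every exon, so planted promoter positions map exactly
## through the chains and exon conservation stays 1; exonic indels can be
## switched on to exercise fractional conservation.

.EXON_W <- c(150L, 200L, 180L)
.INTRON_W <- c(700L, 600L)
.TSS_SPACING <- 1200L
.TSS_PAD <- 560L

.makeTxExons <- function(tss1, strand, seqname) {
  w <- as.integer(rbind(.EXON_W, c(.INTRON_W, NA))[
    !is.na(rbind(.EXON_W, c(.INTRON_W, NA)))])
  if (strand == "+") {
    b <- tss1 + c(0L, cumsum(w))
    st <- b[c(1, 3, 5)]; en <- b[c(2, 4, 6)] - 1L
  } else {
    b <- tss1 - c(0L, cumsum(w))
    st <- b[c(2, 4, 6)] + 1L; en <- b[c(1, 3, 5)]
    tmp <- st; st <- rev(st); en <- rev(en)
  }
  GRanges(seqname, IRanges(sort(st), sort(en)), strand = strand)
}

## lay out nGenes genes with nTx alternative-promoter transcripts each;
## returns GeneModels plus the per-transcript TSS table
.layoutLocus <- function(nGenes, nTx, seqname, startAt = 5000L,
                         prefix = "g") {
  cursor <- startAt
  exl <- list(); tx_id <- character(); gene_id <- character()
  tss <- integer(); tstr <- character(); n <- 0L
  bodyLen <- sum(.EXON_W) + sum(.INTRON_W)
  for (g in seq_len(nGenes)) {
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    spacing <- as.integer(round(stats::runif(1, 4000, 6000)))
    base <- cursor + spacing
    if (strand == "-") base <- base + bodyLen - 1L
    gid <- sprintf("%s%02d", prefix, g)
    for (t in seq_len(nTx)) {
      n <- n + 1L
      tpos <- base + (t - 1L) * .TSS_SPACING
      exl[[n]] <- .makeTxExons(tpos, strand, seqname)
      tx_id[n] <- sprintf("%s.t%d", gid, t)
      gene_id[n] <- gid
      tss[n] <- tpos; tstr[n] <- strand
    }
    cursor <- max(unlist(lapply(exl[(n - nTx + 1L):n],
                                function(e) end(e))))
  }
  gm <- GeneModels(stats::setNames(GRangesList(exl), tx_id),
                   DataFrame(tx_id = tx_id, gene_id = gene_id))
  list(gm = gm, tss = data.frame(tx_id = tx_id, gene_id = gene_id,
                                 tss = tss, strand = tstr,
                                 stringsAsFactors = FALSE))
}

## descendant coordinate map: conserved blocks (a_start0, size, b_start0)
## from random indels in the free zones between protected intervals, plus
## explicit exonic deletions (ref bases dropped from the alignment)
.makeDescendantMap <- function(span0, protected, offset0, indelRate,
                               exonDeletions = NULL) {
  events <- data.frame(pos0 = integer(), dt = integer(), dq = integer())
  free <- setdiff(IRanges(span0[1] + 1L, span0[2]),
                  IRanges(start(protected), end(protected)))
  for (i in seq_along(free)) {
    if (width(free)[i] < 200L) next
    if (stats::runif(1) >= indelRate) next
    p0 <- start(free)[i] - 1L + width(free)[i] %/% 2L
    size <- as.integer(round(stats::runif(1, 30, 150)))
    if (stats::runif(1) < 0.5)
      events <- rbind(events, data.frame(pos0 = p0, dt = size, dq = 0L))
    else
      events <- rbind(events, data.frame(pos0 = p0, dt = 0L, dq = size))
  }
  if (!is.null(exonDeletions) && nrow(exonDeletions))
    events <- rbind(events, data.frame(pos0 = exonDeletions$start0,
                                       dt = exonDeletions$width, dq = 0L))
  events <- events[order(events$pos0), , drop = FALSE]
  aCur <- span0[1]; bCur <- span0[1] + offset0
  blocks <- data.frame(a_start0 = integer(), size = integer(),
                       b_start0 = integer())
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    sz <- e$pos0 - aCur
    stopifnot(sz > 0L)
    blocks <- rbind(blocks, data.frame(a_start0 = aCur, size = sz,
                                       b_start0 = bCur))
    bCur <- bCur + sz + e$dq
    aCur <- e$pos0 + e$dt
  }
  sz <- span0[2] - aCur
  blocks <- rbind(blocks, data.frame(a_start0 = aCur, size = sz,
                                     b_start0 = bCur))
  blocks
}

.mapPos0 <- function(blocks, p0) {
  vapply(p0, function(p) {
    i <- which(blocks$a_start0 <= p & p < blocks$a_start0 + blocks$size)
    if (!length(i)) NA_integer_
    else blocks$b_start0[i[1]] + (p - blocks$a_start0[i[1]])
  }, 1L)
}

.mapRange1 <- function(blocks, s1, e1) {
  # bounding box of the mapped bases of [s1, e1]
  hits <- blocks[blocks$a_start0 < e1 & blocks$a_start0 + blocks$size >=
                   s1, , drop = FALSE]
  stopifnot(nrow(hits) > 0L)
  ss <- pmax(hits$a_start0 + 1L, s1); ee <- pmin(hits$a_start0 + hits$size,
                                                 e1)
  bs <- hits$b_start0 + (ss - hits$a_start0 - 1L) + 1L
  be <- hits$b_start0 + (ee - hits$a_start0 - 1L) + 1L
  c(min(bs), max(be))
}

.chainFromBlocks <- function(blocks, id, score, tName, qName,
                             tSize = 10000000L, qSize = 10000000L) {
  n <- nrow(blocks)
  chainDf <- data.frame(chain_id = id, score = score, t_name = tName,
                        t_size = tSize, t_strand = "+",
                        t_start = blocks$a_start0[1],
                        t_end = blocks$a_start0[n] + blocks$size[n],
                        q_name = qName, q_size = qSize, q_strand = "+",
                        q_start = blocks$b_start0[1],
                        q_end = blocks$b_start0[n] + blocks$size[n])
  blockDf <- data.frame(t_start0 = blocks$a_start0, size = blocks$size,
                        q_start0 = blocks$b_start0, chain_id = id,
                        score = score, t_name = tName, q_name = qName,
                        orientation = "same")
  list(chain = chainDf, blocks = blockDf)
}

.combineChainParts <- function(parts) {
  .makeChainSet(do.call(rbind, lapply(parts, `[[`, "chain")),
                do.call(rbind, lapply(parts, `[[`, "blocks")))
}

## descendant gene models: exons mapped through the block map; exons whose
## alignment was wholly deleted are dropped
.mapGeneModels <- function(gm, blocks, seqname, suffix = "") {
  exl <- list(); tx_id <- character(); gene_id <- character(); n <- 0L
  for (t in seq_along(gm@exonsByTx)) {
    ex <- gm@exonsByTx[[t]]
    st <- integer(); en <- integer()
    for (i in seq_along(ex)) {
      covered <- any(blocks$a_start0 < end(ex)[i] &
                       blocks$a_start0 + blocks$size >= start(ex)[i])
      if (!covered) next
      r <- .mapRange1(blocks, start(ex)[i], end(ex)[i])
      st <- c(st, r[1]); en <- c(en, r[2])
    }
    if (!length(st)) next
    n <- n + 1L
    exl[[n]] <- GRanges(seqname, IRanges(st, en),
                        strand = as.character(strand(ex))[1])
    tx_id[n] <- paste0(gm@txData$tx_id[t], suffix)
    gene_id[n] <- paste0(gm@txData$gene_id[t], suffix)
  }
  GeneModels(stats::setNames(GRangesList(exl), tx_id),
             DataFrame(tx_id = tx_id, gene_id = gene_id))
}

#' Write gene models as GTF (exon records)
#'
#' @param gm a \code{\link{GeneModels}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelsGTF <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_along(gm@exonsByTx)) {
    ex <- gm@exonsByTx[[t]]
    gid <- gm@txData$gene_id[t]
    gname <- gm@geneData$name[match(gid, gm@geneData$gene_id)]
    for (i in seq_along(ex))
      writeLines(sprintf(
        "%s\thomolocus\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
        as.character(seqnames(ex))[i], start(ex)[i], end(ex)[i],
        as.character(strand(ex))[i], gid, gm@txData$tx_id[t], gname), con)
  }
  invisible(path)
}

#' Write a CAGE library as CTSS text
#'
#' Four whitespace-separated columns: sequence, 1-based position, strand,
#' count.
#'
#' @param lib a \code{\link{CageLibrary}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCTSS <- function(lib, path) {
  tg <- lib@tags
  o <- order(as.character(seqnames(tg)), tg$fivePrime,
             as.character(strand(tg)))
  writeLines(sprintf("%s\t%d\t%s\t%d",
                     as.character(seqnames(tg))[o], tg$fivePrime[o],
                     as.character(strand(tg))[o], tg$count[o]), path)
  invisible(path)
}

#' Simulate a pair of homologous loci with known truth
#'
#' Builds an ancestral locus layout (\code{nGenes} genes, \code{nTxPerGene}
#' alternative-promoter transcripts each), derives descendant loci by
#' constant coordinate offset plus random indels placed between the protected
#' TSS/exon pads (the indels become chain gaps), and plants one CAGE tag
#' cluster per transcript TSS on the reference locus, copying it to the
#' homologous target position with probability \code{1 - tssTurnoverProb}.
#' Half of the turnover events instead gain a novel target cluster shifted
#' 150-250 bp from the homologous position.  Everything is deterministic
#' given \code{seed}.
#'
#' Modes: \code{"ortholog"} (two assemblies, one chain file),
#' \code{"self_paralog"} (one assembly, two loci linked by a self-chain plus
#' a trivial identity chain that consumers are expected to discard), and
#' \code{"bridged_paralog"} (two descendant loci in one assembly, each
#' aligned to the ancestral locus of an outgroup assembly by its own chain
#' file sharing the outgroup on the target side — the ortholog-bridge
#' scenario).
#'
#' @param seed integer seed; same seed, same bundle, byte for byte.
#' @param nGenes,nTxPerGene locus layout (defaults 6 and 2).
#' @param dupMode one of \code{"ortholog"}, \code{"self_paralog"},
#'   \code{"bridged_paralog"}.
#' @param tssTurnoverProb per-TSS probability that the promoter is not
#'   copied to the homologous locus (default 0.3).
#' @param indelRate per-free-zone probability of one 30-150 bp indel
#'   (default 0.15).
#' @param exonIndels when TRUE, internal exons additionally receive
#'   alignment deletions (probability 0.5 each: 30-60\% of the exon, or with
#'   probability 0.2 the whole exon), exercising fractional exon
#'   conservation.
#' @param outDir when given, the bundle is written there (GTF x2, chain
#'   file(s), CTSS x2, homology TSV, truth JSON) and the paths are returned
#'   in \code{$files}.
#' @return A list: \code{gmRef}, \code{gmTarget} (GeneModels), \code{chains}
#'   (ChainSet; for bridged mode \code{chainsAB}/\code{chainsAC} instead),
#'   \code{cageRef}, \code{cageTarget} (CageLibrary; one shared library for
#'   within-assembly modes), \code{homology} (data.frame), \code{truth}
#'   (list), \code{assemblies}, \code{files} (or NULL).
#' @export
simulateHomologousLoci <- function(seed, nGenes = 6L, nTxPerGene = 2L,
                                   dupMode = c("ortholog", "self_paralog",
                                               "bridged_paralog"),
                                   tssTurnoverProb = 0.3,
                                   indelRate = 0.15,
                                   exonIndels = FALSE,
                                   outDir = NULL) {
  dupMode <- match.arg(dupMode)
  stopifnot(tssTurnoverProb >= 0, tssTurnoverProb <= 1,
            indelRate >= 0, indelRate <= 1, nGenes >= 1L, nTxPerGene >= 1L)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  ancSeq <- switch(dupMode, ortholog = "chrA", self_paralog = "chrS",
                   bridged_paralog = "chrH")
  lay <- .layoutLocus(nGenes, nTxPerGene, ancSeq,
                      prefix = switch(dupMode, ortholog = "gA",
                                      self_paralog = "gS",
                                      bridged_paralog = "gH"))
  anc <- lay$gm; tssTab <- lay$tss
  allEx <- unlist(anc@exonsByTx, use.names = FALSE)
  span0 <- c(min(start(allEx)) - 2000L, max(end(allEx)) + 2000L)
  span0[1] <- span0[1] - 1L  # 0-based start

  ## protected pads: every TSS window, and exon bodies unless exonIndels
  prot <- IRanges(tssTab$tss - .TSS_PAD, tssTab$tss + .TSS_PAD)
  exonDel <- NULL
  exonFrac <- data.frame(tx_id = character(), exon_index = integer(),
                         fraction = numeric())
  if (exonIndels) {
    del <- list(); d <- 0L
    for (t in seq_along(anc@exonsByTx)) {
      ex <- anc@exonsByTx[[t]]
      fr <- rep(1, length(ex))
      five <- if (as.character(strand(ex))[1] == "-") length(ex) else 1L
      for (i in seq_along(ex)) {
        if (i == five) next
        if (stats::runif(1) >= 0.5) next
        wEx <- width(ex)[i]
        if (stats::runif(1) < 0.2) {
          dw <- wEx; s0 <- start(ex)[i] - 1L
        } else {
          dw <- as.integer(round(wEx * stats::runif(1, 0.3, 0.6)))
          s0 <- start(ex)[i] - 1L + (wEx - dw) %/% 2L
        }
        d <- d + 1L
        del[[d]] <- data.frame(start0 = s0, width = dw)
        fr[i] <- 1 - dw / wEx
      }
      exonFrac <- rbind(exonFrac,
                        data.frame(tx_id = names(anc@exonsByTx)[t],
                                   exon_index = seq_along(ex),
                                   fraction = fr))
      # keep remaining exons of this tx out of the free zones
      prot <- c(prot, IRanges(start(ex), end(ex)))
    }
    exonDel <- if (d) do.call(rbind, del) else NULL
  } else {
    prot <- c(prot, IRanges(start(allEx) - 50L, end(allEx) + 50L))
    for (t in seq_along(anc@exonsByTx))
      exonFrac <- rbind(exonFrac,
                        data.frame(tx_id = names(anc@exonsByTx)[t],
                                   exon_index =
                                     seq_along(anc@exonsByTx[[t]]),
                                   fraction = rep(1,
                                     length(anc@exonsByTx[[t]]))))
  }
  prot <- reduce(prot)

  ## descendant map(s)
  if (dupMode == "bridged_paralog") {
    mapB <- .makeDescendantMap(span0, prot, 20000L, indelRate, exonDel)
    mapC <- .makeDescendantMap(span0, prot, 60000L, indelRate, exonDel)
  } else {
    mapB <- .makeDescendantMap(span0, prot,
                               if (dupMode == "self_paralog")
                                 span0[2] + 50000L else 10000L,
                               indelRate, exonDel)
  }

  ## assemble per-mode gene models, chains, assemblies
  mkCage <- function(tab, seqname) {
    if (!nrow(tab)) return(GRanges())
    # one planted tag cluster per TSS, count 10-50
    cnt <- as.integer(round(stats::runif(nrow(tab), 10, 50)))
    GRanges(seqname, IRanges(tab$pos, width = 1L), strand = tab$strand,
            count = cnt, fivePrime = tab$pos)
  }

  turn <- stats::runif(nrow(tssTab)) < tssTurnoverProb
  novel <- turn & (stats::runif(nrow(tssTab)) < 0.5)
  shiftSign <- ifelse(stats::runif(nrow(tssTab)) < 0.5, -1L, 1L)
  shiftBp <- as.integer(round(stats::runif(nrow(tssTab), 150, 250)))

  homRows <- function(a, spA, b, spB, rel, taxon)
    data.frame(gene_a = a, species_a = spA, gene_b = b, species_b = spB,
               relation = rel, ancestor_taxon = taxon,
               confidence = "high", stringsAsFactors = FALSE)

  files <- NULL
  truth <- list(mode = dupMode, seed = as.integer(seed),
                params = list(nGenes = nGenes, nTxPerGene = nTxPerGene,
                              tssTurnoverProb = tssTurnoverProb,
                              indelRate = indelRate,
                              exonIndels = exonIndels),
                exonConservation = exonFrac)

  if (dupMode == "ortholog" || dupMode == "self_paralog") {
    tgtSeq <- if (dupMode == "ortholog") "chrB" else "chrS"
    sfx <- if (dupMode == "self_paralog") "p" else "o"
    gmTgt <- .mapGeneModels(anc, mapB, tgtSeq, suffix = sfx)
    part <- .chainFromBlocks(mapB, "1", 9000, ancSeq, tgtSeq)
    parts <- list(part)
    if (dupMode == "self_paralog") {
      # trivial identity self-chain over the first locus span
      ident <- data.frame(a_start0 = span0[1], size = span0[2] - span0[1],
                          b_start0 = span0[1])
      parts <- c(parts, list(.chainFromBlocks(ident, "2", 99999, ancSeq,
                                              ancSeq)))
    }
    chains <- .combineChainParts(parts)
    mappedTss <- .mapPos0(mapB, tssTab$tss - 1L) + 1L
    refTab <- data.frame(pos = tssTab$tss, strand = tssTab$strand)
    tgtKeep <- !turn
    tgtTab <- data.frame(pos = mappedTss[tgtKeep],
                         strand = tssTab$strand[tgtKeep])
    novTab <- data.frame(pos = mappedTss[novel] +
                           shiftSign[novel] * shiftBp[novel],
                         strand = tssTab$strand[novel])
    refTags <- mkCage(refTab, ancSeq)
    tgtTags <- suppressWarnings(c(mkCage(tgtTab, tgtSeq),
                                  mkCage(novTab, tgtSeq)))
    if (dupMode == "self_paralog") {
      gmRef <- GeneModels(c(anc@exonsByTx, gmTgt@exonsByTx),
                          rbind(anc@txData, gmTgt@txData))
      gmTgt2 <- gmRef
      lib <- CageLibrary(sort(suppressWarnings(c(refTags, tgtTags)),
                               ignore.strand = TRUE))
      cageRef <- lib; cageTarget <- lib
      assemblies <- c(ref = "genomeS", target = "genomeS")
      hom <- homRows(unique(anc@txData$gene_id), "genomeS",
                     paste0(unique(anc@txData$gene_id), sfx), "genomeS",
                     "paralog", "Vertebrata")
      gmOut <- list(ref = gmRef, target = gmTgt2)
    } else {
      cageRef <- CageLibrary(sort(refTags, ignore.strand = TRUE))
      cageTarget <- CageLibrary(sort(tgtTags, ignore.strand = TRUE))
      assemblies <- c(ref = "genomeA", target = "genomeB")
      hom <- homRows(unique(anc@txData$gene_id), "genomeA",
                     paste0(unique(anc@txData$gene_id), sfx), "genomeB",
                     "ortholog", "Euarchontoglires")
      gmOut <- list(ref = anc, target = gmTgt)
    }
    truth$sharedPairs <- data.frame(
      tx_id = tssTab$tx_id[!turn],
      ref_seq = rep(ancSeq, sum(!turn)), ref_pos = tssTab$tss[!turn],
      target_seq = rep(tgtSeq, sum(!turn)), target_pos = mappedTss[!turn],
      strand = tssTab$strand[!turn])
    truth$turnoverRef <- data.frame(
      tx_id = tssTab$tx_id[turn], seq = rep(ancSeq, sum(turn)),
      pos = tssTab$tss[turn])
    truth$turnoverTarget <- data.frame(
      seq = rep(tgtSeq, sum(novel)),
      pos = mappedTss[novel] + shiftSign[novel] * shiftBp[novel])
    truth$anchorBlocks <- mapB
    truth$wgdPairs <- NULL
    bundle <- list(gmRef = gmOut$ref, gmTarget = gmOut$target,
                   chains = chains, cageRef = cageRef,
                   cageTarget = cageTarget, homology = hom,
                   assemblies = assemblies, truth = truth)
  } else {
    ## bridged: ancestor is the outgroup (chrH); descendants are two loci of
    ## one duplicated assembly, each with its own chain to the outgroup
    gmB <- .mapGeneModels(anc, mapB, "chrZ1", suffix = "b")
    gmC <- .mapGeneModels(anc, mapC, "chrZ2", suffix = "c")
    chainsAB <- .combineChainParts(list(
      .chainFromBlocks(mapB, "AB1", 9000, "chrH", "chrZ1")))
    chainsAC <- .combineChainParts(list(
      .chainFromBlocks(mapC, "AC1", 8500, "chrH", "chrZ2")))
    mappedB <- .mapPos0(mapB, tssTab$tss - 1L) + 1L
    mappedC <- .mapPos0(mapC, tssTab$tss - 1L) + 1L
    refTab <- data.frame(pos = mappedB, strand = tssTab$strand)
    tgtTab <- data.frame(pos = mappedC[!turn], strand = tssTab$strand[!turn])
    novTab <- data.frame(pos = mappedC[novel] +
                           shiftSign[novel] * shiftBp[novel],
                         strand = tssTab$strand[novel])
    fishTags <- suppressWarnings(c(mkCage(refTab, "chrZ1"),
                                   mkCage(tgtTab, "chrZ2"),
                                   mkCage(novTab, "chrZ2")))
    lib <- CageLibrary(sort(fishTags, ignore.strand = TRUE))
    gmFish <- GeneModels(suppressWarnings(c(gmB@exonsByTx, gmC@exonsByTx)),
                         rbind(gmB@txData, gmC@txData))
    gidH <- unique(anc@txData$gene_id)
    hom <- rbind(homRows(gidH, "genomeH", paste0(gidH, "b"), "genomeZ",
                         "ortholog", "Euteleostomi"),
                 homRows(gidH, "genomeH", paste0(gidH, "c"), "genomeZ",
                         "ortholog", "Euteleostomi"))
    truth$sharedPairs <- data.frame(
      tx_id = tssTab$tx_id[!turn],
      ref_seq = rep("chrZ1", sum(!turn)), ref_pos = mappedB[!turn],
      target_seq = rep("chrZ2", sum(!turn)), target_pos = mappedC[!turn],
      strand = tssTab$strand[!turn])
    truth$turnoverRef <- data.frame(
      tx_id = tssTab$tx_id[turn], seq = rep("chrZ1", sum(turn)),
      pos = mappedB[turn])
    truth$turnoverTarget <- data.frame(
      seq = rep("chrZ2", sum(novel)),
      pos = mappedC[novel] + shiftSign[novel] * shiftBp[novel])
    truth$anchorBlocks <- list(AB = mapB, AC = mapC)
    truth$wgdPairs <- data.frame(gene_b1 = paste0(gidH, "b"),
                                 gene_b2 = paste0(gidH, "c"),
                                 bridge_gene = gidH)
    bundle <- list(gmRef = gmFish, gmTarget = gmFish,
                   gmOutgroup = anc,
                   chainsAB = chainsAB, chainsAC = chainsAC,
                   cageRef = lib, cageTarget = lib, homology = hom,
                   assemblies = c(ref = "genomeZ", target = "genomeZ"),
                   truth = truth)
  }

  ## generation-time self-check: planted shared positions sit inside blocks
  sp <- bundle$truth$sharedPairs
  if (nrow(sp)) {
    if (dupMode == "bridged_paralog") {
      stopifnot(!anyNA(sp$ref_pos), !anyNA(sp$target_pos))
    } else {
      chk <- .mapPos0(bundle$truth$anchorBlocks, sp$ref_pos - 1L) + 1L
      stopifnot(identical(as.integer(chk), as.integer(sp$target_pos)))
    }
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outDir, x)
    files <- list(gtf_ref = fp("genes_ref.gtf"),
                  gtf_target = fp("genes_target.gtf"),
                  ctss_ref = fp("cage_ref.ctss"),
                  ctss_target = fp("cage_target.ctss"),
                  homology = fp("homology.tsv"),
                  truth = fp("truth.json"))
    writeGeneModelsGTF(bundle$gmRef, files$gtf_ref)
    writeGeneModelsGTF(bundle$gmTarget, files$gtf_target)
    writeCTSS(bundle$cageRef, files$ctss_ref)
    writeCTSS(bundle$cageTarget, files$ctss_target)
    utils::write.table(bundle$homology, files$homology, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (dupMode == "bridged_paralog") {
      files$chain_ab <- fp("bridge_AB.chain")
      files$chain_ac <- fp("bridge_AC.chain")
      writeChains(bundle$chainsAB, files$chain_ab)
      writeChains(bundle$chainsAC, files$chain_ac)
    } else {
      files$chain <- fp("alignment.chain")
      writeChains(bundle$chains, files$chain)
    }
    jsonlite::write_json(bundle$truth, files$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    # emitted chains must pass full arithmetic validation on re-read
    for (f in files[grep("^chain", names(files))]) invisible(readChains(f))
    bundle$files <- files
  } else bundle$files <- NULL
  bundle
}
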