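## Anchor extraction: chain blocks restricted to a region of interest and
## classified by multiplicity (1-to-1 versus 1-to-2), with top-k selection
## where more loci align than the display convention allows, self-chain
## handling for within-genome paralogs, and bridged composition of two
## alignments through a shared outgroup assembly.

.emptyAnchors <- function() {
  out <- GRanges()
  mcols(out) <- DataFrame(target = GRanges(), multiplicity = character(),
                          chain_id = character(), score = numeric(),
                          orientation = character(), color = character())
  out
}

## pieces: GRanges on the reference side with mcols mapped/chain_id/score/
## orientation (the shape mapThroughChains emits).  Splits the reference
## footprint into atomic segments of constant covering-chain set, applies
## top-k selection per segment, maps each kept segment through its piece and
## merges contiguous same-chain runs.
.classifySegments <- function(pieces, maxLoci, colors, minWidth = 1L) {
  if (!length(pieces)) return(.emptyAnchors())
  segs <- disjoin(granges(pieces), ignore.strand = TRUE)
  ht <- findOverlaps(segs, pieces, ignore.strand = TRUE)
  footprint <- tapply(width(pieces), pieces$chain_id, sum)
  segi <- queryHits(ht); pci <- subjectHits(ht)
  res <- list(); n <- 0L
  for (s in unique(segi)) {
    pc <- pci[segi == s]
    ids <- pieces$chain_id[pc]
    sc <- pieces$score[pc]
    keyo <- order(-sc, -as.numeric(footprint[ids]), ids)
    keep <- pc[keyo][seq_len(min(maxLoci, length(pc)))]
    mult <- if (length(keep) == 1L) "one_to_one" else "one_to_two"
    for (p in keep) {
      rs <- start(segs)[s]; re <- end(segs)[s]
      ps <- start(pieces)[p]
      mp <- pieces$mapped[p]
      if (pieces$orientation[p] == "opposite") {
        ts <- end(mp) - (re - ps); te <- end(mp) - (rs - ps)
      } else {
        ts <- start(mp) + (rs - ps); te <- start(mp) + (re - ps)
      }
      n <- n + 1L
      res[[n]] <- data.frame(seq = as.character(seqnames(segs))[s],
                             rs = rs, re = re,
                             tseq = as.character(seqnames(mp)),
                             ts = ts, te = te, mult = mult,
                             chain_id = pieces$chain_id[p],
                             score = pieces$score[p],
                             orientation = pieces$orientation[p])
    }
  }
  df <- do.call(rbind, res)
  df <- df[order(df$seq, df$rs, df$chain_id), ]
  # merge runs contiguous on both sides with identical chain and class
  out <- list(); m <- 0L
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    joinable <- !is.null(cur) && cur$chain_id == row$chain_id &&
      cur$mult == row$mult && cur$orientation == row$orientation &&
      cur$seq == row$seq && row$rs == cur$re + 1L &&
      (if (row$orientation == "opposite") row$te == cur$ts - 1L
       else row$ts == cur$te + 1L)
    if (joinable) {
      cur$re <- row$re
      if (row$orientation == "opposite") cur$ts <- row$ts else cur$te <- row$te
    } else {
      if (!is.null(cur)) { m <- m + 1L; out[[m]] <- cur }
      cur <- row
    }
  }
  if (!is.null(cur)) { m <- m + 1L; out[[m]] <- cur }
  df <- do.call(rbind, out)
  df <- df[df$re - df$rs + 1L >= minWidth, , drop = FALSE]
  if (!nrow(df)) return(.emptyAnchors())
  anc <- GRanges(df$seq, IRanges(df$rs, df$re))
  mcols(anc) <- DataFrame(target = GRanges(df$tseq, IRanges(df$ts, df$te)),
                          multiplicity = df$mult, chain_id = df$chain_id,
                          score = df$score, orientation = df$orientation,
                          color = unname(colors[df$mult]))
  anc
}

#' Anchors linking a reference region to its aligned loci
#'
#' Collects the gap-free blocks of every chain overlapping \code{region},
#' trims them to the region, and classifies each reference base by the number
#' of distinct chains covering it: bases covered by one chain yield 1-to-1
#' anchors, bases covered by two or more chains yield the overlapping
#' reference sub-intervals as 1-to-2 anchors from each chain.  Where more
#' than \code{maxAnchorLoci} chains cover a base, only the highest-scoring
#' \code{maxAnchorLoci} chains are kept there (ties: larger aligned span in
#' the region, then lexicographic chain id).  Anchors are colored gray
#' (1-to-1) or blue (1-to-2) by default.
#'
#' @param region \code{GRanges} of length 1 on the target (reference) side of
#'   the chains.
#' @param chains a \code{\link{ChainSet}}.
#' @param params parameter list (\code{maxAnchorLoci}, \code{anchorColors});
#'   see \code{\link{locusParams}}.
#' @param minWidth minimum anchor width in bp (default 1: keep everything).
#' @return \code{GRanges} of reference intervals with metadata columns
#'   \code{target} (GRanges), \code{multiplicity}, \code{chain_id},
#'   \code{score}, \code{orientation}, \code{color}.
#' @export
anchorsForRegion <- function(region, chains, params = locusParams(),
                             minWidth = 1L) {
  stopifnot(length(region) == 1L)
  pieces <- mapThroughChains(chains, region, direction = "t2q")
  .classifySegments(pieces, params$maxAnchorLoci, params$anchorColors,
                    minWidth)
}

#' Anchors between paralogous loci from a self-chain alignment
#'
#' As \code{\link{anchorsForRegion}}, after discarding trivial self-chains in
#' which a span aligns to itself (same sequence, same span, same
#' orientation); the remaining chains link genuinely paralogous loci.
#'
#' @inheritParams anchorsForRegion
#' @param selfChains a \code{\link{ChainSet}} aligning an assembly to itself.
#' @return As \code{\link{anchorsForRegion}}.
#' @export
selfAnchors <- function(region, selfChains, params = locusParams(),
                        minWidth = 1L) {
  ch <- selfChains@chains
  if (nrow(ch)) {
    trivial <- ch$t_name == ch$q_name & ch$q_strand == "+" &
      ch$t_start == ch$q_start & ch$t_end == ch$q_end
    keep <- ch$chain_id[!trivial]
    selfChains <- new("ChainSet", chains = ch[!trivial, ],
                      blocks = selfChains@blocks[
                        selfChains@blocks$chain_id %in% keep])
  }
  anchorsForRegion(region, selfChains, params, minWidth)
}

#' Bridge-composed anchors between two loci aligned to a shared assembly
#'
#' Given chains aligning assembly A to locus B and chains aligning A to locus
#' C (A on the target side of both), composes the two alignments through
#' their shared A coordinates: \code{regionInB} is mapped back to A, the A
#' footprints of both chain sets are intersected, and every intersection is
#' mapped forward into B and into C, yielding width-equal B-to-C anchors.
#' The composed orientation is the product of the two block orientations and
#' the composed score the minimum of the two chain scores.  Composed anchors
#' narrower than \code{minWidth} (default from \code{params$minAnchorWidth})
#' are discarded.  Multiplicity is classified over the composed
#' (chain, chain) pairs as in \code{\link{anchorsForRegion}}.
#'
#' This composition can only recover similarity visible from A: segments
#' conserved between B and C but absent from A are invisible to it.
#'
#' @param chainsAB,chainsAC \code{\link{ChainSet}}s sharing assembly A on the
#'   target side.
#' @param regionInB \code{GRanges} of length 1 on the query side of
#'   \code{chainsAB}.
#' @param params parameter list; see \code{\link{locusParams}}.
#' @param minWidth minimum composed anchor width (default
#'   \code{params$minAnchorWidth}).
#' @return As \code{\link{anchorsForRegion}}, with reference intervals in B
#'   coordinates, targets in C, and composed chain ids \code{"idAB|idAC"}.
#' @export
bridgeAnchors <- function(chainsAB, chainsAC, regionInB,
                          params = locusParams(), minWidth = NULL) {
  stopifnot(length(regionInB) == 1L)
  if (is.null(minWidth)) minWidth <- params$minAnchorWidth
  tA1 <- unique(as.character(seqnames(chainsAB@blocks)))
  tA2 <- unique(as.character(seqnames(chainsAC@blocks)))
  if (length(tA1) && length(tA2) && !length(intersect(tA1, tA2)))
    stop("the two chain sets share no target-side (bridge) sequence: ",
         paste(tA1, collapse = ","), " vs ", paste(tA2, collapse = ","))
  toA <- mapThroughChains(chainsAB, regionInB, direction = "q2t")
  if (!length(toA)) return(.emptyAnchors())
  res <- list(); n <- 0L
  for (i in seq_along(toA)) {
    bIv <- granges(toA)[i]
    aIv <- toA$mapped[i]
    o1 <- toA$orientation[i]; s1 <- toA$score[i]; id1 <- toA$chain_id[i]
    toC <- mapThroughChains(chainsAC, aIv, direction = "t2q")
    if (!length(toC)) next
    for (j in seq_along(toC)) {
      as_ <- start(toC)[j]; ae_ <- end(toC)[j]
      # back from the A sub-interval into B through the AB piece
      if (o1 == "opposite") {
        bs <- start(bIv) + (end(aIv) - ae_)
        be <- start(bIv) + (end(aIv) - as_)
      } else {
        bs <- start(bIv) + (as_ - start(aIv))
        be <- start(bIv) + (ae_ - start(aIv))
      }
      o2 <- toC$orientation[j]
      # composed per-base map B -> C; express C interval plus-strand
      comp <- if (o1 == o2) "same" else "opposite"
      cIv <- toC$mapped[j]
      # when o1 is opposite the B sub-interval runs against the A sub-interval,
      # so the C interval endpoints swap exactly when comp is opposite; the
      # plus-strand C span is unchanged either way.
      n <- n + 1L
      res[[n]] <- data.frame(seq = as.character(seqnames(bIv)),
                             rs = bs, re = be,
                             tseq = as.character(seqnames(cIv)),
                             ts = start(cIv), te = end(cIv),
                             chain_id = paste0(id1, "|", toC$chain_id[j]),
                             score = pmin(s1, toC$score[j]),
                             orientation = comp)
    }
  }
  if (!n) return(.emptyAnchors())
  df <- do.call(rbind, res)
  pieces <- GRanges(df$seq, IRanges(df$rs, df$re))
  mcols(pieces) <- DataFrame(mapped = GRanges(df$tseq, IRanges(df$ts, df$te)),
                             chain_id = df$chain_id, score = df$score,
                             orientation = df$orientation)
  .classifySegments(pieces, params$maxAnchorLoci, params$anchorColors,
                    minWidth)
}

#' Map a reference position through an anchor
#'
#' @param anchor single anchor (length-1 subset of an anchor GRanges).
#' @param pos 1-based reference position(s) inside the anchor.
#' @return Mapped position(s) on the target side.
#' @export
mapAnchorPosition <- function(anchor, pos) {
  stopifnot(length(anchor) == 1L)
  tgt <- anchor$target
  if (anchor$orientation == "opposite") end(tgt) - (pos - start(anchor))
  else start(tgt) + (pos - start(anchor))
}
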