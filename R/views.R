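## Assembly of the three comparison views for a pair of homologous genes, and
## the derived annotations: shared/turnover TSSes and per-exon conservation.

.trackSet <- function(gm, region, tcs, assembly) {
  gsel <- genesInRegion(gm, region)
  genes <- if (length(gsel)) subsetGenes(gm, geneIds = gsel)
           else GeneModels(GRangesList(),
                           DataFrame(tx_id = character(),
                                     gene_id = character()))
  tsel <- if (!is.null(tcs) && length(tcs))
    tcs[overlapsAny(tcs, region, ignore.strand = TRUE)] else GRanges()
  if (length(tsel) && !is.null(tsel$revmap)) tsel$revmap <- NULL
  S4Vectors::new2("LocusTrackSet", region = region, genes = genes,
                  tagClusters = tsel, assembly = assembly, check = FALSE)
}

## keep only the anchor portions whose target side falls inside targetRegion,
## trimming both sides consistently (mirror-aware).
.trimAnchorsToTarget <- function(anc, targetRegion) {
  if (!length(anc)) return(anc)
  tgt <- anc$target
  keep <- as.character(seqnames(tgt)) ==
    as.character(seqnames(targetRegion)) &
    start(tgt) <= end(targetRegion) & end(tgt) >= start(targetRegion)
  anc <- anc[keep]
  if (!length(anc)) return(anc)
  tgt <- anc$target
  dL <- pmax(start(targetRegion) - start(tgt), 0L)
  dR <- pmax(end(tgt) - end(targetRegion), 0L)
  start(tgt) <- start(tgt) + dL
  end(tgt) <- end(tgt) - dR
  opp <- anc$orientation == "opposite"
  ns <- ifelse(opp, start(anc) + dR, start(anc) + dL)
  ne <- ifelse(opp, end(anc) - dL, end(anc) - dR)
  ranges(anc) <- IRanges(ns, ne)
  anc$target <- tgt
  anc
}

.computeAnchors <- function(refRegion, targetRegion, chains, bridge,
                            selfChain, params) {
  anc <- if (!is.null(bridge)) {
    bridgeAnchors(bridge$ab, bridge$ac, refRegion, params)
  } else if (!is.null(chains)) {
    cs <- chains
    refSeq <- as.character(seqnames(refRegion))
    tseqs <- unique(as.character(seqnames(cs@blocks)))
    qseqs <- unique(cs@blocks$q_seq)
    if (!(refSeq %in% tseqs) && refSeq %in% qseqs) cs <- invertChains(cs)
    if (selfChain) selfAnchors(refRegion, cs, params)
    else anchorsForRegion(refRegion, cs, params)
  } else .emptyAnchors()
  .trimAnchorsToTarget(anc, targetRegion)
}

.buildPairView <- function(mode, geneRef, geneTarget, gmRef, gmTarget,
                           tcsRef, tcsTarget, chains, bridge, selfChain,
                           assemblies, params) {
  idR <- resolveGene(gmRef, geneRef)
  idT <- resolveGene(gmTarget, geneTarget)
  span <- switch(mode,
    promoter = function(gm, id) promoterSpan(gm, id, params$promoterFlank),
    gene_structure = function(gm, id)
      geneStructureSpan(gm, id, params$transcriptFlank),
    neighborhood = function(gm, id)
      neighborhoodRegion(gm, id, params$neighborhoodHalfWidth))
  refRegion <- span(gmRef, idR)
  tgtRegion <- span(gmTarget, idT)
  anc <- .computeAnchors(refRegion, tgtRegion, chains, bridge, selfChain,
                         params)
  ref <- .trackSet(gmRef, refRegion, tcsRef, assemblies[["ref"]])
  tgt <- .trackSet(gmTarget, tgtRegion, tcsTarget, assemblies[["target"]])
  view <- new("ComparisonView", mode = mode, ref = ref, target = tgt,
              anchors = anc, annotations = list(geneRef = idR,
                                                geneTarget = idT),
              params = params)
  view
}

#' Build the promoter comparison view
#'
#' The displayed region on each side is the union of the per-transcript
#' promoter regions of the gene (each TSS extended \code{promoterFlank} bp up
#' and downstream).  Sequence anchors between the two regions are computed
#' from \code{chains} (inverted automatically when the reference region lives
#' on the query side), from a self-chain set (\code{selfChain = TRUE}) or by
#' bridge composition (\code{bridge = list(ab = , ac = )}).  Shared and
#' turnover TSSes between the two tag-cluster tracks are annotated via
#' \code{\link{sharedTssPairs}}.
#'
#' @param geneRef,geneTarget gene ids (or names/synonyms) on each side.
#' @param gmRef,gmTarget \code{\link{GeneModels}} for each assembly.
#' @param tcsRef,tcsTarget tag clusters from \code{\link{clusterTags}} for
#'   each assembly (optional).
#' @param chains a \code{\link{ChainSet}} connecting the two assemblies.
#' @param bridge \code{list(ab=, ac=)} of \code{ChainSet}s for bridged
#'   composition through a shared outgroup assembly.
#' @param selfChain logical; treat \code{chains} as a self-alignment and drop
#'   trivial identity chains.
#' @param assemblies named character(2) labels, \code{c(ref=, target=)}.
#' @param params parameter list from \code{\link{locusParams}}.
#' @return A \code{\link{ComparisonView}} with annotations
#'   \code{promoterCentersRef}/\code{Target} (distinct TSS positions),
#'   \code{sharedTss}, \code{turnoverRef}, \code{turnoverTarget}.
#' @export
buildPromoterView <- function(geneRef, geneTarget, gmRef, gmTarget,
                              tcsRef = NULL, tcsTarget = NULL, chains = NULL,
                              bridge = NULL, selfChain = FALSE,
                              assemblies = c(ref = "ref", target = "target"),
                              params = locusParams()) {
  view <- .buildPairView("promoter", geneRef, geneTarget, gmRef, gmTarget,
                         tcsRef, tcsTarget, chains, bridge, selfChain,
                         assemblies, params)
  idR <- view@annotations$geneRef; idT <- view@annotations$geneTarget
  view@annotations$promoterCentersRef <-
    sort(unique(unname(tssOf(subsetGenes(gmRef, geneIds = idR)))))
  view@annotations$promoterCentersTarget <-
    sort(unique(unname(tssOf(subsetGenes(gmTarget, geneIds = idT)))))
  st <- sharedTssPairs(view, params$sharedTssTolerance)
  view@annotations$sharedTss <- st$shared
  view@annotations$turnoverRef <- st$turnoverRef
  view@annotations$turnoverTarget <- st$turnoverTarget
  view
}

#' Build the gene-structure comparison view
#'
#' The displayed region on each side is the smallest interval containing
#' every transcript span of the gene extended by \code{transcriptFlank} bp on
#' both sides.  Per-exon anchor coverage of every transcript on both sides is
#' annotated via \code{\link{exonConservation}}.
#'
#' @inheritParams buildPromoterView
#' @return A \code{\link{ComparisonView}} with annotation
#'   \code{exonConservation} (data.frame: side, tx_id, exon_index, fraction).
#' @export
buildGeneStructureView <- function(geneRef, geneTarget, gmRef, gmTarget,
                                   tcsRef = NULL, tcsTarget = NULL,
                                   chains = NULL, bridge = NULL,
                                   selfChain = FALSE,
                                   assemblies = c(ref = "ref",
                                                  target = "target"),
                                   params = locusParams()) {
  view <- .buildPairView("gene_structure", geneRef, geneTarget, gmRef,
                         gmTarget, tcsRef, tcsTarget, chains, bridge,
                         selfChain, assemblies, params)
  anc <- view@anchors
  cons <- list(); n <- 0L
  for (side in c("ref", "target")) {
    genes <- if (side == "ref") view@ref@genes else view@target@genes
    cover <- if (side == "ref") granges(anc)
             else if (length(anc)) anc$target else GRanges()
    for (tx in names(genes@exonsByTx)) {
      ec <- exonConservation(genes@exonsByTx[[tx]], cover)
      if (nrow(ec)) {
        n <- n + 1L
        cons[[n]] <- cbind(side = side, tx_id = tx, ec)
      }
    }
  }
  view@annotations$exonConservation <- if (n) do.call(rbind, cons)
    else data.frame(side = character(), tx_id = character(),
                    exon_index = integer(), fraction = numeric())
  view
}

#' Per-exon anchor coverage
#'
#' Fraction of each exon covered by at least one anchor interval; 0 for
#' every exon when no anchors exist, 1 for exons fully inside an anchor.
#'
#' @param exons \code{GRanges} of the transcript's exons (sorted by start).
#' @param anchors \code{GRanges} of covering intervals (reference side of an
#'   anchor set, or its \code{target} column for the other locus).
#' @return data.frame with \code{exon_index} and \code{fraction} in [0, 1].
#' @export
exonConservation <- function(exons, anchors) {
  if (!length(exons))
    return(data.frame(exon_index = integer(), fraction = numeric()))
  cov <- reduce(granges(anchors), ignore.strand = TRUE)
  cov <- cov[as.character(seqnames(cov)) ==
               as.character(seqnames(exons))[1]]
  covered <- vapply(seq_along(exons), function(i) {
    if (!length(cov)) return(0L)
    ov <- pmin(end(exons)[i], end(cov)) - pmax(start(exons)[i],
                                               start(cov)) + 1L
    sum(pmax(ov, 0L))
  }, 1L)
  data.frame(exon_index = seq_along(exons),
             fraction = covered / width(exons))
}

#' Shared and turned-over TSSes between the two loci of a view
#'
#' A reference tag cluster and a target tag cluster are shared when the
#' reference representative position lies inside some sequence anchor, its
#' anchor-mapped position is within \code{tolerance} bp of the target
#' representative position, and the strands are consistent with the anchor
#' orientation (equal for same-orientation anchors, flipped for opposite).
#' Candidates are paired greedily by smallest mapped distance (ties: higher
#' combined tpm), each cluster participating in at most one pair; unmatched
#' clusters are reported as promoter turnover on their side.
#'
#' @param view a \code{\link{ComparisonView}} with tag-cluster tracks.
#' @param tolerance bp (default from the view's parameters).
#' @return list with \code{shared} (data.frame: ref_tc, target_tc indices
#'   into the view's tracks, ref_pos, target_pos, mapped_distance),
#'   \code{turnoverRef} and \code{turnoverTarget} (integer indices).
#' @export
sharedTssPairs <- function(view, tolerance = NULL) {
  if (is.null(tolerance)) tolerance <- view@params$sharedTssTolerance
  rtc <- view@ref@tagClusters
  ttc <- view@target@tagClusters
  anc <- view@anchors
  empty <- data.frame(ref_tc = integer(), target_tc = integer(),
                      ref_pos = integer(), target_pos = integer(),
                      mapped_distance = integer())
  if (!length(rtc) || !length(ttc) || !length(anc))
    return(list(shared = empty, turnoverRef = seq_along(rtc),
                turnoverTarget = seq_along(ttc)))
  cand <- list(); n <- 0L
  rstr <- as.character(strand(rtc)); tstr <- as.character(strand(ttc))
  for (i in seq_along(rtc)) {
    p <- rtc$repPos[i]
    hits <- which(as.character(seqnames(anc)) ==
                    as.character(seqnames(rtc))[i] &
                  start(anc) <= p & end(anc) >= p)
    for (a in hits) {
      mp <- mapAnchorPosition(anc[a], p)
      wantStrand <- if (anc$orientation[a] == "opposite")
        c("+" = "-", "-" = "+")[rstr[i]] else rstr[i]
      js <- which(as.character(seqnames(ttc)) ==
                    as.character(seqnames(anc$target[a])) &
                  tstr == wantStrand &
                  abs(ttc$repPos - mp) <= tolerance)
      for (j in js) {
        n <- n + 1L
        cand[[n]] <- data.frame(i = i, j = j,
                                dist = abs(ttc$repPos[j] - mp),
                                tpm = rtc$tpm[i] + ttc$tpm[j], mp = mp)
      }
    }
  }
  if (!n)
    return(list(shared = empty, turnoverRef = seq_along(rtc),
                turnoverTarget = seq_along(ttc)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, -cand$tpm, cand$i, cand$j), ]
  usedI <- logical(length(rtc)); usedJ <- logical(length(ttc))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!usedI[cand$i[k]] && !usedJ[cand$j[k]]) {
      keep[k] <- TRUE
      usedI[cand$i[k]] <- TRUE
      usedJ[cand$j[k]] <- TRUE
    }
  }
  sh <- cand[keep, ]
  shared <- data.frame(ref_tc = sh$i, target_tc = sh$j,
                       ref_pos = rtc$repPos[sh$i],
                       target_pos = ttc$repPos[sh$j],
                       mapped_distance = sh$dist)
  shared <- shared[order(shared$ref_tc), , drop = FALSE]
  rownames(shared) <- NULL
  list(shared = shared,
       turnoverRef = which(!usedI),
       turnoverTarget = which(!usedJ))
}

#' Build the genomic-neighborhood comparison view
#'
#' Each side shows the window of width twice \code{neighborhoodHalfWidth}
#' (default 2 Mb) centered on the gene.  Links between the two panels are
#' gene-homology links: every gene in the reference window is linked to its
#' homologs (per the homology table) among the genes of the target window;
#' the query pair itself is always linked.  Links carry a strand-agreement
#' flag, and the view carries a conserved-gene-order flag (target partners
#' monotone along the reference order).
#'
#' @inheritParams buildPromoterView
#' @param homology data.frame from \code{\link{readHomologyTable}}.
#' @return A \code{\link{ComparisonView}}; gene links are stored both as
#'   anchors (gene spans, chain_id = "geneA|geneB") and as the
#'   \code{neighborLinks} annotation (data.frame: gene_ref, gene_target,
#'   relation, strands_agree), with the \code{conservedOrder} flag.
#' @export
buildNeighborhoodView <- function(geneRef, geneTarget, gmRef, gmTarget,
                                  homology, tcsRef = NULL, tcsTarget = NULL,
                                  assemblies = c(ref = "ref",
                                                 target = "target"),
                                  params = locusParams()) {
  view <- .buildPairView("neighborhood", geneRef, geneTarget, gmRef,
                         gmTarget, tcsRef, tcsTarget, chains = NULL,
                         bridge = NULL, selfChain = FALSE, assemblies,
                         params)
  idR <- view@annotations$geneRef; idT <- view@annotations$geneTarget
  refGenes <- genesInRegion(gmRef, view@ref@region)
  tgtGenes <- genesInRegion(gmTarget, view@target@region)
  links <- data.frame(gene_ref = character(), gene_target = character(),
                      relation = character())
  if (!is.null(homology) && nrow(homology)) {
    fwd <- homology[homology$gene_a %in% refGenes &
                    homology$gene_b %in% tgtGenes, , drop = FALSE]
    rev <- homology[homology$gene_b %in% refGenes &
                    homology$gene_a %in% tgtGenes, , drop = FALSE]
    links <- rbind(
      data.frame(gene_ref = fwd$gene_a, gene_target = fwd$gene_b,
                 relation = fwd$relation),
      data.frame(gene_ref = rev$gene_b, gene_target = rev$gene_a,
                 relation = rev$relation))
  }
  if (!any(links$gene_ref == idR & links$gene_target == idT))
    links <- rbind(links, data.frame(gene_ref = idR, gene_target = idT,
                                     relation = "query"))
  links <- links[!duplicated(links[, c("gene_ref", "gene_target")]), ,
                 drop = FALSE]
  spR <- geneSpans(gmRef); spT <- geneSpans(gmTarget)
  links <- links[links$gene_ref %in% names(spR) &
                 links$gene_target %in% names(spT), , drop = FALSE]
  links$strands_agree <- as.character(strand(spR[links$gene_ref])) ==
    as.character(strand(spT[links$gene_target]))
  links <- links[order(start(spR[links$gene_ref]),
                       start(spT[links$gene_target])), , drop = FALSE]
  rownames(links) <- NULL
  ts <- start(spT[links$gene_target])
  conservedOrder <- nrow(links) < 2L ||
    all(diff(ts) >= 0) || all(diff(ts) <= 0)
  anc <- GRanges(seqnames(spR[links$gene_ref]), ranges(spR[links$gene_ref]))
  mcols(anc) <- DataFrame(
    target = granges(spT[links$gene_target]),
    multiplicity = rep("one_to_one", nrow(links)),
    chain_id = paste0(links$gene_ref, "|", links$gene_target),
    score = rep(0, nrow(links)),
    orientation = ifelse(links$strands_agree, "same", "opposite"),
    color = rep("gene", nrow(links)))
  names(anc) <- NULL
  view@anchors <- anc
  view@annotations$neighborLinks <- links
  view@annotations$conservedOrder <- conservedOrder
  view
}
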