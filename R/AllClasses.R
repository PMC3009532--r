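#' @import methods
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' CAGE library: mapped tags plus library size
#'
#' Holds collapsed CAGE tags as a \code{GRanges} (one range per mapped tag
#' span, metadata columns \code{count} and \code{fivePrime}) together with the
#' total mapped-tag count used for tags-per-million normalization.  The
#' library size defaults to the sum of retained tag counts but may be larger
#' when tags were filtered upstream of import.
#'
#' @slot tags \code{GRanges} with integer metadata columns \code{count}
#'   (collapsed identical-tag multiplicity, >= 1) and \code{fivePrime}
#'   (1-based genomic position of the strand-aware 5' end, inside the span).
#' @slot librarySize numeric(1), total mapped tags for tpm normalization.
#' @exportClass CageLibrary
setClass("CageLibrary",
  representation(tags = "GRanges", librarySize = "numeric"))

setValidity("CageLibrary", function(object) {
  tg <- object@tags
  msgs <- character()
  if (length(tg)) {
    mc <- mcols(tg)
    if (is.null(mc$count) || is.null(mc$fivePrime))
      return("tags must carry 'count' and 'fivePrime' metadata columns")
    if (any(mc$count < 1L))
      msgs <- c(msgs, "all tag counts must be >= 1")
    if (any(mc$fivePrime < start(tg) | mc$fivePrime > end(tg)))
      msgs <- c(msgs, "fivePrime must lie inside the tag span")
    if (any(!as.character(strand(tg)) %in% c("+", "-")))
      msgs <- c(msgs, "tags must be stranded (+ or -)")
  }
  if (length(object@librarySize) != 1L || object@librarySize < 0)
    msgs <- c(msgs, "librarySize must be a single non-negative number")
  if (length(tg) && object@librarySize < sum(mcols(tg)$count))
    msgs <- c(msgs, "librarySize cannot be smaller than the sum of tag counts")
  if (length(msgs)) msgs else TRUE
})

#' Gene models: transcripts grouped under genes
#'
#' Exon structures per transcript (a \code{GRangesList}, one element per
#' transcript, exons sorted by start and non-overlapping, all on one
#' sequence/strand) plus transcript-to-gene and gene-level tables.
#'
#' @slot exonsByTx \code{GRangesList} named by transcript id.
#' @slot txData \code{DataFrame} with columns \code{tx_id}, \code{gene_id}.
#' @slot geneData \code{DataFrame} with columns \code{gene_id}, \code{name},
#'   \code{synonyms} (CharacterList or comma-joined character).
#' @exportClass GeneModels
setClass("GeneModels",
  representation(exonsByTx = "GRangesList", txData = "DataFrame",
                 geneData = "DataFrame"))

setValidity("GeneModels", function(object) {
  msgs <- character()
  ex <- object@exonsByTx
  if (length(ex) != nrow(object@txData))
    msgs <- c(msgs, "one txData row per transcript required")
  if (!all(c("tx_id", "gene_id") %in% colnames(object@txData)))
    msgs <- c(msgs, "txData needs tx_id and gene_id columns")
  if (!all(c("gene_id", "name") %in% colnames(object@geneData)))
    msgs <- c(msgs, "geneData needs gene_id and name columns")
  if (length(ex)) {
    nex <- S4Vectors::elementNROWS(ex)
    if (any(nex < 1L)) msgs <- c(msgs, "every transcript needs >= 1 exon")
    if (any(S4Vectors::elementNROWS(S4Vectors::runValue(seqnames(ex))) > 1L))
      msgs <- c(msgs, "exons of one transcript must share a sequence")
    if (any(S4Vectors::elementNROWS(S4Vectors::runValue(strand(ex))) > 1L))
      msgs <- c(msgs, "exons of one transcript must share a strand")
    if (!all(IRanges::isDisjoint(ex)))
      msgs <- c(msgs, "exons of one transcript must be non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' A set of UCSC chain alignments
#'
#' Parsed chains plus their gap-free aligned blocks.  Block coordinates on
#' both sides are normalized to the plus strand; the original query-strand of
#' each chain is retained in the header table and per-block as the
#' \code{orientation} flag (\code{"same"} or \code{"opposite"}).
#'
#' @slot chains \code{DataFrame}, one row per chain: \code{chain_id},
#'   \code{score}, \code{t_name}, \code{t_size}, \code{t_start},
#'   \code{t_end}, \code{q_name}, \code{q_size}, \code{q_strand},
#'   \code{q_start}, \code{q_end} (header coordinates kept in the native
#'   0-based half-open convention of the chain format).
#' @slot blocks \code{GRanges} on the target side (plus strand, 1-based
#'   closed) with metadata columns \code{chain_id}, \code{score},
#'   \code{q_seq}, \code{q_start}, \code{q_end} (query side, plus strand,
#'   1-based closed) and \code{orientation}.
#' @exportClass ChainSet
setClass("ChainSet",
  representation(chains = "DataFrame", blocks = "GRanges"))

setValidity("ChainSet", function(object) {
  msgs <- character()
  need <- c("chain_id", "score", "q_seq", "q_start", "q_end", "orientation")
  if (length(object@blocks) &&
      !all(need %in% colnames(mcols(object@blocks))))
    msgs <- c(msgs, "blocks lack required metadata columns")
  if (length(object@blocks)) {
    mc <- mcols(object@blocks)
    if (any(width(object@blocks) != mc$q_end - mc$q_start + 1L))
      msgs <- c(msgs, "target and query block widths must be equal")
  }
  if (length(msgs)) msgs else TRUE
})

#' One locus with its annotation tracks
#'
#' A display region on one assembly, the gene models falling in it and the
#' CAGE tag clusters falling in it.
#'
#' @slot region \code{GRanges} of length 1.
#' @slot genes \code{GeneModels} restricted to transcripts overlapping region.
#' @slot tagClusters \code{GRanges} of tag clusters overlapping region
#'   (metadata: totalCount, tpm, repPos, shape).
#' @slot assembly character(1) assembly label.
#' @exportClass LocusTrackSet
setClass("LocusTrackSet",
  representation(region = "GRanges", genes = "GeneModels",
                 tagClusters = "GRanges", assembly = "character"))

setValidity("LocusTrackSet", function(object) {
  msgs <- character()
  if (length(object@region) != 1L)
    msgs <- c(msgs, "region must be a single range")
  if (length(object@tagClusters) &&
      !all(IRanges::overlapsAny(object@tagClusters, object@region,
                                ignore.strand = TRUE)))
    msgs <- c(msgs, "all tag clusters must overlap the region")
  if (length(msgs)) msgs else TRUE
})

#' A two-locus comparison view
#'
#' The assembled product of the three comparison modes: two
#' \code{LocusTrackSet}s, the anchors linking them (sequence-level for the
#' promoter and gene-structure views, gene-homology links for the
#' neighborhood view), and derived annotations (shared-TSS pairs, turnover
#' lists, per-exon conservation, neighbor links, conserved-order flag).
#'
#' @slot mode one of \code{"promoter"}, \code{"gene_structure"},
#'   \code{"neighborhood"}.
#' @slot ref,target \code{LocusTrackSet}s.
#' @slot anchors \code{GRanges} on the reference side with a \code{target}
#'   GRanges metadata column plus multiplicity/chain_id/score/orientation/
#'   color columns; empty for views without sequence anchors.
#' @slot annotations named \code{list}.
#' @slot params the effective parameter list (see \code{\link{locusParams}}).
#' @exportClass ComparisonView
setClass("ComparisonView",
  representation(mode = "character", ref = "LocusTrackSet",
                 target = "LocusTrackSet", anchors = "GRanges",
                 annotations = "list", params = "list"))

setValidity("ComparisonView", function(object) {
  msgs <- character()
  if (!object@mode %in% c("promoter", "gene_structure", "neighborhood"))
    msgs <- c(msgs, "unknown view mode")
  if (length(object@anchors) &&
      !all(IRanges::overlapsAny(object@anchors, object@ref@region,
                                ignore.strand = TRUE)))
    msgs <- c(msgs, "anchor reference intervals must lie in ref region")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CageLibrary", function(object) {
  cat("CageLibrary with", length(object@tags), "collapsed tags,",
      "library size", format(object@librarySize, big.mark = ","), "\n")
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", nrow(object@geneData), "genes,",
      length(object@exonsByTx), "transcripts on",
      length(unique(as.character(seqnames(unlist(object@exonsByTx,
                                                 use.names = FALSE))))),
      "sequence(s)\n")
})

setMethod("show", "ChainSet", function(object) {
  cat("ChainSet:", nrow(object@chains), "chains,",
      length(object@blocks), "aligned blocks\n")
  if (nrow(object@chains)) {
    cat("  target side:",
        paste(unique(object@chains$t_name), collapse = ", "), "\n")
    cat("  query side: ",
        paste(unique(object@chains$q_name), collapse = ", "), "\n")
  }
})

setMethod("show", "LocusTrackSet", function(object) {
  r <- object@region
  cat(sprintf("LocusTrackSet [%s] %s:%d-%d (%s genes, %d tag clusters)\n",
              object@assembly, as.character(seqnames(r)), start(r), end(r),
              nrow(object@genes@geneData), length(object@tagClusters)))
})

setMethod("show", "ComparisonView", function(object) {
  cat("ComparisonView <", object@mode, ">\n", sep = "")
  cat("  ref:    "); show(object@ref)
  cat("  target: "); show(object@target)
  cat("  anchors:", length(object@anchors), "\n")
  if (length(object@annotations))
    cat("  annotations:", paste(names(object@annotations), collapse = ", "),
        "\n")
})
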