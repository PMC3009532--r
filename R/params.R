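#' Analysis parameters
#'
#' One place for the distance and selection constants used across the three
#' comparison views.  Defaults follow the conventions of CAGE-based promoter
#' comparison: a proximal promoter is the 1000 bp window centered on a TSS
#' (500 bp each side), tag clusters are assigned to a gene when their
#' representative position falls in the closed [-500, +500] bp window around
#' an annotated TSS, gene-structure views pad the transcript span by 500 bp,
#' neighborhood views show a 2 Mb window (1 Mb half-width) centered on the
#' gene, a reference span aligning to more than \code{maxAnchorLoci} loci is
#' reduced to the top-scoring \code{maxAnchorLoci} (default 2, the 1-to-2
#' anchor convention), and tag-cluster shape is sharp when the count-weighted
#' 0.10-0.90 interquantile width of its 5' ends is at most 4 bp.
#'
#' @param promoterFlank bp added on each side of a TSS for the promoter view.
#' @param transcriptFlank bp added on each side of the transcript span for
#'   the gene-structure view.
#' @param tcGeneWindow bp each side of a TSS for tag-cluster-to-gene
#'   assignment (closed window).
#' @param neighborhoodHalfWidth bp half-width of the neighborhood view.
#' @param sharedTssTolerance bp; a reference tag cluster maps to a target tag
#'   cluster when its anchor-mapped representative position is within this
#'   distance of the target representative position.
#' @param shapeQuantiles numeric(2) in (0,1), lower/upper quantiles of the
#'   count-weighted 5'-end distribution used for the shape width.
#' @param sharpWidthMax bp; interquantile width at or below which a tag
#'   cluster is classed sharp.
#' @param maxAnchorLoci maximum number of distinct chains allowed to anchor
#'   one reference base; extra chains are dropped by score.
#' @param minAnchorWidth bp; composed (bridged) anchors narrower than this
#'   are discarded.
#' @param anchorColors named character(2): display colors for one_to_one and
#'   one_to_two anchors.
#'
#' @return A named list of validated parameters.
#' @examples
#' p <- locusParams()
#' p$promoterFlank
#' @export
locusParams <- function(promoterFlank = 500L,
                        transcriptFlank = 500L,
                        tcGeneWindow = 500L,
                        neighborhoodHalfWidth = 1000000L,
                        sharedTssTolerance = 100L,
                        shapeQuantiles = c(0.10, 0.90),
                        sharpWidthMax = 4L,
                        maxAnchorLoci = 2L,
                        minAnchorWidth = 10L,
                        anchorColors = c(one_to_one = "gray",
                                         one_to_two = "blue")) {
  p <- list(promoterFlank = as.integer(promoterFlank),
            transcriptFlank = as.integer(transcriptFlank),
            tcGeneWindow = as.integer(tcGeneWindow),
            neighborhoodHalfWidth = as.integer(neighborhoodHalfWidth),
            sharedTssTolerance = as.integer(sharedTssTolerance),
            shapeQuantiles = as.numeric(shapeQuantiles),
            sharpWidthMax = as.numeric(sharpWidthMax),
            maxAnchorLoci = as.integer(maxAnchorLoci),
            minAnchorWidth = as.integer(minAnchorWidth),
            anchorColors = anchorColors)
  stopifnot(p$promoterFlank > 0L, p$transcriptFlank >= 0L,
            p$tcGeneWindow > 0L, p$neighborhoodHalfWidth > 0L,
            p$sharedTssTolerance >= 0L,
            length(p$shapeQuantiles) == 2L,
            p$shapeQuantiles[1] > 0, p$shapeQuantiles[2] < 1,
            p$shapeQuantiles[1] < p$shapeQuantiles[2],
            p$sharpWidthMax >= 0, p$maxAnchorLoci >= 1L,
            p$minAnchorWidth >= 1L,
            all(c("one_to_one", "one_to_two") %in% names(p$anchorColors)))
  p
}
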