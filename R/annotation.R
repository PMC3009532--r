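## Gene-model import and the strand-aware region arithmetic behind the three
## comparison views.  All coordinates in memory are GRanges (1-based closed);
## GTF/BED conventions are converted on import only.

#' Construct a GeneModels object
#'
#' @param exonsByTx \code{GRangesList} of exons per transcript, named by
#'   transcript id.
#' @param txData \code{DataFrame} (or data.frame) with \code{tx_id},
#'   \code{gene_id}.
#' @param geneData optional \code{DataFrame} with \code{gene_id},
#'   \code{name}, \code{synonyms}; derived from \code{txData} when missing.
#' @return A \code{GeneModels} object.
#' @export
GeneModels <- function(exonsByTx, txData, geneData = NULL) {
  txData <- as(txData, "DataFrame")
  if (is.null(geneData)) {
    gid <- unique(txData$gene_id)
    geneData <- DataFrame(gene_id = gid, name = gid,
                          synonyms = rep("", length(gid)))
  }
  geneData <- as(geneData, "DataFrame")
  if (is.null(geneData$synonyms)) geneData$synonyms <- rep("", nrow(geneData))
  if (!is(exonsByTx, "GRangesList")) exonsByTx <- GRangesList(exonsByTx)
  exonsByTx <- sort(exonsByTx, ignore.strand = TRUE)
  o <- order(txData$gene_id, txData$tx_id)
  new("GeneModels", exonsByTx = exonsByTx[o], txData = txData[o, ],
      geneData = geneData[order(geneData$gene_id), ])
}

#' Read gene models from GTF or BED12
#'
#' GTF coordinates (1-based inclusive) and BED12 block arithmetic (0-based
#' half-open) are both converted to the in-memory GRanges convention.
#' Transcripts are grouped under genes by \code{gene_id}; for BED12 input the
#' \code{name} field is the transcript id and the gene id is taken from an
#' optional 13th column, falling back to the transcript id.
#'
#' @param path file path.
#' @param format \code{"gtf"} or \code{"bed12"} (default guessed from the
#'   file extension).
#' @param seqLengths optional named integer vector of sequence lengths, or
#'   path to a two-column TSV (seq_id, length) in UCSC chromInfo shape.
#' @return A \code{\link{GeneModels}} object, transcripts ordered by
#'   (gene_id, tx_id).
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "bed12"),
                           seqLengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  if (!file.exists(path)) stop("gene model file not found: ", path)
  sl <- readSeqLengths(seqLengths)
  if (format == "gtf") {
    if (!any(nzchar(trimws(readLines(path)))))
      return(GeneModels(GRangesList(), DataFrame(tx_id = character(),
                                                 gene_id = character())))
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("GTF parse error in ", path,
                                            ": ", conditionMessage(e)))
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(ex) == 0L)
      return(GeneModels(GRangesList(), DataFrame(tx_id = character(),
                                                 gene_id = character())))
    if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
      stop("GTF exon records lack transcript_id in ", path)
    gene_id <- if (!is.null(ex$gene_id)) ex$gene_id else ex$transcript_id
    name <- if (!is.null(ex$gene_name)) ex$gene_name else gene_id
    exl <- S4Vectors::split(granges(ex), ex$transcript_id)
    t2g <- tapply(gene_id, ex$transcript_id, function(x) x[1])
    t2n <- tapply(as.character(name), ex$transcript_id, function(x) x[1])
    txData <- DataFrame(tx_id = names(exl),
                        gene_id = as.character(t2g[names(exl)]))
    gd <- unique(data.frame(gene_id = txData$gene_id,
                            name = as.character(t2n[names(exl)])))
    geneData <- DataFrame(gene_id = gd$gene_id, name = gd$name,
                          synonyms = rep("", nrow(gd)))
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("BED12 parse error in ", path,
                                            ": ", conditionMessage(e)))
    if (length(gr) == 0L)
      return(GeneModels(GRangesList(), DataFrame(tx_id = character(),
                                                 gene_id = character())))
    exl <- rtracklayer::blocks(gr)
    names(exl) <- gr$name
    str <- as.character(strand(gr))
    exl <- GRangesList(mapply(function(g, s) { strand(g) <- s; g },
                              as.list(exl), str))
    txData <- DataFrame(tx_id = gr$name, gene_id = gr$name)
    geneData <- NULL
  }
  if (length(sl)) {
    exl <- GRangesList(lapply(exl, function(g) {
      known <- intersect(seqlevels(g), names(sl))
      seqlengths(g)[known] <- sl[known]
      g
    }))
  }
  GeneModels(exl, txData, geneData)
}

#' Read a sequence-length registry (UCSC chromInfo-shaped TSV)
#'
#' @param x \code{NULL}, a named integer vector, or a path to a two-column
#'   TSV of (seq_id, length).
#' @return Named integer vector (possibly empty).
#' @export
readSeqLengths <- function(x) {
  if (is.null(x)) return(integer())
  if (is.numeric(x) && !is.null(names(x))) return(as.integer(round(x)) |>
    stats::setNames(names(x)))
  tab <- utils::read.table(x, sep = "\t", header = FALSE,
                           col.names = c("seq_id", "length"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$length), tab$seq_id)
}

#' @describeIn geneIds transcript ids, in storage order.
#' @export
txIds <- function(gm) gm@txData$tx_id

#' Gene and transcript identifiers of a GeneModels object
#'
#' @param gm a \code{GeneModels} object.
#' @return character vector of ids.
#' @export
geneIds <- function(gm) gm@geneData$gene_id

#' Exons per transcript
#' @param gm a \code{GeneModels} object.
#' @return \code{GRangesList} named by transcript id.
#' @export
exonsByTx <- function(gm) gm@exonsByTx

#' Transcript spans (first exon start to last exon end)
#' @param gm a \code{GeneModels} object.
#' @return \code{GRanges} named by transcript id.
#' @export
txSpans <- function(gm) {
  ex <- gm@exonsByTx
  if (!length(ex)) return(GRanges())
  # exons are stored sorted by start, so each span is first-start/last-end
  nex <- S4Vectors::elementNROWS(ex)
  iF <- cumsum(nex) - nex + 1L
  iL <- cumsum(nex)
  flat <- unlist(ex, use.names = FALSE)
  out <- GRanges(seqnames(flat)[iF],
                 IRanges(start(flat)[iF], end(flat)[iL]),
                 strand = strand(flat)[iF], seqinfo = seqinfo(flat))
  names(out) <- names(ex)
  out
}

#' Gene bounding boxes (union of transcript spans)
#' @param gm a \code{GeneModels} object.
#' @return \code{GRanges} named by gene id, sorted by (seqnames, start).
#' @export
geneSpans <- function(gm) {
  ts <- txSpans(gm)
  if (!length(ts)) return(GRanges())
  sp <- unlist(range(S4Vectors::split(ts, gm@txData$gene_id)))
  sort(sp, ignore.strand = TRUE)
}

#' Subset gene models by gene or transcript ids
#'
#' @param gm a \code{GeneModels} object.
#' @param geneIds,txIds character vectors (one of the two).
#' @return A \code{GeneModels} restricted to the selection.
#' @export
subsetGenes <- function(gm, geneIds = NULL, txIds = NULL) {
  keep <- if (!is.null(geneIds)) gm@txData$gene_id %in% geneIds
          else gm@txData$tx_id %in% txIds
  gsel <- unique(gm@txData$gene_id[keep])
  # subsets of a valid object stay valid; skip the validity pass
  S4Vectors::new2("GeneModels", exonsByTx = gm@exonsByTx[keep],
                  txData = gm@txData[keep, ],
                  geneData = gm@geneData[gm@geneData$gene_id %in% gsel, ],
                  check = FALSE)
}

#' Resolve a gene by id, symbol or synonym
#'
#' @param gm a \code{GeneModels} object.
#' @param query gene id, name or synonym.
#' @return The matching gene id (length 1); errors listing near misses when
#'   no exact match exists.
#' @export
resolveGene <- function(gm, query) {
  gd <- gm@geneData
  syn <- strsplit(as.character(gd$synonyms), ",", fixed = TRUE)
  hit <- which(gd$gene_id == query | gd$name == query |
               vapply(syn, function(s) query %in% trimws(s), logical(1)))
  if (length(hit) >= 1L) return(gd$gene_id[hit[1]])
  pool <- unique(c(gd$gene_id, gd$name))
  near <- pool[utils::adist(tolower(query), tolower(pool)) <= 2]
  stop("gene not found: '", query, "'",
       if (length(near)) paste0("; did you mean: ",
                                paste(utils::head(near, 5), collapse = ", "),
                                "?") else "")
}

#' Transcription start sites
#'
#' The TSS of a transcript is the start of its first exon on the plus strand
#' and the end of its last exon on the minus strand.
#'
#' @param gm a \code{GeneModels} object.
#' @return Named integer vector (1-based position) per transcript, with the
#'   sequence name and strand as attributes via \code{tssSites}.
#' @export
tssOf <- function(gm) {
  ts <- txSpans(gm)
  pos <- ifelse(as.character(strand(ts)) == "-", end(ts), start(ts))
  stats::setNames(as.integer(pos), names(ts))
}

#' TSS positions as a GRanges (width-1 ranges)
#' @param gm a \code{GeneModels} object.
#' @return \code{GRanges} of width-1 TSS positions named by transcript id.
#' @export
tssSites <- function(gm) {
  ts <- txSpans(gm)
  pos <- tssOf(gm)
  GRanges(seqnames(ts), IRanges(pos, width = 1L), strand = strand(ts),
          tx_id = names(ts), seqinfo = seqinfo(ts))
}

.clipCoords <- function(template, st, en) {
  st <- pmax(st, 1L)
  sl <- seqlengths(template)[as.character(seqnames(template))]
  has <- !is.na(sl)
  en[has] <- pmin(en[has], sl[has])
  list(start = st, end = en)
}

#' Per-transcript promoter regions
#'
#' A promoter region is the window of width 2*flank centered on the TSS,
#' symmetric in genomic coordinates on both strands, silently clipped at the
#' sequence bounds when lengths are known.
#'
#' @param gm a \code{GeneModels} object.
#' @param flank bp on each side of the TSS (default 500, i.e. a 1000 bp
#'   promoter).
#' @return \code{GRanges} named by transcript id.
#' @export
promoterRegions <- function(gm, flank = 500L) {
  stopifnot(flank > 0L)
  tss <- tssSites(gm)
  cc <- .clipCoords(tss, start(tss) - flank, start(tss) + flank - 1L)
  r <- GRanges(seqnames(tss), IRanges(cc$start, cc$end),
               strand = strand(tss), seqinfo = seqinfo(tss))
  names(r) <- names(tss)
  r
}

#' Gene-level promoter span
#'
#' Smallest interval containing the promoter region of every transcript of
#' the gene — the region displayed in the promoter view.
#'
#' @param gm a \code{GeneModels} object.
#' @param geneId gene id.
#' @param flank bp each side of each TSS (default 500).
#' @return \code{GRanges} of length 1.
#' @export
promoterSpan <- function(gm, geneId, flank = 500L) {
  sub <- subsetGenes(gm, geneIds = geneId)
  if (!length(sub@exonsByTx)) stop("gene has no transcripts: ", geneId)
  r <- range(promoterRegions(sub, flank), ignore.strand = TRUE)
  names(r) <- geneId
  r
}

#' Gene-structure span
#'
#' Smallest interval containing every transcript span extended by
#' \code{flank} bp up- and downstream — the region displayed in the
#' gene-structure view.
#'
#' @param gm a \code{GeneModels} object.
#' @param geneId gene id.
#' @param flank bp each side (default 500; 0 gives the gene bounding box).
#' @return \code{GRanges} of length 1.
#' @export
geneStructureSpan <- function(gm, geneId, flank = 500L) {
  stopifnot(flank >= 0L)
  sub <- subsetGenes(gm, geneIds = geneId)
  if (!length(sub@exonsByTx)) stop("gene has no transcripts: ", geneId)
  ts <- txSpans(sub)
  cc <- .clipCoords(ts, start(ts) - flank, end(ts) + flank)
  r <- range(GRanges(seqnames(ts), IRanges(cc$start, cc$end),
                     seqinfo = seqinfo(ts)), ignore.strand = TRUE)
  names(r) <- geneId
  r
}

#' Genomic-neighborhood window
#'
#' The window of width 2*halfWidth centered on the midpoint of the gene
#' bounding box (default 2 Mb), clipped at sequence bounds.
#'
#' @param gm a \code{GeneModels} object.
#' @param geneId gene id.
#' @param halfWidth bp half-width (default 1e6).
#' @return \code{GRanges} of length 1.
#' @export
neighborhoodRegion <- function(gm, geneId, halfWidth = 1000000L) {
  stopifnot(halfWidth > 0L)
  box <- geneSpans(subsetGenes(gm, geneIds = geneId))
  if (!length(box)) stop("gene has no transcripts: ", geneId)
  # midpoint under half-open arithmetic: floor((start0 + end0) / 2)
  mid0 <- (start(box) - 1L + end(box)) %/% 2L
  cc <- .clipCoords(box, mid0 - halfWidth + 1L, mid0 + halfWidth)
  r <- GRanges(seqnames(box), IRanges(cc$start, cc$end),
               seqinfo = seqinfo(box))
  names(r) <- geneId
  r
}

#' Genes overlapping a region
#'
#' Genes whose bounding box shares at least one base with \code{region},
#' sorted by start.
#'
#' @param gm a \code{GeneModels} object.
#' @param region \code{GRanges} of length 1.
#' @return character vector of gene ids, sorted by gene start.
#' @export
genesInRegion <- function(gm, region) {
  sp <- geneSpans(gm)
  if (!length(sp)) return(character())
  hit <- IRanges::overlapsAny(sp, region, ignore.strand = TRUE)
  names(sp)[hit][order(start(sp)[hit])]
}
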