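## CAGE tag import, single-linkage tag clustering, representative position,
## tags-per-million and sharp/broad promoter shape.

#' Construct a CageLibrary
#'
#' @param tags \code{GRanges} with metadata columns \code{count} and
#'   \code{fivePrime}.
#' @param librarySize total mapped tags; defaults to the sum of tag counts.
#' @return A \code{CageLibrary}.
#' @export
CageLibrary <- function(tags = GRanges(), librarySize = NULL) {
  if (length(tags) && is.null(tags$fivePrime))
    tags$fivePrime <- ifelse(as.character(strand(tags)) == "-",
                             end(tags), start(tags))
  if (is.null(librarySize))
    librarySize <- if (length(tags)) sum(as.numeric(tags$count)) else 0
  new("CageLibrary", tags = tags, librarySize = as.numeric(librarySize))
}

#' Library size and tags accessors
#' @param lib a \code{CageLibrary}.
#' @return \code{librarySize}: numeric(1); \code{cageTags}: \code{GRanges}.
#' @export
librarySize <- function(lib) lib@librarySize

#' @rdname librarySize
#' @export
cageTags <- function(lib) lib@tags

#' Read CAGE tags from BED6 or CTSS text
#'
#' BED6 input uses the score column as the collapsed tag count; CTSS input is
#' whitespace-separated (sequence, 1-based position, strand, count) with tag
#' width 1.  The strand-aware 5' end is the tag start on the plus strand and
#' the tag end on the minus strand.
#'
#' @param path file path (plain or gzip).
#' @param format \code{"bed6"} or \code{"ctss"} (default guessed from the
#'   extension: .bed is BED6, anything else CTSS).
#' @param librarySize optional true mapped-tag total overriding the default
#'   (sum of retained counts) when tags were filtered upstream.
#' @return A \code{\link{CageLibrary}}.
#' @export
readCAGE <- function(path, format = c("auto", "bed6", "ctss"),
                     librarySize = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed6" else "ctss"
  if (!file.exists(path)) stop("CAGE file not found: ", path)
  if (format == "ctss") {
    lines <- readLines(gzfile(path))
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(CageLibrary(GRanges(), librarySize))
    f <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(f)
    if (any(nf != 4L))
      stop("CTSS parse error at line ", which(nf != 4L)[1], " of ", path,
           ": expected 4 fields")
    seq <- vapply(f, `[`, "", 1L)
    pos <- suppressWarnings(as.integer(vapply(f, `[`, "", 2L)))
    str <- vapply(f, `[`, "", 3L)
    cnt <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4L)))
    if (anyNA(pos) || any(pos < 1L))
      stop("CTSS parse error: bad position at line ",
           which(is.na(pos) | pos < 1L)[1], " of ", path)
    if (!all(str %in% c("+", "-")))
      stop("CTSS parse error: unknown strand symbol at line ",
           which(!str %in% c("+", "-"))[1], " of ", path)
    if (anyNA(cnt) || any(cnt <= 0))
      stop("CTSS parse error: non-positive count at line ",
           which(is.na(cnt) | cnt <= 0)[1], " of ", path)
    tg <- GRanges(seq, IRanges(pos, width = 1L), strand = str,
                  count = as.integer(round(cnt)), fivePrime = pos)
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("BED6 parse error in ", path,
                                            ": ", conditionMessage(e)))
    if (!length(gr)) return(CageLibrary(GRanges(), librarySize))
    if (is.null(gr$score) || anyNA(gr$score) || any(gr$score <= 0))
      stop("BED6 CAGE input needs a positive tag count in the score column: ",
           path)
    if (any(!as.character(strand(gr)) %in% c("+", "-")))
      stop("BED6 CAGE input has records without strand: ", path)
    tg <- granges(gr)
    tg$count <- as.integer(round(gr$score))
    tg$fivePrime <- ifelse(as.character(strand(tg)) == "-", end(tg),
                           start(tg))
  }
  CageLibrary(sort(tg, ignore.strand = TRUE), librarySize)
}

#' Cluster CAGE tags into tag clusters
#'
#' Single-linkage clustering per (sequence, strand): two tags belong to the
#' same cluster exactly when they are connected by a chain of pairwise
#' overlaps of at least 1 bp.  Tag clusters on the same strand are therefore
#' pairwise non-overlapping and partition the input tags.  Each cluster
#' carries its representative position (the 5'-end position supported by the
#' most tags), tags-per-million, and sharp/broad shape class.
#'
#' @param lib a \code{\link{CageLibrary}}.
#' @param params parameter list from \code{\link{locusParams}} (shape
#'   quantiles and sharp width cutoff).
#' @return \code{GRanges} of clusters sorted by (sequence, strand, start)
#'   with metadata columns \code{nTags}, \code{totalCount}, \code{tpm},
#'   \code{repPos}, \code{shape} and \code{revmap} (indices of member tags in
#'   \code{cageTags(lib)}).
#' @export
clusterTags <- function(lib, params = locusParams()) {
  tg <- lib@tags
  if (!length(tg)) {
    out <- GRanges()
    mcols(out) <- DataFrame(nTags = integer(), totalCount = integer(),
                            tpm = numeric(), repPos = integer(),
                            shape = character())
    return(out)
  }
  # min.gapwidth = 0 merges only ranges sharing >= 1 base (abutting stay apart)
  red <- reduce(tg, min.gapwidth = 0L, with.revmap = TRUE)
  rev <- mcols(red)$revmap
  fp <- tg$fivePrime
  cnt <- as.numeric(tg$count)
  q <- params$shapeQuantiles
  n <- length(red)
  totalCount <- integer(n); repPos <- integer(n); shape <- character(n)
  minus <- as.character(strand(red)) == "-"
  for (i in seq_len(n)) {
    idx <- rev[[i]]
    totalCount[i] <- sum(cnt[idx])
    repPos[i] <- representativePosition(fp[idx], cnt[idx],
                                        if (minus[i]) "-" else "+")
    shape[i] <- classifyShape(fp[idx], cnt[idx], quantiles = q,
                              sharpWidthMax = params$sharpWidthMax)
  }
  out <- granges(red)
  mcols(out) <- DataFrame(nTags = lengths(rev),
                          totalCount = totalCount,
                          tpm = computeTPM(totalCount, lib@librarySize),
                          repPos = repPos, shape = shape, revmap = rev)
  o <- order(as.character(seqnames(out)), as.character(strand(out)),
             start(out))
  out[o]
}

#' Representative position of a tag cluster
#'
#' The 5'-end position whose summed tag count is maximal; ties resolve to the
#' 5'-most position relative to the strand (smallest coordinate on plus,
#' largest on minus).
#'
#' @param fivePrime integer vector of member 5'-end positions.
#' @param counts numeric vector of member tag counts.
#' @param strand \code{"+"} or \code{"-"}.
#' @return integer(1) position.
#' @export
representativePosition <- function(fivePrime, counts, strand = "+") {
  stopifnot(length(fivePrime) >= 1L, length(fivePrime) == length(counts))
  tot <- tapply(counts, fivePrime, sum)
  pos <- as.integer(names(tot))
  best <- pos[tot == max(tot)]
  as.integer(if (identical(strand, "-")) max(best) else min(best))
}

#' Tags per million
#'
#' @param totalCount tag count(s).
#' @param librarySize total mapped tags (> 0).
#' @return numeric, \code{totalCount * 1e6 / librarySize}.
#' @export
computeTPM <- function(totalCount, librarySize) {
  if (length(librarySize) != 1L || is.na(librarySize) || librarySize <= 0)
    stop("librarySize must be a single positive number")
  as.numeric(totalCount) * 1e6 / librarySize
}

#' Sharp/broad shape class of a tag cluster
#'
#' Computes the count-weighted empirical distribution of the member 5' ends
#' and measures the interquantile width (position at the upper quantile minus
#' position at the lower quantile, both via the left-continuous inverse CDF).
#' The cluster is sharp when the width is at most \code{sharpWidthMax} bp.
#'
#' @param fivePrime integer vector of member 5'-end positions.
#' @param counts numeric vector of member tag counts.
#' @param quantiles numeric(2) lower/upper quantiles (default 0.10/0.90).
#' @param sharpWidthMax maximum width for the sharp class (default 4 bp).
#' @return \code{"sharp"} or \code{"broad"}.
#' @export
classifyShape <- function(fivePrime, counts, quantiles = c(0.10, 0.90),
                          sharpWidthMax = 4) {
  stopifnot(length(fivePrime) >= 1L, length(fivePrime) == length(counts))
  tot <- tapply(counts, fivePrime, sum)
  pos <- as.integer(names(tot))
  o <- order(pos)
  cdf <- cumsum(as.numeric(tot[o])) / sum(counts)
  lo <- pos[o][which(cdf >= quantiles[1])[1]]
  hi <- pos[o][which(cdf >= quantiles[2])[1]]
  if (hi - lo <= sharpWidthMax) "sharp" else "broad"
}

#' Assign representative tag clusters to transcripts and genes
#'
#' A tag cluster maps to a transcript when it lies on the same strand and its
#' representative position falls in the closed window
#' \code{[tss - window, tss + window]}.  Per transcript the highest-tpm
#' candidate is kept; the gene-level representative is the highest-tpm
#' cluster over all its transcripts' candidates.  Ties break by higher total
#' count, then by the 5'-most representative position relative to the gene
#' strand.
#'
#' @param gm a \code{\link{GeneModels}} object.
#' @param tcs tag clusters from \code{\link{clusterTags}}.
#' @param window bp each side of the TSS (default 500; the closed
#'   [-500, +500] assignment window).
#' @return list with \code{perTx} (DataFrame: tx_id, gene_id, tc — index into
#'   \code{tcs} or NA) and \code{perGene} (DataFrame: gene_id, tc).
#' @export
assignRepresentativeTC <- function(gm, tcs, window = 500L) {
  tss <- tssSites(gm)
  perTx <- DataFrame(tx_id = gm@txData$tx_id, gene_id = gm@txData$gene_id,
                     tc = rep(NA_integer_, length(tss)))
  txStrand <- as.character(strand(tss))
  if (length(tcs) && length(tss)) {
    win <- GRanges(seqnames(tss),
                   IRanges(start(tss) - window, start(tss) + window),
                   strand = strand(tss))
    rp <- GRanges(seqnames(tcs), IRanges(tcs$repPos, width = 1L),
                  strand = strand(tcs))
    ht <- findOverlaps(win, rp)   # strand-aware by default
    qh <- queryHits(ht); sh <- subjectHits(ht)
    for (tx in unique(qh)) {
      j <- sh[qh == tx]
      key <- order(-tcs$tpm[j], -tcs$totalCount[j],
                   if (txStrand[tx] == "-") -tcs$repPos[j] else tcs$repPos[j])
      perTx$tc[tx] <- j[key[1]]
    }
  }
  genes <- unique(perTx$gene_id)
  perGene <- DataFrame(gene_id = genes, tc = rep(NA_integer_, length(genes)))
  for (k in seq_along(genes)) {
    rows <- which(perTx$gene_id == genes[k])
    cand <- unique(perTx$tc[rows][!is.na(perTx$tc[rows])])
    if (!length(cand)) next
    gstr <- txStrand[rows[1]]
    key <- order(-tcs$tpm[cand], -tcs$totalCount[cand],
                 if (gstr == "-") -tcs$repPos[cand] else tcs$repPos[cand])
    perGene$tc[k] <- cand[key[1]]
  }
  list(perTx = perTx, perGene = perGene)
}

#' Write tag clusters as BED6+3
#'
#' Columns: chrom, chromStart (0-based), chromEnd, name, score (total tag
#' count), strand, tpm, representative position (0-based), shape — in this
#' exact order.
#'
#' @param tcs tag clusters from \code{\link{clusterTags}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTagClusters <- function(tcs, path) {
  df <- data.frame(chrom = as.character(seqnames(tcs)),
                   start = start(tcs) - 1L, end = end(tcs),
                   name = if (length(tcs))
                     paste0("TC", seq_along(tcs)) else character(),
                   score = if (length(tcs)) tcs$totalCount else integer(),
                   strand = as.character(strand(tcs)),
                   tpm = if (length(tcs)) sprintf("%.6g", tcs$tpm)
                         else character(),
                   repPos = if (length(tcs)) tcs$repPos - 1L else integer(),
                   shape = if (length(tcs)) tcs$shape else character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
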