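## Serialization of comparison views: a versioned JSON document (the stable,
## machine-readable report) and a presentation-only SVG rendering with two
## locus panels, anchor ribbons colored by multiplicity and tag-cluster bars
## scaled by tpm.

.VIEW_SCHEMA_VERSION <- "1.0"

.regionJSON <- function(r) list(seq = as.character(seqnames(r)),
                                start = start(r), end = end(r),
                                name = if (is.null(names(r)))
                                  NA_character_ else names(r))

.trackSetJSON <- function(ts) {
  gm <- ts@genes
  genes <- lapply(seq_len(nrow(gm@geneData)), function(k) {
    gid <- gm@geneData$gene_id[k]
    txs <- which(gm@txData$gene_id == gid)
    list(gene_id = gid, name = gm@geneData$name[k],
         synonyms = as.character(gm@geneData$synonyms[k]),
         transcripts = lapply(txs, function(t) {
           ex <- gm@exonsByTx[[t]]
           list(tx_id = gm@txData$tx_id[t],
                seq = as.character(seqnames(ex))[1],
                strand = as.character(strand(ex))[1],
                exons = data.frame(start = start(ex), end = end(ex)))
         }))
  })
  tc <- ts@tagClusters
  list(assembly = ts@assembly, region = .regionJSON(ts@region),
       genes = genes,
       tag_clusters = if (length(tc)) data.frame(
         seq = as.character(seqnames(tc)), start = start(tc),
         end = end(tc), strand = as.character(strand(tc)),
         n_tags = tc$nTags, total_count = tc$totalCount, tpm = tc$tpm,
         rep_pos = tc$repPos, shape = tc$shape) else list())
}

.anchorsJSON <- function(anc) {
  if (!length(anc)) return(list())
  data.frame(ref_seq = as.character(seqnames(anc)), ref_start = start(anc),
             ref_end = end(anc),
             target_seq = as.character(seqnames(anc$target)),
             target_start = start(anc$target),
             target_end = end(anc$target),
             multiplicity = anc$multiplicity, chain_id = anc$chain_id,
             score = anc$score, orientation = anc$orientation,
             color = anc$color)
}

#' Serialize a comparison view
#'
#' \code{"json"} produces the stable, versioned report document whose parse
#' round-trips all coordinates exactly (see \code{\link{readViewJSON}});
#' \code{"svg"} produces a presentation-only rendering (two horizontal locus
#' panels, anchor ribbons colored by multiplicity, tag-cluster bars with
#' height proportional to tpm).
#'
#' @param view a \code{\link{ComparisonView}}.
#' @param format \code{"json"} or \code{"svg"}.
#' @param path optional output file.
#' @return The document as a single character string, invisibly when
#'   \code{path} is given.
#' @export
serializeView <- function(view, format = c("json", "svg"), path = NULL) {
  format <- match.arg(format)
  doc <- if (format == "json") .viewJSON(view) else .viewSVG(view)
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

.viewJSON <- function(view) {
  ann <- view@annotations
  obj <- list(schema_version = .VIEW_SCHEMA_VERSION,
              mode = view@mode,
              params = view@params[setdiff(names(view@params),
                                           "anchorColors")],
              anchor_colors = as.list(view@params$anchorColors),
              ref = .trackSetJSON(view@ref),
              target = .trackSetJSON(view@target),
              anchors = .anchorsJSON(view@anchors),
              annotations = ann)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

.trackSetFromJSON <- function(x) {
  exl <- list(); tx_id <- character(); gene_id <- character()
  gd <- list(); n <- 0L
  for (g in x$genes) {
    gd[[length(gd) + 1L]] <- data.frame(gene_id = g$gene_id, name = g$name,
      synonyms = if (is.null(g$synonyms)) "" else g$synonyms)
    for (t in g$transcripts) {
      n <- n + 1L
      exl[[n]] <- GRanges(t$seq, IRanges(t$exons$start, t$exons$end),
                          strand = t$strand)
      tx_id[n] <- t$tx_id; gene_id[n] <- g$gene_id
    }
  }
  gm <- if (n) GeneModels(stats::setNames(GRangesList(exl), tx_id),
                          DataFrame(tx_id = tx_id, gene_id = gene_id),
                          as(do.call(rbind, gd), "DataFrame"))
        else GeneModels(GRangesList(), DataFrame(tx_id = character(),
                                                 gene_id = character()))
  tc <- x$tag_clusters
  tcs <- if (is.data.frame(tc) && nrow(tc)) {
    g <- GRanges(tc$seq, IRanges(tc$start, tc$end), strand = tc$strand)
    mcols(g) <- DataFrame(nTags = as.integer(tc$n_tags),
                          totalCount = as.integer(tc$total_count),
                          tpm = tc$tpm, repPos = as.integer(tc$rep_pos),
                          shape = tc$shape)
    g
  } else GRanges()
  region <- GRanges(x$region$seq, IRanges(x$region$start, x$region$end))
  if (!is.null(x$region$name) && !is.na(x$region$name))
    names(region) <- x$region$name
  new("LocusTrackSet", region = region, genes = gm, tagClusters = tcs,
      assembly = x$assembly)
}

#' Read a serialized view back from JSON
#'
#' Inverse of \code{serializeView(view, "json")}: reconstructs the
#' \code{ComparisonView} with all coordinates exactly as serialized.
#'
#' @param path JSON file path (or a JSON string).
#' @return A \code{\link{ComparisonView}}.
#' @export
readViewJSON <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  # genes/transcripts need list-shaped parsing
  y <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ref <- .trackSetFromJSON(.mergeTrack(y$ref, x$ref))
  tgt <- .trackSetFromJSON(.mergeTrack(y$target, x$target))
  anc <- x$anchors
  anchors <- if (is.data.frame(anc) && nrow(anc)) {
    g <- GRanges(anc$ref_seq, IRanges(anc$ref_start, anc$ref_end))
    mcols(g) <- DataFrame(
      target = GRanges(anc$target_seq,
                       IRanges(anc$target_start, anc$target_end)),
      multiplicity = anc$multiplicity, chain_id = anc$chain_id,
      score = anc$score, orientation = anc$orientation, color = anc$color)
    g
  } else .emptyAnchors()
  prm <- x$params
  params <- locusParams(
    promoterFlank = prm$promoterFlank,
    transcriptFlank = prm$transcriptFlank,
    tcGeneWindow = prm$tcGeneWindow,
    neighborhoodHalfWidth = prm$neighborhoodHalfWidth,
    sharedTssTolerance = prm$sharedTssTolerance,
    shapeQuantiles = prm$shapeQuantiles,
    sharpWidthMax = prm$sharpWidthMax,
    maxAnchorLoci = prm$maxAnchorLoci,
    minAnchorWidth = prm$minAnchorWidth,
    anchorColors = unlist(x$anchor_colors))
  new("ComparisonView", mode = x$mode, ref = ref, target = tgt,
      anchors = anchors, annotations = as.list(x$annotations),
      params = params)
}

## transcripts come from the non-simplified parse; flat tables from the
## simplified one
.mergeTrack <- function(listForm, dfForm) {
  list(assembly = listForm$assembly,
       region = listForm$region,
       genes = lapply(listForm$genes, function(g) {
         g$transcripts <- lapply(g$transcripts, function(t) {
           t$exons <- data.frame(
             start = vapply(t$exons, function(e) e$start, 1),
             end = vapply(t$exons, function(e) e$end, 1))
           t
         })
         g
       }),
       tag_clusters = dfForm$tag_clusters)
}

.viewSVG <- function(view) {
  W <- 1000; panelH <- 120; gap <- 120; margin <- 40
  H <- 2 * panelH + gap + 2 * margin
  sc <- function(pos, region) {
    margin + (pos - start(region)) / max(width(region), 1L) * (W - 2 * margin)
  }
  panel <- function(ts, yTop) {
    r <- ts@region
    out <- sprintf(
      '<text x="%d" y="%d" font-size="12">%s %s:%d-%d</text>',
      margin, yTop - 6, ts@assembly, as.character(seqnames(r)), start(r),
      end(r))
    axisY <- yTop + panelH / 2
    out <- c(out, sprintf(
      '<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="black"/>',
      margin, axisY, W - margin, axisY))
    gm <- ts@genes
    for (t in seq_along(gm@exonsByTx)) {
      ex <- gm@exonsByTx[[t]]
      sp <- range(ex)
      out <- c(out, sprintf(
        '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="darkblue"/>',
        sc(start(sp), r), axisY, sc(end(sp), r), axisY))
      for (i in seq_along(ex))
        out <- c(out, sprintf(
          '<rect x="%.1f" y="%.1f" width="%.2f" height="10" fill="darkblue"/>',
          sc(start(ex)[i], r), axisY - 5,
          max(sc(end(ex)[i], r) - sc(start(ex)[i], r), 0.5)))
    }
    tc <- ts@tagClusters
    if (length(tc)) {
      hmax <- max(tc$tpm)
      for (i in seq_along(tc)) {
        h <- 8 + 40 * tc$tpm[i] / max(hmax, 1e-9)
        out <- c(out, sprintf(
          '<rect x="%.1f" y="%.1f" width="%.2f" height="%.1f" fill="%s"/>',
          sc(start(tc)[i], r), axisY - 12 - h,
          max(sc(end(tc)[i], r) - sc(start(tc)[i], r), 1), h,
          if (tc$shape[i] == "sharp") "red" else "orange"))
      }
    }
    out
  }
  yRef <- margin; yTgt <- margin + panelH + gap
  body <- c(panel(view@ref, yRef), panel(view@target, yTgt))
  anc <- view@anchors
  rr <- view@ref@region; tr <- view@target@region
  yA <- yRef + panelH / 2 + 8; yB <- yTgt + panelH / 2 - 8
  for (i in seq_along(anc)) {
    tgt <- anc$target[i]
    body <- c(body, sprintf(
      paste0('<polygon points="%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f" ',
             'fill="%s" fill-opacity="0.45"/>'),
      sc(start(anc)[i], rr), yA, sc(end(anc)[i], rr), yA,
      sc(end(tgt), tr), yB, sc(start(tgt), tr), yB,
      anc$color[i]))
  }
  paste(c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                         'width="%d" height="%d">'), W, H),
          sprintf('<title>%s view</title>', view@mode),
          body, "</svg>"), collapse = "\n")
}
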