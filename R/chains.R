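## UCSC chain parsing, block decomposition and interval mapping.  The chain
## format is 0-based half-open with query coordinates given on the query
## strand; blocks are normalized here to plus-strand GRanges on both sides,
## with the original relative orientation kept as a flag.

#' Read a UCSC chain file
#'
#' Parses chain headers and gap-free block lines, verifies the block
#' arithmetic of every chain against its header spans (fail-fast: a malformed
#' chain aborts the load), and decomposes each chain into plus-strand aligned
#' blocks.
#'
#' @param path chain file, plain text or gzip.
#' @return A \code{\link{ChainSet}}.
#' @export
readChains <- function(path) {
  if (!file.exists(path)) stop("chain file not found: ", path)
  lines <- readLines(gzfile(path))
  lines <- trimws(lines)
  hdr_i <- grep("^chain\\b", lines)
  chains <- vector("list", length(hdr_i))
  blocks <- vector("list", length(hdr_i))
  bounds <- c(hdr_i, length(lines) + 1L)
  for (k in seq_along(hdr_i)) {
    f <- strsplit(lines[hdr_i[k]], "[ \t]+")[[1]]
    if (length(f) < 12L)
      stop("chain header with too few fields at line ", hdr_i[k])
    id <- if (length(f) >= 13L) f[13] else as.character(k)
    h <- list(chain_id = id, score = as.numeric(f[2]),
              t_name = f[3], t_size = as.integer(f[4]),
              t_strand = f[5], t_start = as.integer(f[6]),
              t_end = as.integer(f[7]),
              q_name = f[8], q_size = as.integer(f[9]),
              q_strand = f[10], q_start = as.integer(f[11]),
              q_end = as.integer(f[12]))
    if (!identical(h$t_strand, "+"))
      stop("chain ", id, ": target strand must be '+'")
    if (!h$q_strand %in% c("+", "-"))
      stop("chain ", id, ": query strand must be '+' or '-'")
    body <- lines[seq(hdr_i[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(body) & !grepl("^#", body)]
    if (!length(body)) stop("chain ", id, ": no alignment blocks")
    bf <- strsplit(body, "[ \t]+")
    nl <- lengths(bf)
    if (any(nl[-length(nl)] != 3L) || nl[length(nl)] != 1L)
      stop("chain ", id, ": malformed block lines (need 'size dt dq' ",
           "triples and a final bare size)")
    size <- vapply(bf, function(x) as.integer(x[1]), 1L)
    dt <- c(vapply(bf[-length(bf)], function(x) as.integer(x[2]), 1L), 0L)
    dq <- c(vapply(bf[-length(bf)], function(x) as.integer(x[3]), 1L), 0L)
    if (any(size <= 0L) || any(dt < 0L) || any(dq < 0L))
      stop("chain ", id, ": block sizes must be positive, gaps non-negative")
    if (sum(size + dt) != h$t_end - h$t_start)
      stop("chain ", id, ": target block arithmetic (", sum(size + dt),
           ") disagrees with header span (", h$t_end - h$t_start, ")")
    if (sum(size + dq) != h$q_end - h$q_start)
      stop("chain ", id, ": query block arithmetic (", sum(size + dq),
           ") disagrees with header span (", h$q_end - h$q_start, ")")
    chains[[k]] <- h
    # cursor walk in native (0-based) coordinates
    t0 <- h$t_start + c(0L, cumsum(size + dt))[seq_along(size)]
    q0 <- h$q_start + c(0L, cumsum(size + dq))[seq_along(size)]
    if (h$q_strand == "-") {
      qs_plus <- h$q_size - (q0 + size)   # 0-based plus-strand starts
      orientation <- "opposite"
    } else {
      qs_plus <- q0
      orientation <- "same"
    }
    blocks[[k]] <- data.frame(t_start0 = t0, size = size,
                              q_start0 = qs_plus,
                              chain_id = id, score = h$score,
                              t_name = h$t_name, q_name = h$q_name,
                              orientation = orientation)
  }
  .makeChainSet(do.call(rbind, lapply(chains, as.data.frame)),
                do.call(rbind, blocks))
}

.makeChainSet <- function(chainDf, blockDf) {
  if (is.null(chainDf) || nrow(chainDf) == 0L)
    return(new("ChainSet", chains = DataFrame(), blocks = GRanges()))
  bl <- GRanges(blockDf$t_name,
                IRanges(blockDf$t_start0 + 1L,
                        blockDf$t_start0 + blockDf$size),
                chain_id = blockDf$chain_id, score = blockDf$score,
                q_seq = blockDf$q_name,
                q_start = blockDf$q_start0 + 1L,
                q_end = blockDf$q_start0 + blockDf$size,
                orientation = blockDf$orientation)
  new("ChainSet", chains = as(chainDf, "DataFrame"), blocks = bl)
}

#' Chain header table and block accessors
#' @param cs a \code{ChainSet}.
#' @param chainId optional chain id filter for \code{blocksOf}.
#' @return \code{chainTable}: the header \code{DataFrame};
#'   \code{blocksOf}: plus-strand block \code{GRanges} (target side) with
#'   query-side metadata columns, sorted by target start.
#' @export
chainTable <- function(cs) cs@chains

#' @rdname chainTable
#' @export
blocksOf <- function(cs, chainId = NULL) {
  bl <- cs@blocks
  if (!is.null(chainId)) bl <- bl[bl$chain_id %in% chainId]
  bl[order(as.character(seqnames(bl)), start(bl))]
}

#' Swap the target and query sides of a chain set
#'
#' Useful when a region of interest lives on the query assembly of the
#' available chain file: all block-level operations treat the target side as
#' the reference.
#'
#' @param cs a \code{ChainSet}.
#' @return A \code{ChainSet} with the sides exchanged (orientation flags are
#'   unchanged; header coordinates are swapped at block precision).
#' @export
invertChains <- function(cs) {
  bl <- cs@blocks
  if (!length(bl)) return(cs)
  inv <- GRanges(bl$q_seq, IRanges(bl$q_start, bl$q_end),
                 chain_id = bl$chain_id, score = bl$score,
                 q_seq = as.character(seqnames(bl)),
                 q_start = start(bl), q_end = end(bl),
                 orientation = bl$orientation)
  ch <- cs@chains
  if (nrow(ch)) {
    swapped <- ch
    swapped$t_name <- ch$q_name; swapped$q_name <- ch$t_name
    swapped$t_size <- ch$q_size; swapped$q_size <- ch$t_size
    qs <- ch$q_start; qe <- ch$q_end
    minus <- ch$q_strand == "-"
    # query header coords are on the query strand; convert to plus
    swapped$t_start <- ifelse(minus, ch$q_size - qe, qs)
    swapped$t_end <- ifelse(minus, ch$q_size - qs, qe)
    swapped$q_start <- ch$t_start; swapped$q_end <- ch$t_end
    ch <- swapped
  }
  new("ChainSet", chains = ch, blocks = inv)
}

#' Map intervals through chain alignments
#'
#' Every gap-free block overlapping an input interval contributes the
#' overlapping sub-interval, offset-mapped to the other side
#' (mirror-offset for opposite-orientation blocks).  The output covers
#' exactly the aligned portion of the input; bases falling in chain gaps are
#' dropped.
#'
#' @param cs a \code{\link{ChainSet}}.
#' @param iv \code{GRanges} of intervals to map.
#' @param direction \code{"t2q"} (intervals live on the target side of the
#'   chains, default) or \code{"q2t"}.
#' @param chainIds optional chain id filter.
#' @return \code{GRanges} of sub-intervals of \code{iv} (on the input side)
#'   with metadata columns \code{mapped} (a \code{GRanges} on the other
#'   side), \code{chain_id}, \code{orientation}, \code{score} and
#'   \code{query} (index into \code{iv}); sorted by (query, start).
#' @export
mapThroughChains <- function(cs, iv, direction = c("t2q", "q2t"),
                             chainIds = NULL) {
  direction <- match.arg(direction)
  eff <- if (direction == "q2t") invertChains(cs) else cs
  bl <- eff@blocks
  if (!is.null(chainIds)) bl <- bl[bl$chain_id %in% chainIds]
  empty <- GRanges()
  mcols(empty) <- DataFrame(mapped = GRanges(), chain_id = character(),
                            orientation = character(), score = numeric(),
                            query = integer())
  if (!length(bl) || !length(iv)) return(empty)
  ht <- findOverlaps(iv, bl, ignore.strand = TRUE)
  if (!length(ht)) return(empty)
  qi <- queryHits(ht); bi <- subjectHits(ht)
  ss <- pmax(start(iv)[qi], start(bl)[bi])
  ee <- pmin(end(iv)[qi], end(bl)[bi])
  opp <- bl$orientation[bi] == "opposite"
  ms <- ifelse(opp, bl$q_end[bi] - (ee - start(bl)[bi]),
                    bl$q_start[bi] + (ss - start(bl)[bi]))
  me <- ifelse(opp, bl$q_end[bi] - (ss - start(bl)[bi]),
                    bl$q_start[bi] + (ee - start(bl)[bi]))
  out <- GRanges(seqnames(iv)[qi], IRanges(ss, ee))
  mcols(out) <- DataFrame(mapped = GRanges(bl$q_seq[bi], IRanges(ms, me)),
                          chain_id = bl$chain_id[bi],
                          orientation = bl$orientation[bi],
                          score = bl$score[bi], query = qi)
  out[order(mcols(out)$query, start(out), mcols(out)$chain_id)]
}

#' Write a ChainSet in UCSC chain format
#'
#' Reconstructs headers and block lines from the stored blocks (native
#' 0-based coordinates, query side re-expressed on the original query
#' strand).
#'
#' @param cs a \code{\link{ChainSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChains <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ch <- cs@chains
  for (k in seq_len(nrow(ch))) {
    h <- ch[k, ]
    writeLines(paste("chain", format(h$score, scientific = FALSE),
                     h$t_name, h$t_size, "+", h$t_start, h$t_end,
                     h$q_name, h$q_size, h$q_strand, h$q_start, h$q_end,
                     h$chain_id), con)
    bl <- cs@blocks[cs@blocks$chain_id == h$chain_id]
    bl <- bl[order(start(bl))]
    t0 <- start(bl) - 1L
    size <- width(bl)
    if (h$q_strand == "-") {
      q0 <- h$q_size - bl$q_end           # native (minus-strand) starts
      o <- order(q0)                       # native q ascends as t ascends
      stopifnot(identical(o, order(t0)))
    } else {
      q0 <- bl$q_start - 1L
    }
    n <- length(size)
    dt <- if (n > 1L) t0[-1L] - (t0[-n] + size[-n]) else integer()
    dq <- if (n > 1L) q0[-1L] - (q0[-n] + size[-n]) else integer()
    if (n > 1L)
      writeLines(paste(size[-n], dt, dq), con)
    writeLines(c(as.character(size[n]), ""), con)
  }
  invisible(path)
}
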