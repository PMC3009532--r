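## Homology tables (BioMart-style gene-pair exports), the ortholog-bridge
## derivation of whole-genome-duplication paralog pairs, and grouping of
## paralog pairs by their last-common-ancestor taxon.

.pairKey <- function(a, sa, b, sb) {
  ka <- paste(sa, a, sep = ":"); kb <- paste(sb, b, sep = ":")
  paste(pmin(ka, kb), pmax(ka, kb), sep = "|")
}

#' Read a homology table
#'
#' Tab-separated file with header columns \code{gene_a}, \code{species_a},
#' \code{gene_b}, \code{species_b}, \code{relation} (\code{ortholog} or
#' \code{paralog}), \code{ancestor_taxon} and optionally \code{confidence}.
#' Pairs are unordered: duplicate rows listing the same pair in either
#' orientation are collapsed.  Same-species self-pairs are rejected with a
#' report of the offending rows.
#'
#' @param path TSV path.
#' @return data.frame of deduplicated pairs, stably sorted by
#'   (species_a, gene_a, species_b, gene_b).
#' @export
readHomologyTable <- function(path) {
  if (!file.exists(path)) stop("homology table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("gene_a", "species_a", "gene_b", "species_b", "relation",
            "ancestor_taxon")
  if (!all(need %in% colnames(tab)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  if (!"confidence" %in% colnames(tab))
    tab$confidence <- rep(NA_character_, nrow(tab))
  if (!nrow(tab)) return(tab[, c(need, "confidence")])
  bad <- !tab$relation %in% c("ortholog", "paralog")
  if (any(bad))
    stop("unknown relation token(s): ",
         paste(unique(tab$relation[bad]), collapse = ", "))
  self <- tab$species_a == tab$species_b & tab$gene_a == tab$gene_b
  if (any(self))
    stop("self-pair(s) in the same species rejected at row(s): ",
         paste(which(self), collapse = ", "))
  key <- .pairKey(tab$gene_a, tab$species_a, tab$gene_b, tab$species_b)
  tab <- tab[!duplicated(key), c(need, "confidence")]
  tab[order(tab$species_a, tab$gene_a, tab$species_b, tab$gene_b), ,
      drop = FALSE]
}

#' WGD-candidate paralog pairs through an ortholog bridge
#'
#' Given orthologs between an outgroup species A (which approximates the
#' pre-duplication ancestor) and a duplicated species B, every A gene with
#' two or more distinct B orthologs votes for all unordered combinations of
#' those B genes as candidate whole-genome-duplication paralog pairs.
#'
#' @param orthologs data.frame of A:B ortholog pairs in the
#'   \code{\link{readHomologyTable}} layout (species A in the
#'   \code{gene_a}/\code{species_a} columns, or mixed orientation — rows are
#'   normalized by the \code{speciesA} argument).
#' @param speciesA label of the bridging species (default: the most frequent
#'   \code{species_a} value).
#' @return data.frame with columns \code{gene_b1}, \code{gene_b2} (unordered,
#'   b1 < b2), \code{species}, \code{bridge_gene} (the A gene), deduplicated
#'   on (gene_b1, gene_b2, bridge_gene) and sorted.
#' @export
wgdPairsViaBridge <- function(orthologs, speciesA = NULL) {
  ort <- orthologs[orthologs$relation == "ortholog", , drop = FALSE]
  if (!nrow(ort))
    return(data.frame(gene_b1 = character(), gene_b2 = character(),
                      species = character(), bridge_gene = character()))
  if (is.null(speciesA))
    speciesA <- names(sort(table(ort$species_a), decreasing = TRUE))[1]
  flip <- ort$species_b == speciesA
  a <- ifelse(flip, ort$gene_b, ort$gene_a)
  b <- ifelse(flip, ort$gene_a, ort$gene_b)
  spB <- ifelse(flip, ort$species_a, ort$species_b)
  keep <- (ifelse(flip, ort$species_b, ort$species_a)) == speciesA &
    spB != speciesA
  a <- a[keep]; b <- b[keep]; spB <- spB[keep]
  res <- list(); n <- 0L
  for (g in unique(a)) {
    bs <- sort(unique(b[a == g]))
    if (length(bs) < 2L) next
    cmb <- utils::combn(bs, 2L)
    n <- n + 1L
    res[[n]] <- data.frame(gene_b1 = cmb[1, ], gene_b2 = cmb[2, ],
                           species = spB[a == g][1], bridge_gene = g)
  }
  if (!n)
    return(data.frame(gene_b1 = character(), gene_b2 = character(),
                      species = character(), bridge_gene = character()))
  out <- do.call(rbind, res)
  out <- out[!duplicated(out[, c("gene_b1", "gene_b2", "bridge_gene")]), ]
  out <- out[order(out$gene_b1, out$gene_b2, out$bridge_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count paralog pairs by last-common-ancestor taxon
#'
#' @param pairs data.frame in the \code{\link{readHomologyTable}} layout;
#'   missing or empty \code{ancestor_taxon} values are grouped as
#'   \code{"unknown"}.
#' @return named integer vector of exact multiset counts.
#' @export
paralogCountsByAncestor <- function(pairs) {
  if (!nrow(pairs)) return(stats::setNames(integer(), character()))
  tax <- pairs$ancestor_taxon
  tax[is.na(tax) | !nzchar(tax)] <- "unknown"
  tb <- table(tax)
  stats::setNames(as.integer(tb), names(tb))
}
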