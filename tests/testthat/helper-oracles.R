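# Independent oracles: brute-force or per-base re-implementations used only
# to check package results on small instances.  They share no code with the
# package internals.

suppressMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# --- single-linkage clustering oracle: enumerate all O(n^2) overlapping
# pairs, then take connected components with a plain union-find --------------
oracleClusterMembership <- function(seqs, starts, ends, strands) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  grp <- paste(seqs, strands)
  for (i in seq_len(n - 1L)) {
    js <- which(grp[(i + 1L):n] == grp[i]) + i
    ov <- js[starts[js] <= ends[i] & ends[js] >= starts[i]]
    for (j in ov) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 1L)
}

# --- per-base chain map oracle: from the raw chain numbers (native, 0-based)
# build a map vector over the target span; entry t0+1 holds the plus-strand
# 0-based query position or NA ------------------------------------------------
oracleBaseMap <- function(tStart0, sizes, dts, dqs, qStart0, qStrand, qSize) {
  span <- sum(sizes + dts)
  map <- rep(NA_integer_, span)
  tc <- 0L; qc <- qStart0
  for (k in seq_along(sizes)) {
    for (b in seq_len(sizes[k])) {
      tOff <- tc + b - 1L
      qNat <- qc + b - 1L
      map[tOff + 1L] <- if (qStrand == "-") qSize - 1L - qNat else qNat
    }
    tc <- tc + sizes[k] + dts[k]
    qc <- qc + sizes[k] + dqs[k]
  }
  list(map = map, tStart0 = tStart0)
}

# mapped plus-strand 0-based query positions of a 1-based target interval
oracleMapBases <- function(bm, s1, e1) {
  idx <- (s1:e1) - 1L - bm$tStart0 + 1L
  idx <- idx[idx >= 1L & idx <= length(bm$map)]
  out <- bm$map[idx]
  out[!is.na(out)]
}

# --- per-base anchor multiplicity oracle ------------------------------------
# chainsSpec: list of list(id, score, bm (oracleBaseMap), tName)
# returns, for each base of region (1-based), the sorted ids of the chains
# kept after top-k selection (score desc, footprint-in-region desc, id asc)
oracleMultiplicity <- function(regionSeq, s1, e1, chainsSpec, maxLoci) {
  covers <- lapply(chainsSpec, function(cs) {
    if (cs$tName != regionSeq) return(rep(FALSE, e1 - s1 + 1L))
    idx <- (s1:e1) - 1L - cs$bm$tStart0 + 1L
    ok <- idx >= 1L & idx <= length(cs$bm$map)
    covered <- rep(FALSE, e1 - s1 + 1L)
    covered[ok] <- !is.na(cs$bm$map[idx[ok]])
    covered
  })
  foot <- vapply(covers, sum, 1L)
  ids <- vapply(chainsSpec, `[[`, "", "id")
  scores <- vapply(chainsSpec, function(x) as.numeric(x$score), 1)
  lapply(seq_len(e1 - s1 + 1L), function(b) {
    cov <- which(vapply(covers, `[`, TRUE, b))
    if (!length(cov)) return(character())
    o <- cov[order(-scores[cov], -foot[cov], ids[cov])]
    sort(ids[o[seq_len(min(maxLoci, length(o)))]])
  })
}

# --- per-base bridge composition oracle -------------------------------------
# bmAB, bmAC map A (target side) to B and C; returns for each B base
# (plus-strand 0-based) the composed C base, over the given B interval
oracleBridgeMap <- function(bmAB, bmAC, bS1, bE1) {
  # invert A->B
  res <- rep(NA_integer_, bE1 - bS1 + 1L)
  for (aOff in seq_along(bmAB$map)) {
    b0 <- bmAB$map[aOff]
    if (is.na(b0)) next
    bPos1 <- b0 + 1L
    if (bPos1 < bS1 || bPos1 > bE1) next
    aIdx <- aOff  # same A base in the AC map (both maps share tStart0 frame)
    shift <- bmAB$tStart0 - bmAC$tStart0
    aIdx2 <- aOff + shift
    if (aIdx2 >= 1L && aIdx2 <= length(bmAC$map))
      res[bPos1 - bS1 + 1L] <- bmAC$map[aIdx2]
  }
  res
}

# expand package anchors into a per-base map over the reference interval
anchorsToBaseMap <- function(anc, s1, e1) {
  ids <- vector("list", e1 - s1 + 1L)
  for (i in seq_along(ids)) ids[[i]] <- character()
  mapped <- rep(NA_integer_, e1 - s1 + 1L)
  as_ <- start(anc); ae_ <- end(anc); cid <- anc$chain_id
  ts_ <- start(anc$target); te_ <- end(anc$target)
  opp <- anc$orientation == "opposite"
  for (k in seq_along(as_)) {
    for (p in max(as_[k], s1):min(ae_[k], e1)) {
      ids[[p - s1 + 1L]] <- c(ids[[p - s1 + 1L]], cid[k])
      mapped[p - s1 + 1L] <- (if (opp[k]) te_[k] - (p - as_[k])
                              else ts_[k] + (p - as_[k])) - 1L
    }
  }
  list(ids = lapply(ids, sort), mapped = mapped)
}
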