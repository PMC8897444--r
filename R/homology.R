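# Self-homology blacklist: a k-mer-seeded, ungapped extension scan over
# sliding CDS windows, replacing an external local aligner. Windows of the
# coding sequence are compared against every other locus reachable through an
# exact k-mer seed (both orientations); within qualifying ungapped local hits
# (length and identity thresholds) the mismatched positions -- and the
# substitution types they imply, in both directions -- are blacklisted.

#' Build the self-homology blacklist
#'
#' Slides a window over each coding exon (window 76 bp, step 19 bp -- a
#' quarter of the window), seeds candidate subject loci with exact k-mer
#' matches against the whole genome in both orientations, evaluates each
#' candidate diagonal as an ungapped alignment, and keeps the longest
#' sub-segment with identity at or above \code{minIdentity} and length at
#' least \code{minLen}. Hits at the window's own locus are ignored. Perfect
#' duplicates yield hits but no blacklist entries (no mismatched positions).
#'
#' @param genome a \code{DNAStringSet}.
#' @param exons a \code{GRanges} of coding exons.
#' @param window,step sliding-window size and step in bp (defaults 76/19).
#' @param minLen minimal hit length (default 61).
#' @param minIdentity minimal hit identity (default 0.94).
#' @param k seed k-mer size (default 12).
#' @return A list with \code{blacklist} (data.table: chrom, pos, ref, alt,
#'   source -- one row per suppressed (position, substitution) pair, both
#'   directions) and \code{hits} (data.table of qualifying hits: query/subject
#'   intervals, orientation, length, identity, mismatches).
#' @examples
#' ref <- generateReference(simConfig(seed = 2, nDonors = 2))
#' hb <- homologyBlacklist(refGenome(ref), refExons(ref))
#' nrow(hb$blacklist)
#' @export
homologyBlacklist <- function(genome, exons, window = 76L, step = 19L,
                              minLen = 61L, minIdentity = 0.94, k = 12L) {
  chromSeq <- lapply(names(genome), function(ch)
    strsplit(as.character(genome[[ch]]), "")[[1]])
  names(chromSeq) <- names(genome)

  idx <- kmerIndex(genome, k)

  exDf <- as.data.frame(exons)
  hits <- list(); bl <- list()
  for (i in seq_len(nrow(exDf))) {
    ch <- as.character(exDf$seqnames[i])
    starts <- seq(exDf$start[i], max(exDf$start[i], exDf$end[i] - window + 1L),
                  by = step)
    for (qs in starts) {
      qe <- min(qs + window - 1L, exDf$end[i])
      if (qe - qs + 1L < minLen) next
      q <- chromSeq[[ch]][qs:qe]
      cand <- seedDiagonals(q, ch, qs, idx, k)
      for (ci in seq_len(nrow(cand))) {
        sch <- cand$chrom[ci]; ss <- cand$start[ci]; rc <- cand$rc[ci]
        len <- length(q)
        if (ss < 1L || ss + len - 1L > length(chromSeq[[sch]])) next
        # skip the query's own locus
        if (!rc && sch == ch && ss < qe && ss + len - 1L > qs) next
        s <- chromSeq[[sch]][ss:(ss + len - 1L)]
        if (rc) s <- rev(compBase(s))
        seg <- bestSegment(q == s, minLen, minIdentity)
        if (is.null(seg)) next
        segIdx <- seg$from:seg$to
        mmIdx <- segIdx[q[segIdx] != s[segIdx]]
        qPos <- qs + segIdx - 1L
        sPos <- if (rc) ss + (len - segIdx) else ss + segIdx - 1L
        src <- sprintf("%s:%d-%d%s", sch, ss, ss + len - 1L,
                       if (rc) "(-)" else "(+)")
        hits[[length(hits) + 1L]] <- data.table(
          q_chrom = ch, q_start = min(qPos), q_end = max(qPos),
          s_chrom = sch, s_start = min(sPos), s_end = max(sPos),
          rc = rc, length = seg$to - seg$from + 1L, identity = seg$identity,
          mismatches = length(mmIdx))
        if (length(mmIdx)) {
          qb <- q[mmIdx]; sb <- s[mmIdx]
          qp <- qs + mmIdx - 1L
          sp <- if (rc) ss + (len - mmIdx) else ss + mmIdx - 1L
          sbGenomic <- if (rc) compBase(sb) else sb   # subject's own strand
          qbAtSubject <- if (rc) compBase(qb) else qb
          bl[[length(bl) + 1L]] <- rbind(
            data.table(chrom = ch, pos = qp, ref = qb, alt = sb, source = src),
            data.table(chrom = sch, pos = sp, ref = sbGenomic,
                       alt = qbAtSubject,
                       source = sprintf("%s:%d-%d", ch, qs, qe)))
        }
      }
    }
  }
  hits <- if (length(hits)) unique(rbindlist(hits)) else
    data.table(q_chrom = character(), q_start = integer(), q_end = integer(),
               s_chrom = character(), s_start = integer(), s_end = integer(),
               rc = logical(), length = integer(), identity = numeric(),
               mismatches = integer())
  bl <- if (length(bl)) unique(rbindlist(bl)) else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), source = character())
  list(blacklist = bl[order(chrom, pos)], hits = hits)
}

# exact k-mer position index of the genome (plus strand)
kmerIndex <- function(genome, k) {
  tabs <- lapply(names(genome), function(ch) {
    s <- as.character(genome[[ch]])
    n <- nchar(s) - k + 1L
    data.table(kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
               chrom = ch, pos = seq_len(n))
  })
  idx <- rbindlist(tabs)
  setkey(idx, kmer)
  idx
}

# candidate subject diagonals for a query window, from exact k-mer seeds in
# both orientations; returns implied subject start for the full window
seedDiagonals <- function(q, qChrom, qStart, idx, k) {
  len <- length(q)
  offs <- unique(c(seq(1L, len - k + 1L, by = k), len - k + 1L))
  qs <- vapply(offs, function(o) paste(q[o:(o + k - 1L)], collapse = ""),
               character(1))
  fwd <- idx[.(qs), nomatch = 0L]
  if (nrow(fwd)) {
    fwd[, off := offs[match(kmer, qs)]]
    fwd <- fwd[, .(chrom, start = pos - off + 1L, rc = FALSE)]
  } else fwd <- data.table(chrom = character(), start = integer(), rc = logical())
  # reverse-complement orientation: seed with the rc of each query k-mer;
  # a subject match at pos means the window aligns rc over
  # [pos - (len - off - k + 1), pos + off + k - 2] ... derive start directly
  qrc <- vapply(offs, function(o)
    paste(rev(compBase(q[o:(o + k - 1L)])), collapse = ""), character(1))
  rev_ <- idx[.(qrc), nomatch = 0L]
  if (nrow(rev_)) {
    rev_[, off := offs[match(kmer, qrc)]]
    # subject window start such that subject[start..start+len-1] reversed-
    # complemented aligns to q: query offset o maps to subject pos
    # start + len - (o + k - 1); the seed's first subject base is pos
    rev_ <- rev_[, .(chrom, start = pos - (len - (off + k - 1L)), rc = TRUE)]
  } else rev_ <- data.table(chrom = character(), start = integer(), rc = logical())
  unique(rbind(fwd, rev_))
}

# longest sub-interval of a logical match vector with length >= minLen and
# identity >= minIdentity (exhaustive over end points; windows are small)
bestSegment <- function(match, minLen, minIdentity) {
  n <- length(match)
  if (n < minLen) return(NULL)
  cs <- c(0L, cumsum(match))
  if (cs[n + 1L] / n >= minIdentity) {          # whole alignment qualifies
    return(list(from = 1L, to = n, identity = cs[n + 1L] / n))
  }
  if (cs[n + 1L] < minLen * minIdentity) return(NULL)
  best <- NULL
  for (from in seq_len(n - minLen + 1L)) {
    to <- seq(from + minLen - 1L, n)
    len <- to - from + 1L
    id <- (cs[to + 1L] - cs[from]) / len
    ok <- which(id >= minIdentity)
    if (!length(ok)) next
    iBest <- ok[which.max(len[ok] + id[ok])]    # longest, ties by identity
    if (is.null(best) || len[iBest] > best$len ||
        (len[iBest] == best$len && id[iBest] > best$identity)) {
      best <- list(from = from, to = to[iBest], len = len[iBest],
                   identity = id[iBest])
    }
  }
  if (is.null(best)) return(NULL)
  list(from = best$from, to = best$to, identity = best$identity)
}
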