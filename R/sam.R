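# Read-level mismatch detection: a minimal SAM subset (FLAG, POS, indel-free
# CIGAR, SEQ, QUAL), the read- and base-level exclusion rules, and
# aggregation into per-sample, per-site, per-strand evidence counts.
#
# Read filters, applied in fixed order (the reason reports the first failing
# rule): low_quality (>= 25% of bases with q < 20), vendor_fail, not proper
# pair, duplicate, mismatch_excess (>= 3 mismatches of more than two distinct
# substitution types).
#
# Mismatch filters, fixed order: read_end (within 5 bp of either read end or
# reference-projected alignment end), splice (within 4 bp of an annotated
# exon boundary, exonic side), homopolymer (inside or immediately flanking a
# run >= 5), base_quality (q < 30).

FLAG_PROPER <- 0x2L
FLAG_REVERSE <- 0x10L
FLAG_VENDOR <- 0x200L
FLAG_DUP <- 0x400L

#' Read a minimal SAM file
#'
#' Supports single-M CIGAR alignments (no indels, no clipping). Mismatches
#' are derived by comparing SEQ to the reference.
#'
#' @param file path to a SAM file.
#' @param genome a \code{DNAStringSet} reference.
#' @return A list with \code{reads} (data.table: id, flag, chrom, pos, end,
#'   strand, qual) and \code{mismatches} (data.table: id, chrom, pos,
#'   read_pos, ref, obs, qual).
#' @export
readSam <- function(file, genome) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  bad <- which(vapply(f, length, integer(1)) < 11L)
  if (length(bad)) stop("malformed SAM record at line ", bad[1])
  reads <- data.table(
    id = vapply(f, `[[`, character(1), 1L),
    flag = as.integer(vapply(f, `[[`, character(1), 2L)),
    chrom = vapply(f, `[[`, character(1), 3L),
    pos = as.integer(vapply(f, `[[`, character(1), 4L)),
    cigar = vapply(f, `[[`, character(1), 6L),
    seq = vapply(f, `[[`, character(1), 10L),
    qual = vapply(f, `[[`, character(1), 11L))
  if (any(!grepl("^[0-9]+M$", reads$cigar))) {
    stop("only indel-free single-M CIGAR alignments are supported")
  }
  reads[, end := pos + nchar(seq) - 1L]
  reads[, strand := ifelse(bitwAnd(flag, FLAG_REVERSE) > 0L, "-", "+")]
  mm <- lapply(seq_len(nrow(reads)), function(i) {
    refseq <- strsplit(as.character(
      Biostrings::subseq(genome[[reads$chrom[i]]], reads$pos[i],
                         reads$end[i])), "")[[1]]
    obs <- strsplit(reads$seq[i], "")[[1]]
    d <- which(obs != refseq)
    if (!length(d)) return(NULL)
    data.table(id = reads$id[i], chrom = reads$chrom[i],
               pos = reads$pos[i] + d - 1L, read_pos = d,
               ref = refseq[d], obs = obs[d],
               qual = utf8ToInt(reads$qual[i])[d] - 33L)
  })
  mm <- rbindlist(mm[!vapply(mm, is.null, logical(1))])
  if (!nrow(mm)) {
    mm <- data.table(id = character(), chrom = character(), pos = integer(),
                     read_pos = integer(), ref = character(),
                     obs = character(), qual = integer())
  }
  list(reads = reads[, .(id, flag, chrom, pos, end, strand, cigar, qual)],
       mismatches = mm)
}

#' Read-level exclusion rules
#'
#' @param reads data.table as returned by [readSam()].
#' @param mismatches matching mismatch table.
#' @param qualLow,lowFrac read-quality rule: discard when at least
#'   \code{lowFrac} of bases have quality below \code{qualLow}
#'   (defaults 20 and 0.25).
#' @return data.table: id, keep, reason ("ok" when kept).
#' @export
filterReads <- function(reads, mismatches, qualLow = 20L, lowFrac = 0.25) {
  if (any(is.na(reads$qual) | reads$qual == "*")) {
    stop("read without a quality array cannot be evaluated")
  }
  qfrac <- vapply(reads$qual, function(q) {
    v <- utf8ToInt(q) - 33L
    mean(v < qualLow)
  }, numeric(1), USE.NAMES = FALSE)
  mmTypes <- mismatches[, .(n = .N,
                            types = data.table::uniqueN(paste0(ref, ">", obs))),
                        by = id]
  n_mm <- mmTypes$n[match(reads$id, mmTypes$id)]
  n_ty <- mmTypes$types[match(reads$id, mmTypes$id)]
  n_mm[is.na(n_mm)] <- 0L; n_ty[is.na(n_ty)] <- 0L

  reason <- rep("ok", nrow(reads))
  fail <- function(cond, code) reason <<- ifelse(reason == "ok" & cond, code, reason)
  fail(qfrac >= lowFrac, "low_quality")
  fail(bitwAnd(reads$flag, FLAG_VENDOR) > 0L, "vendor_fail")
  fail(bitwAnd(reads$flag, FLAG_PROPER) == 0L, "not_proper_pair")
  fail(bitwAnd(reads$flag, FLAG_DUP) > 0L, "duplicate")
  fail(n_mm >= 3L & n_ty > 2L, "mismatch_excess")
  data.table(id = reads$id, keep = reason == "ok", reason = reason)
}

#' Mismatch-level exclusion rules
#'
#' @param mismatches,reads tables as returned by [readSam()].
#' @param genome reference \code{DNAStringSet}.
#' @param exons exon annotation (\code{GRanges}) for splice proximity, or
#'   \code{NULL} to skip the rule.
#' @param endDist exclusion distance from read/alignment ends (default 5).
#' @param spliceDist exonic distance from a splice junction (default 4).
#' @param hpMinRun minimal homopolymer run (default 5).
#' @param qualMin minimal base quality (default 30).
#' @return data.table parallel to \code{mismatches}: keep, reason.
#' @export
filterMismatches <- function(mismatches, reads, genome, exons = NULL,
                             endDist = 5L, spliceDist = 4L, hpMinRun = 5L,
                             qualMin = 30L) {
  if (!nrow(mismatches)) {
    return(data.table(keep = logical(), reason = character()))
  }
  lens <- reads$end - reads$pos + 1L
  len <- lens[match(mismatches$id, reads$id)]
  if (anyNA(len)) stop("mismatch references an unknown read")
  chromLens <- setNames(Biostrings::width(genome), names(genome))
  if (any(mismatches$pos < 1L |
          mismatches$pos > chromLens[mismatches$chrom])) {
    stop("mismatch outside reference bounds")
  }
  nearEnd <- mismatches$read_pos <= endDist | mismatches$read_pos > len - endDist
  nearSplice <- rep(FALSE, nrow(mismatches))
  if (!is.null(exons)) {
    df <- as.data.frame(exons)
    for (i in seq_len(nrow(df))) {
      onChrom <- mismatches$chrom == as.character(df$seqnames[i])
      d <- pmin(mismatches$pos - df$start[i], df$end[i] - mismatches$pos) + 1L
      nearSplice <- nearSplice |
        (onChrom & mismatches$pos >= df$start[i] & mismatches$pos <= df$end[i] &
           d <= spliceDist)
    }
  }
  hp <- homopolymerRuns(genome, hpMinRun)
  nearHp <- maskSites(mismatches$chrom, mismatches$pos, flank1(hp))
  reason <- rep("ok", nrow(mismatches))
  fail <- function(cond, code) reason <<- ifelse(reason == "ok" & cond, code, reason)
  fail(nearEnd, "read_end")
  fail(nearSplice, "splice")
  fail(nearHp, "homopolymer")
  fail(mismatches$qual < qualMin, "base_quality")
  data.table(keep = reason == "ok", reason = reason)
}

#' Aggregate filtered mismatch events into site evidence
#'
#' @param events data.table of kept mismatches with columns chrom, pos, ref,
#'   obs, strand (alignment strand of the carrying read) and sample.
#' @param coverage data.table of per-position coverage: sample, chrom, pos,
#'   C (total covering reads), C_plus (plus-strand covering reads).
#' @return data.table of per (sample, site, substitution) evidence: E, C,
#'   E_plus, C_plus. Distinct substitution types at one position yield
#'   separate rows sharing C.
#' @export
aggregateEvidence <- function(events, coverage) {
  ev <- as.data.table(events)[, .(
    E = .N, E_plus = sum(strand == "+")),
    by = .(sample, chrom, pos, ref, obs)]
  out <- merge(ev, as.data.table(coverage), by = c("sample", "chrom", "pos"))
  if (any(out$E > out$C) || any(out$E_plus > out$C_plus)) {
    stop("inconsistent input: mismatch-supporting reads exceed coverage")
  }
  out[, type := paste0(ref, ">", obs)]
  setcolorder(out, c("sample", "chrom", "pos", "ref", "obs", "type",
                     "E", "C", "E_plus", "C_plus"))
  setorder(out, sample, chrom, pos, type)
  out[]
}

#' Per-position pileup coverage of a read set
#'
#' @param reads data.table as returned by [readSam()] (after any read-level
#'   filtering).
#' @param sample sample label attached to the output.
#' @return data.table: sample, chrom, pos, C, C_plus.
#' @export
samPileup <- function(reads, sample = "sample1") {
  long <- reads[, .(pos = seq(pos, end)), by = .(id, chrom, strand)]
  out <- long[, .(C = .N, C_plus = sum(strand == "+")), by = .(chrom, pos)]
  out[, sample := sample]
  setcolorder(out, c("sample", "chrom", "pos", "C", "C_plus"))
  setorder(out, chrom, pos)
  out[]
}

#' Emit a simulated sample as minimal SAM records
#'
#' For each gene exon of the reference, emits the sample's per-gene depth as
#' full-exon-length proper-pair reads (alternating alignment strand) and
#' plants the sample's evidence mismatches on distinct reads (round-robin),
#' so that an unfiltered pileup of the emitted reads reproduces the
#' count-table evidence exactly. Intended for read-level testing on small
#' configurations without antisense intervals.
#'
#' @param cohort an \linkS4class{EditingCohort}.
#' @param sample sample id to emit.
#' @param file optional output path; when NULL the SAM lines are returned.
#' @return Invisibly, the SAM lines.
#' @export
writeCohortSam <- function(cohort, sample, file = NULL) {
  ref <- cohort@reference
  if (length(ref@antisense)) {
    stop("SAM emission supports configurations without antisense intervals")
  }
  cov <- cohort@coverage[sample, on = "sample"]
  ev <- cohort@evidence[sample, on = "sample", nomatch = 0L]
  exDf <- as.data.frame(ref@exons)
  lines <- character(0)
  rid <- 0L
  planted <- character(0)   # positions in a dual-strand overlap belong to
                            # two exons; each mismatch row is planted once
  for (i in seq_len(nrow(exDf))) {
    D <- cov[gene_id == exDf$gene_id[i], depth]
    if (!length(D) || D == 0L) next
    ch <- as.character(exDf$seqnames[i])
    st <- exDf$start[i]; en <- exDf$end[i]
    refseq <- strsplit(as.character(
      Biostrings::subseq(ref@genome[[ch]], st, en)), "")[[1]]
    readSeqs <- matrix(rep(refseq, D), nrow = D, byrow = TRUE)
    here <- ev[chrom == ch & pos >= st & pos <= en]
    nextRead <- 1L
    for (j in seq_len(nrow(here))) {
      col <- here$pos[j] - st + 1L
      for (b in BASES) {
        k <- here[[paste0(b, "_plus")]][j] + here[[paste0(b, "_minus")]][j]
        if (b == here$ref[j] || k == 0L) next
        tag <- paste(here$pos[j], b)
        if (tag %in% planted) next
        planted <- c(planted, tag)
        if (k > D) stop("evidence exceeds per-gene depth; cannot emit reads")
        rows <- ((nextRead - 1L + seq_len(k) - 1L) %% D) + 1L
        readSeqs[rows, col] <- b
        nextRead <- nextRead + k
      }
    }
    flags <- ifelse(seq_len(D) %% 2L == 0L,
                    FLAG_PROPER + FLAG_REVERSE, FLAG_PROPER)
    qual <- strrep(rawToChar(as.raw(40L + 33L)), en - st + 1L)
    lines <- c(lines, sprintf(
      "r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
      rid + seq_len(D), flags, ch, st, en - st + 1L,
      apply(readSeqs, 1L, paste, collapse = ""), qual))
    rid <- rid + D
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref@genome),
                      Biostrings::width(ref@genome)))
  out <- c(header, lines)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
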