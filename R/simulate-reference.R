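# Synthetic reference generator: genome, transcript models, variant and
# repeat masks, paralog duplications, antisense intervals, and the planted
# site-level events later realized into read evidence by simulateCohort().
#
# Coordinates: 1-based inclusive internally for site tables (VCF-like);
# GRanges intervals are 1-based closed as usual; BED export converts.

#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom Biostrings DNAStringSet DNAString subseq replaceLetterAt
#'   width writeXStringSet readDNAStringSet GENETIC_CODE reverseComplement
NULL

INTRON_LEN <- 150L
GENE_GAP <- 300L

#' Generate a synthetic reference bundle
#'
#' Builds a random genome and plants, deterministically under the config
#' seed: multi-exon protein-coding genes (all exonic sequence is CDS, length
#' forced to a multiple of 3), a dual-strand overlapping gene pair,
#' homopolymer runs at known positions, paralog duplications at configured
#' identity, repeat (Alu/rDNA) intervals, common SNPs and indels, rare
#' reference-allele SNPs, antisense transcription intervals, and the planted
#' site-level events (editing sites, rare SNPs, antisense editing sites)
#' whose read-level consequences [simulateCohort()] draws.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{ReferenceBundle}.
#' @examples
#' ref <- generateReference(simConfig(seed = 7, nDonors = 2,
#'   editingLevels = c(0.1, 0.3), snpFreqs = 0.05, snpHom = FALSE))
#' ref
#' @export
generateReference <- function(config) {
  validObject(config)
  set.seed(deriveSeed(config@seed, 11L))

  chroms <- paste0("chr", seq_len(config@nChromosomes))
  geneSpan <- config@exonsPerGene * config@exonLength +
    (config@exonsPerGene - 1L) * INTRON_LEN

  # feasibility: genes + dual-strand pair + paralog copies + repeats must fit
  perChrom <- ceiling(config@nGenes / config@nChromosomes)
  needed <- 1000L + perChrom * (geneSpan + GENE_GAP) + 2L * 400L +
    sum(config@paralogLength) + 2L * (400L + GENE_GAP)
  if (needed > config@chromLength) {
    stop("infeasible config: ", needed, " bp required per chromosome but ",
         "chromLength is ", config@chromLength)
  }

  genome <- DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(BASES, config@chromLength, replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- chroms

  # ---- gene placement ------------------------------------------------------
  exonList <- list()
  cursor <- setNames(rep(500L, length(chroms)), chroms)
  geneChrom <- chroms[((seq_len(config@nGenes) - 1L) %% length(chroms)) + 1L]
  cdsLen <- config@exonsPerGene * config@exonLength
  lastExtra <- (3L - cdsLen %% 3L) %% 3L   # pad last exon to a codon multiple

  for (g in seq_len(config@nGenes)) {
    ch <- geneChrom[g]
    st <- cursor[ch]
    exStarts <- st + (seq_len(config@exonsPerGene) - 1L) *
      (config@exonLength + INTRON_LEN)
    exWidths <- rep(config@exonLength, config@exonsPerGene)
    exWidths[config@exonsPerGene] <- exWidths[config@exonsPerGene] + lastExtra
    exonList[[g]] <- data.frame(
      chrom = ch, start = exStarts, end = exStarts + exWidths - 1L,
      strand = if (g %% 2L) "+" else "-",
      gene_id = sprintf("gene%02d", g),
      exon_rank = seq_len(config@exonsPerGene))
    cursor[ch] <- max(exStarts + exWidths - 1L) + GENE_GAP
  }

  # dual-strand overlapping pair (opposite strands, 60 bp overlap)
  ch <- chroms[1L]
  st <- cursor[ch]
  ovA <- data.frame(chrom = ch, start = st, end = st + 149L, strand = "+",
                    gene_id = "geneDSa", exon_rank = 1L)
  ovB <- data.frame(chrom = ch, start = st + 90L, end = st + 239L, strand = "-",
                    gene_id = "geneDSb", exon_rank = 1L)
  cursor[ch] <- st + 240L + GENE_GAP
  exonDf <- do.call(rbind, c(exonList, list(ovA, ovB)))
  exons <- GRanges(exonDf$chrom, IRanges(exonDf$start, exonDf$end),
                   strand = exonDf$strand,
                   gene_id = exonDf$gene_id, exon_rank = exonDf$exon_rank)
  dualStrand <- GRanges(ch, IRanges(st + 90L, st + 149L))

  # ---- repeats (Alu, rDNA) in intergenic space -----------------------------
  repeats <- GRanges(
    c(chroms[1L], chroms[length(chroms)]),
    IRanges(c(cursor[chroms[1L]],
              config@chromLength - 900L),
            width = 400L),
    class = c("Alu", "rDNA"))
  cursor[chroms[1L]] <- cursor[chroms[1L]] + 400L + GENE_GAP

  # ---- homopolymer runs planted inside gene bodies -------------------------
  hp <- list()
  hpGenes <- sprintf("gene%02d", seq(1L, config@nGenes, by = 4L))
  for (gid in hpGenes) {
    ex <- exonDf[exonDf$gene_id == gid & exonDf$exon_rank == 1L, ]
    pos <- ex$start + 30L
    base <- sample(BASES, 1L)
    genome[[ex$chrom]] <- replaceAt(genome[[ex$chrom]], pos, strrep(base, 5L))
    hp[[gid]] <- data.frame(chrom = ex$chrom, start = pos, end = pos + 4L)
  }
  hp <- do.call(rbind, hp)
  homopolymers <- GRanges(hp$chrom, IRanges(hp$start, hp$end))

  # ---- paralog duplications ------------------------------------------------
  paralogs <- list(); paralogDiffs <- list()
  srcGenes <- sprintf("gene%02d", seq(2L, by = 3L,
                                      length.out = length(config@paralogLength)))
  for (i in seq_along(config@paralogLength)) {
    len <- config@paralogLength[i]
    ex <- exonDf[exonDf$gene_id == srcGenes[i] & exonDf$exon_rank == 1L, ]
    if (len > ex$end - ex$start + 1L) {
      stop("infeasible config: paralog length exceeds exon length")
    }
    srcStart <- ex$start
    srcSeq <- as.character(subseq(genome[[ex$chrom]], srcStart, srcStart + len - 1L))
    nMut <- round((1 - config@paralogIdentity[i]) * len)
    mutAt <- sort(sample.int(len, nMut))
    copyChars <- strsplit(srcSeq, "")[[1]]
    newBase <- vapply(copyChars[mutAt],
                      function(b) sample(setdiff(BASES, b), 1L), character(1))
    srcBase <- copyChars[mutAt]
    copyChars[mutAt] <- newBase
    dstChrom <- chroms[length(chroms)]
    dstStart <- cursor[dstChrom]
    cursor[dstChrom] <- dstStart + len + GENE_GAP
    genome[[dstChrom]] <- replaceAt(genome[[dstChrom]], dstStart,
                                    paste(copyChars, collapse = ""))
    paralogs[[i]] <- data.frame(
      paralog = i, src_chrom = ex$chrom, src_start = srcStart,
      src_end = srcStart + len - 1L, dst_chrom = dstChrom,
      dst_start = dstStart, dst_end = dstStart + len - 1L,
      identity = 1 - nMut / len,
      mis_fraction = config@paralogMisFraction[i],
      src_gene = srcGenes[i])
    paralogDiffs[[i]] <- data.frame(
      paralog = i, chrom = ex$chrom,
      src_pos = srcStart + mutAt - 1L,
      dst_chrom = dstChrom, dst_pos = dstStart + mutAt - 1L,
      src_base = srcBase, dst_base = unname(newBase))
  }
  paralogs <- data.table::rbindlist(paralogs)
  paralogDiffs <- data.table::rbindlist(paralogDiffs)

  # ---- position bookkeeping for event placement ----------------------------
  # blocked for any planted site: repeats, the dual-strand overlap, every
  # homopolymer run (natural or planted) with 1 bp flanks, splice-proximal
  # positions, and the paralog source genes (their artifact clusters must not
  # chain with genuine events)
  cdsTab <- cdsPositions(genome, exons)
  allRuns <- homopolymerRuns(genome, 5L)
  blockedGr <- GenomicRanges::reduce(
    suppressWarnings(c(repeats, dualStrand, flank1(allRuns))),
    ignore.strand = TRUE)
  cdsTab <- cdsTab[!overlapsAny1(cdsTab, blockedGr) &
                     cdsTab$splice_dist > 4L &
                     !cdsTab$gene_id %in% c("geneDSa", "geneDSb", srcGenes), ]

  used <- character(0)
  usedEvents <- data.frame(gene_id = character(0), mrna_pos = integer(0))
  takePositions <- function(pool, n, spacing = 0L) {
    if (n == 0L) return(pool[integer(0), ])
    pool <- pool[!paste(pool$chrom, pool$pos) %in% used, ]
    pool <- pool[sample.int(nrow(pool)), ]
    if (spacing == 0L) {
      if (nrow(pool) < n) stop("infeasible config: not enough plantable positions")
      sel <- pool[seq_len(n), ]
    } else {
      # greedy selection keeping planted events of any type at least
      # `spacing` bp apart in mRNA coordinates (emulates the genomic
      # sparsity of real events relative to the cluster-joining distance)
      take <- integer(0)
      for (i in seq_len(nrow(pool))) {
        g <- pool$gene_id[i]; mp <- pool$mrna_pos[i]
        near <- usedEvents$gene_id == g & abs(usedEvents$mrna_pos - mp) < spacing
        if (any(near)) next
        take <- c(take, i)
        usedEvents <<- rbind(usedEvents,
                             data.frame(gene_id = g, mrna_pos = mp))
        if (length(take) == n) break
      }
      if (length(take) < n) stop("infeasible config: not enough plantable positions")
      sel <- pool[take, ]
    }
    used <<- c(used, paste(sel$chrom, sel$pos))
    sel
  }

  # antisense transcription intervals are fixed within their host genes;
  # reserve them (with indel-flank padding) before placing mask fodder
  asGenes <- sprintf("gene%02d", seq(3L, by = 4L,
                                     length.out = length(config@antisenseRatio)))
  asList <- lapply(seq_along(config@antisenseRatio), function(i) {
    ex <- exonDf[exonDf$gene_id == asGenes[i] & exonDf$exon_rank == 1L, ]
    data.frame(chrom = ex$chrom, start = ex$start + 60L, end = ex$start + 179L,
               ratio = config@antisenseRatio[i],
               level = config@antisenseLevel[i])
  })
  asDf <- do.call(rbind, asList)
  antisense <- if (!is.null(asDf)) {
    GRanges(asDf$chrom, IRanges(asDf$start, asDf$end),
            ratio = asDf$ratio, level = asDf$level)
  } else GRanges()
  fodderPool <- if (length(antisense)) {
    pad <- GRanges(seqnames(antisense),
                   IRanges(pmax(start(antisense) - 50L, 1L),
                           end(antisense) + 50L))
    cdsTab[!overlapsAny1(cdsTab, pad), ]
  } else cdsTab

  # mask fodder, so indel flanks can be blocked for event placement
  commonSel <- takePositions(fodderPool, config@nCommonSnps)
  rareRefSel <- takePositions(fodderPool, 2L)
  snps <- data.table::data.table(
    chrom = c(commonSel$chrom, rareRefSel$chrom),
    pos = c(commonSel$pos, rareRefSel$pos),
    ref = c(commonSel$ref, rareRefSel$ref),
    alt = vapply(c(commonSel$ref, rareRefSel$ref),
                 function(b) sample(setdiff(BASES, b), 1L), character(1)),
    freq = c(runif(config@nCommonSnps, 0.05, 0.5), rep(0.995, 2L)),
    class = c(rep("common", config@nCommonSnps), rep("rare_ref", 2L)))
  indelSel <- takePositions(fodderPool, config@nCommonIndels)
  indels <- data.table::data.table(chrom = indelSel$chrom, pos = indelSel$pos)
  maskGr <- suppressWarnings(
    c(GRanges(snps$chrom, IRanges(snps$pos, snps$pos)),
      GRanges(indels$chrom, IRanges(pmax(indels$pos - 50L, 1L),
                                    indels$pos + 50L))))
  cdsTab <- cdsTab[!overlapsAny1(cdsTab, maskGr), ]

  # antisense editing sites: sense-strand thymines within each interval
  asEvents <- list()
  for (i in seq_along(config@antisenseRatio)) {
    pool <- cdsTab[cdsTab$chrom == asDf$chrom[i] &
                     cdsTab$pos >= asDf$start[i] &
                     cdsTab$pos <= asDf$end[i] & cdsTab$ref == "T", ]
    sel <- takePositions(pool, config@antisenseSites[i])
    # register the interval against later events of other types, so no
    # mixed-type cluster can chain through it
    usedEvents <- rbind(usedEvents,
                        data.frame(gene_id = sel$gene_id,
                                   mrna_pos = sel$mrna_pos))
    asEvents[[i]] <- data.frame(
      class = "antisense_editing", chrom = sel$chrom, pos = sel$pos,
      strand = "-", ref = sel$ref, alt = "C", gene_id = sel$gene_id,
      level_mean = config@antisenseLevel[i], dispersion = 0.02,
      freq = NA_real_, hom = NA, interval = i)
  }

  # keep further events out of antisense intervals so their observed levels
  # are not diluted by antisense-origin coverage
  cdsTab <- cdsTab[!overlapsAny1(cdsTab, antisense), ]

  # editing sites: sense-strand adenosines
  senseA <- cdsTab[(cdsTab$strand == "+" & cdsTab$ref == "A") |
                     (cdsTab$strand == "-" & cdsTab$ref == "T"), ]
  nEd <- length(config@editingLevels)
  edSel <- takePositions(senseA, nEd, spacing = 110L)
  edEvents <- if (nEd > 0) data.frame(
    class = "editing", chrom = edSel$chrom, pos = edSel$pos,
    strand = edSel$strand, ref = edSel$ref,
    alt = ifelse(edSel$strand == "+", "G", "C"),
    gene_id = edSel$gene_id,
    level_mean = config@editingLevels,
    dispersion = config@editingDispersion,
    freq = NA_real_, hom = NA, interval = NA_integer_) else NULL

  # rare SNPs (absent from the common-variant mask; caught by model/WES)
  nSnp <- length(config@snpFreqs)
  snpEvents <- NULL
  if (nSnp > 0) {
    snpSel <- takePositions(cdsTab, nSnp, spacing = 110L)
    alt <- vapply(snpSel$ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))
    snpEvents <- data.frame(
      class = ifelse(config@snpHom, "hom_snp", "het_snp"),
      chrom = snpSel$chrom, pos = snpSel$pos, strand = snpSel$strand,
      ref = snpSel$ref, alt = unname(alt), gene_id = snpSel$gene_id,
      level_mean = NA_real_, dispersion = NA_real_,
      freq = config@snpFreqs, hom = config@snpHom, interval = NA_integer_)
  }

  events <- data.table::rbindlist(
    c(list(edEvents), asEvents, list(snpEvents)), use.names = TRUE)
  events[, site_id := sprintf("site%04d", seq_len(nrow(events)))]
  data.table::setcolorder(events, "site_id")

  new("ReferenceBundle",
      genome = genome, exons = exons, snps = snps, indels = indels,
      repeats = repeats, dualStrand = dualStrand, paralogs = paralogs,
      paralogDiffs = paralogDiffs, homopolymers = homopolymers,
      antisense = antisense, events = events, config = config)
}

# replace a substring of a DNAString starting at `at` (1-based)
replaceAt <- function(dna, at, what) {
  Biostrings::replaceLetterAt(
    dna, at + seq_len(nchar(what)) - 1L,
    Biostrings::DNAString(what))
}

# one-bp flanks included (homopolymer adjacency rule)
flank1 <- function(gr) {
  GRanges(seqnames(gr), IRanges(pmax(start(gr) - 1L, 1L), end(gr) + 1L))
}

overlapsAny1 <- function(tab, gr) {
  q <- GRanges(tab$chrom, IRanges(tab$pos, tab$pos))
  suppressWarnings(IRanges::overlapsAny(q, gr, ignore.strand = TRUE))
}

#' Per-base CDS position table
#'
#' Expands the exon annotation into one row per coding position with the
#' plus-strand reference base, mRNA coordinate (1-based along the spliced
#' transcript in gene orientation), codon index/offset, and the distance to
#' the nearest exon boundary (splice-proximity filtering).
#'
#' @param genome a \code{DNAStringSet}.
#' @param exons a \code{GRanges} of coding exons with \code{gene_id} and
#'   \code{exon_rank}.
#' @return A data.frame with columns chrom, pos, ref, gene_id, strand,
#'   mrna_pos, splice_dist.
#' @export
cdsPositions <- function(genome, exons) {
  df <- as.data.frame(exons)
  df <- df[order(df$gene_id, df$exon_rank), ]
  out <- lapply(seq_len(nrow(df)), function(i) {
    pos <- df$start[i]:df$end[i]
    data.frame(chrom = as.character(df$seqnames[i]), pos = pos,
               gene_id = df$gene_id[i], strand = as.character(df$strand[i]),
               exon_rank = df$exon_rank[i],
               splice_dist = pmin(pos - df$start[i], df$end[i] - pos) + 1L)
  })
  tab <- do.call(rbind, out)
  tab$ref <- character(nrow(tab))
  for (ch in unique(tab$chrom)) {
    idx <- tab$chrom == ch
    tab$ref[idx] <- strsplit(as.character(genome[[ch]]), "")[[1]][tab$pos[idx]]
  }
  # mRNA coordinate: genomic order within gene for '+', reversed for '-'
  tab <- tab[order(tab$gene_id, tab$pos), ]
  tab$mrna_pos <- stats::ave(seq_len(nrow(tab)), tab$gene_id,
                             FUN = seq_along)
  neg <- tab$strand == "-"
  if (any(neg)) {
    tot <- stats::ave(rep(1L, nrow(tab)), tab$gene_id, FUN = sum)
    tab$mrna_pos[neg] <- tot[neg] - tab$mrna_pos[neg] + 1L
  }
  tab
}
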