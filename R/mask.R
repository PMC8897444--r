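# Annotation-derived exclusion masks: common SNPs, 50 bp windows around
# common indels, rare reference-allele SNPs, rDNA and Alu repeats, and
# dual-strand CDS overlap.

#' Build the annotation exclusion mask
#'
#' Assembles the named interval collections excluded from site calling:
#' common SNP positions, 50 bp windows around common insertions/deletions,
#' positions where the reference genome carries a rare allele (reference
#' allele frequency below \code{rareRefFreq}), rDNA and Alu repeat intervals,
#' and regions where both strands are annotated as coding exons.
#'
#' @param ref a \linkS4class{ReferenceBundle}, or \code{NULL} when the
#'   component tables are given directly.
#' @param snps data.frame with chrom, pos, ref, alt, freq (alternative-allele
#'   frequency) and optionally class; overrides the bundle's table.
#' @param indels data.frame with chrom, pos.
#' @param repeats \code{GRanges} with a \code{class} column ("Alu", "rDNA").
#' @param dualStrand \code{GRanges} of dual-strand CDS overlap.
#' @param commonFreq alternative-allele frequency at or above which a SNP is
#'   "common" (default 0.01).
#' @param rareRefFreq reference allele frequency below which the reference is
#'   deemed to carry the rare allele (default 0.01), i.e. alternative-allele
#'   frequency above \code{1 - rareRefFreq}.
#' @param indelPad bp padding around indels (default 50).
#' @return A \code{GRanges} with a \code{collection} metadata column;
#'   intervals are merged within each collection.
#' @examples
#' ref <- generateReference(simConfig(seed = 5, nDonors = 2))
#' mask <- buildMask(ref)
#' table(mask$collection)
#' @export
buildMask <- function(ref = NULL, snps = NULL, indels = NULL, repeats = NULL,
                      dualStrand = NULL, commonFreq = 0.01,
                      rareRefFreq = 0.01, indelPad = 50L) {
  snps <- snps %||% if (!is.null(ref)) ref@snps else NULL
  indels <- indels %||% if (!is.null(ref)) ref@indels else NULL
  repeats <- repeats %||% if (!is.null(ref)) ref@repeats else GRanges()
  dualStrand <- dualStrand %||% if (!is.null(ref)) ref@dualStrand else GRanges()

  parts <- list()
  if (!is.null(snps) && nrow(snps)) {
    common <- snps[snps$freq >= commonFreq & snps$freq <= 1 - rareRefFreq, ]
    if (nrow(common)) {
      parts$common_snp <- GRanges(common$chrom, IRanges(common$pos, common$pos))
    }
    rareRef <- snps[snps$freq > 1 - rareRefFreq, ]
    if (nrow(rareRef)) {
      parts$rare_ref_snp <- GRanges(rareRef$chrom,
                                    IRanges(rareRef$pos, rareRef$pos))
    }
  }
  if (!is.null(indels) && nrow(indels)) {
    if (any(indels$pos <= 0)) stop("malformed indel table: non-positive position")
    parts$indel_flank <- GRanges(
      indels$chrom,
      IRanges(pmax(indels$pos - indelPad, 1L), indels$pos + indelPad))
  }
  for (cl in unique(as.character(mcols(repeats)$class %||% character(0)))) {
    parts[[cl]] <- repeats[mcols(repeats)$class == cl]
  }
  if (length(dualStrand)) parts$dual_strand <- dualStrand

  if (!length(parts)) {
    return(GRanges(collection = character(0)))
  }
  merged <- lapply(names(parts), function(nm) {
    gr <- GenomicRanges::reduce(parts[[nm]], ignore.strand = TRUE)
    if (any(end(gr) < start(gr))) stop("malformed interval: end < start")
    mcols(gr)$collection <- nm
    gr
  })
  out <- suppressWarnings(do.call(c, unname(merged)))
  GenomicRanges::strand(out) <- "*"
  sort(out, ignore.strand = TRUE)
}

#' Test sites against a mask
#'
#' A site is maskable iff it intersects any collection. Masking is
#' idempotent: applying the induced filter twice equals applying it once.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param mask a \code{GRanges} from [buildMask()].
#' @return Logical vector: TRUE where the site is masked.
#' @export
maskSites <- function(chrom, pos, mask) {
  if (!length(mask)) return(rep(FALSE, length(pos)))
  q <- GRanges(chrom, IRanges(pos, pos))
  suppressWarnings(IRanges::overlapsAny(q, mask, ignore.strand = TRUE))
}

#' Site-level sequence filters
#'
#' Marks CDS positions excluded by the sequence-context rules of mismatch
#' calling: within \code{spliceDist} bp of an exon boundary (exonic side) or
#' inside / immediately flanking (1 bp) a homopolymer run of
#' \code{hpMinRun} bp or more.
#'
#' @param ref a \linkS4class{ReferenceBundle} (or any object with genome and
#'   exon accessors).
#' @param spliceDist exonic distance to a splice site below which positions
#'   are excluded (default 4).
#' @param hpMinRun minimal homopolymer run length (default 5).
#' @return A data.table keyed by (chrom, pos) with logical columns
#'   \code{near_splice} and \code{near_homopolymer} for every CDS position.
#' @export
positionFilters <- function(ref, spliceDist = 4L, hpMinRun = 5L) {
  tab <- as.data.table(cdsPositions(ref@genome, ref@exons))
  tab[, near_splice := splice_dist <= spliceDist]
  hp <- homopolymerRuns(ref@genome, hpMinRun)
  tab[, near_homopolymer := maskSites(chrom, pos, flank1(hp))]
  out <- tab[, .(near_splice = any(near_splice),
                 near_homopolymer = any(near_homopolymer)),
             by = .(chrom, pos)]
  setkey(out, chrom, pos)
  out[]
}

#' Homopolymer runs of a genome
#'
#' @param genome a \code{DNAStringSet}.
#' @param minRun minimal run length (default 5).
#' @return A \code{GRanges} of maximal single-base runs of length
#'   \code{>= minRun}.
#' @export
homopolymerRuns <- function(genome, minRun = 5L) {
  out <- lapply(names(genome), function(ch) {
    r <- rle(strsplit(as.character(genome[[ch]]), "")[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= minRun
    if (!any(keep)) return(NULL)
    GRanges(ch, IRanges(ends[keep] - r$lengths[keep] + 1L, ends[keep]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(GRanges())
  suppressWarnings(do.call(c, out))
}
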