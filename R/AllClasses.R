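#' @import methods
#' @importFrom stats pbinom rbinom rpois rbeta runif var sd quantile
#'   p.adjust fisher.test t.test wilcox.test complete.cases setNames
#' @importFrom utils head read.table write.table
NULL

#' Statistical model parameters for the three-hypothesis site test
#'
#' Holds the constants of the per-donor, per-site binomial hypothesis tests:
#' the maximal base-calling error probability, the expected alternative-allele
#' fraction and prior probability of a rare heterozygous SNP, the expected
#' fraction and prior of a rare homozygous SNP, and the rule used to choose a
#' single p-value per donor before Fisher combination.
#'
#' @slot eError maximal probability of a base-calling sequencing error
#'   (default \code{1e-3}, the error rate implied by Phred quality 30).
#' @slot eHetero expected alternative-allele fraction of a heterozygous SNP
#'   (default 0.5).
#' @slot pHetero prior probability of a rare heterozygous SNP at a given CDS
#'   position (default \code{1e-4}, a conservative round-up of the
#'   rare-SNP-density estimate of about \code{3.06e-5}).
#' @slot eHomo expected alternative-allele fraction of a homozygous SNP
#'   (default 1).
#' @slot pHomo prior probability of a rare homozygous SNP (default
#'   \code{1e-8 = pHetero^2}).
#' @slot combiner how the per-donor p-value is chosen among the three
#'   hypothesis p-values: \code{"max"} (default; the hardest-to-reject
#'   alternative must still be rejected) or \code{"literal_min"}.
#'
#' @seealso [modelParams()], [pError()], [siteScore()]
#' @export
setClass("ModelParams", representation(
  eError = "numeric", eHetero = "numeric", pHetero = "numeric",
  eHomo = "numeric", pHomo = "numeric", combiner = "character"
))

setValidity("ModelParams", function(object) {
  p <- c(object@eError, object@eHetero, object@pHetero, object@eHomo, object@pHomo)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    return("all model probabilities must lie in [0, 1]")
  }
  if (!object@combiner %in% c("max", "literal_min")) {
    return("combiner must be 'max' or 'literal_min'")
  }
  TRUE
})

#' Construct model parameters
#'
#' @param eError,eHetero,pHetero,eHomo,pHomo,combiner see
#'   \linkS4class{ModelParams}.
#' @return A \linkS4class{ModelParams} object.
#' @examples
#' modelParams()
#' modelParams(combiner = "literal_min")
#' @export
modelParams <- function(eError = 1e-3, eHetero = 0.5, pHetero = 1e-4,
                        eHomo = 1, pHomo = 1e-8, combiner = "max") {
  new("ModelParams", eError = eError, eHetero = eHetero, pHetero = pHetero,
      eHomo = eHomo, pHomo = pHomo, combiner = combiner)
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat(sprintf("  E_error: %g   E_hetero: %g (prior %g)   E_homo: %g (prior %g)\n",
              object@eError, object@eHetero, object@pHetero,
              object@eHomo, object@pHomo))
  cat(sprintf("  per-donor combiner: %s\n", object@combiner))
})

#' Simulation configuration for the synthetic cohort generator
#'
#' Fully specifies a synthetic genome, transcript annotation and
#' multi-donor/multi-tissue read-evidence cohort with planted editing sites,
#' SNPs, paralog-misalignment artifacts, antisense transcription and
#' sequencing error, so that each pipeline stage can be tested against known
#' ground truth.
#'
#' @slot seed integer; identical seed implies byte-identical outputs.
#' @slot nChromosomes,chromLength genome shape (bp per chromosome).
#' @slot nGenes,exonsPerGene,exonLength transcript models; total CDS length
#'   per gene is forced to a multiple of 3.
#' @slot nDonors,tissues cohort shape; each donor contributes one sample per
#'   tissue.
#' @slot depthMean mean per-gene read depth per sample (Poisson).
#' @slot errorRate base-calling error probability (default \code{1e-3}).
#' @slot editingLevels mean editing level of each planted editing site.
#' @slot editingDispersion per-site dispersion of the donor-level Beta
#'   distribution (variance = dispersion * m * (1 - m)); 0 means a fixed level.
#' @slot editingTissueLevels optional sites x tissues matrix of mean levels
#'   overriding \code{editingLevels} per tissue.
#' @slot snpFreqs population alternative-allele frequencies of planted rare
#'   SNPs (each is guaranteed at least one carrier).
#' @slot snpHom logical; for each planted SNP, whether carriers are homozygous.
#' @slot nCommonSnps,nCommonIndels counts of planted common (maskable)
#'   variants.
#' @slot paralogLength,paralogIdentity,paralogMisFraction one entry per
#'   planted paralog duplication: copy length, sequence identity of the copy,
#'   and the fraction of reads at the source locus that originate from the
#'   copy (count-level misalignment model).
#' @slot antisenseRatio,antisenseLevel,antisenseSites one entry per planted
#'   antisense transcription interval: antisense/sense expression ratio, mean
#'   editing level of antisense adenosines, number of edited antisense sites.
#' @slot stranded logical; if TRUE the library preserves transcript strand of
#'   origin and evidence rows carry an origin strand.
#' @slot wesDepth mean per-gene whole-exome depth per donor.
#' @slot wesErrorRate residual DNA mismatch rate in WES pileups (default
#'   \code{1e-4}; post-quality-filter DNA mismatch rates sit well below the
#'   q30 ceiling).
#'
#' @seealso [simConfig()], [generateReference()], [simulateCohort()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromosomes = "integer", chromLength = "integer",
  nGenes = "integer", exonsPerGene = "integer", exonLength = "integer",
  nDonors = "integer", tissues = "character",
  depthMean = "numeric", errorRate = "numeric",
  editingLevels = "numeric", editingDispersion = "numeric",
  editingTissueLevels = "ANY",
  snpFreqs = "numeric", snpHom = "logical",
  nCommonSnps = "integer", nCommonIndels = "integer",
  paralogLength = "integer", paralogIdentity = "numeric",
  paralogMisFraction = "numeric",
  antisenseRatio = "numeric", antisenseLevel = "numeric",
  antisenseSites = "integer",
  stranded = "logical",
  wesDepth = "numeric", wesErrorRate = "numeric"
))

setValidity("SimConfig", function(object) {
  probs <- c(object@errorRate, object@editingLevels, object@editingDispersion,
             object@snpFreqs, object@paralogIdentity, object@paralogMisFraction,
             object@antisenseLevel, object@wesErrorRate)
  if (length(probs) && (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))) {
    return("all probabilities must lie in [0, 1]")
  }
  if (object@depthMean < 0 || object@wesDepth < 0) return("depth must be >= 0")
  if (object@nChromosomes < 1L || object@chromLength < 1000L) {
    return("need at least one chromosome of >= 1000 bp")
  }
  if (length(object@snpHom) != length(object@snpFreqs)) {
    return("snpHom must match snpFreqs in length")
  }
  if (length(object@paralogIdentity) != length(object@paralogLength) ||
      length(object@paralogMisFraction) != length(object@paralogLength)) {
    return("paralog spec vectors must share one length")
  }
  if (length(object@antisenseLevel) != length(object@antisenseRatio) ||
      length(object@antisenseSites) != length(object@antisenseRatio)) {
    return("antisense spec vectors must share one length")
  }
  if (!is.null(object@editingTissueLevels)) {
    m <- object@editingTissueLevels
    if (!is.matrix(m) || nrow(m) != length(object@editingLevels) ||
        ncol(m) != length(object@tissues)) {
      return("editingTissueLevels must be a sites x tissues matrix")
    }
  }
  TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the packaged demonstration cohort: 50 donors across 5
#' tissues at mean depth 50, sequencing error 1e-3, editing sites spanning
#' mean levels 1--30\% with moderate donor-to-donor dispersion, rare
#' heterozygous and homozygous SNPs, two paralog duplications, and antisense
#' transcription intervals.
#'
#' @param seed integer random seed.
#' @param nChromosomes,chromLength,nGenes,exonsPerGene,exonLength genome and
#'   annotation shape.
#' @param nDonors,tissues,depthMean,errorRate cohort shape and noise.
#' @param editingLevels,editingDispersion,editingTissueLevels planted editing.
#' @param snpFreqs,snpHom,nCommonSnps,nCommonIndels planted genomic variants.
#' @param paralogLength,paralogIdentity,paralogMisFraction planted paralogs.
#' @param antisenseRatio,antisenseLevel,antisenseSites planted antisense
#'   transcription.
#' @param stranded library strandedness.
#' @param wesDepth,wesErrorRate matched whole-exome companion.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, nDonors = 4, tissues = c("brain", "liver"))
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 2L, chromLength = 80000L,
                      nGenes = 30L, exonsPerGene = 2L, exonLength = 300L,
                      nDonors = 50L,
                      tissues = c("brain", "cerebellum", "liver", "muscle", "artery"),
                      depthMean = 50, errorRate = 1e-3,
                      editingLevels = rep(c(0.01, 0.02, 0.05, 0.10, 0.20, 0.30), each = 10),
                      editingDispersion = 0.02,
                      editingTissueLevels = NULL,
                      snpFreqs = rep(c(0.02, 0.05), c(25, 15)),
                      snpHom = rep(c(FALSE, TRUE), c(30, 10)),
                      nCommonSnps = 10L, nCommonIndels = 4L,
                      paralogLength = c(300L, 300L),
                      paralogIdentity = c(0.96, 0.96),
                      paralogMisFraction = c(0.10, 0.10),
                      antisenseRatio = c(0.5, 0.5),
                      antisenseLevel = c(0.30, 0.30),
                      antisenseSites = c(6L, 6L),
                      stranded = FALSE,
                      wesDepth = 20, wesErrorRate = 1e-4) {
  editingDispersion <- rep_len(editingDispersion, length(editingLevels))
  new("SimConfig",
      seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes), chromLength = as.integer(chromLength),
      nGenes = as.integer(nGenes), exonsPerGene = as.integer(exonsPerGene),
      exonLength = as.integer(exonLength),
      nDonors = as.integer(nDonors), tissues = tissues,
      depthMean = depthMean, errorRate = errorRate,
      editingLevels = editingLevels, editingDispersion = editingDispersion,
      editingTissueLevels = editingTissueLevels,
      snpFreqs = snpFreqs, snpHom = snpHom,
      nCommonSnps = as.integer(nCommonSnps), nCommonIndels = as.integer(nCommonIndels),
      paralogLength = as.integer(paralogLength), paralogIdentity = paralogIdentity,
      paralogMisFraction = paralogMisFraction,
      antisenseRatio = antisenseRatio, antisenseLevel = antisenseLevel,
      antisenseSites = as.integer(antisenseSites),
      stranded = stranded, wesDepth = wesDepth, wesErrorRate = wesErrorRate)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp, %d genes x %d exon(s) x %d bp\n",
              object@nChromosomes, object@chromLength, object@nGenes,
              object@exonsPerGene, object@exonLength))
  cat(sprintf("  cohort: %d donors x %d tissues, depth %g, error rate %g, %s\n",
              object@nDonors, length(object@tissues), object@depthMean,
              object@errorRate,
              if (object@stranded) "stranded" else "unstranded"))
  cat(sprintf("  planted: %d editing sites, %d rare SNPs, %d paralogs, %d antisense intervals\n",
              length(object@editingLevels), length(object@snpFreqs),
              length(object@paralogLength), length(object@antisenseRatio)))
})

#' Synthetic reference genome and annotation bundle
#'
#' The output of [generateReference()]: genome sequences, transcript models
#' (every exon is coding), variant and repeat masks, planted paralog
#' duplications with their diff tables, planted homopolymers, antisense
#' intervals, and the planted functional events that [simulateCohort()] will
#' realize into read evidence.
#'
#' @slot genome a \code{DNAStringSet}, one entry per chromosome.
#' @slot exons a \code{GRanges} of coding exons with \code{gene_id} and
#'   \code{exon_rank} metadata; gene strand is the exon strand.
#' @slot snps data.table of planted SNPs (chrom, pos, ref, alt, freq, class),
#'   class in {common, rare_ref, rare_event}.
#' @slot indels data.table of common indel positions (chrom, pos).
#' @slot repeats \code{GRanges} of repeat intervals with a \code{class}
#'   column ("Alu", "rDNA").
#' @slot dualStrand \code{GRanges} of planted dual-strand CDS overlap.
#' @slot paralogs data.table of planted duplications.
#' @slot paralogDiffs data.table of positions differing between source and
#'   copy (chrom, src_pos, dst_pos, src_base, dst_base, paralog).
#' @slot homopolymers \code{GRanges} of planted homopolymer runs (>= 5 bp).
#' @slot antisense \code{GRanges} of antisense transcription intervals with
#'   ratio/level metadata.
#' @slot events data.table of planted site-level events (editing, SNPs,
#'   antisense editing) with their parameters.
#' @slot config the generating \linkS4class{SimConfig}.
#' @export
setClass("ReferenceBundle", representation(
  genome = "ANY", exons = "ANY", snps = "ANY", indels = "ANY",
  repeats = "ANY", dualStrand = "ANY", paralogs = "ANY",
  paralogDiffs = "ANY", homopolymers = "ANY", antisense = "ANY",
  events = "ANY", config = "SimConfig"
))

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  cat(sprintf("  genome: %d chromosome(s), %s bp total\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ",")))
  cat(sprintf("  annotation: %d exons / %d genes; %d SNPs; %d paralog diffs; %d planted events\n",
              length(object@exons),
              length(unique(object@exons$gene_id)),
              nrow(object@snps), nrow(object@paralogDiffs), nrow(object@events)))
})

#' Simulated cohort evidence
#'
#' The output of [simulateCohort()]: sparse per-site mismatch evidence (rows
#' exist only where at least one mismatch-supporting read was drawn), the
#' per-sample per-gene depth tables needed to recover total coverage at any
#' CDS position, the matched whole-exome companion, and the realized truth
#' table.
#'
#' @slot evidence data.table: sample, donor, tissue, chrom, pos (1-based),
#'   ref (plus-strand base), origin ("*" unstranded, else transcript strand of
#'   origin), and per-alignment-strand base counts A_plus..T_minus.
#' @slot coverage data.table: sample, donor, tissue, gene_id, depth.
#' @slot antisenseCoverage data.table: sample, interval index, depth of
#'   antisense-origin reads.
#' @slot wes data.table of WES mismatch evidence (donor, chrom, pos, ref,
#'   A, C, G, T).
#' @slot wesCoverage data.table: donor, gene_id, depth.
#' @slot truth data.table of planted ground truth (site_id, class, chrom,
#'   pos, strand, ref, alt, gene_id, level_mean, dispersion, freq, hom).
#' @slot reference the generating \linkS4class{ReferenceBundle}.
#' @export
setClass("EditingCohort", representation(
  evidence = "ANY", coverage = "ANY", antisenseCoverage = "ANY",
  wes = "ANY", wesCoverage = "ANY", truth = "ANY", reference = "ReferenceBundle"
))

setMethod("show", "EditingCohort", function(object) {
  cat("EditingCohort\n")
  cat(sprintf("  %d evidence rows over %d samples (%d donors x %d tissues)\n",
              nrow(object@evidence),
              length(unique(object@evidence$sample)),
              object@reference@config@nDonors,
              length(object@reference@config@tissues)))
  cat(sprintf("  truth: %s\n",
              paste(sprintf("%s=%d", names(table(object@truth$class)),
                            as.integer(table(object@truth$class))), collapse = ", ")))
})

#' Pipeline result
#'
#' The output of [runPipeline()]: the surviving site table, the per-stage
#' provenance log (every candidate is either a survivor or removed at exactly
#' one stage with a reason), and the per-stage substitution-type spectrum.
#'
#' @slot sites data.table of surviving sites (chrom, pos, strand, ref, alt,
#'   type, per-tissue levels, maximal level, score, donors).
#' @slot removed data.table of removed candidates with the removing stage.
#' @slot stageLog data.table: stage, candidates in, removed, survivors.
#' @slot spectra data.table: per-stage substitution-type counts.
#' @slot params the \linkS4class{ModelParams} used.
#' @export
setClass("PipelineResult", representation(
  sites = "ANY", removed = "ANY", stageLog = "ANY", spectra = "ANY",
  params = "ModelParams"
))

setMethod("show", "PipelineResult", function(object) {
  cat("PipelineResult\n")
  print(as.data.frame(object@stageLog), row.names = FALSE)
  n <- nrow(object@sites)
  ag <- sum(object@sites$type == "A>G")
  cat(sprintf("  %d surviving sites (%d A>G, %.1f%%)\n", n, ag,
              if (n) 100 * ag / n else 0))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for simulator and pipeline containers
#'
#' @param x a \linkS4class{ReferenceBundle}, \linkS4class{EditingCohort} or
#'   \linkS4class{PipelineResult}.
#' @return The requested component (a \code{DNAStringSet}, \code{GRanges} or
#'   data.table).
#' @name accessors
NULL

#' @rdname accessors
#' @export
refGenome <- function(x) x@genome

#' @rdname accessors
#' @export
refExons <- function(x) x@exons

#' @rdname accessors
#' @export
refEvents <- function(x) x@events

#' @rdname accessors
#' @export
cohortEvidence <- function(x) x@evidence

#' @rdname accessors
#' @export
cohortTruth <- function(x) x@truth

#' @rdname accessors
#' @export
calledSites <- function(x) x@sites

#' @rdname accessors
#' @export
stageLog <- function(x) x@stageLog

#' @rdname accessors
#' @export
stageSpectra <- function(x) x@spectra
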