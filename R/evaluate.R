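# Evaluation of pipeline calls against planted ground truth, plus small
# derived summary statistics of the detection results.

#' Evaluate called sites against planted truth
#'
#' Each call is assigned to exactly one truth class by position (and origin
#' strand where the truth event is strand-specific), or to "novel" when no
#' planted event exists at the position.
#'
#' @param calls data.frame of calls with chrom, pos, type and strand (the
#'   site table of a \linkS4class{PipelineResult}).
#' @param truth truth table of an \linkS4class{EditingCohort}; may be empty,
#'   in which case all calls are "novel".
#' @return A list with \code{calls} (input plus truth_class and site_id) and
#'   \code{byClass} (data.table: class, n_truth, n_called, recall).
#' @export
evaluateCalls <- function(calls, truth) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  if (nrow(truth)) {
    idx <- match(paste(calls$chrom, calls$pos), paste(truth$chrom, truth$pos))
    calls[, truth_class := ifelse(is.na(idx), "novel", truth$class[idx])]
    calls[, site_id := ifelse(is.na(idx), NA_character_, truth$site_id[idx])]
    byClass <- truth[, .(n_truth = .N), by = class]
    calledIds <- unique(calls$site_id[!is.na(calls$site_id)])
    nCalled <- truth[site_id %in% calledIds, .(n_called = .N), by = class]
    byClass <- merge(byClass, nCalled, by = "class", all.x = TRUE)
    byClass[is.na(n_called), n_called := 0L]
    byClass[, recall := n_called / n_truth]
  } else {
    calls[, `:=`(truth_class = "novel", site_id = NA_character_)]
    byClass <- data.table(class = character(), n_truth = integer(),
                          n_called = integer(), recall = numeric())
  }
  list(calls = calls[], byClass = byClass[])
}

#' Precision and recall for one substitution type against one truth class
#'
#' @param result a \linkS4class{PipelineResult} (or its site table).
#' @param truth the cohort truth table.
#' @param type substitution type of the calls to assess, in expressed-strand
#'   space (default "A>G").
#' @param classes truth classes counted as true positives (default
#'   "editing").
#' @param minLevel when not NULL, recall is restricted to truth sites with
#'   \code{level_mean >= minLevel}; precision always uses all calls of the
#'   type.
#' @param strand when not NULL, only calls on this strand are assessed
#'   (stranded mode).
#' @return A list: precision, recall, TP, FP, FN, n_calls.
#' @export
precisionRecall <- function(result, truth, type = "A>G",
                            classes = "editing", minLevel = NULL,
                            strand = NULL) {
  sites <- if (is(result, "PipelineResult")) result@sites else as.data.table(result)
  truth <- as.data.table(truth)
  sel <- sites[["type"]] == type
  if (!is.null(strand)) sel <- sel & sites[["strand"]] == strand
  calls <- sites[which(sel), ]
  tsub <- truth[class %in% classes]
  isTP <- paste(calls$chrom, calls$pos) %in% paste(tsub$chrom, tsub$pos)
  TP <- sum(isTP); FP <- sum(!isTP)
  tRecall <- tsub
  if (!is.null(minLevel)) tRecall <- tRecall[level_mean >= minLevel]
  found <- paste(tRecall$chrom, tRecall$pos) %in% paste(calls$chrom, calls$pos)
  list(precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (nrow(tRecall) > 0) mean(found) else NA_real_,
       TP = TP, FP = FP, FN = sum(!found), n_calls = nrow(calls))
}

#' Fraction of planted sites of given classes rejected by the pipeline
#'
#' @param result a \linkS4class{PipelineResult}.
#' @param truth the cohort truth table.
#' @param classes truth classes to assess (e.g. \code{c("het_snp",
#'   "hom_snp")}).
#' @return Fraction of planted sites of those classes with no surviving call
#'   at their position.
#' @export
rejectionRate <- function(result, truth, classes) {
  truth <- as.data.table(truth)
  tsub <- truth[class %in% classes]
  if (!nrow(tsub)) return(NA_real_)
  called <- paste(tsub$chrom, tsub$pos) %in%
    paste(result@sites$chrom, result@sites$pos)
  mean(!called)
}

#' Cross-type false-positive proxy
#'
#' With adenosine-to-inosine editing producing only one genuine substitution
#' type on the expressed strand, the count of calls of a comparison type with
#' no genuine source (G-to-A by default) relative to the A-to-G calls
#' estimates the false-positive fraction of the A-to-G set.
#'
#' @param result a \linkS4class{PipelineResult} (or a site table).
#' @param type the genuine type (default "A>G").
#' @param proxyType the no-truth comparison type (default "G>A").
#' @return A list: n_type, n_proxy, fpr (proxy/type).
#' @export
falsePositiveProxy <- function(result, type = "A>G", proxyType = "G>A") {
  sites <- if (is(result, "PipelineResult")) result@sites else as.data.table(result)
  nT <- sum(sites[["type"]] == type)
  nP <- sum(sites[["type"]] == proxyType)
  list(n_type = nT, n_proxy = nP,
       fpr = if (nT > 0) nP / nT else NA_real_)
}

#' Rare-SNP prior from coding-sequence SNP density
#'
#' Upper-bound estimate of the probability that a given CDS position harbors
#' a rare SNP: (number of CDS SNPs per individual / CDS length) times the
#' fraction of SNPs that are rare. With 2.6e4 SNPs over 3.4e7 CDS bp and a
#' rare fraction of 4\% this gives 3.06e-5, motivating the conservative
#' heterozygous prior of 1e-4.
#'
#' @param nSnps SNPs per individual in the CDS.
#' @param cdsLength total CDS length in bp.
#' @param rareFraction fraction of SNPs that are rare.
#' @return The per-position rare-SNP probability.
#' @examples
#' snpPriorEstimate(2.6e4, 3.4e7, 0.04)
#' @export
snpPriorEstimate <- function(nSnps = 2.6e4, cdsLength = 3.4e7,
                             rareFraction = 0.04) {
  (nSnps / cdsLength) * rareFraction
}

#' Antisense attribution summary for strand-specific validation
#'
#' Given the number of candidate T-to-C sites covered in stranded data and
#' how many of them show their signal on the antisense strand, returns the
#' confirmed fraction and the implied number of false-positive T-to-C
#' detections in the full (non-stranded) set.
#'
#' @param confirmed sites whose signal lies on the antisense strand.
#' @param covered sites covered in the stranded data.
#' @param total size of the full T-to-C set.
#' @return A list: fraction_confirmed (percent), estimated_false_positives.
#' @examples
#' antisenseAttribution(539, 552, 1006)
#' @export
antisenseAttribution <- function(confirmed, covered, total) {
  frac <- confirmed / covered
  list(fraction_confirmed = 100 * frac,
       estimated_false_positives = (1 - frac) * total)
}
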