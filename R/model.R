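# Core statistical machinery: the three-hypothesis per-donor tests, the
# Fisher-combined site score, the strand-consistency test, the WES filter,
# editing-level recalculation, maximal level, and the pooled editing index.

#' Sequencing-error p-value
#'
#' Probability of observing at least \code{E} mismatch-supporting reads out
#' of \code{C} covering reads if every mismatch is a base-calling error:
#' the upper tail \eqn{P(X \ge E)} for \eqn{X \sim Bin(C, E_{error})}.
#'
#' @param E integer vector, mismatch-supporting read counts.
#' @param C integer vector, total covering read counts.
#' @param params a \linkS4class{ModelParams}.
#' @return Numeric vector of upper-tail probabilities.
#' @examples
#' pError(0, 100)        # 1
#' pError(1, 1)          # 1e-3
#' pError(3, 10)
#' @export
pError <- function(E, C, params = modelParams()) {
  checkEC(E, C)
  pbinom(E - 1, C, params@eError, lower.tail = FALSE)
}

#' Rare-heterozygous-SNP p-value
#'
#' Probability that the observation is explained by a rare heterozygous SNP:
#' the lower tail \eqn{P(X \le E)} for \eqn{X \sim Bin(C, E_{hetero})},
#' multiplied by the prior probability of such a genomic event.
#'
#' @inheritParams pError
#' @return Numeric vector, bounded above by the heterozygous prior.
#' @examples
#' pHetero(20, 20)       # equals the prior, 1e-4
#' pHetero(0, 20)        # 1e-4 * 0.5^20
#' @export
pHetero <- function(E, C, params = modelParams()) {
  checkEC(E, C)
  params@pHetero * pbinom(E, C, params@eHetero)
}

#' Rare-homozygous-SNP p-value
#'
#' With an expected alternative-allele fraction of 1 the lower-tail binomial
#' sum collapses analytically: every term with \eqn{j < C} vanishes, so the
#' value is the homozygous prior when \eqn{E = C} and zero otherwise. The
#' degenerate case \eqn{E = C = 0} is the vacuous full sum and returns the
#' prior.
#'
#' @inheritParams pError
#' @return Numeric vector with values in \code{{0, pHomo}} at default
#'   parameters.
#' @examples
#' pHomo(10, 10)   # 1e-8
#' pHomo(9, 10)    # 0
#' @export
pHomo <- function(E, C, params = modelParams()) {
  checkEC(E, C)
  params@pHomo * pbinom(E, C, params@eHomo)
}

checkEC <- function(E, C) {
  if (any(E < 0) || any(C < 0)) stop("counts must be non-negative")
  if (any(E > C)) stop("E must not exceed C")
  invisible(NULL)
}

#' Per-donor chosen p-value
#'
#' Applies the configured combiner to the three hypothesis p-values. In the
#' default \code{"max"} mode the chosen value is the largest of the three:
#' a site is only called when even the most plausible non-editing explanation
#' is rejected. The \code{"literal_min"} mode takes the minimum as printed in
#' the score definition; it degenerates (the homozygous p-value is zero
#' whenever \eqn{E < C}) and errors on a zero p-value.
#'
#' @inheritParams pError
#' @return Numeric vector of chosen per-donor p-values.
#' @export
chosenP <- function(E, C, params = modelParams()) {
  pe <- pError(E, C, params)
  ph <- pHetero(E, C, params)
  po <- pHomo(E, C, params)
  if (params@combiner == "max") {
    pmax(pe, ph, po)
  } else {
    p <- pmin(pe, ph, po)
    if (any(p == 0)) {
      stop("literal_min combiner produced a zero p-value (E < C makes the ",
           "homozygous term vanish); use the default 'max' combiner")
    }
    p
  }
}

#' Fisher-combined site score
#'
#' Combines the chosen per-donor p-values with Fisher's method (natural
#' logarithm): \eqn{S = -2 \sum_i \ln p_i} over the \eqn{N} contributing
#' donors. Because the chosen values are not bona fide uniform p-values the
#' score is used only as a filter, never converted to a site p-value: a site
#' fails when \eqn{S < 2N}, the mean of the reference chi-square distribution.
#'
#' @param E,C integer vectors of per-donor mismatch-supporting and total
#'   covering read counts (one entry per donor; donors with zero coverage must
#'   be excluded beforehand).
#' @param params a \linkS4class{ModelParams}.
#' @return A list with \code{S}, \code{N}, \code{p} (per-donor chosen
#'   p-values) and \code{pass} (logical, \code{S >= 2N}).
#' @examples
#' siteScore(E = c(5, 3), C = c(50, 40))
#' @export
siteScore <- function(E, C, params = modelParams()) {
  if (length(E) < 1L) stop("need at least one donor")
  if (length(E) != length(C)) stop("E and C must have equal length")
  if (any(C < 1)) stop("zero-coverage donors must be excluded before scoring")
  p <- chosenP(E, C, params)
  S <- -2 * sum(log(p))
  N <- length(p)
  list(S = S, N = N, p = p, pass = S >= 2 * N)
}

#' Strand-consistency test
#'
#' A genuine editing event is sequenced on both strands of the amplified
#' cDNA, while several technical error modes are strand-specific. Pooling
#' reads over all samples, the sequencing-error test is applied separately to
#' reads aligned to each genomic strand; the site passes only when both
#' strands individually reject the error hypothesis at
#' \eqn{p < \exp(-N/4)}, with \eqn{N} the number of contributing donors.
#' A strand with zero coverage cannot demonstrate the mismatch and fails.
#'
#' @param Eplus,Cplus pooled mismatch-supporting and covering read counts on
#'   plus-strand alignments.
#' @param Eminus,Cminus same for minus-strand alignments.
#' @param N number of donors contributing evidence at the site.
#' @param params a \linkS4class{ModelParams}.
#' @return Logical vector: pass/fail per site.
#' @examples
#' strandConsistency(50, 500, 45, 480, N = 10)
#' strandConsistency(0, 500, 45, 480, N = 10)  # FALSE
#' @export
strandConsistency <- function(Eplus, Cplus, Eminus, Cminus, N,
                              params = modelParams()) {
  thr <- exp(-N / 4)
  ok <- Cplus > 0 & Cminus > 0
  pp <- rep(1, length(Eplus)); pm <- rep(1, length(Eminus))
  if (any(ok)) {
    pp[ok] <- pError(Eplus[ok], Cplus[ok], params)
    pm[ok] <- pError(Eminus[ok], Cminus[ok], params)
  }
  ok & pp < thr & pm < thr
}

#' Whole-exome-sequencing filter
#'
#' Discards a candidate site when matched WES (DNA) reads are insufficient
#' (fewer than \code{minCoverage}) or when the WES mismatch level exceeds
#' \code{maxLevel} (the maximal expected sequencing-error rate), indicating a
#' genomic origin. The boundary is strict: a level exactly equal to
#' \code{maxLevel} is kept.
#'
#' @param E,C pooled WES mismatch-supporting and covering read counts.
#' @param minCoverage minimum WES reads required (default 100).
#' @param maxLevel maximal tolerated WES mismatch level (default 0.001).
#' @return Logical vector: TRUE to keep.
#' @examples
#' wesFilter(0, 99)      # FALSE: insufficient coverage
#' wesFilter(2, 1000)    # FALSE: 0.2% > 0.1%
#' wesFilter(1, 1000)    # TRUE: exactly 0.1%
#' @export
wesFilter <- function(E, C, minCoverage = 100, maxLevel = 0.001) {
  C >= minCoverage & (E / pmax(C, 1)) <= maxLevel
}

#' Recalculate per-tissue editing levels and apply the level threshold
#'
#' Levels are recomputed from pooled, unfiltered counts per tissue; a site is
#' kept only if its editing level reaches \code{minLevel} in at least one
#' tissue.
#'
#' @param edited,coverage numeric vectors of pooled per-tissue counts (one
#'   entry per tissue, parallel to \code{tissues}).
#' @param tissues tissue labels.
#' @param minLevel threshold (default 0.01).
#' @return A list with \code{levels} (named per-tissue levels; NA where the
#'   tissue has no coverage), \code{keep}, and \code{reason} ("ok",
#'   "low_level" or "no_coverage").
#' @examples
#' recomputeLevels(c(1, 8), c(200, 400), c("brain", "liver"))
#' @export
recomputeLevels <- function(edited, coverage, tissues, minLevel = 0.01) {
  lv <- ifelse(coverage > 0, edited / coverage, NA_real_)
  names(lv) <- tissues
  if (all(coverage == 0)) {
    list(levels = lv, keep = FALSE, reason = "no_coverage")
  } else if (max(lv, na.rm = TRUE) < minLevel) {
    list(levels = lv, keep = FALSE, reason = "low_level")
  } else {
    list(levels = lv, keep = TRUE, reason = "ok")
  }
}

#' Maximal editing level
#'
#' The maximum per-tissue editing level among tissues with coverage of at
#' least \code{minCoverage} reads; \code{NA} (flagged undefined) when no
#' tissue qualifies.
#'
#' @param levels per-tissue editing levels.
#' @param coverage per-tissue pooled coverages.
#' @param minCoverage coverage required for a tissue to contribute
#'   (default 100).
#' @return A single level, or \code{NA} when undefined.
#' @examples
#' maximalLevel(c(0.5, 0.1), c(99, 200))   # 0.1
#' maximalLevel(c(0.5, 0.1), c(99, 80))    # NA
#' @export
maximalLevel <- function(levels, coverage, minCoverage = 100) {
  ok <- coverage >= minCoverage & !is.na(levels)
  if (!any(ok)) return(NA_real_)
  max(levels[ok])
}

#' Pooled RNA editing index
#'
#' For a chosen set of A-to-G editing sites, the index is the percentage of
#' G reads out of A and G reads combined, pooled over all sites -- i.e. the
#' coverage-weighted aggregate editing level, not the mean of per-site
#' levels. The T-to-C index is computed symmetrically by passing T and C
#' counts as \code{refCounts} and \code{altCounts}.
#'
#' @param refCounts per-site pooled reference-base read counts (A for the
#'   A-to-G index).
#' @param altCounts per-site pooled edited-base read counts (G for the
#'   A-to-G index).
#' @return Index in percent, or \code{NA} when no reads are available.
#' @examples
#' editingIndex(900, 100)               # 10
#' editingIndex(c(900, 100), c(100, 900))  # 50: weighted pooling
#' @export
editingIndex <- function(refCounts, altCounts) {
  tot <- sum(refCounts) + sum(altCounts)
  if (tot == 0) return(NA_real_)
  100 * sum(altCounts) / tot
}
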