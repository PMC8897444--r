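# End-to-end site-calling pipeline: candidate mismatch aggregation followed
# by, in order, position filters (splice/homopolymer context), annotation
# mask, self-homology blacklist, the per-donor statistical score, the pooled
# strand-consistency test, the mixed-type cluster filter, the WES filter and
# the editing-level threshold. Every candidate is either a survivor or is
# removed at exactly one stage with a reason.

PIPELINE_STAGES <- c("position", "mask", "homology", "score", "strand",
                     "cluster", "wes", "level")

#' Pooled coverage at sites
#'
#' Total read coverage at the given positions pooled over samples, by tissue,
#' reconstructed from the per-sample per-gene depth tables (plus
#' antisense-interval depth where applicable).
#'
#' @param cohort an \linkS4class{EditingCohort}.
#' @param sites data.frame with chrom, pos and (for stranded cohorts) origin.
#' @return data.table: chrom, pos, origin, tissue, coverage.
#' @export
poolCoverage <- function(cohort, sites) {
  ref <- cohort@reference
  stranded <- ref@config@stranded
  posTab <- as.data.table(cdsPositions(ref@genome, ref@exons))
  sites <- unique(as.data.table(sites)[, .(chrom, pos,
    origin = if (stranded && "origin" %in% names(sites)) origin else "*")])
  sites <- merge(sites, posTab[, .(chrom, pos, gene_id, gstrand = strand)],
                 by = c("chrom", "pos"), sort = FALSE)
  covT <- cohort@coverage[, .(depth = sum(depth)), by = .(tissue, gene_id)]
  out <- merge(sites, covT, by = "gene_id", allow.cartesian = TRUE)
  setnames(out, "depth", "coverage")
  asIv <- as.data.table(ref@antisense)
  if (nrow(asIv)) {
    asIv[, interval := .I]
    acT <- cohort@antisenseCoverage[, .(adepth = sum(depth)),
                                    by = .(tissue, interval)]
    for (i in asIv$interval) {
      inIv <- out$chrom == asIv$seqnames[i] & out$pos >= asIv$start[i] &
        out$pos <= asIv$end[i]
      if (!any(inIv)) next
      ad <- acT[interval == i]
      adep <- ad$adepth[match(out$tissue, ad$tissue)]
      if (stranded) {
        anti <- inIv & out$origin != out$gstrand
        out$coverage[anti] <- adep[anti]
      } else {
        out$coverage[inIv] <- out$coverage[inIv] + adep[inIv]
      }
    }
  }
  out[, .(chrom, pos, origin, tissue, coverage)]
}

# long-format per-donor mismatch evidence: one row per
# (sample, site, origin, alt base with E >= 1)
candidateEvidence <- function(cohort) {
  ev <- cohort@evidence
  long <- rbindlist(lapply(BASES, function(b) {
    E <- ev[[paste0(b, "_plus")]] + ev[[paste0(b, "_minus")]]
    keep <- E > 0L & ev$ref != b
    data.table(sample = ev$sample[keep], donor = ev$donor[keep],
               tissue = ev$tissue[keep], chrom = ev$chrom[keep],
               pos = ev$pos[keep], origin = ev$origin[keep],
               ref = ev$ref[keep], alt = b, E = E[keep],
               E_plus = ev[[paste0(b, "_plus")]][keep])
  }))
  tot <- Reduce(`+`, lapply(c(paste0(BASES, "_plus"), paste0(BASES, "_minus")),
                            function(cc) ev[[cc]]))
  totp <- Reduce(`+`, lapply(paste0(BASES, "_plus"), function(cc) ev[[cc]]))
  covRow <- data.table(sample = ev$sample, chrom = ev$chrom, pos = ev$pos,
                       origin = ev$origin, C = tot, C_plus = totp)
  merge(long, covRow, by = c("sample", "chrom", "pos", "origin"), sort = FALSE)
}

#' Run the site-calling pipeline
#'
#' @param cohort an \linkS4class{EditingCohort}.
#' @param params a \linkS4class{ModelParams}.
#' @param stages character vector of stages to apply, a subset of
#'   \code{c("position", "mask", "homology", "score", "strand", "cluster",
#'   "wes", "level")}; an empty vector returns all candidate mismatches.
#' @param minLevel editing-level threshold (default 0.01).
#' @param maxGap cluster joining distance (default 100).
#' @param wesMinCoverage,wesMaxLevel WES filter constants (defaults 100 and
#'   0.001).
#' @param homology optional precomputed result of [homologyBlacklist()]
#'   (recomputed from the bundle when NULL).
#' @param strictBlacklist if TRUE a blacklisted position suppresses all
#'   substitution types there, not only the type implied by the homologous
#'   locus.
#' @return A \linkS4class{PipelineResult}.
#' @examples
#' \donttest{
#' cohort <- simulateCohort(generateReference(simConfig(seed = 1, nDonors = 6,
#'   tissues = c("brain", "liver"))))
#' res <- runPipeline(cohort)
#' res
#' }
#' @export
runPipeline <- function(cohort, params = modelParams(),
                        stages = PIPELINE_STAGES,
                        minLevel = 0.01, maxGap = 100L,
                        wesMinCoverage = 100, wesMaxLevel = 0.001,
                        homology = NULL, strictBlacklist = FALSE) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  ref <- cohort@reference
  stranded <- ref@config@stranded
  posTab <- as.data.table(cdsPositions(ref@genome, ref@exons))

  donorEv <- candidateEvidence(cohort)
  donorEv <- merge(donorEv,
                   posTab[, .(chrom, pos, gene_id, gstrand = strand)],
                   by = c("chrom", "pos"), sort = FALSE)
  # expressed-strand assignment: annotated coding strand when unstranded,
  # the read origin strand when stranded
  donorEv[, strand := if (stranded) origin else gstrand]
  donorEv[, type := ifelse(strand == "+", paste0(ref, ">", alt),
                           paste0(compBase(ref), ">", compBase(alt)))]

  cand <- unique(donorEv[, .(chrom, pos, strand, ref_plus = ref,
                             alt_plus = alt, type, gene_id)])
  cand[, stage_removed := NA_character_]
  cand[, reason := NA_character_]
  setkey(cand, chrom, pos, strand, type)

  alive <- function() is.na(cand$stage_removed)
  spectra <- list(candidates = spectrum(cand[alive()], "candidates"))
  log <- list(data.table(stage = "candidates", n_in = nrow(cand),
                         removed = 0L, survivors = nrow(cand)))
  mark <- function(stage, cond, why) {
    hit <- alive() & cond
    n_in <- sum(alive())
    cand[hit, `:=`(stage_removed = stage,
                   reason = if (length(why) == 1L) why else why[hit])]
    log[[length(log) + 1L]] <<- data.table(
      stage = stage, n_in = n_in, removed = sum(hit),
      survivors = n_in - sum(hit))
    spectra[[stage]] <<- spectrum(cand[alive()], stage)
  }

  if ("position" %in% stages) {
    pf <- positionFilters(ref)
    m <- pf[cand[, .(chrom, pos)], on = c("chrom", "pos")]
    why <- ifelse(m$near_splice %in% TRUE, "splice",
                  ifelse(m$near_homopolymer %in% TRUE, "homopolymer", "ok"))
    mark("position", why != "ok", why)
  }
  if ("mask" %in% stages) {
    mask <- buildMask(ref)
    mark("mask", maskSites(cand$chrom, cand$pos, mask), "masked")
  }
  if ("homology" %in% stages) {
    hb <- homology %||% homologyBlacklist(ref@genome, ref@exons)
    blk <- hb$blacklist
    hit <- if (strictBlacklist) {
      paste(cand$chrom, cand$pos) %in% paste(blk$chrom, blk$pos)
    } else {
      paste(cand$chrom, cand$pos, cand$ref_plus, cand$alt_plus) %in%
        paste(blk$chrom, blk$pos, blk$ref, blk$alt)
    }
    mark("homology", hit, "homology")
  }
  if ("score" %in% stages) {
    sc <- donorEv[, .(p = chosenP(E, C, params)),
                  by = .(chrom, pos, strand, type, tissue, donor)]
    sc <- sc[, .(S = -2 * sum(log(p)), N = .N),
             by = .(chrom, pos, strand, type, tissue)]
    best <- sc[, .(pass = any(S >= 2 * N), S = max(S),
                   N = N[which.max(S)]), by = .(chrom, pos, strand, type)]
    cand[best, `:=`(S = i.S, N = i.N), on = c("chrom", "pos", "strand", "type")]
    pass <- best[cand, x.pass, on = c("chrom", "pos", "strand", "type")]
    mark("score", !(pass %in% TRUE), "low_score")
  }
  if ("strand" %in% stages) {
    # data are pooled over all samples; N counts the donors contributing
    # coverage at the site (not only those carrying the mismatch)
    covDonors <- cohort@coverage[depth > 0,
                                 .(Ncov = data.table::uniqueN(donor)),
                                 by = gene_id]
    pooled <- donorEv[, .(E = sum(E), E_plus = sum(E_plus),
                          gene_id = gene_id[1L]),
                      by = .(chrom, pos, strand, type)]
    pooled[covDonors, N := i.Ncov, on = "gene_id"]
    pooled[is.na(N), N := data.table::uniqueN(cohort@coverage$donor)]
    covTot <- poolCoverage(cohort, donorEv[, .(chrom, pos, origin)])
    covTot <- covTot[, .(Ctot = sum(coverage)), by = .(chrom, pos, origin)]
    pooled <- merge(pooled,
                    unique(donorEv[, .(chrom, pos, strand, type, origin)]),
                    by = c("chrom", "pos", "strand", "type"), sort = FALSE)
    pooled <- merge(pooled, covTot, by = c("chrom", "pos", "origin"),
                    sort = FALSE)
    pooled[, `:=`(Cp = Ctot %/% 2L, Cm = Ctot - Ctot %/% 2L)]
    pooled[, Ep := pmin(E_plus, Cp)]
    pooled[, Em := pmin(E - E_plus, Cm)]
    pooled[, pass := strandConsistency(Ep, Cp, Em, Cm, N, params)]
    pass <- pooled[cand, x.pass, on = c("chrom", "pos", "strand", "type")]
    mark("strand", !(pass %in% TRUE), "strand_inconsistent")
  }
  if ("cluster" %in% stages) {
    surv <- cand[alive()]
    if (nrow(surv)) {
      mp <- mapToMrna(ref, surv$chrom, surv$pos)
      cf <- clusterFilter(mp$gene_id, mp$mrna_pos, surv$type, maxGap = maxGap)
      drop <- surv[!cf$keep, .(chrom, pos, strand, type)]
      hit <- paste(cand$chrom, cand$pos, cand$strand, cand$type) %in%
        paste(drop$chrom, drop$pos, drop$strand, drop$type)
      mark("cluster", hit, "mixed_cluster")
    } else mark("cluster", rep(FALSE, nrow(cand)), "mixed_cluster")
  }
  if ("wes" %in% stages) {
    wesCovG <- cohort@wesCoverage[, .(C = sum(depth)), by = gene_id]
    cand[, wesC := wesCovG$C[match(gene_id, wesCovG$gene_id)]]
    if (nrow(cohort@wes)) {
      wesPool <- cohort@wes[, lapply(.SD, sum), by = .(chrom, pos),
                            .SDcols = BASES]
      m <- wesPool[cand[, .(chrom, pos)], on = c("chrom", "pos")]
      wesE <- as.matrix(m[, BASES, with = FALSE])[
        cbind(seq_len(nrow(cand)), match(cand$alt_plus, BASES))]
      wesE[is.na(wesE)] <- 0L
    } else wesE <- rep(0L, nrow(cand))
    cand[, wesE := as.integer(wesE)]
    mark("wes", !wesFilter(cand$wesE, cand$wesC, wesMinCoverage, wesMaxLevel),
         "wes")
  }

  # per-tissue levels from pooled, unfiltered counts (always computed for the
  # survivors so the site table carries levels even when the stage is off)
  tissues <- ref@config@tissues
  edT <- donorEv[, .(edited = sum(E)), by = .(chrom, pos, strand, type, tissue)]
  covT <- poolCoverage(cohort, donorEv[, .(chrom, pos, origin)])
  covT <- merge(covT, unique(donorEv[, .(chrom, pos, origin, strand, type)]),
                by = c("chrom", "pos", "origin"), allow.cartesian = TRUE)
  lv <- merge(covT, edT, by = c("chrom", "pos", "strand", "type", "tissue"),
              all.x = TRUE)
  lv[is.na(edited), edited := 0L]
  lv[, level := ifelse(coverage > 0, edited / coverage, NA_real_)]
  lvStats <- lv[, .(max_any = suppressWarnings(max(level, na.rm = TRUE)),
                    max_level = maximalLevel(level, coverage)),
                by = .(chrom, pos, strand, type)]
  cand[lvStats, `:=`(max_any = i.max_any, max_level = i.max_level),
       on = c("chrom", "pos", "strand", "type")]
  if ("level" %in% stages) {
    mark("level", is.na(cand$max_any) | cand$max_any < minLevel, "low_level")
  }

  sites <- cand[alive()]
  lvWide <- dcast(lv, chrom + pos + strand + type ~ tissue,
                  value.var = "level")
  setnames(lvWide, tissues, paste0("level_", tissues), skip_absent = TRUE)
  sites <- merge(sites, lvWide, by = c("chrom", "pos", "strand", "type"),
                 all.x = TRUE, sort = FALSE)
  sites[, ref := substr(type, 1L, 1L)]
  sites[, alt := substr(type, 3L, 3L)]
  sites[, c("stage_removed", "reason", "max_any") := NULL]
  setorder(sites, chrom, pos, strand, type)

  removed <- cand[!alive(), .(chrom, pos, strand, type, stage_removed, reason)]
  new("PipelineResult",
      sites = sites[], removed = removed,
      stageLog = rbindlist(log), spectra = rbindlist(spectra, fill = TRUE),
      params = params)
}

spectrum <- function(cand, stage) {
  if (!nrow(cand)) return(data.table(stage = stage))
  tab <- as.data.table(as.list(table(cand$type)))
  tab[, stage := stage]
  setcolorder(tab, "stage")
  tab
}
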