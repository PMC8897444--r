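# Cohort simulator: realizes the planted events of a ReferenceBundle into
# per-sample, per-site, per-alignment-strand mismatch evidence, a matched
# whole-exome companion, and the ground-truth table.
#
# Count-level model:
#   * per (sample, gene) read depth is Poisson(depthMean) and constant along
#     the gene; antisense intervals add Poisson(depthMean * ratio) reads;
#   * sequencing errors at every CDS position: Binomial(depth, errorRate),
#     split uniformly over the three non-reference bases;
#   * editing: per donor/tissue level drawn from a Beta with the configured
#     mean and dispersion, edited reads Binomial(depth, level);
#   * rare SNPs: carriers drawn once per site (>= 1 guaranteed), alternative
#     reads Binomial(depth, 0.5) for heterozygotes, all reads for homozygotes;
#   * paralog misalignment: at each position differing between copy and
#     source, Binomial(depth, misFraction) reads carry the copy's base;
#   * every read's alignment strand is Bernoulli(1/2); per-strand base counts
#     therefore sum to per-strand coverage by construction.

#' @import data.table
NULL
.datatable.aware <- TRUE

#' Simulate a multi-donor, multi-tissue evidence cohort
#'
#' @param ref a \linkS4class{ReferenceBundle} from [generateReference()].
#' @param config the same \linkS4class{SimConfig} used to generate \code{ref}
#'   (defaults to the one stored in the bundle).
#' @return An \linkS4class{EditingCohort}.
#' @examples
#' cfg <- simConfig(seed = 3, nDonors = 3, tissues = "brain",
#'   nGenes = 8L, editingLevels = c(0.2, 0.3), snpFreqs = 0.2, snpHom = FALSE,
#'   nCommonSnps = 2L, nCommonIndels = 1L,
#'   paralogLength = 200L, paralogIdentity = 0.95, paralogMisFraction = 0.1,
#'   antisenseRatio = 0.5, antisenseLevel = 0.3, antisenseSites = 2L)
#' cohort <- simulateCohort(generateReference(cfg))
#' cohort
#' @export
simulateCohort <- function(ref, config = ref@config) {
  set.seed(deriveSeed(config@seed, 23L))
  donors <- sprintf("D%03d", seq_len(config@nDonors))
  tissues <- config@tissues
  samples <- data.table(expand.grid(donor = donors, tissue = tissues,
                                    stringsAsFactors = FALSE))
  samples[, sample := paste(donor, tissue, sep = ".")]
  setkey(samples, sample)

  posTab <- as.data.table(cdsPositions(ref@genome, ref@exons))
  genes <- unique(posTab$gene_id)

  # ---- coverage tables -------------------------------------------------------
  coverage <- samples[, .(gene_id = genes), by = .(sample, donor, tissue)]
  coverage[, depth := rpois(.N, config@depthMean)]
  setkey(coverage, sample, gene_id)

  asIv <- as.data.table(ref@antisense)[, interval := .I]
  antisenseCoverage <- if (nrow(asIv)) {
    ac <- samples[, .(interval = asIv$interval, ratio = asIv$ratio),
                  by = .(sample, donor, tissue)]
    ac[, depth := rpois(.N, config@depthMean * ratio)][, ratio := NULL]
  } else {
    data.table(sample = character(), donor = character(), tissue = character(),
               interval = integer(), depth = integer())
  }

  wesCoverage <- CJ(donor = donors, gene_id = genes)
  wesCoverage[, depth := rpois(.N, config@wesDepth)]
  setkey(wesCoverage, donor, gene_id)

  events <- data.table::copy(ref@events)

  # ---- RNA mismatch draws ----------------------------------------------------
  mmList <- vector("list", nrow(samples) + 8L)

  # sequencing errors at every CDS position (positions carrying a planted
  # event are handled by their own process below)
  eventKey <- paste(events$chrom, events$pos)
  errPos <- posTab[!paste(chrom, pos) %in% eventKey]
  for (i in seq_len(nrow(samples))) {
    dep <- coverage[.(samples$sample[i], errPos$gene_id), depth]
    k <- rbinom(nrow(errPos), dep, config@errorRate)
    nz <- which(k > 0L)
    if (!length(nz)) next
    reads <- rep(nz, k[nz])
    alt <- altDraw(errPos$ref[reads])
    dt <- data.table(idx = reads, alt = alt)[, .(k = .N), by = .(idx, alt)]
    mmList[[i]] <- data.table(
      sample = samples$sample[i], donor = samples$donor[i],
      tissue = samples$tissue[i],
      chrom = errPos$chrom[dt$idx], pos = errPos$pos[dt$idx],
      gene_id = errPos$gene_id[dt$idx], strand = errPos$strand[dt$idx],
      alt = dt$alt, k = dt$k, origin = errPos$strand[dt$idx])
  }
  j <- nrow(samples)

  # planted editing sites
  ed <- events[class == "editing"]
  if (nrow(ed)) {
    grid <- CJ(site = seq_len(nrow(ed)), s = seq_len(nrow(samples)))
    grid <- cbind(ed[grid$site, .(site_id, chrom, pos, gene_id, strand, alt,
                                  level_mean, dispersion)],
                  samples[grid$s, .(sample, donor, tissue)])
    if (!is.null(config@editingTissueLevels)) {
      m <- config@editingTissueLevels
      grid[, level_mean := m[cbind(match(site_id, ed$site_id),
                                   match(tissue, tissues))]]
    }
    grid[, p := rbetaMean(.N, level_mean, dispersion)]
    grid[, depth := coverage[.(grid$sample, grid$gene_id), depth]]
    grid[, k := rbinom(.N, depth, p)]
    grid <- grid[k > 0L]
    j <- j + 1L
    mmList[[j]] <- grid[, .(sample, donor, tissue, chrom, pos, gene_id,
                            strand, alt, k, origin = strand)]
  }

  # antisense editing (reads originate from the strand opposite the gene)
  as_ev <- events[class == "antisense_editing"]
  if (nrow(as_ev)) {
    grid <- CJ(site = seq_len(nrow(as_ev)), s = seq_len(nrow(samples)))
    grid <- cbind(as_ev[grid$site, .(site_id, chrom, pos, gene_id,
                                     alt, level_mean, dispersion, interval)],
                  samples[grid$s, .(sample, donor, tissue)])
    ac <- antisenseCoverage[, .(sample, interval, adepth = depth)]
    grid <- merge(grid, ac, by = c("sample", "interval"), sort = FALSE)
    grid[, p := rbetaMean(.N, level_mean, dispersion)]
    grid[, k := rbinom(.N, adepth, p)]
    grid <- grid[k > 0L]
    j <- j + 1L
    mmList[[j]] <- grid[, .(sample, donor, tissue, chrom, pos, gene_id,
                            strand = "-", alt, k, origin = "-")]
  }

  # rare SNPs: carriers drawn once, shared with the WES companion
  snp <- events[class %in% c("het_snp", "hom_snp")]
  carrierList <- list()
  if (nrow(snp)) {
    rows <- vector("list", nrow(snp))
    for (i in seq_len(nrow(snp))) {
      nc <- max(1L, rbinom(1L, config@nDonors, snp$freq[i]))
      car <- sample(donors, nc)
      carrierList[[snp$site_id[i]]] <- car
      sc <- samples[donor %in% car]
      frac <- if (isTRUE(snp$hom[i])) 1 else 0.5
      dep <- coverage[.(sc$sample, snp$gene_id[i]), depth]
      k <- rbinom(nrow(sc), dep, frac)
      rows[[i]] <- data.table(
        sample = sc$sample, donor = sc$donor, tissue = sc$tissue,
        chrom = snp$chrom[i], pos = snp$pos[i], gene_id = snp$gene_id[i],
        strand = snp$strand[i], alt = snp$alt[i], k = k,
        origin = snp$strand[i])[k > 0L]
    }
    j <- j + 1L
    mmList[[j]] <- rbindlist(rows)
  }

  # paralog misalignment at count level
  pd <- as.data.table(ref@paralogDiffs)
  if (nrow(pd)) {
    pinfo <- as.data.table(ref@paralogs)
    pd <- merge(pd, pinfo[, .(paralog, src_gene, mis_fraction)], by = "paralog")
    geneStrand <- posTab[, .(strand = strand[1L]), by = gene_id]
    pd <- merge(pd, geneStrand, by.x = "src_gene", by.y = "gene_id")
    grid <- CJ(d = seq_len(nrow(pd)), s = seq_len(nrow(samples)))
    grid <- cbind(pd[grid$d, .(chrom, pos = src_pos, gene_id = src_gene,
                               strand, alt = dst_base, mis_fraction)],
                  samples[grid$s, .(sample, donor, tissue)])
    grid[, depth := coverage[.(grid$sample, grid$gene_id), depth]]
    grid[, k := rbinom(.N, depth, mis_fraction)]
    grid <- grid[k > 0L & alt != refBaseAt(posTab, chrom, pos)]
    j <- j + 1L
    mmList[[j]] <- grid[, .(sample, donor, tissue, chrom, pos, gene_id,
                            strand, alt, k, origin = strand)]
  }

  mm <- rbindlist(mmList, use.names = TRUE)
  mm <- mm[, .(k = sum(k)), by = .(sample, donor, tissue, chrom, pos,
                                   gene_id, origin, alt)]

  evidence <- buildEvidence(mm, posTab, coverage, antisenseCoverage, asIv,
                            config)

  # ---- WES companion ---------------------------------------------------------
  wes <- simulateWes(ref, config, posTab, donors, wesCoverage, snp,
                     carrierList, pd = if (nrow(ref@paralogDiffs)) pd else NULL)

  truth <- data.table::copy(events)
  truth[, n_carriers := vapply(site_id, function(s)
    length(carrierList[[s]] %||% character(0)), integer(1))]

  new("EditingCohort",
      evidence = evidence, coverage = coverage,
      antisenseCoverage = antisenseCoverage,
      wes = wes$evidence, wesCoverage = wesCoverage,
      truth = truth, reference = ref)
}

# draw a non-reference base uniformly, vectorized
altDraw <- function(refs) {
  offs <- sample.int(3L, length(refs), replace = TRUE)
  m <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
             G = c("A", "C", "T"), T = c("A", "C", "G"))
  m[cbind(match(refs, rownames(m)), offs)]
}

# Beta draws parameterized by mean m and dispersion rho:
# var = rho * m * (1 - m); rho = 0 gives the fixed level m
rbetaMean <- function(n, m, rho) {
  out <- numeric(n)
  fixed <- rho <= 0 | m <= 0 | m >= 1
  out[fixed] <- m[if (length(m) > 1) fixed else 1]
  if (any(!fixed)) {
    mm <- if (length(m) > 1) m[!fixed] else rep(m, sum(!fixed))
    rr <- if (length(rho) > 1) rho[!fixed] else rep(rho, sum(!fixed))
    a <- mm * (1 - rr) / rr
    b <- (1 - mm) * (1 - rr) / rr
    out[!fixed] <- rbeta(sum(!fixed), a, b)
  }
  out
}

refBaseAt <- function(posTab, chroms, poss) {
  idx <- match(paste(chroms, poss), paste(posTab$chrom, posTab$pos))
  posTab$ref[idx]
}

# assemble wide per-strand base-count evidence rows from the mismatch table
buildEvidence <- function(mm, posTab, coverage, antisenseCoverage, asIv,
                          config) {
  if (nrow(mm) == 0L) return(emptyEvidence())
  mm[, ref := refBaseAt(posTab, chrom, pos)]

  if (!config@stranded) {
    # unstranded libraries pool sense and antisense reads at each position
    mm[, origin := "*"]
    mm <- mm[, .(k = sum(k)), by = .(sample, donor, tissue, chrom, pos,
                                     gene_id, origin, ref, alt)]
  }
  key <- mm[, .(ktot = sum(k)), by = .(sample, donor, tissue, chrom, pos,
                                       gene_id, origin, ref)]
  key[, depth := coverage[.(key$sample, key$gene_id), depth]]
  if (nrow(asIv)) {
    geneStrand <- posTab[, .(gstrand = strand[1L]), by = gene_id]
    key <- merge(key, geneStrand, by = "gene_id", sort = FALSE)
    for (i in asIv$interval) {
      inIv <- key$chrom == asIv$seqnames[i] & key$pos >= asIv$start[i] &
        key$pos <= asIv$end[i]
      if (!any(inIv)) next
      ad <- antisenseCoverage[interval == i]
      adep <- ad[match(key$sample, ad$sample), depth]
      if (config@stranded) {
        # a row holds reads of one origin: antisense rows draw from the
        # antisense pool, sense rows keep the gene depth
        anti <- inIv & key$origin != key$gstrand
        key$depth[anti] <- adep[anti]
      } else {
        key$depth[inIv] <- key$depth[inIv] + adep[inIv]
      }
    }
    key[, gstrand := NULL]
  }
  key[, refN := pmax(depth - ktot, 0L)]

  # alignment-strand split: each read lands on the plus strand w.p. 1/2
  mm[, kplus := rbinom(.N, k, 0.5)]
  key[, refplus := rbinom(.N, refN, 0.5)]

  long <- rbind(
    mm[, .(sample, donor, tissue, chrom, pos, origin, ref, base = alt,
           plus = kplus, minus = k - kplus)],
    key[, .(sample, donor, tissue, chrom, pos, origin, ref, base = ref,
            plus = refplus, minus = refN - refplus)])
  long <- long[, .(plus = sum(plus), minus = sum(minus)),
               by = .(sample, donor, tissue, chrom, pos, origin, ref, base)]

  wide <- dcast(long, sample + donor + tissue + chrom + pos + origin + ref ~
                  base, value.var = c("plus", "minus"), fill = 0L)
  for (b in BASES) {
    for (s in c("plus", "minus")) {
      colOld <- paste(s, b, sep = "_")
      if (!colOld %in% names(wide)) wide[, (colOld) := 0L]
    }
  }
  setnames(wide,
           c(paste("plus", BASES, sep = "_"), paste("minus", BASES, sep = "_")),
           c(paste(BASES, "plus", sep = "_"), paste(BASES, "minus", sep = "_")))
  setcolorder(wide, c("sample", "donor", "tissue", "chrom", "pos", "origin",
                      "ref", paste(BASES, "plus", sep = "_"),
                      paste(BASES, "minus", sep = "_")))
  setkey(wide, chrom, pos)
  wide[]
}

emptyEvidence <- function() {
  cols <- c(paste(BASES, "plus", sep = "_"), paste(BASES, "minus", sep = "_"))
  ev <- data.table(sample = character(), donor = character(),
                   tissue = character(), chrom = character(), pos = integer(),
                   origin = character(), ref = character())
  for (cc in cols) ev[, (cc) := integer()]
  ev
}

simulateWes <- function(ref, config, posTab, donors, wesCoverage, snp,
                        carrierList, pd = NULL) {
  rows <- list()
  eventKey <- paste(ref@events$chrom, ref@events$pos)
  errPos <- posTab[!paste(chrom, pos) %in% eventKey]
  for (d in donors) {
    dep <- wesCoverage[.(d, errPos$gene_id), depth]
    k <- rbinom(nrow(errPos), dep, config@wesErrorRate)
    nz <- which(k > 0L)
    if (!length(nz)) next
    reads <- rep(nz, k[nz])
    alt <- altDraw(errPos$ref[reads])
    dt <- data.table(idx = reads, alt = alt)[, .(k = .N), by = .(idx, alt)]
    rows[[length(rows) + 1L]] <- data.table(
      donor = d, chrom = errPos$chrom[dt$idx], pos = errPos$pos[dt$idx],
      gene_id = errPos$gene_id[dt$idx], alt = dt$alt, k = dt$k)
  }
  if (nrow(snp)) {
    for (i in seq_len(nrow(snp))) {
      car <- carrierList[[snp$site_id[i]]]
      dep <- wesCoverage[.(car, snp$gene_id[i]), depth]
      frac <- if (isTRUE(snp$hom[i])) 1 else 0.5
      k <- rbinom(length(car), dep, frac)
      rows[[length(rows) + 1L]] <- data.table(
        donor = car, chrom = snp$chrom[i], pos = snp$pos[i],
        gene_id = snp$gene_id[i], alt = snp$alt[i], k = k)[k > 0L]
    }
  }
  if (!is.null(pd) && nrow(pd)) {
    grid <- CJ(d = seq_len(nrow(pd)), donor = donors)
    grid <- cbind(pd[grid$d, .(chrom, pos = src_pos, gene_id = src_gene,
                               alt = dst_base, mis_fraction)],
                  data.table(donor = grid$donor))
    grid[, depth := wesCoverage[.(grid$donor, grid$gene_id), depth]]
    grid[, k := rbinom(.N, depth, mis_fraction)]
    grid <- grid[k > 0L & alt != refBaseAt(posTab, chrom, pos)]
    rows[[length(rows) + 1L]] <- grid[, .(donor, chrom, pos, gene_id, alt, k)]
  }
  mm <- rbindlist(rows, use.names = TRUE)
  if (nrow(mm) == 0L) {
    return(list(evidence = data.table(donor = character(), chrom = character(),
                                      pos = integer(), ref = character(),
                                      A = integer(), C = integer(),
                                      G = integer(), T = integer())))
  }
  mm <- mm[, .(k = sum(k)), by = .(donor, chrom, pos, gene_id, alt)]
  mm[, ref := refBaseAt(posTab, chrom, pos)]
  key <- mm[, .(ktot = sum(k)), by = .(donor, chrom, pos, gene_id, ref)]
  key[, depth := wesCoverage[.(key$donor, key$gene_id), depth]]
  key[, refN := pmax(depth - ktot, 0L)]
  long <- rbind(mm[, .(donor, chrom, pos, ref, base = alt, n = k)],
                key[, .(donor, chrom, pos, ref, base = ref, n = refN)])
  long <- long[, .(n = sum(n)), by = .(donor, chrom, pos, ref, base)]
  wide <- dcast(long, donor + chrom + pos + ref ~ base, value.var = "n",
                fill = 0L)
  for (b in BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  setcolorder(wide, c("donor", "chrom", "pos", "ref", BASES))
  setkey(wide, chrom, pos)
  list(evidence = wide[])
}
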