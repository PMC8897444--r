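# Cross-species conservation calling, emergence placement on the species
# tree, synonymous/nonsynonymous recoding incidence with context-matched
# randomization, restorative/diversifying classification, and the search for
# editing complementary sequences (ECS).

#' Cross-species conservation calls
#'
#' Pooled per-(group, category) counts are tested against the null that the
#' site is not edited in that group and mismatches are sequencing errors
#' (binomial upper tail at \code{errorRate}); p-values are BH-adjusted within
#' each (group, category) list. A site is conserved in a group when
#' significant (FDR \code{fdrConserved}) in either category; non-conserved
#' when not conserved, with an adjusted p above \code{fdrAbsent} and coverage
#' of at least \code{minCoverage} in some category; otherwise indeterminate.
#'
#' @param counts data.frame: site_id, group, category, edited, coverage.
#' @param groups valid group labels; unknown labels raise an error.
#' @param errorRate sequencing error rate (default 1e-3).
#' @param fdrConserved FDR threshold to call presence (default 0.001).
#' @param fdrAbsent adjusted-p floor to call absence (default 0.05).
#' @param minCoverage coverage required to call absence (default 500).
#' @return data.table: site_id, group, status in
#'   {conserved, non_conserved, indeterminate}.
#' @export
conservationCall <- function(counts, groups = unique(counts$group),
                             errorRate = 1e-3, fdrConserved = 0.001,
                             fdrAbsent = 0.05, minCoverage = 500) {
  counts <- as.data.table(counts)
  if (any(!counts$group %in% groups)) {
    stop("unknown group label: ",
         paste(setdiff(counts$group, groups), collapse = ", "))
  }
  if (any(counts$edited > counts$coverage)) stop("edited exceeds coverage")
  counts[, p := pbinom(edited - 1, coverage, errorRate, lower.tail = FALSE)]
  counts[, q := p.adjust(p, method = "BH"), by = .(group, category)]
  out <- counts[, .(
    conserved = any(q <= fdrConserved),
    absent_ok = any(q > fdrAbsent & coverage >= minCoverage)),
    by = .(site_id, group)]
  out[, status := ifelse(conserved, "conserved",
                         ifelse(absent_ok, "non_conserved", "indeterminate"))]
  out[, .(site_id, group, status)]
}

#' Emergence node of editing on the species tree
#'
#' For each site, finds the last common ancestor (LCA) of human and the most
#' distant group in which editing is conserved, requiring the most recent
#' outgroup of that LCA's descendants to be non-conserved; returns
#' "unresolved" when the outgroup condition cannot be established
#' (indeterminate outgroup), and "human_specific_candidate" when no group is
#' conserved and the nearest nonhuman group is non-conserved.
#'
#' @param calls data.table from [conservationCall()].
#' @param tree an \code{ape} phylo whose tips are the group labels plus
#'   \code{human}; internal nodes should be labeled.
#' @param human tip label of the focal species (default "human").
#' @return data.table: site_id, lca (node label or special value).
#' @export
emergenceLca <- function(calls, tree, human = "human") {
  calls <- as.data.table(calls)
  groups <- setdiff(tree$tip.label, human)
  if (!human %in% tree$tip.label) stop("tree must contain the focal species")
  missing <- setdiff(unique(calls$group), groups)
  if (length(missing)) stop("tree missing group(s): ",
                            paste(missing, collapse = ", "))
  # order groups near -> distant by the depth of their MRCA with human
  depth <- ape::node.depth.edgelength(tree)
  mrca <- vapply(groups, function(g) ape::getMRCA(tree, c(human, g)), integer(1))
  ord <- groups[order(depth[mrca], decreasing = TRUE)]   # nearest first
  nodeLabel <- function(node) {
    lbl <- if (!is.null(tree$node.label)) {
      tree$node.label[node - length(tree$tip.label)]
    } else ""
    if (is.na(lbl) || lbl == "") paste0("node", node) else lbl
  }
  out <- calls[, {
    st <- setNames(status, group)[ord]
    st[is.na(st)] <- "indeterminate"
    consIdx <- which(st == "conserved")
    if (!length(consIdx)) {
      lca <- if (st[1L] == "non_conserved") "human_specific_candidate"
             else "unresolved"
    } else {
      gStar <- max(consIdx)
      if (gStar == length(ord)) {               # conserved out to the root
        lca <- nodeLabel(ape::getMRCA(tree, c(human, ord[gStar])))
      } else if (st[gStar + 1L] == "non_conserved") {
        lca <- nodeLabel(ape::getMRCA(tree, c(human, ord[gStar])))
      } else {
        lca <- "unresolved"
      }
    }
    .(lca = lca)
  }, by = site_id]
  out[]
}

#' Count potential synonymous and nonsynonymous editing sites
#'
#' Classifies every sense-strand CDS adenosine by the consequence of its
#' A-to-G substitution under the standard genetic code, using the longest
#' coding transcript per gene. A stop codon is treated as a 21st amino acid:
#' edits retaining the stop are synonymous, stop-loss edits nonsynonymous.
#' Transcripts whose CDS length is not a multiple of 3 are skipped with a
#' warning.
#'
#' @param ref a \linkS4class{ReferenceBundle}, or NULL when \code{genome} and
#'   \code{exons} are given.
#' @param genome,exons explicit genome (\code{DNAStringSet}) and exon
#'   annotation (\code{GRanges}).
#' @return A list: \code{S} and \code{N} (potential synonymous /
#'   nonsynonymous counts) and \code{table} (one row per CDS adenosine:
#'   gene_id, chrom, pos, mrna_pos, codon, codon_pos, ref_aa, alt_aa, class,
#'   context -- coding-strand trinucleotide).
#' @export
countPotentialSites <- function(ref = NULL, genome = refGenome(ref),
                                exons = refExons(ref)) {
  posTab <- as.data.table(cdsPositions(genome, exons))
  # longest coding transcript per gene: with one transcript per gene this is
  # the identity; kept explicit for multi-transcript annotations
  lens <- posTab[, .N, by = gene_id]
  rows <- list()
  gc <- Biostrings::GENETIC_CODE
  for (g in lens$gene_id) {
    sub <- posTab[gene_id == g][order(mrna_pos)]
    n <- nrow(sub)
    if (n %% 3L != 0L) {
      warning("CDS length of ", g, " is not a multiple of 3; skipped")
      next
    }
    seq <- sub$ref
    if (sub$strand[1L] == "-") seq <- compBase(seq)   # coding-strand bases
    isA <- which(seq == "A")
    if (!length(isA)) next
    codonIdx <- (isA - 1L) %/% 3L
    codonPos <- (isA - 1L) %% 3L + 1L
    codon <- vapply(codonIdx, function(ci)
      paste(seq[ci * 3L + 1:3], collapse = ""), character(1))
    edited <- codon
    substr(edited, codonPos, codonPos) <- "G"
    refAA <- unname(gc[codon]); altAA <- unname(gc[edited])
    ctx <- paste0(c("", seq)[isA], seq[isA], c(seq[-1L], "")[isA])
    rows[[g]] <- data.table(
      gene_id = g, chrom = sub$chrom[isA], pos = sub$pos[isA],
      mrna_pos = sub$mrna_pos[isA], codon = codon, codon_pos = codonPos,
      ref_aa = refAA, alt_aa = altAA,
      class = ifelse(refAA == altAA, "synonymous", "nonsynonymous"),
      context = ctx)
  }
  tab <- rbindlist(rows)
  list(S = sum(tab$class == "synonymous"),
       N = sum(tab$class == "nonsynonymous"),
       table = tab[])
}

#' Relative incidence of nonsynonymous vs synonymous editing
#'
#' Computes \eqn{f_N / f_S}, the per-potential-site incidence of called
#' nonsynonymous editing relative to synonymous editing, with a
#' randomization p-value built from R random site sets of the same size drawn
#' from the potential-site table matched on chromosome and coding-strand
#' trinucleotide context (sampling with replacement within each stratum).
#' The p-value is one-sided: the fraction of null ratios greater than or
#' equal to the observed one.
#'
#' @param called data.frame of called sites with chrom, pos.
#' @param potential the \code{table} component of [countPotentialSites()].
#' @param R number of randomization replicates (default 1e4).
#' @return A list: fS, fN, ratio, p, nullRatios.
#' @export
incidenceRatio <- function(called, potential, R = 1e4) {
  called <- as.data.table(called)
  potential <- as.data.table(potential)
  idx <- match(paste(called$chrom, called$pos),
               paste(potential$chrom, potential$pos))
  if (anyNA(idx)) stop("called site not present in the potential-site table")
  obs <- potential[idx]
  nS <- sum(potential$class == "synonymous")
  nN <- sum(potential$class == "nonsynonymous")
  fS <- sum(obs$class == "synonymous") / nS
  fN <- sum(obs$class == "nonsynonymous") / nN
  if (fS == 0) {
    return(list(fS = fS, fN = fN, ratio = NA_real_, p = NA_real_,
                nullRatios = numeric(0)))
  }
  ratio <- fN / fS
  # stratified null draws: for each called site, a random potential site
  # from the same (chrom, context) stratum
  potential[, stratum := paste(chrom, context)]
  obs[, stratum := paste(chrom, context)]
  pools <- split(potential$class == "nonsynonymous", potential$stratum)
  nullRatios <- numeric(R)
  strata <- table(obs$stratum)
  draws <- lapply(names(strata), function(s) {
    pool <- pools[[s]]
    matrix(sample(pool, strata[[s]] * R, replace = TRUE), nrow = R)
  })
  nonsyn <- Reduce(`+`, lapply(draws, function(m) rowSums(m)))
  syn <- length(idx) - nonsyn
  nullRatios <- (nonsyn / nN) / pmax(syn / nS, .Machine$double.xmin)
  nullRatios[syn == 0] <- Inf
  p <- mean(nullRatios >= ratio)
  list(fS = fS, fN = fN, ratio = ratio, p = p, nullRatios = nullRatios)
}

#' Human-specific editing-site call
#'
#' A site is a human-specific candidate when either (i) the reconstructed
#' ancestral Hominin nucleotide at the position is not an adenosine (so the
#' site could not have been edited ancestrally), or (ii) the site is edited
#' above \code{minLevel} in both cerebellum and cortex while non-conserved
#' in the nearest nonhuman group and in at least one of the two next groups.
#' The two criteria combine with OR.
#'
#' @param ancestralBase reconstructed ancestral nucleotide ("A", "C", "G",
#'   "T" or NA when unavailable).
#' @param levelCerebellum,levelCortex human editing levels in the two
#'   tissues.
#' @param statusHomininae,statusCercopithecinae,statusNonCatarrhini
#'   conservation status of the nearest three group levels (values of
#'   [conservationCall()]).
#' @param minLevel tissue-level threshold for criterion (ii) (default 0.02).
#' @return Logical.
#' @export
humanSpecific <- function(ancestralBase, levelCerebellum, levelCortex,
                          statusHomininae, statusCercopithecinae,
                          statusNonCatarrhini, minLevel = 0.02) {
  critI <- !is.na(ancestralBase) & ancestralBase != "A"
  critII <- !is.na(levelCerebellum) & !is.na(levelCortex) &
    levelCerebellum > minLevel & levelCortex > minLevel &
    statusHomininae == "non_conserved" &
    (statusCercopithecinae == "non_conserved" |
       statusNonCatarrhini == "non_conserved")
  critI | critII
}

#' Restorative/diversifying classification of a recoding site
#'
#' @param codon reference codon (coding strand).
#' @param codonPos position of the edited adenosine within the codon (1-3).
#' @param ancestralAAs character vector of amino acids observed at the
#'   homologous position in the reconstructed ancestral proteins (may be
#'   empty).
#' @return One of "synonymous", "restorative", "diversifying",
#'   "unclassified".
#' @examples
#' classifyRestorative("AAG", 2, c("R", "K"))  # Lys->Arg, Arg ancestral
#' classifyRestorative("AAA", 3, character(0)) # synonymous
#' @export
classifyRestorative <- function(codon, codonPos, ancestralAAs) {
  gc <- Biostrings::GENETIC_CODE
  if (substr(codon, codonPos, codonPos) != "A") {
    stop("edited position is not an adenosine")
  }
  edited <- codon
  substr(edited, codonPos, codonPos) <- "G"
  refAA <- unname(gc[codon]); altAA <- unname(gc[edited])
  if (refAA == altAA) return("synonymous")
  if (!length(ancestralAAs)) return("unclassified")
  if (altAA %in% ancestralAAs) "restorative" else "diversifying"
}

#' Search for an editing complementary sequence (ECS)
#'
#' Takes the 41 bp genomic sequence flanking the editing site (20 bp each
#' side; truncated and flagged near contig ends) and scans a window around
#' the site for reversely oriented complementary hits, by exact k-mer seeding
#' of the reverse complement followed by ungapped evaluation. Hits of length
#' at least \code{minLen} and identity at least \code{minIdentity} are
#' classified by location: inside the transcript, within
#' \code{downstreamLimit} bp downstream of it, or rejected. The free energy
#' of the longest located hit is computed by \code{foldFn(query, subject)};
#' a missing function, no hit, or a positive energy yields 0.
#'
#' @param genome a \code{DNAStringSet}.
#' @param chrom,pos the editing site.
#' @param txStart,txEnd,txStrand transcript span and strand of the host gene.
#' @param flank half-width of the query (default 20).
#' @param window search half-width around the site (default 10000).
#' @param minLen,minIdentity hit thresholds (defaults 30 and 0.70).
#' @param downstreamLimit allowed downstream extension (default 5000).
#' @param k seed size (default 8).
#' @param foldFn optional function(query, subject) returning a free energy.
#' @return A list: \code{hits} (data.table: start, end, length, identity,
#'   location), \code{dG}, and \code{truncated} (query clipped at a contig
#'   end).
#' @export
ecsSearch <- function(genome, chrom, pos, txStart, txEnd, txStrand = "+",
                      flank = 20L, window = 10000L, minLen = 30L,
                      minIdentity = 0.70, downstreamLimit = 5000L, k = 8L,
                      foldFn = NULL) {
  chromLen <- Biostrings::width(genome[names(genome) == chrom])
  qs <- max(1L, pos - flank); qe <- min(chromLen, pos + flank)
  truncated <- (qe - qs + 1L) < (2L * flank + 1L)
  q <- strsplit(as.character(
    Biostrings::subseq(genome[[chrom]], qs, qe)), "")[[1]]
  ws <- max(1L, pos - window); we <- min(chromLen, pos + window)
  s <- strsplit(as.character(
    Biostrings::subseq(genome[[chrom]], ws, we)), "")[[1]]

  qrc <- rev(compBase(q))
  len <- length(q)
  # exact k-mer seeds of the reverse-complemented query within the window
  sStr <- paste(s, collapse = "")
  starts <- integer(0)
  for (o in seq(1L, len - k + 1L)) {
    seed <- paste(qrc[o:(o + k - 1L)], collapse = "")
    hit <- gregexpr(seed, sStr, fixed = TRUE)[[1]]
    if (hit[1L] == -1L) next
    starts <- c(starts, as.integer(hit) - o + 1L)
  }
  starts <- unique(starts)
  hits <- list()
  for (st in starts) {
    if (st < 1L || st + len - 1L > length(s)) next
    seg <- bestSegment(qrc == s[st:(st + len - 1L)], minLen, minIdentity)
    if (is.null(seg)) next
    hs <- ws + st + seg$from - 2L
    he <- ws + st + seg$to - 2L
    if (he >= qs && hs <= qe) next       # the site's own locus
    loc <- if (hs >= txStart && he <= txEnd) {
      "same_transcript"
    } else if (txStrand == "+" && hs > txEnd && hs <= txEnd + downstreamLimit) {
      "downstream_5kb"
    } else if (txStrand == "-" && he < txStart && he >= txStart - downstreamLimit) {
      "downstream_5kb"
    } else "rejected"
    hits[[length(hits) + 1L]] <- data.table(
      start = hs, end = he, length = he - hs + 1L,
      identity = seg$identity, location = loc)
  }
  hits <- if (length(hits)) unique(rbindlist(hits)) else
    data.table(start = integer(), end = integer(), length = integer(),
               identity = numeric(), location = character())
  dG <- 0
  located <- hits[location != "rejected"]
  if (nrow(located) && !is.null(foldFn)) {
    top <- located[which.max(length)]
    subject <- as.character(Biostrings::subseq(genome[[chrom]], top$start,
                                               top$end))
    val <- foldFn(paste(q, collapse = ""), subject)
    if (is.finite(val) && val < 0) dG <- val
  }
  list(hits = hits[], dG = dG, truncated = truncated)
}
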