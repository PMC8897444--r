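# Proteomic support: in-silico tryptic digestion, construction of
# edited-vs-genomic distinguishing peptide databases from recoding sites, and
# the peptide-evidence enrichment test.

#' In-silico tryptic digestion
#'
#' Cleaves after K or R, suppressed before P (configurable); emits all
#' contiguous concatenations of up to \code{maxMissed + 1} fragments. At zero
#' missed cleavages the fragments partition the protein exactly.
#'
#' @param protein amino-acid sequence (a trailing stop "*" is stripped).
#' @param maxMissed maximal missed cleavages (default 2).
#' @param prolineRule suppress cleavage before proline (default TRUE).
#' @return data.table: peptide, start, end (1-based residue coordinates),
#'   missed.
#' @examples
#' trypticDigest("MKRPAK", maxMissed = 0)$peptide  # "MK", "RPAK"
#' @export
trypticDigest <- function(protein, maxMissed = 2L, prolineRule = TRUE) {
  protein <- sub("\\*$", "", protein)
  n <- nchar(protein)
  if (n == 0L) {
    return(data.table(peptide = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  aa <- strsplit(protein, "")[[1]]
  cut <- which(aa %in% c("K", "R"))
  if (prolineRule) cut <- cut[!(cut < n & aa[cut + 1L] == "P")]
  cut <- cut[cut < n]
  bounds <- c(0L, cut, n)                       # fragment i = (bounds[i]+1) .. bounds[i+1]
  nf <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nf)) {
    for (m in 0:min(maxMissed, nf - i)) {
      st <- bounds[i] + 1L; en <- bounds[i + 1L + m]
      rows[[length(rows) + 1L]] <- data.table(
        peptide = substr(protein, st, en), start = st, end = en, missed = m)
    }
  }
  rbindlist(rows)
}

#' Build an edited-peptide database for recoding sites
#'
#' For each protein, enumerates all combinations of edited and non-edited
#' states of its sites (capped at \code{maxSitesPerProtein} strongest sites;
#' 2^s variants), translates each variant CDS, digests it, and marks each
#' peptide as \code{edited_only}, \code{genomic_only} or \code{shared} by
#' exact sequence comparison across the variant proteomes. Editing-created or
#' -destroyed K/R change the cleavage pattern naturally. Edits turning a
#' codon into a stop are dropped; edits removing a stop are dropped as well
#' (stop losses are not modeled) -- both controlled by \code{dropStopGain}
#' and \code{dropStopLoss}.
#'
#' @param cds named character vector of coding sequences (one per protein,
#'   length divisible by 3).
#' @param sites data.frame: protein (name in \code{cds}), cds_pos (1-based
#'   position of the edited adenosine within the CDS), and optionally
#'   \code{level} used for strongest-site truncation.
#' @param maxMissed maximal missed cleavages (default 2).
#' @param maxSitesPerProtein cap on combinatorial enumeration (default 12).
#' @param dropStopGain,dropStopLoss stop-handling conventions (default TRUE).
#' @return data.table: protein, peptide, class, n_sites_covered, states
#'   (site-state vector of the generating variant, e.g. "101").
#' @export
buildEditedDb <- function(cds, sites, maxMissed = 2L,
                          maxSitesPerProtein = 12L,
                          dropStopGain = TRUE, dropStopLoss = TRUE) {
  sites <- as.data.table(sites)
  out <- list()
  for (prot in names(cds)) {
    seqStr <- cds[[prot]]
    if (nchar(seqStr) %% 3L != 0L) stop("CDS of ", prot,
                                        " is not a multiple of 3")
    ss <- sites[protein == prot]
    ps <- ss$cds_pos
    if (length(ps) > maxSitesPerProtein) {
      ord <- order(-(ss$level %||% rep(0, nrow(ss))))
      ps <- ps[ord][seq_len(maxSitesPerProtein)]
      warning(prot, ": ", nrow(ss), " sites truncated to the ",
              maxSitesPerProtein, " strongest")
    }
    ps <- sort(ps)
    base <- strsplit(seqStr, "")[[1]]
    if (length(ps) && any(base[ps] != "A")) stop("site is not an adenosine")
    # drop edits whose codon becomes a stop / whose codon is a stop
    keep <- rep(TRUE, length(ps))
    for (j in seq_along(ps)) {
      ci <- (ps[j] - 1L) %/% 3L
      codon <- paste(base[ci * 3L + 1:3], collapse = "")
      ed <- codon
      substr(ed, (ps[j] - 1L) %% 3L + 1L, (ps[j] - 1L) %% 3L + 1L) <- "G"
      gc <- Biostrings::GENETIC_CODE
      if (dropStopGain && gc[[ed]] == "*" && gc[[codon]] != "*") keep[j] <- FALSE
      if (dropStopLoss && gc[[codon]] == "*" && gc[[ed]] != "*") keep[j] <- FALSE
    }
    ps <- ps[keep]
    s <- length(ps)
    states <- expand.grid(rep(list(c(0L, 1L)), s))
    pepByState <- list()
    for (r in seq_len(max(nrow(states), 1L))) {
      v <- if (s) as.integer(states[r, ]) else integer(0)
      chars <- base
      chars[ps[v == 1L]] <- "G"
      protSeq <- translateCds(paste(chars, collapse = ""))
      dig <- trypticDigest(protSeq, maxMissed = maxMissed)
      key <- paste(v, collapse = "")
      pepByState[[key]] <- unique(dig$peptide)
    }
    allStates <- names(pepByState)
    genomicKey <- paste(rep(0L, s), collapse = "")
    genomicSet <- pepByState[[genomicKey]]
    editedSets <- pepByState[setdiff(allStates, genomicKey)]
    editedAll <- unique(unlist(editedSets))
    for (key in allStates) {
      peps <- pepByState[[key]]
      cls <- if (key == genomicKey) {
        ifelse(peps %in% editedAll, "shared", "genomic_only")
      } else {
        ifelse(peps %in% genomicSet, "shared", "edited_only")
      }
      out[[length(out) + 1L]] <- data.table(
        protein = prot, peptide = peps, class = cls, states = key,
        n_sites_covered = s)
    }
  }
  db <- rbindlist(out)
  unique(db, by = c("protein", "peptide", "class", "states"))
}

translateCds <- function(cdsStr) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cdsStr) %/% 3L
  codons <- substring(cdsStr, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(gc[codons])
  # translation stops at an internal stop codon
  stopAt <- which(aa == "*")
  if (length(stopAt)) aa <- aa[seq_len(stopAt[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Peptide-evidence enrichment test
#'
#' Two-tailed exact test comparing the fraction of sites with edited-peptide
#' support between a test and a control site set. The default table follows
#' the reported construction [supported, covered] per stratum; the
#' \code{"complement"} margins give the textbook [supported, unsupported]
#' form (both agree except for extreme tables).
#'
#' @param k1,n1 supported and covered site counts in the test stratum.
#' @param k2,n2 same for the control stratum.
#' @param margins "covered" (default) or "complement".
#' @return The two-tailed exact p-value.
#' @examples
#' evidenceEnrichment(11, 17, 18, 158)   # 0.00032
#' evidenceEnrichment(13, 89, 18, 158)   # 0.56
#' @export
evidenceEnrichment <- function(k1, n1, k2, n2,
                               margins = c("covered", "complement")) {
  margins <- match.arg(margins)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  if (k1 > n1 || k2 > n2) stop("supported count exceeds covered count")
  m <- if (margins == "covered") {
    matrix(c(k1, n1, k2, n2), nrow = 2, byrow = TRUE)
  } else {
    matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  }
  fisher.test(m)$p.value
}
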