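# File formats: FASTA via Biostrings, BED-style interval tables, TSV schemas
# for evidence / site / truth tables, Newick trees via ape. Site tables are
# 1-based (VCF-like); BED exports are 0-based half-open.

#' Write and read the reference genome as FASTA
#'
#' @param genome a \code{DNAStringSet}.
#' @param file path.
#' @return \code{readGenomeFasta} returns a \code{DNAStringSet}.
#' @export
writeGenomeFasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome, file)
  invisible(file)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(file) {
  Biostrings::readDNAStringSet(file)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr a \code{GRanges}; a \code{name} column is taken from the first
#'   metadata column when present.
#' @param file path.
#' @export
writeBed <- function(gr, file) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = if (ncol(mcols(gr))) as.character(mcols(gr)[[1]]) else ".",
    score = 0L,
    strand = as.character(strand(gr)))
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file into GRanges
#'
#' Validates coordinates and reports the offending line on error.
#'
#' @param file path.
#' @return A \code{GRanges}; the 4th BED column becomes a \code{name}
#'   metadata column.
#' @export
readBed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t")
  nf <- vapply(f, length, integer(1))
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  }
  start0 <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
  if (length(bad)) stop("malformed BED line ", bad[1], ": end <= start")
  gr <- GRanges(vapply(f, `[[`, character(1), 1L),
                IRanges(start0 + 1L, end0),
                strand = ifelse(nf >= 6L,
                                vapply(f, function(x) x[6], character(1)), "*"))
  mcols(gr)$name <- ifelse(nf >= 4L,
                           vapply(f, function(x) x[4], character(1)), ".")
  gr
}

# generic schema-checked TSV reader
readTsvSchema <- function(file, required, what) {
  df <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " file ", file, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  as.data.table(df)
}

#' Write and read evidence tables
#'
#' The evidence schema: sample, donor, tissue, chrom, pos (1-based), origin,
#' ref, and per-alignment-strand base counts A_plus..T_minus.
#'
#' @param evidence data.frame in the evidence schema.
#' @param file path.
#' @export
writeEvidence <- function(evidence, file) {
  write.table(evidence, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeEvidence
#' @export
readEvidence <- function(file) {
  req <- c("sample", "donor", "tissue", "chrom", "pos", "origin", "ref",
           paste(BASES, "plus", sep = "_"), paste(BASES, "minus", sep = "_"))
  ev <- readTsvSchema(file, req, "evidence")
  setkey(ev, chrom, pos)
  ev[]
}

#' Write and read called-site tables
#'
#' @param sites site table of a \linkS4class{PipelineResult}.
#' @param file path.
#' @export
writeSiteTable <- function(sites, file) {
  write.table(sites, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(file) {
  readTsvSchema(file, c("chrom", "pos", "strand", "type"), "site table")
}

#' Write and read truth tables
#'
#' @param truth truth table of an \linkS4class{EditingCohort}.
#' @param file path.
#' @export
writeTruthTable <- function(truth, file) {
  write.table(truth, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(file) {
  readTsvSchema(file, c("site_id", "class", "chrom", "pos"), "truth table")
}

#' Read a species tree in Newick format
#'
#' @param file path to a Newick file.
#' @return An \code{ape} phylo object; errors when tip labels are missing.
#' @export
readSpeciesTree <- function(file) {
  tree <- ape::read.tree(file)
  if (is.null(tree)) stop("could not parse Newick file ", file)
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == "")) {
    stop("Newick tree has a missing tip label")
  }
  tree
}
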