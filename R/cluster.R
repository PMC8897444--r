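# Mixed-type mismatch cluster filter: candidate sites are mapped to mature
# mRNA coordinates (longest coding transcript per gene), pairs of sites at a
# distance <= maxGap are joined iteratively (single-linkage transitive
# closure), and any cluster containing more than one substitution type is
# discarded entirely.

#' Map genomic sites to mRNA coordinates
#'
#' Uses, per gene, the longest coding transcript (in this annotation each
#' gene has one transcript; when several are present the one with the largest
#' summed exon width wins). Positions are 1-based along the spliced transcript
#' in gene orientation.
#'
#' @param ref a \linkS4class{ReferenceBundle}.
#' @param chrom,pos site coordinates.
#' @return A data.frame with gene_id and mrna_pos; error if a site is not on
#'   any transcript.
#' @export
mapToMrna <- function(ref, chrom, pos) {
  tab <- cdsPositions(ref@genome, ref@exons)
  idx <- match(paste(chrom, pos), paste(tab$chrom, tab$pos))
  if (anyNA(idx)) {
    stop("site not on any transcript: ",
         paste(head(paste0(chrom, ":", pos)[is.na(idx)], 3), collapse = ", "))
  }
  data.frame(gene_id = tab$gene_id[idx], mrna_pos = tab$mrna_pos[idx])
}

#' Mixed-type mismatch cluster filter
#'
#' @param gene_id,mrna_pos,type per-site transcript id, mRNA coordinate and
#'   substitution type (e.g. "A>G").
#' @param maxGap maximal joining distance in mRNA coordinates (default 100).
#' @return A list with \code{keep} (logical per input site), \code{cluster}
#'   (integer cluster id per site, unique within gene) and \code{report}
#'   (data.table of clusters: gene, span, size, n_types, discarded).
#' @examples
#' clusterFilter(rep("g", 3), c(100, 150, 260), c("A>G", "A>G", "C>A"))$keep
#' clusterFilter(rep("g", 2), c(100, 180), c("A>G", "C>A"))$keep
#' @export
clusterFilter <- function(gene_id, mrna_pos, type, maxGap = 100L) {
  n <- length(mrna_pos)
  stopifnot(length(gene_id) == n, length(type) == n)
  dt <- data.table(i = seq_len(n), gene_id = gene_id,
                   mrna_pos = as.integer(mrna_pos), type = type)
  setorder(dt, gene_id, mrna_pos)
  # on a line, single-linkage closure of the <= maxGap relation is the
  # consecutive-gap rule
  dt[, newc := c(TRUE, diff(mrna_pos) > maxGap), by = gene_id]
  dt[, cluster := cumsum(newc), by = gene_id]
  dt[, n_types := data.table::uniqueN(type), by = .(gene_id, cluster)]
  dt[, keep := n_types == 1L]
  report <- dt[, .(span_start = min(mrna_pos), span_end = max(mrna_pos),
                   size = .N, n_types = n_types[1L],
                   discarded = n_types[1L] > 1L), by = .(gene_id, cluster)]
  setorder(dt, i)
  list(keep = dt$keep, cluster = dt$cluster, report = report)
}
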