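# Conservation calling, emergence placement, codon consequences,
# incidence-ratio randomization, restorative classification, and ECS search.

test_that("conservation calls follow the FDR and coverage rules", {
  counts <- data.frame(
    site_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    group = "Glires",
    category = rep(c("brain", "non-brain"), 3),
    edited = c(0, 0, 50, 40, 0, 0),
    coverage = c(1000, 800, 1000, 900, 300, 250))
  cc <- conservationCall(counts)
  expect_equal(cc[cc$site_id == "s1", ]$status, "non_conserved")
  expect_equal(cc[cc$site_id == "s2", ]$status, "conserved")
  expect_equal(cc[cc$site_id == "s3", ]$status, "indeterminate")
  expect_error(conservationCall(counts, groups = "Laurasiatheria"), "unknown")
})

test_that("conservation is monotone in evidence at fixed coverage", {
  status_at <- function(e) {
    cc <- conservationCall(data.frame(site_id = "s", group = "g",
                                      category = "brain", edited = e,
                                      coverage = 1000))
    cc$status
  }
  st <- vapply(c(0, 1, 2, 5, 10, 20, 50, 100), status_at, character(1))
  ranks <- c(non_conserved = 0, indeterminate = 1, conserved = 2)
  expect_true(all(diff(ranks[st]) >= 0))
})

test_that("emergence LCA follows the outgroup rule on a toy tree", {
  tree <- ape::read.tree(text = paste0(
    "(((human:1,Homininae:1)HomininaeAnc:1,Cercopithecinae:2)CatarrhiniAnc:1,",
    "Glires:3)MammalAnc;"))
  calls <- function(...) {
    st <- c(...)
    data.frame(site_id = "s", group = names(st), status = unname(st))
  }
  # conserved only in the nearest group, outgroup non-conserved
  r1 <- emergenceLca(calls(Homininae = "conserved",
                           Cercopithecinae = "non_conserved",
                           Glires = "non_conserved"), tree)
  expect_equal(r1$lca, "HomininaeAnc")
  # conserved in all groups: the root
  r2 <- emergenceLca(calls(Homininae = "conserved",
                           Cercopithecinae = "conserved",
                           Glires = "conserved"), tree)
  expect_equal(r2$lca, "MammalAnc")
  # nothing conserved, nearest group non-conserved: human-specific candidate
  r3 <- emergenceLca(calls(Homininae = "non_conserved",
                           Cercopithecinae = "indeterminate",
                           Glires = "indeterminate"), tree)
  expect_equal(r3$lca, "human_specific_candidate")
  # indeterminate outgroup blocks the assignment
  r4 <- emergenceLca(calls(Homininae = "conserved",
                           Cercopithecinae = "indeterminate",
                           Glires = "non_conserved"), tree)
  expect_equal(r4$lca, "unresolved")
  expect_error(emergenceLca(calls(Unknown = "conserved"), tree), "missing")
})

test_that("codon consequences match the exhaustive 64 x 3 oracle", {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # one long CDS containing all 64 codons
  cdsSeq <- paste(codons, collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 100), cdsSeq, strrep("C", 100))))
  exons <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(101, 100 + nchar(cdsSeq)),
                                  strand = "+", gene_id = "g", exon_rank = 1L)
  got <- countPotentialSites(genome = genome, exons = exons)
  # oracle: translate original and edited codons with Biostrings
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  expS <- 0L; expN <- 0L
  for (cd in codons) {
    for (i in 1:3) {
      if (substr(cd, i, i) != "A") next
      ed <- cd; substr(ed, i, i) <- "G"
      if (tr(cd) == tr(ed)) expS <- expS + 1L else expN <- expN + 1L
    }
  }
  expect_equal(got$S, expS)
  expect_equal(got$N, expN)
  # the documented single-codon examples
  aaa <- got$table[got$table$codon == "AAA", ]
  expect_equal(sort(aaa[aaa$class == "nonsynonymous", ]$codon_pos), c(1, 2))
  expect_equal(aaa[aaa$class == "synonymous", ]$codon_pos, 3)
  taa2 <- got$table[got$table$codon == "TAA" & got$table$codon_pos == 2, ]
  expect_equal(taa2$class, "synonymous")    # TGA stays a stop
})

test_that("consequence counting uses the coding strand on minus genes", {
  # minus-strand gene: coding sequence is the reverse complement
  cds <- "AAATTTGGG"   # K F G on the coding strand
  genomeSeq <- paste0(strrep("C", 50),
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(cds))), strrep("C", 50))
  genome <- Biostrings::DNAStringSet(c(chr1 = genomeSeq))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 59),
                                  strand = "-", gene_id = "g", exon_rank = 1L)
  got <- countPotentialSites(genome = genome, exons = exons)
  expect_equal(nrow(got$table), 3L)   # the three As of the AAA codon
  expect_equal(got$S, 1L)
  expect_equal(got$N, 2L)
})

test_that("incidence ratio is near 1 with uniform calls and recovers enrichment", {
  bases <- c("A", "C", "G", "T")
  set.seed(77)
  cdsSeq <- paste(sample(bases, 3000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 10), cdsSeq, strrep("C", 10))))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 3010),
                                  strand = "+", gene_id = "g", exon_rank = 1L)
  pot <- countPotentialSites(genome = genome, exons = exons)
  # uniform draws: ratio near 1, randomization p moderate
  called <- pot$table[sample(nrow(pot$table), 200), ]
  r <- incidenceRatio(called, pot$table, R = 500)
  expect_equal(r$ratio, 1, tolerance = 0.35)
  expect_gt(r$p, 0.01)
  # all-synonymous calls: ratio 0
  syn <- pot$table[pot$table$class == "synonymous", ][1:50, ]
  expect_equal(incidenceRatio(syn, pot$table, R = 50)$ratio, 0)
  # planted 2x relative enrichment of nonsynonymous calls
  tabS <- pot$table[pot$table$class == "synonymous", ]
  tabN <- pot$table[pot$table$class == "nonsynonymous", ]
  called2 <- rbind(tabN[sample(nrow(tabN), 160), ],
                   tabS[sample(nrow(tabS), round(80 * nrow(tabS) / nrow(tabN))), ])
  r2 <- incidenceRatio(called2, pot$table, R = 2000)
  expect_equal(r2$ratio, 2, tolerance = 0.35)
  expect_lt(r2$p, 0.05)
})

test_that("human-specific calls combine the two criteria with OR", {
  # criterion (i): non-adenosine ancestral base suffices on its own
  expect_true(humanSpecific("G", 0.001, 0.001, "conserved", "conserved",
                            "conserved"))
  # criterion (ii): >2% in both tissues, nearest group non-conserved and one
  # of the next two non-conserved
  expect_true(humanSpecific("A", 0.05, 0.03, "non_conserved",
                            "non_conserved", "indeterminate"))
  expect_true(humanSpecific("A", 0.05, 0.03, "non_conserved",
                            "indeterminate", "non_conserved"))
  expect_false(humanSpecific("A", 0.05, 0.03, "non_conserved",
                             "indeterminate", "indeterminate"))
  expect_false(humanSpecific("A", 0.05, 0.015, "non_conserved",
                             "non_conserved", "non_conserved"))
  expect_false(humanSpecific("A", 0.05, 0.03, "conserved",
                             "non_conserved", "non_conserved"))
})

test_that("restorative classification follows the ancestral amino-acid rule", {
  expect_equal(classifyRestorative("AAG", 2, c("R", "K")), "restorative")
  expect_equal(classifyRestorative("AAA", 3, c("Q")), "synonymous")
  expect_equal(classifyRestorative("AAG", 2, c("K", "Q")), "diversifying")
  expect_equal(classifyRestorative("AAG", 2, character(0)), "unclassified")
  expect_error(classifyRestorative("CCG", 2, "R"), "adenosine")
})

test_that("ECS search finds planted reverse-complement partners by location", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  flank41 <- paste(sample(bases, 41, replace = TRUE), collapse = "")
  rcHit <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(flank41, 1, 40))))
  # ~90% identity: mutate 4 of 40 positions
  rcv <- strsplit(rcHit, "")[[1]]
  at <- c(5, 15, 25, 35)
  rcv[at] <- vapply(rcv[at], function(b) setdiff(bases, b)[1], character(1))
  rcHit90 <- paste(rcv, collapse = "")
  mkGenome <- function(offset) {
    pre <- paste(sample(bases, 5000, replace = TRUE), collapse = "")
    post <- paste(sample(bases, 12000, replace = TRUE), collapse = "")
    s <- paste0(pre, flank41, post)
    # plant the partner `offset` bp downstream of the site
    sitePos <- 5000 + 21
    substr(s, sitePos + offset, sitePos + offset + 39) <- rcHit90
    Biostrings::DNAStringSet(c(chr1 = s))
  }
  g1 <- mkGenome(2000)
  r1 <- ecsSearch(g1, "chr1", 5021, txStart = 4800, txEnd = 5600)
  expect_true(any(r1$hits$location == "downstream_5kb" |
                    r1$hits$location == "same_transcript"))
  expect_gte(max(r1$hits$identity), 0.85)
  # the same partner 6 kb beyond the transcript end is rejected
  g2 <- mkGenome(6500)
  r2 <- ecsSearch(g2, "chr1", 5021, txStart = 4800, txEnd = 5100)
  expect_true(all(r2$hits$location == "rejected"))
  # no complementary sequence: empty hits, dG = 0
  g3 <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 12000)))
  r3 <- ecsSearch(g3, "chr1", 6000, txStart = 5000, txEnd = 7000)
  expect_equal(nrow(r3$hits), 0L)
  expect_equal(r3$dG, 0)
  # the injected fold function sets the free energy; positive maps to 0
  r4 <- ecsSearch(g1, "chr1", 5021, txStart = 4800, txEnd = 5600,
                  foldFn = function(q, s) -12.5)
  expect_equal(r4$dG, -12.5)
  r5 <- ecsSearch(g1, "chr1", 5021, txStart = 4800, txEnd = 5600,
                  foldFn = function(q, s) 3.2)
  expect_equal(r5$dG, 0)
  # a site near the contig end yields a truncated, flagged query
  r6 <- ecsSearch(g1, "chr1", 10, txStart = 1, txEnd = 100)
  expect_true(r6$truncated)
})
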