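# Annotation masks, the k-mer seeded homology blacklist, and the mixed-type
# cluster filter.

test_that("indel masking covers 50 bp on each side", {
  snps <- data.frame(chrom = "chr1", pos = 5, ref = "A", alt = "G",
                     freq = 0.2, class = "common")
  indels <- data.frame(chrom = "chr1", pos = 1000)
  mask <- buildMask(snps = snps, indels = indels)
  iv <- mask[mask$collection == "indel_flank"]
  expect_equal(GenomicRanges::start(iv), 950)
  expect_equal(GenomicRanges::end(iv), 1050)
  expect_true(maskSites("chr1", 950, mask))
  expect_true(maskSites("chr1", 1050, mask))
  expect_false(maskSites("chr1", 1051, mask))
})

test_that("the rare-reference-allele rule and dual-strand rule mask sites", {
  ref <- generateReference(smallConfig())
  mask <- buildMask(ref)
  rare <- as.data.frame(ref@snps)
  rare <- rare[rare$class == "rare_ref", ]
  expect_true(all(maskSites(rare$chrom, rare$pos, mask)))
  ds <- ref@dualStrand
  mid <- (GenomicRanges::start(ds) + GenomicRanges::end(ds)) %/% 2
  expect_true(maskSites(as.character(GenomicRanges::seqnames(ds)), mid, mask))
  # an empty SNP table leaves only annotation-derived collections
  m2 <- buildMask(snps = NULL, indels = NULL, repeats = ref@repeats,
                  dualStrand = ref@dualStrand)
  expect_true(all(m2$collection %in% c("Alu", "rDNA", "dual_strand")))
  # malformed interval
  expect_error(buildMask(snps = NULL, indels = data.frame(chrom = "chr1",
                                                          pos = -10)),
               "malformed")
})

test_that("masking is idempotent", {
  ref <- generateReference(smallConfig())
  mask <- buildMask(ref)
  pos <- seq(1000, 4000, by = 7)
  once <- maskSites("chr1", pos, mask)
  keep <- pos[!once]
  twice <- maskSites("chr1", keep, mask)
  expect_false(any(twice))
})

test_that("a 97%-identical paralog has all differing positions blacklisted", {
  # evenly spread mutations keep every 76 bp window above 94% identity
  set.seed(7)
  src <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  mutAt <- seq(15, 285, by = 34)                # 9 mutations over 300 bp: 97%
  cpy <- src
  cpy[mutAt] <- vapply(src[mutAt],
                       function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                       character(1))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    pad(200), paste(src, collapse = ""), pad(1500),
    paste(cpy, collapse = ""), pad(200))))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 500),
                                  strand = "+", gene_id = "g", exon_rank = 1L)
  hb <- homologyBlacklist(genome, exons)
  srcPos <- 200L + mutAt
  dstPos <- 2000L + mutAt
  found <- paste(srcPos, src[mutAt], cpy[mutAt]) %in%
    paste(hb$blacklist$pos, hb$blacklist$ref, hb$blacklist$alt)
  expect_true(all(found))
  # the reciprocal entries exist at the copy locus (count-level symmetry)
  mirrored <- paste(dstPos, cpy[mutAt], src[mutAt]) %in%
    paste(hb$blacklist$pos, hb$blacklist$ref, hb$blacklist$alt)
  expect_true(all(mirrored))
})

test_that("perfect duplicates hit without blacklist entries; short ones do not hit", {
  base <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
  dup <- substr(base, 101, 200)                 # 100 bp perfect duplicate
  short <- substr(base, 401, 460)               # 60 bp duplicate
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(base, dup, strrep("ACGTG", 40), short)))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 401),
                                                           c(200, 460)),
                                  strand = "+",
                                  gene_id = c("g1", "g2"), exon_rank = 1L)
  hb <- homologyBlacklist(genome, exons)
  dupHits <- hb$hits[hb$hits$s_start >= 4001 & hb$hits$s_chrom == "chr1"]
  expect_gt(nrow(dupHits[dupHits$length >= 61]), 0)
  expect_equal(nrow(hb$blacklist), 0L)          # no mismatched positions
  # the 60 bp copy cannot reach the minimal hit length
  expect_false(any(hb$hits$s_start >= 4301 & hb$hits$length >= 61 &
                     hb$hits$q_start >= 401 & hb$hits$q_start <= 460))
})

test_that("cluster filter reproduces the documented examples", {
  r1 <- clusterFilter(rep("g", 3), c(100, 150, 260), c("A>G", "A>G", "C>A"))
  expect_equal(r1$keep, c(TRUE, TRUE, TRUE))    # {100,150} kept, {260} kept
  expect_equal(r1$cluster, c(1, 1, 2))
  r2 <- clusterFilter(rep("g", 2), c(100, 180), c("A>G", "C>A"))
  expect_equal(r2$keep, c(FALSE, FALSE))        # one mixed cluster
  r3 <- clusterFilter("g", 500, "A>G")
  expect_true(r3$keep)
})

test_that("cluster filter equals the O(n^2) transitive-closure oracle", {
  set.seed(404)
  for (rep_ in 1:200) {
    n <- sample(2:50, 1)
    pos <- sort(sample.int(2000, n))
    type <- sample(c("A>G", "C>A", "T>C"), n, replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    got <- clusterFilter(rep("g", n), pos, type)
    oc <- oracle_clusters(pos)
    # same partition
    expect_equal(length(unique(got$cluster)), length(unique(oc)))
    expect_true(all(tapply(got$cluster, oc, function(x) length(unique(x))) == 1))
    # same mixed-type verdicts
    okeep <- ave(as.integer(factor(type)), oc,
                 FUN = function(x) length(unique(x))) == 1
    expect_equal(got$keep, okeep)
  }
})

test_that("sites not on any transcript raise an error in mRNA mapping", {
  ref <- generateReference(smallConfig())
  expect_error(mapToMrna(ref, "chr1", 1L), "not on any transcript")
  ex1 <- refExons(ref)[1]
  mp <- mapToMrna(ref, as.character(GenomicRanges::seqnames(ex1)),
                  GenomicRanges::start(ex1) + 10L)
  expect_equal(nrow(mp), 1L)
})
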