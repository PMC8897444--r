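# Read- and base-level exclusion rules, evidence aggregation, and the SAM
# round trip against the count-table simulator.

qualString <- function(q) {
  paste(vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1)),
        collapse = "")
}

makeReads <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(
      id = r$id, flag = r$flag %||% 2L, chrom = r$chrom %||% "chr1",
      pos = r$pos %||% 1L, end = (r$pos %||% 1L) + r$len - 1L,
      strand = "+", cigar = paste0(r$len, "M"),
      qual = r$qual %||% qualString(rep(40L, r$len)))
  }))
}

test_that("read-level rules discard in the documented order", {
  emptyMm <- data.table::data.table(id = character(), chrom = character(),
                                    pos = integer(), read_pos = integer(),
                                    ref = character(), obs = character(),
                                    qual = integer())
  # 100 bp with 25 bases below q20: exactly at the 25% boundary
  reads <- makeReads(list(id = "lowq", len = 100,
                          qual = qualString(c(rep(19L, 25), rep(40L, 75)))),
                     list(id = "dup", flag = 2L + 1024L, len = 100),
                     list(id = "vendor", flag = 2L + 512L, len = 100),
                     list(id = "unpaired", flag = 0L, len = 100),
                     list(id = "clean", len = 100))
  res <- filterReads(reads, emptyMm)
  expect_equal(res$reason,
               c("low_quality", "duplicate", "vendor_fail",
                 "not_proper_pair", "ok"))
  expect_equal(res$keep, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("the mismatch-excess rule needs >= 3 mismatches of > 2 types", {
  reads <- makeReads(list(id = "a", len = 100), list(id = "b", len = 100),
                     list(id = "c", len = 100))
  mm <- data.table::data.table(
    id = c(rep("a", 3), rep("b", 3), rep("c", 2)),
    chrom = "chr1", pos = 1:8, read_pos = 1:8,
    ref = c("A", "C", "G",  "A", "A", "A",  "A", "C"),
    obs = c("G", "A", "T",  "G", "G", "G",  "G", "A"),
    qual = 40L)
  res <- filterReads(reads, mm)
  # a: 3 mismatches, 3 types -> discard; b: 3 mismatches, 1 type -> keep;
  # c: 2 mismatches of 2 types -> keep
  expect_equal(res$reason, c("mismatch_excess", "ok", "ok"))
  expect_error(filterReads(data.table::data.table(
    id = "x", flag = 2L, chrom = "chr1", pos = 1L, end = 10L, strand = "+",
    cigar = "10M", qual = NA_character_), mm), "quality")
})

test_that("mismatch-level rules fire in order: ends, splice, homopolymer, quality", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("ACGT", 20), collapse = ""),   # 80 bp, no homopolymer
    "AAAAA",                                  # 81..85 homopolymer
    paste(rep("GTCA", 10), collapse = ""))))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 125),
                                  strand = "+", gene_id = "g", exon_rank = 1L)
  reads <- makeReads(list(id = "r", len = 60, pos = 11L))
  mk <- function(pos, read_pos, qual = 40L) {
    data.table::data.table(id = "r", chrom = "chr1", pos = pos,
                           read_pos = read_pos, ref = "A", obs = "G",
                           qual = qual)
  }
  mm <- rbind(mk(13L, 3L),            # 3 bp from the read 5' end
              mk(40L, 30L, qual = 29L),  # low base quality
              mk(66L, 56L),           # read_pos 56 (within 5 of end: 56 > 55)
              mk(40L, 30L))           # clean
  res <- filterMismatches(mm, reads, genome, exons = NULL)
  expect_equal(res$reason, c("read_end", "base_quality", "read_end", "ok"))

  # homopolymer adjacency: inside the run or its 1 bp flanks
  reads2 <- makeReads(list(id = "r", len = 60, pos = 56L))
  mm2 <- rbind(mk(80L, 25L), mk(86L, 31L), mk(87L, 32L))
  res2 <- filterMismatches(mm2, reads2, genome, exons = NULL)
  expect_equal(res2$reason, c("homopolymer", "homopolymer", "ok"))

  # splice proximity: within 4 bp of an exon boundary on the exonic side
  exons2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(31, 90),
                                   strand = "+", gene_id = "g", exon_rank = 1L)
  mm3 <- rbind(mk(33L, 23L), mk(40L, 30L))
  res3 <- filterMismatches(mm3, reads, genome, exons = exons2)
  expect_equal(res3$reason, c("splice", "ok"))

  expect_error(filterMismatches(mk(1e6L, 30L), reads, genome), "bounds")
})

test_that("aggregation yields one row per substitution type sharing coverage", {
  events <- data.table::data.table(
    sample = "s1", chrom = "chr1", pos = rep(100L, 5),
    ref = "A", obs = c("G", "G", "G", "T", "T"),
    strand = c("+", "-", "+", "+", "-"))
  coverage <- data.table::data.table(sample = "s1", chrom = "chr1",
                                     pos = 100L, C = 10L, C_plus = 6L)
  agg <- aggregateEvidence(events, coverage)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg[agg$type == "A>G", ]$E, 3L)
  expect_equal(agg[agg$type == "A>T", ]$E, 2L)
  expect_equal(unique(agg$C), 10L)
  # order independence
  agg2 <- aggregateEvidence(events[c(4, 2, 5, 1, 3)], coverage)
  expect_equal(agg, agg2)
  # inconsistent input
  badCov <- data.table::data.table(sample = "s1", chrom = "chr1",
                                   pos = 100L, C = 2L, C_plus = 1L)
  expect_error(aggregateEvidence(events, badCov), "inconsistent")
})

test_that("SAM emission round-trips to the simulator's count tables", {
  cohort <- simulateCohort(generateReference(samConfig()))
  samp <- cohort@evidence$sample[1]
  f <- tempfile(fileext = ".sam")
  writeCohortSam(cohort, samp, f)
  parsed <- readSam(f, refGenome(cohort@reference))
  # with all filters disabled, E and C equal the count-table evidence
  pile <- samPileup(parsed$reads, sample = samp)
  events <- parsed$mismatches
  events[, `:=`(sample = samp,
                strand = parsed$reads$strand[match(id, parsed$reads$id)])]
  agg <- aggregateEvidence(events, pile)
  ev <- cohort@evidence[sample == samp]
  for (i in seq_len(nrow(ev))) {
    for (b in setdiff(c("A", "C", "G", "T"), ev$ref[i])) {
      k <- ev[[paste0(b, "_plus")]][i] + ev[[paste0(b, "_minus")]][i]
      got <- agg[chrom == ev$chrom[i] & pos == ev$pos[i] & obs == b]
      if (k == 0L) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$E, k)
        expect_equal(got$C, pile[chrom == ev$chrom[i] & pos == ev$pos[i], C])
      }
    }
  }
})
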