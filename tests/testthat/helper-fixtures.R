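# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a small cohort exercising every planted event class
smallConfig <- function(seed = 11, stranded = FALSE) {
  simConfig(
    seed = seed, nChromosomes = 2L, chromLength = 30000L,
    nGenes = 10L, exonsPerGene = 2L, exonLength = 300L,
    nDonors = 12L, tissues = c("brain", "liver"),
    depthMean = 50, errorRate = 1e-3,
    editingLevels = c(0.05, 0.10, 0.20, 0.30),
    editingDispersion = 0.02,
    snpFreqs = c(0.1, 0.2), snpHom = c(FALSE, TRUE),
    nCommonSnps = 3L, nCommonIndels = 1L,
    paralogLength = 250L, paralogIdentity = 0.95, paralogMisFraction = 0.1,
    antisenseRatio = 0.5, antisenseLevel = 0.3, antisenseSites = 3L,
    stranded = stranded)
}

smallCohort <- function() {
  if (is.null(.fixtures$small)) {
    ref <- generateReference(smallConfig())
    .fixtures$small <- simulateCohort(ref)
  }
  .fixtures$small
}

smallPipeline <- function() {
  if (is.null(.fixtures$smallRes)) {
    .fixtures$smallRes <- suppressWarnings(runPipeline(smallCohort()))
  }
  .fixtures$smallRes
}

# a cohort without antisense intervals, for SAM emission tests
samConfig <- function() {
  simConfig(
    seed = 5, nChromosomes = 1L, chromLength = 15000L,
    nGenes = 4L, exonsPerGene = 2L, exonLength = 300L,
    nDonors = 2L, tissues = "brain", depthMean = 20,
    editingLevels = c(0.2, 0.3), snpFreqs = 0.5, snpHom = FALSE,
    nCommonSnps = 1L, nCommonIndels = 1L,
    paralogLength = integer(0), paralogIdentity = numeric(0),
    paralogMisFraction = numeric(0),
    antisenseRatio = numeric(0), antisenseLevel = numeric(0),
    antisenseSites = integer(0))
}
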