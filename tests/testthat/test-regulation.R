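# ADAR influence and specificity, the variability estimator, differential
# tests, and the multiple-testing procedures they rely on.

test_that("ADAR influence matches its closed-form special cases", {
  expect_equal(adarInfluence(0.4, 0.001, 0.4), 1)
  expect_equal(adarInfluence(0.4, 0.4, 0.001), 0)
  expect_equal(adarInfluence(0.4, 0.1, 0.1), 0.5)
  # swapping the knockouts maps I to 1 - I
  set.seed(9)
  wt <- runif(50, 0.05, 0.6); k1 <- runif(50, 0, 0.6); k2 <- runif(50, 0, 0.6)
  up <- pmax(k1, wt * 0.99)  # keep both logs non-negative so no clamping
  I1 <- adarInfluence(wt, pmin(k1, wt), pmin(k2, wt))
  I2 <- adarInfluence(wt, pmin(k2, wt), pmin(k1, wt))
  expect_equal(I1, 1 - I2, tolerance = 1e-12)
  # undefined when both logs vanish
  expect_true(is.na(adarInfluence(0.2, 0.2, 0.2)))
})

test_that("ADAR classification needs significance plus direction", {
  counts <- data.frame(
    site_id = rep(c("a2", "shared", "none"), each = 5),
    condition = rep(c("WT", "ADAR1_KO", "ADAR2_KO", "ADAR1_OE", "ADAR2_OE"), 3),
    edited = c(400, 390, 5, 420, 800,      # a2: ADAR2 KO crashes the level
               400, 100, 90, 800, 820,     # shared: both KOs drop, both OEs rise
               50, 48, 52, 49, 51),        # none: nothing moves
    coverage = 1000)
  cls <- classifyAdar(counts)
  expect_equal(cls[cls$site_id == "a2", ]$class, "ADAR2")
  expect_equal(cls[cls$site_id == "shared", ]$class, "shared")
  expect_equal(cls[cls$site_id == "none", ]$class, "unclassified")
  expect_error(classifyAdar(data.frame(site_id = "x", condition = "ADAR1_KO",
                                       edited = 1, coverage = 10)), "WT")
})

test_that("the variability estimator reproduces its hand-computed example", {
  r <- biologicalVariability(c(0.2, 0.4), c(1000, 1000))
  expect_equal(r$p, 0.3)
  expect_equal(r$cInv, 0.001)
  expect_equal(r$varE, 0.02)
  expect_equal(r$v, (0.02 - 0.001 * 0.21) / 0.999, tolerance = 1e-9)
  expect_equal(round(r$v, 6), 0.01981)
  # constant levels at high coverage: clamped to zero
  expect_equal(biologicalVariability(rep(0.25, 10), rep(2000, 10))$v, 0)
  expect_error(biologicalVariability(c(0.1, 0.2), c(1, 1)), "undefined")
})

test_that("the variability estimator recovers a planted Beta variance", {
  set.seed(123)
  vhat <- replicate(60, {
    p <- rbeta(200, 0.3 * 29, 0.7 * 29)   # mean 0.3, var ~ 0.007
    g <- rbinom(200, 500, p)
    biologicalVariability(g / 500, rep(500, 200))$v
  })
  trueVar <- 0.3 * 0.7 / 30
  expect_equal(mean(vhat), trueVar, tolerance = 0.1)   # relative, within 10%
})

test_that("paired differential honors its exclusion rules and finds shifts", {
  set.seed(5)
  mkSite <- function(id, lvN, lvT, donors = 20, cov = 200) {
    data.frame(site_id = id, donor = rep(sprintf("d%02d", 1:donors), 2),
               group = rep(c("normal", "tumor"), each = donors),
               edited = c(rbinom(donors, cov, lvN), rbinom(donors, cov, lvT)),
               coverage = cov)
  }
  dat <- rbind(mkSite("shift", 0.10, 0.25), mkSite("null", 0.10, 0.10))
  res <- pairedDifferential(dat)
  expect_true(res[res$site_id == "shift", ]$verdict)
  expect_false(res[res$site_id == "null", ]$verdict)
  # a donor with combined coverage below 40 is excluded for the site
  low <- mkSite("low", 0.2, 0.2, donors = 3, cov = 19)
  resLow <- pairedDifferential(rbind(low, mkSite("ok", 0.1, 0.3, donors = 5)))
  expect_false("low" %in% resLow$site_id)
  # sites below 0.5% pooled level in both groups are excluded
  tiny <- mkSite("tiny", 0.003, 0.004, donors = 20, cov = 2000)
  resTiny <- pairedDifferential(rbind(tiny, mkSite("ok", 0.1, 0.3)))
  expect_false("tiny" %in% resTiny$site_id)
  # a >10% difference is required even when significant
  small <- mkSite("small", 0.10, 0.16, donors = 40, cov = 2000)
  resSmall <- pairedDifferential(small)
  expect_true(resSmall$q <= 0.05 && !resSmall$verdict)
})

test_that("group differential skips small strata and detects shifts", {
  set.seed(6)
  mk <- function(id, lvA, lvB, nA = 15, nB = 15, cov = 100) {
    data.frame(site_id = id,
               donor = c(sprintf("a%02d", 1:nA), sprintf("b%02d", 1:nB)),
               group = rep(c("healthy", "diseased"), c(nA, nB)),
               edited = c(rbinom(nA, cov, lvA), rbinom(nB, cov, lvB)),
               coverage = cov)
  }
  expect_message(r0 <- groupDifferential(mk("x", 0.2, 0.4, nB = 9)),
                 "skipped")
  expect_null(r0)
  res <- groupDifferential(rbind(mk("shift", 0.15, 0.40), mk("null", 0.2, 0.2)))
  expect_true(res[res$site_id == "shift", ]$verdict)
  expect_false(res[res$site_id == "null", ]$verdict)
})

test_that("single-cell differential applies inclusion rules and both tests", {
  mkCells <- function(site, popA, popB, nCells, covA, covB, lvA, lvB) {
    rbind(
      data.frame(cell_id = sprintf("%s_a%03d", site, 1:nCells), site_id = site,
                 population = popA, coverage = covA,
                 edited = rbinom(nCells, covA, lvA)),
      data.frame(cell_id = sprintf("%s_b%03d", site, 1:nCells), site_id = site,
                 population = popB, coverage = covB,
                 edited = rbinom(nCells, covB, lvB)))
  }
  set.seed(8)
  dat <- rbind(
    mkCells("diff", "T", "B", 50, 4, 4, 0.9, 0.3),
    mkCells("same", "T", "B", 50, 4, 4, 0.5, 0.5),
    mkCells("weak", "T", "B", 50, 4, 4, 0.09, 0.05))  # below the 10% rule
  res <- singleCellDifferential(dat)
  expect_false("weak" %in% res$site_id)
  expect_true(res[res$site_id == "diff", ]$q_count <= 0.05)
  expect_gt(res[res$site_id == "same", ]$q_count, 0.05)
  # pooled 90/100 vs 60/100: the count test alone is significant
  one <- rbind(
    data.frame(cell_id = sprintf("a%02d", 1:20), site_id = "s",
               population = "T", coverage = 5, edited = c(rep(5, 10), rep(4, 10))),
    data.frame(cell_id = sprintf("b%02d", 1:20), site_id = "s",
               population = "B", coverage = 5, edited = 3))
  r1 <- singleCellDifferential(one)
  expect_equal(r1$p_count,
               fisher.test(matrix(c(90, 10, 60, 40), 2))$p.value,
               tolerance = 1e-9)
})

test_that("BH and BY adjustments equal the textbook step-up procedures", {
  p <- c(0.0001, 0.004, 0.019, 0.095, 0.201, 0.278, 0.298, 0.344, 0.459, 0.9)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  expect_equal(p.adjust(p, "BY"), oracle_by(p))
  set.seed(10)
  for (i in 1:20) {
    pv <- runif(sample(3:30, 1))
    expect_equal(p.adjust(pv, "BH"), oracle_bh(pv))
    expect_equal(p.adjust(pv, "BY"), oracle_by(pv))
  }
})
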