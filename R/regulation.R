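# ADAR specificity and influence, the biological-variability estimator
# separating binomial sampling noise from donor-to-donor variance, and
# differential-editing tests: paired tumor/normal, condition groups, and
# single-cell population pairs.

#' Relative ADAR1 influence on a site's editing level
#'
#' \eqn{I = L_1 / (L_1 + L_2)} where
#' \eqn{L_k = \log_2((wt + c) / (ko_k + c))} with pseudo-count \code{c};
#' negative values are clamped to 0, and the undefined case
#' \eqn{L_1 + L_2 = 0} returns NA.
#'
#' @param wt,adar1Ko,adar2Ko editing levels in the wild type and the two
#'   knockouts.
#' @param pseudo pseudo-count added to every level (default 0.001, as
#'   defined).
#' @return Influence in [0, 1], or NA when undefined.
#' @examples
#' adarInfluence(0.4, 0.001, 0.4)   # 1: the site is ADAR1-driven
#' adarInfluence(0.4, 0.1, 0.1)     # 0.5: symmetric
#' @export
adarInfluence <- function(wt, adar1Ko, adar2Ko, pseudo = 0.001) {
  L1 <- log2((wt + pseudo) / (adar1Ko + pseudo))
  L2 <- log2((wt + pseudo) / (adar2Ko + pseudo))
  I <- ifelse(L1 + L2 == 0, NA_real_, L1 / (L1 + L2))
  ifelse(!is.na(I) & I < 0, 0, I)
}

#' Classify a site by targeting ADAR
#'
#' Pooled replicate counts for each perturbation (ADAR1/ADAR2 overexpression
#' or knockout) are compared to the matched wild type with a two-sided exact
#' count test on edited vs non-edited reads; p-values are BH-adjusted across
#' all sites for each perturbation. A site is enzyme-specific when exactly
#' one enzyme shows a significant, direction-consistent change (up for OE,
#' down for KO); both enzymes significant and consistent gives "shared";
#' otherwise "unclassified".
#'
#' @param counts data.frame with columns site_id, condition (one of WT,
#'   ADAR1_KO, ADAR2_KO, ADAR1_OE, ADAR2_OE), edited, coverage (replicates
#'   already pooled).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.table: site_id, class in {ADAR1, ADAR2, shared,
#'   unclassified}, plus per-enzyme adjusted p-values.
#' @export
classifyAdar <- function(counts, alpha = 0.05) {
  counts <- as.data.table(counts)
  if (!"WT" %in% counts$condition) stop("missing WT condition")
  wt <- counts[condition == "WT", .(site_id, e0 = edited, c0 = coverage)]
  pert <- counts[condition != "WT"]
  pert[, enzyme := ifelse(grepl("ADAR1", condition), "ADAR1", "ADAR2")]
  pert[, dirUp := grepl("OE", condition)]
  pert <- merge(pert, wt, by = "site_id")
  pert[, p := mapply(function(e, c, e0, c0)
    fisher.test(matrix(c(e, c - e, e0, c0 - e0), 2))$p.value,
    edited, coverage, e0, c0)]
  pert[, lvl := edited / coverage]
  pert[, lvl0 := e0 / c0]
  pert[, consistent := ifelse(dirUp, lvl > lvl0, lvl < lvl0)]
  pert[, q := p.adjust(p, method = "BH"), by = condition]
  perEnz <- pert[, .(hit = any(q <= alpha & consistent), q = min(q)),
                 by = .(site_id, enzyme)]
  wideHit <- dcast(perEnz, site_id ~ enzyme, value.var = c("hit", "q"))
  for (cc in c("hit_ADAR1", "hit_ADAR2")) {
    if (!cc %in% names(wideHit)) wideHit[, (cc) := FALSE]
    wideHit[is.na(get(cc)), (cc) := FALSE]
  }
  wideHit[, class := ifelse(hit_ADAR1 & hit_ADAR2, "shared",
                     ifelse(hit_ADAR1, "ADAR1",
                     ifelse(hit_ADAR2, "ADAR2", "unclassified")))]
  wideHit[]
}

#' Biological variability of editing levels
#'
#' Decomposes the observed variance of per-sample editing levels into
#' binomial sampling noise and the variance \eqn{v} of the underlying level
#' over the population:
#' \deqn{v = (Var(e_i) - c^{-1} (p - p^2)) / (1 - c^{-1})}
#' with \eqn{p} the mean observed level and \eqn{c^{-1}} the mean reciprocal
#' coverage. \eqn{Var(e_i)} is the unbiased (n-1) sample variance; negative
#' estimates (statistical error) are clamped to 0.
#'
#' @param e per-sample observed editing levels.
#' @param c per-sample coverages (all at least 1; not all equal to 1).
#' @return A list: n, p, cInv, varE, v.
#' @examples
#' biologicalVariability(c(0.2, 0.4), c(1000, 1000))
#' @export
biologicalVariability <- function(e, c) {
  if (length(e) < 2L) stop("need at least two samples")
  if (length(e) != length(c)) stop("e and c must have equal length")
  if (any(c < 1)) stop("coverages must be >= 1")
  cInv <- mean(1 / c)
  if (cInv == 1) stop("all coverages equal 1: the estimator is undefined")
  p <- mean(e)
  varE <- var(e)
  v <- max(0, (varE - cInv * (p - p^2)) / (1 - cInv))
  list(n = length(e), p = p, cInv = cInv, varE = varE, v = v)
}

#' Paired differential editing (matched normal/tumor)
#'
#' Per donor, sites with combined (normal + tumor) coverage below
#' \code{minPairCoverage} are excluded; sites whose pooled levels are below
#' \code{minPooledLevel} in both groups are excluded; remaining sites are
#' tested with a paired two-sided t-test on per-donor levels, BH-adjusted per
#' stratum, and a verdict additionally requires an absolute difference in
#' mean level above \code{minDiff}.
#'
#' @param data data.frame: site_id, donor, group ("normal"/"tumor"), edited,
#'   coverage; one stratum (e.g. cancer type) per call.
#' @param minPairCoverage combined per-donor coverage floor (default 40).
#' @param minPooledLevel pooled-level floor (default 0.005).
#' @param fdr BH threshold (default 0.05).
#' @param minDiff required absolute mean-level difference (default 0.10).
#' @return data.table: site_id, n_pairs, mean_normal, mean_tumor, diff,
#'   p, q, verdict.
#' @export
pairedDifferential <- function(data, minPairCoverage = 40,
                               minPooledLevel = 0.005, fdr = 0.05,
                               minDiff = 0.10) {
  dt <- as.data.table(data)
  wide <- dcast(dt, site_id + donor ~ group,
                value.var = c("edited", "coverage"))
  wide <- wide[complete.cases(wide)]
  wide <- wide[coverage_normal + coverage_tumor >= minPairCoverage]
  pooled <- wide[, .(lvl_n = sum(edited_normal) / sum(coverage_normal),
                     lvl_t = sum(edited_tumor) / sum(coverage_tumor)),
                 by = site_id]
  keepSites <- pooled[lvl_n >= minPooledLevel | lvl_t >= minPooledLevel,
                      site_id]
  wide <- wide[site_id %in% keepSites]
  res <- wide[, {
    if (.N < 2L) {
      .(n_pairs = .N, mean_normal = NA_real_, mean_tumor = NA_real_,
        diff = NA_real_, p = NA_real_)
    } else {
      en <- edited_normal / coverage_normal
      et <- edited_tumor / coverage_tumor
      tt <- t.test(et, en, paired = TRUE)
      .(n_pairs = .N, mean_normal = mean(en), mean_tumor = mean(et),
        diff = mean(et) - mean(en), p = tt$p.value)
    }
  }, by = site_id]
  res[, q := p.adjust(p, method = "BH")]
  res[, verdict := !is.na(q) & q <= fdr & abs(diff) > minDiff]
  res[]
}

#' Group differential editing (e.g. healthy vs diseased)
#'
#' Donors with coverage below \code{minCoverage} are discarded; the stratum
#' is skipped unless both groups retain at least \code{minGroup} subjects.
#' Levels are compared with a two-sided rank (Mann-Whitney) test, BH-adjusted
#' across sites; a verdict requires an absolute mean-level difference above
#' \code{minDiff}.
#'
#' @param data data.frame: site_id, donor, group (two labels), edited,
#'   coverage.
#' @param minCoverage per-donor coverage floor (default 20).
#' @param minGroup minimal subjects per group (default 10).
#' @param fdr BH threshold (default 0.05).
#' @param minDiff required absolute mean-level difference (default 0.10).
#' @return data.table per site: group means, difference, p, q, verdict;
#'   NULL (with a message) when the stratum is skipped.
#' @export
groupDifferential <- function(data, minCoverage = 20, minGroup = 10,
                              fdr = 0.05, minDiff = 0.10) {
  dt <- as.data.table(data)[coverage >= minCoverage]
  gl <- sort(unique(dt$group))
  if (length(gl) != 2L) stop("exactly two groups are required")
  sizes <- dt[, data.table::uniqueN(donor), by = group]
  if (nrow(sizes) < 2L || any(sizes$V1 < minGroup)) {
    message("stratum skipped: fewer than ", minGroup, " subjects in a group")
    return(NULL)
  }
  dt[, lvl := edited / coverage]
  res <- dt[, {
    a <- lvl[group == gl[1L]]; b <- lvl[group == gl[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      .(mean_a = NA_real_, mean_b = NA_real_, diff = NA_real_, p = NA_real_)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b))
      .(mean_a = mean(a), mean_b = mean(b), diff = mean(b) - mean(a),
        p = wt$p.value)
    }
  }, by = site_id]
  res[, q := p.adjust(p, method = "BH")]
  res[, verdict := !is.na(q) & q <= fdr & abs(diff) > minDiff]
  res[]
}

#' Single-cell differential editing between cell populations
#'
#' A site is included when some population reaches an editing level of at
#' least \code{minLevel} with pooled coverage of at least \code{minCoverage}
#' reads. For each population pair within a tissue two tests are run: an
#' exact count test on pooled edited/non-edited reads, and a rank test on
#' per-cell levels. Both p-value sets are Benjamini-Yekutieli adjusted.
#'
#' @param cells data.frame: cell_id, site_id, population, edited, coverage.
#' @param minLevel,minCoverage site-inclusion thresholds (defaults 0.10
#'   and 5).
#' @param alpha adjusted-p threshold for reporting (default 0.05).
#' @return data.table: site_id, pop_a, pop_b, pooled levels, p/q for both
#'   tests, and significant (both adjusted p at or below \code{alpha} is not
#'   required: each test is reported separately).
#' @export
singleCellDifferential <- function(cells, minLevel = 0.10, minCoverage = 5,
                                   alpha = 0.05) {
  dt <- as.data.table(cells)
  pop <- dt[, .(edited = sum(edited), coverage = sum(coverage)),
            by = .(site_id, population)]
  keep <- pop[coverage >= minCoverage & edited / coverage >= minLevel,
              unique(site_id)]
  dt <- dt[site_id %in% keep]
  pop <- pop[site_id %in% keep]
  if (!nrow(pop)) return(data.table())
  pops <- sort(unique(pop$population))
  pairs <- if (length(pops) >= 2L) utils::combn(pops, 2L, simplify = FALSE)
           else list()
  rows <- list()
  for (pr in pairs) {
    sub <- pop[population %in% pr]
    both <- sub[, .N, by = site_id][N == 2L, site_id]
    for (s in both) {
      a <- sub[site_id == s & population == pr[1L]]
      b <- sub[site_id == s & population == pr[2L]]
      if (a$coverage == 0 || b$coverage == 0) next
      pc <- fisher.test(matrix(c(a$edited, a$coverage - a$edited,
                                 b$edited, b$coverage - b$edited), 2))$p.value
      la <- dt[site_id == s & population == pr[1L], edited / coverage]
      lb <- dt[site_id == s & population == pr[2L], edited / coverage]
      pr_ <- if (length(la) >= 2L && length(lb) >= 2L) {
        suppressWarnings(wilcox.test(la, lb))$p.value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.table(
        site_id = s, pop_a = pr[1L], pop_b = pr[2L],
        level_a = a$edited / a$coverage, level_b = b$edited / b$coverage,
        p_count = pc, p_rank = pr_)
    }
  }
  if (!length(rows)) return(data.table())
  res <- rbindlist(rows)
  res[, q_count := p.adjust(p_count, method = "BY")]
  res[, q_rank := p.adjust(p_rank, method = "BY")]
  res[, significant := q_count <= alpha]
  res[]
}
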