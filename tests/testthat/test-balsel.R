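test_that("beta scores match the direct-formula oracle on a toy window", {
  ## 10 SNPs with hand-set folded frequencies via haplotype counts
  counts <- c(5, 5, 4, 6, 5, 2, 9, 5, 1, 5)   # of 10 haplotypes
  S <- length(counts)
  hap <- matrix(0L, 10, S)
  for (m in seq_len(S)) hap[seq_len(counts[m]), m] <- 1L
  pos <- c(100L, 300L, 450L, 600L, 800L, 950L, 1200L, 1500L, 1700L, 2100L)
  gd <- gd_from_haps(hap, pos = pos)
  pm <- PopMap(sampleIds(gd), rep("p", 5))
  bt <- betaScores(gd, pm, "p", minFreq = 0.1, halfwidthBp = 500L,
                   maxDiff = 0.1)
  p <- counts / 10
  folded <- pmin(p, 1 - p)
  seg <- folded > 0
  density <- sum(seg) / (max(pos) - min(pos) + 1)
  for (k in seq_len(nrow(bt))) {
    core <- which(pos == bt$pos[k])
    want <- oracle_beta(pos[seg], folded[seg], which(which(seg) == core),
                        500, 0.1, 10, density)
    expect_equal(bt$beta[k], want, tolerance = 1e-9)
  }
  ## folded frequencies below the core minimum are not cores
  expect_false(200 %in% bt$pos)  # no such site anyway
  expect_equal(nrow(bt), sum(folded >= 0.1))
})

test_that("beta is negative for an isolated core and folded-invariant", {
  ## a single intermediate-frequency site with no flanking SNPs
  hap <- matrix(0L, 10, 3)
  hap[1:5, 2] <- 1L
  hap[1:5, 1] <- 1L; hap[6:10, 3] <- 1L  # distant flank sites
  gd <- gd_from_haps(hap, pos = c(100L, 50000L, 99000L))
  pm <- PopMap(sampleIds(gd), rep("p", 5))
  bt <- betaScores(gd, pm, "p", halfwidthBp = 1000L)
  expect_true(all(bt$beta < 0))
  ## allele-label flip leaves beta unchanged (folded statistic)
  gdFlip <- gd_from_haps(1L - hap, pos = c(100L, 50000L, 99000L))
  btF <- betaScores(gdFlip, PopMap(sampleIds(gdFlip), rep("p", 5)), "p",
                    halfwidthBp = 1000L)
  expect_equal(bt$beta, btF$beta, tolerance = 1e-12)
  ## too-small populations are rejected
  expect_error(betaScores(gd, PopMap(sampleIds(gd),
                                     c("p", "q", "q", "q", "q")), "p"),
               "4 haplotypes")
})

test_that("shared-site intersection is exact set algebra", {
  mk <- function(pos, sig) data.frame(pos = pos, q = ifelse(sig, 1e-4, 0.5))
  tabs <- list(a = mk(1:4, c(TRUE, TRUE, TRUE, FALSE)),
               b = mk(1:4, c(FALSE, TRUE, TRUE, TRUE)),
               c = mk(1:4, c(FALSE, FALSE, TRUE, FALSE)))
  sh <- sharedBsSites(tabs)
  expect_equal(sh$shared, 3L)
  expect_equal(unname(sh$perPop), c(3L, 3L, 1L))
  ## identical tables: intersection equals each population's set
  same <- sharedBsSites(list(a = tabs$a, b = tabs$a))
  expect_equal(same$shared, c(1L, 2L, 3L))
  ## monotone: adding a population never enlarges the intersection
  expect_lte(length(sharedBsSites(tabs)$shared),
             length(sharedBsSites(tabs[1:2])$shared))
  ## order-invariant
  expect_equal(sharedBsSites(rev(tabs))$shared, sh$shared)
  ## disjoint universes error
  expect_error(sharedBsSites(list(a = mk(1:3, TRUE), b = mk(7:9, TRUE))),
               "disjoint")
})

test_that("bin counting and qualification follow the threshold", {
  bb <- bsBins(c(100L, 10050L, 10051L), c(chr1 = 30000), binBp = 10000L,
               minSites = 2L)
  expect_equal(bb$bins$n_bs_sites, c(1L, 2L, 0L))
  expect_equal(bb$bins$qualifies, c(FALSE, TRUE, FALSE))
  ## a bin with 14 sites does not qualify at the default threshold of 15
  many <- bsBins(seq(5001L, 5014L), c(chr1 = 10000))
  expect_equal(many$bins$n_bs_sites, 14L)
  expect_false(any(many$bins$qualifies))
  full <- bsBins(seq(5001L, 5015L), c(chr1 = 10000))
  expect_true(all(full$bins$qualifies))
})

test_that("planted clusters are shared, their bins qualify, pi is elevated", {
  sim <- simulateCohort(simConfig(seed = 301L))
  gd <- applySiteFilters(sim$genotypes)$data
  pm <- sim$popmap
  pops <- setdiff(populations(pm), "outgroup")
  tabs <- lapply(pops, function(p) betaScores(gd, pm, p))
  names(tabs) <- pops
  sh <- sharedBsSites(tabs, fdr = 0.01)
  planted <- sim$truth@bsLoci$pos
  expect_gt(sum(planted %in% sh$shared) / length(planted), 0.8)
  div <- windowedDiversity(gd, pm, chromLengths = c(chr1 = 1e6))
  bb <- bsBins(sh$shared, c(chr1 = 1e6), diversity = div)
  plantedBins <- unique((planted - 1) %/% 10000)
  expect_gte(sum(bb$bins$qualifies[plantedBins + 1]), 2L)
  expect_gt(bb$piQualifying, bb$piGenome)
})

test_that("beta-ADD classes follow the dosage rules", {
  tr <- new("DosageTrack", chrom = rep("chr1", 4), pos = c(10L, 20L, 30L, 40L),
            samples = "s", donors = c("dA", "dB"),
            dosageB = matrix(c(0.5, 0.9, 0.1, 0.5), 4, 1),
            meanA = c(0.5, 0.1, 0.9, 0.5), meanB = c(0.5, 0.9, 0.1, 0.5),
            add = c(0, 0.8, 0.8, 0))
  bt <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                   f_core = 0.5, beta = 5,
                   p = c(1e-5, 1e-5, 1e-5, 0.5, 1e-5),
                   q = c(0.001, 0.001, 0.001, 0.9, 0.001))
  cls <- betaAddClassify(bt, tr, fdr = 0.01, addMin = 0.5)
  expect_equal(cls$class,
               c("shared-standing",        # q sig, ADD 0
                 "donor-derived-B",        # ADD 0.8, meanB > 0.5
                 "donor-derived-A",        # ADD 0.8, meanA > 0.5
                 "nonsignificant",         # q = 0.9
                 "unscored"))              # no ADD at pos 50
})

test_that("planted loci separate by donor origin across the ADD boundary", {
  sim <- simulateCohort(simConfig(seed = 302L))
  gd <- applySiteFilters(sim$genotypes)$data
  pm <- sim$popmap
  dos <- ancestryDosageHmm(gd, pm, "hybridN")
  bt <- betaScores(gd, pm, "hybridN")
  cls <- betaAddClassify(bt, dos)
  bs <- sim$truth@bsLoci
  tractCls <- cls$class[cls$pos %in% bs$pos[bs$kind == "tract"]]
  sharedCls <- cls$class[cls$pos %in% bs$pos[bs$kind == "shared"]]
  expect_gt(mean(tractCls == "donor-derived-B"), 0.9)
  expect_gt(mean(!sharedCls %in% c("donor-derived-A", "donor-derived-B")),
            0.9)
})
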