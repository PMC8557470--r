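## donor panels with exactly controlled allele frequencies: 5 samples
## (10 haplotypes) each, allele counts set directly
panel_fixture <- function(fA, fB, hybHaps, pos = NULL) {
  S <- length(fA)
  mkPanel <- function(f) {
    h <- matrix(0L, 10, S)
    for (m in seq_len(S)) if (round(f[m] * 10) > 0)
      h[seq_len(round(f[m] * 10)), m] <- 1L
    h
  }
  hap <- rbind(mkPanel(fA), mkPanel(fB), hybHaps)
  gd <- gd_from_haps(hap, pos = pos)
  nHyb <- nrow(hybHaps) / 2
  pm <- PopMap(sampleIds(gd), c(rep("dA", 5), rep("dB", 5),
                                rep("hy", nHyb)),
               roles = list(dA = "donorA", dB = "donorB", hy = "hybrid"),
               donors = list(hy = c(donorA = "dA", donorB = "dB")))
  list(gd = gd, pm = pm)
}

test_that("supervised admixture recovers pure and mixed individuals", {
  set.seed(19)
  S <- 4000
  fA <- runif(S, 0.05, 0.95)
  fB <- pmin(0.98, pmax(0.02, fA + sample(c(-1, 1), S, TRUE) *
                          runif(S, 0.15, 0.4)))
  ## hybrid 1: drawn from donor A; hybrid 2: exact 50/50 mixture dosages
  h1 <- t(replicate(2, rbinom(S, 1, fA)))
  fx <- panel_fixture(fA, fB, h1)
  q <- supervisedAdmixture(fx$gd, fx$pm, c("dA", "dB"))
  hyRow <- q[samplesOf(fx$pm, "hy"), ]
  expect_gte(hyRow["dA"], 0.95)
  ## proportions lie on the simplex for every sample
  expect_true(all(q >= -1e-9 & q <= 1 + 1e-9))
  expect_equal(unname(rowSums(q)), rep(1, nrow(q)), tolerance = 1e-9)
})

test_that("an exact mixture genotype yields exact mixture proportions", {
  ## genotype dosage equal to 2 * mean of panel frequencies at every
  ## site: proportions must be (0.5, 0.5).  Build via the least-squares
  ## surface directly (no sampling noise).
  S <- 200
  set.seed(29)
  fA <- round(runif(S, 0.1, 0.9), 1)
  fB <- round(pmin(0.9, pmax(0.1, 1 - fA + 0.1)), 1)
  fx <- panel_fixture(fA, fB, matrix(0L, 2, S))
  g <- genotypes(fx$gd)
  gmix <- as.integer(round(fA + fB))   # 2 * (fA+fB)/2, rounded to dosage
  g[, samplesOf(fx$pm, "hy")[1]] <- gmix
  gd2 <- GenotypeData(g, chroms(fx$gd), positions(fx$gd), refAllele(fx$gd),
                      altAllele(fx$gd))
  q <- supervisedAdmixture(gd2, fx$pm, c("dA", "dB"),
                           samples = samplesOf(fx$pm, "hy")[1])
  ## rounding to integer dosages leaves a small residual
  expect_equal(unname(q[1, ]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("HMM posteriors equal exhaustive path enumeration", {
  eps <- 0.02; g <- 100L; r <- 3e-7; prior <- 0.5
  fA <- c(0.9, 0.2, 0.7, 0.4, 0.8)
  fB <- c(0.1, 0.8, 0.3, 0.9, 0.2)
  pos <- c(1000L, 6000L, 21000L, 41000L, 90000L)
  hapsHy <- rbind(c(1L, 0L, 1L, 0L, 1L),   # A-like
                  c(0L, 1L, 0L, 1L, 0L))   # B-like
  fx <- panel_fixture(fA, fB, hapsHy, pos = pos)
  dos <- ancestryDosageHmm(fx$gd, fx$pm, "hy",
                           cfg = hmmConfig(g = g, recombRate = r,
                                           eps = eps, prior = prior))
  for (hapIdx in 1:2) {
    want <- oracle_hmm_posterior(hapsHy[hapIdx, ], fA, fB, pos, g, r, eps,
                                 prior)
    ## per-sample dosage is the mean of its two haplotype posteriors
    if (hapIdx == 1) acc <- want else {
      got <- dos@dosageB[, 1]
      expect_equal(got, (acc + want) / 2, tolerance = 1e-9)
    }
  }
})

test_that("unphased decoding matches enumeration over diploid paths", {
  eps <- 0.05; g <- 50L; r <- 1e-6; prior <- 0.4
  fA <- c(0.8, 0.1, 0.6)     # exactly representable with 10 haplotypes
  fB <- c(0.2, 0.9, 0.3)
  pos <- c(500L, 9000L, 30000L)
  hy <- matrix(c(2L, 1L, 0L), 3, 1, dimnames = list(NULL, "h1"))
  fx <- panel_fixture(fA, fB, matrix(0L, 2, 3), pos = pos)
  g_ <- genotypes(fx$gd)
  g_[, samplesOf(fx$pm, "hy")[1]] <- hy[, 1]
  gdU <- GenotypeData(g_, chroms(fx$gd), positions(fx$gd),
                      refAllele(fx$gd), altAllele(fx$gd))  # no phase
  dos <- ancestryDosageHmm(gdU, fx$pm, "hy",
                           cfg = hmmConfig(g = g, recombRate = r,
                                           eps = eps, prior = prior))
  ## exhaustive oracle over ordered two-haplotype state paths
  eAd <- eps + fA * (1 - 2 * eps); eBd <- eps + fB * (1 - 2 * eps)
  emis <- function(geno, s1, s2, i) {
    p1 <- if (s1 == 1) eAd[i] else eBd[i]
    p2 <- if (s2 == 1) eAd[i] else eBd[i]
    switch(geno + 1L, (1 - p1) * (1 - p2),
           p1 * (1 - p2) + p2 * (1 - p1), p1 * p2)
  }
  trans <- function(s1, s2, d) {
    th <- 1 - exp(-g * r * d)
    stay <- if (s2 == 1) th * prior else th * (1 - prior)
    if (s1 == s2) 1 - th + stay else stay
  }
  grid <- expand.grid(rep(list(1:2), 6))   # (a1,b1,a2,b2,a3,b3)
  probs <- apply(grid, 1, function(st) {
    p <- (if (st[1] == 1) prior else 1 - prior) *
         (if (st[2] == 1) prior else 1 - prior) *
         emis(2L, st[1], st[2], 1)
    p * trans(st[1], st[3], 8500) * trans(st[2], st[4], 8500) *
      emis(1L, st[3], st[4], 2) *
      trans(st[3], st[5], 21000) * trans(st[4], st[6], 21000) *
      emis(0L, st[5], st[6], 3)
  })
  dosOracle <- vapply(1:3, function(i) {
    sB <- (grid[[2 * i - 1]] == 2) + (grid[[2 * i]] == 2)
    sum(probs * sB / 2) / sum(probs)
  }, numeric(1))
  expect_equal(unname(dos@dosageB[, 1]), dosOracle, tolerance = 1e-9)
})

test_that("fully informative donors give saturated dosage and exact ADD", {
  S <- 40
  fx <- panel_fixture(rep(0, S), rep(1, S),
                      matrix(1L, 4, S))    # two hybrids, all donor-B alleles
  dos <- ancestryDosageHmm(fx$gd, fx$pm, "hy")
  expect_true(all(dos@dosageB >= 0.99))
  expect_true(all(addScores(dos) >= 0.98))
  ## ADD identities
  expect_equal(abs(0.9 - 0.1), 0.8)
  tr <- new("DosageTrack", chrom = rep("chr1", 2), pos = c(1L, 2L),
            samples = "s", donors = c("a", "b"),
            dosageB = matrix(c(0.1, 0.5), 2, 1),
            meanA = c(0.9, 0.5), meanB = c(0.1, 0.5), add = c(0.8, 0))
  expect_equal(addScores(tr), c(0.8, 0))
  ## dosage sum-to-one is structural: meanA + meanB == 1
  expect_equal(tr@meanA + tr@meanB, c(1, 1))
})

test_that("ADD is invariant to donor relabeling", {
  set.seed(37)
  S <- 300
  fA <- runif(S, .1, .9); fB <- runif(S, .1, .9)
  hy <- matrix(rbinom(6 * S, 1, 0.5), 6, S)
  fx <- panel_fixture(fA, fB, hy)
  d1 <- ancestryDosageHmm(fx$gd, fx$pm, "hy", donors = c("dA", "dB"))
  d2 <- ancestryDosageHmm(fx$gd, fx$pm, "hy", donors = c("dB", "dA"))
  expect_equal(addScores(d1), addScores(d2), tolerance = 1e-9)
  expect_equal(d1@dosageB, 1 - d2@dosageB, tolerance = 1e-9)
})

test_that("more admixture generations shorten decoded ancestry segments", {
  sim <- simulateCohort(simConfig(nSites = 3000L, chromLengthBp = 300000L,
                                  tract = NULL, sweep = NULL,
                                  bsLoci = list(), seed = 33L))
  segLen <- function(g_) {
    dos <- ancestryDosageHmm(sim$genotypes, sim$popmap, "hybridN",
                             cfg = hmmConfig(g = g_, recombRate = 3e-7))
    st <- dos@dosageB[, 1] > 0.5
    mean(rle(st)$lengths)
  }
  lens <- vapply(c(10L, 100L, 1000L), segLen, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("ADD quantile threshold uses linear interpolation with >= ties", {
  q <- addQuantileMask(c(0, 0, 0, 1), q = 0.75)
  expect_equal(q$threshold, 0.25)
  expect_equal(q$mask, c(FALSE, FALSE, FALSE, TRUE))
  cst <- addQuantileMask(rep(0.4, 6))
  expect_true(all(cst$mask))            # tie rule: >= at the threshold
  expect_error(addQuantileMask(numeric(0)), "empty")
})
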