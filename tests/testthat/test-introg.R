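cfg4 <- fourTaxonConfig("P1pop", "P2pop", "P3pop", "Opop")

freq_matrix <- function(p1, p2, p3, pO) {
  m <- cbind(P1pop = p1, P2pop = p2, P3pop = p3, Opop = pO)
  m
}

test_that("site patterns equal the direct formula on random frequencies", {
  set.seed(13)
  p <- matrix(runif(80), 20, 4)
  sp <- sitePatterns(freq_matrix(p[, 1], p[, 2], p[, 3], p[, 4]), cfg4)
  expect_equal(sp$patterns$abba,
               (1 - p[, 1]) * p[, 2] * p[, 3] * (1 - p[, 4]),
               tolerance = 1e-12)
  expect_equal(sp$patterns$baba,
               p[, 1] * (1 - p[, 2]) * p[, 3] * (1 - p[, 4]),
               tolerance = 1e-12)
  ## forced cases
  one <- sitePatterns(freq_matrix(0, 1, 1, 0), cfg4)
  expect_equal(one$patterns$abba, 1)
  expect_equal(one$patterns$baba, 0)
  sym <- sitePatterns(freq_matrix(0.4, 0.4, 0.8, 0), cfg4)
  expect_equal(sym$patterns$abba - sym$patterns$baba, 0)
  ## unpolarized sites are excluded and counted
  sp2 <- sitePatterns(freq_matrix(c(0.1, NA), c(1, 1), c(1, 1), c(0, 0)),
                      cfg4)
  expect_equal(sp2$nExcluded, 1L)
  expect_equal(nrow(sp2$patterns), 1L)
})

## four-population cohort with hand-controlled derived frequencies via
## haplotype construction; outgroup all-ancestral so polarization is alt
dstat_fixture <- function(hapList, pos) {
  hap <- do.call(rbind, hapList)
  gd <- gd_from_haps(hap, pos = pos)
  n <- vapply(hapList, nrow, 1L) / 2
  pm <- PopMap(sampleIds(gd),
               rep(c("P1pop", "P2pop", "P3pop", "Opop"), times = n),
               roles = list(P1pop = "P1", P2pop = "P2", P3pop = "P3",
                            Opop = "O"))
  list(gd = gd, pm = pm)
}

test_that("windowed D and fdM hit their forced limit values", {
  S <- 12
  ## every site (p1,p2,p3,pO) = (0,1,1,0): D = fdM = 1
  fx <- dstat_fixture(list(matrix(0L, 4, S), matrix(1L, 4, S),
                           matrix(1L, 4, S), matrix(0L, 4, S)),
                      pos = seq(10L, by = 50L, length.out = S))
  cfg <- fourTaxonConfig("P1pop", "P2pop", "P3pop", "Opop",
                         windowBp = 1000L, minSnps = 5L)
  w <- windowDstats(fx$gd, fx$pm, cfg, chromLengths = c(chr1 = 1000))
  expect_equal(w$D, 1)
  expect_equal(w$f_dM, 1)
  expect_equal(w$d_f, 1)
  ## p1 == p2 everywhere: D = fdM = d_f = 0
  set.seed(3)
  hp <- matrix(rbinom(4 * S, 1, 0.5), 4, S)
  h3 <- matrix(rbinom(4 * S, 1, 0.5), 4, S)
  fx0 <- dstat_fixture(list(hp, hp, h3, matrix(0L, 4, S)),
                       pos = seq(10L, by = 50L, length.out = S))
  w0 <- windowDstats(fx0$gd, fx0$pm, cfg, chromLengths = c(chr1 = 1000))
  expect_equal(w0$D, 0)
  expect_equal(w0$f_dM, 0)
  expect_equal(w0$d_f, 0)
})

test_that("windows below the SNP minimum are masked", {
  S <- 99
  set.seed(8)
  mats <- lapply(1:4, function(i) matrix(rbinom(4 * S, 1, 0.5), 4, S))
  mats[[4]] <- matrix(0L, 4, S)
  fx <- dstat_fixture(mats, pos = sort(sample(1:10000, S)))
  cfg <- fourTaxonConfig("P1pop", "P2pop", "P3pop", "Opop",
                         windowBp = 10000L, minSnps = 100L)
  w <- windowDstats(fx$gd, fx$pm, cfg, chromLengths = c(chr1 = 10000))
  expect_equal(w$n_snps, 99L)
  expect_true(is.na(w$D) && is.na(w$f_dM) && is.na(w$d_f))
  ## with exactly 100 SNPs the window is scored
  cfg99 <- fourTaxonConfig("P1pop", "P2pop", "P3pop", "Opop",
                           windowBp = 10000L, minSnps = 99L)
  w2 <- windowDstats(fx$gd, fx$pm, cfg99, chromLengths = c(chr1 = 10000))
  expect_false(is.na(w2$D))
})

test_that("D, fdM and d_f are antisymmetric under P1 <-> P2 and bounded", {
  set.seed(17)
  for (rep_ in 1:4) {
    S <- 120
    mats <- list(matrix(rbinom(6 * S, 1, runif(1, .2, .8)), 6, S),
                 matrix(rbinom(6 * S, 1, runif(1, .2, .8)), 6, S),
                 matrix(rbinom(6 * S, 1, runif(1, .2, .8)), 6, S),
                 matrix(rbinom(6 * S, 1, 0.05), 6, S))
    fx <- dstat_fixture(mats, pos = sort(sample(1:4000, S)))
    cfg <- fourTaxonConfig("P1pop", "P2pop", "P3pop", "Opop",
                           windowBp = 1000L, minSnps = 5L)
    cfgSwap <- fourTaxonConfig("P2pop", "P1pop", "P3pop", "Opop",
                               windowBp = 1000L, minSnps = 5L)
    w <- windowDstats(fx$gd, fx$pm, cfg, chromLengths = c(chr1 = 4000))
    ws <- windowDstats(fx$gd, fx$pm, cfgSwap, chromLengths = c(chr1 = 4000))
    expect_equal(w$D, -ws$D, tolerance = 1e-12)
    expect_equal(w$f_dM, -ws$f_dM, tolerance = 1e-12)
    expect_equal(w$d_f, -ws$d_f, tolerance = 1e-12)
    ok <- is.finite(w$D)
    expect_true(all(abs(w$D[ok]) <= 1 + 1e-12))
    expect_true(all(abs(w$f_dM[is.finite(w$f_dM)]) <= 1 + 1e-12))
    expect_true(all(abs(w$d_f[is.finite(w$d_f)]) <= 1 + 1e-12))
  }
})

test_that("BH outlier calling matches the step-up oracle", {
  set.seed(23)
  d_f <- c(rnorm(60, 0, 0.05), rnorm(4, 0.6, 0.02))
  rec <- data.frame(chrom = "chr1", start = seq_along(d_f) * 10000 - 10000,
                    end = seq_along(d_f) * 10000, n_snps = 200L, d_f = d_f)
  out <- outlierWindows(rec, fdr = 0.05)
  z <- (d_f - mean(d_f)) / sd(d_f)
  p <- pnorm(z, lower.tail = FALSE)
  expect_equal(out$outlier, oracle_bh(p, 0.05))
  expect_equal(out$q, p.adjust(p, "BH"), tolerance = 1e-12)
  ## identical values: degenerate null, no outliers
  rec2 <- rec; rec2$d_f <- rep(0.3, nrow(rec2))
  expect_warning(out2 <- outlierWindows(rec2), "zero genome-wide SD")
  expect_false(any(out2$outlier))
  ## too few unmasked windows errors
  expect_error(outlierWindows(rec[1:10, ]), "30")
})

test_that("a planted donor tract is recovered and only the tract flags", {
  sim <- simulateCohort(simConfig(seed = 101L))
  gd <- applySiteFilters(sim$genotypes)$data
  ftc <- fourTaxonConfig("hybridS", "hybridN", "donorB", "outgroup")
  w <- windowDstats(gd, sim$popmap, ftc, chromLengths = c(chr1 = 1e6))
  ow <- outlierWindows(w, fdr = 0.05)
  tract <- sim$truth@tract
  inTract <- w$start >= tract[1] & w$end <= tract[2]
  expect_gt(sum(ow$outlier[inTract]), 3)        # most tract windows flag
  expect_equal(sum(ow$outlier[!inTract]), 0L)   # nothing else does
  expect_gt(mean(w$f_dM[inTract]), 0.4)
  expect_gt(mean(w$d_f[inTract]), 0.4)
})
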