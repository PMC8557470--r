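test_that("VCF reading parses genotypes, phase and coordinates", {
  f <- system.file("extdata", "toy.vcf", package = "admixscan")
  expect_message(gd <- readVcfGT(f), "dropped 1")
  expect_equal(attr(gd, "dropped"), 1L)          # the multi-allelic record
  expect_equal(nSites(gd), 3L)
  expect_equal(sampleIds(gd), c("s1", "s2", "s3"))
  expect_equal(positions(gd), c(100L, 250L, 420L))
  ## site 1 phased 0|0,0|1,1|1 ; site 2 unphased 0/0,./.,1/1
  expect_equal(unname(genotypes(gd)[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(genotypes(gd)[2, ]), c(0L, NA_integer_, 2L))
  h <- haplotypes(gd)
  expect_equal(unname(h[1, ]), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(is.na(h[2, ])))                # phase absent for site 2
  expect_equal(unname(h[3, 1:2]), c(0L, 1L))     # 0|1
})

test_that("header-only VCF yields an empty matrix and regions subset", {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb")
  f <- withr::local_tempfile(lines = hdr, fileext = ".vcf")
  gd <- readVcfGT(f)
  expect_equal(nSites(gd), 0L)
  expect_equal(sampleIds(gd), c("a", "b"))
  f2 <- system.file("extdata", "toy.vcf", package = "admixscan")
  sub <- suppressMessages(readVcfGT(f2, region = "chr1:200-430"))
  expect_equal(positions(sub), c(250L, 420L))
  none <- suppressMessages(readVcfGT(f2, region = "chr9"))
  expect_equal(nSites(none), 0L)
})

test_that("VCF write/read round-trips simulator output exactly", {
  sim <- simulateCohort(simConfig(nSites = 300L, chromLengthBp = 30000L,
                                  tract = NULL, sweep = NULL,
                                  bsLoci = list(), seed = 7L))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfGT(sim$genotypes, f)
  back <- readVcfGT(f)
  expect_identical(unname(genotypes(back)), unname(genotypes(sim$genotypes)))
  expect_identical(unname(haplotypes(back)),
                   unname(haplotypes(sim$genotypes)))
  expect_equal(positions(back), positions(sim$genotypes))
  expect_equal(refAllele(back), refAllele(sim$genotypes))
})

test_that("site filters match a brute-force application of the rules", {
  set.seed(11)
  g <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                     prob = c(.35, .3, .25, .1)), 10, 20)
  ## one high-missingness site, one rare site, one all-het site
  g[1, 1:9] <- NA
  g[2, ] <- c(rep(0L, 19), 1L)
  g[3, ] <- 1L
  gd <- gd_from_geno(g)
  cfg <- filterConfig()
  res <- applySiteFilters(gd, cfg)
  ## brute force
  miss <- rowMeans(is.na(g)) > cfg$max_missing_fraction
  p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  maf <- pmin(p, 1 - p) < cfg$min_maf
  q <- p.adjust(excessHetPValues(gd), "BH")
  het <- !is.na(q) & q < cfg$excess_het_fdr
  expect_equal(positions(res$data), positions(gd)[!(miss | maf | het)])
  expect_equal(unname(res$removed["missingness"]), sum(miss))
  expect_equal(unname(res$removed["maf"]), sum(maf))
  expect_equal(unname(res$removed["excess_het"]), sum(het))
  expect_true(het[3])   # the all-heterozygous site is flagged
  ## the all-het site has the smallest p-value in the batch
  expect_equal(which.min(excessHetPValues(gd)), 3L)
})

test_that("site filtering is idempotent", {
  sim <- simulateCohort(simConfig(nSites = 1500L, chromLengthBp = 100000L,
                                  tract = NULL, sweep = NULL,
                                  bsLoci = list(), missingRate = 0.05,
                                  seed = 3L))
  once <- applySiteFilters(sim$genotypes)
  twice <- applySiteFilters(once$data)
  expect_equal(sum(twice$removed), 0L)
  expect_equal(nSites(twice$data), nSites(once$data))
})

test_that("excess-het exact test matches closed-form cases", {
  ## n=2: genotypes {AB, AB}: P(het=2 | nA=2, n=2) = 2/3, one-sided p
  gd <- gd_from_geno(matrix(c(1L, 1L), 1, 2))
  expect_equal(excessHetPValues(gd), 2 / 3, tolerance = 1e-12)
  ## het count at its minimum given allele counts -> p = 1
  gd2 <- gd_from_geno(matrix(c(0L, 2L), 1, 2))
  expect_equal(excessHetPValues(gd2), 1, tolerance = 1e-12)
})

test_that("LD pruning matches the greedy brute-force oracle", {
  set.seed(5)
  base <- matrix(sample(0:2, 120, replace = TRUE), 6, 20)
  g <- base[rep(1:6, length.out = 20), ]        # blocks of correlated sites
  g <- g + matrix(sample(0:1, 400, replace = TRUE, prob = c(.8, .2)), 20, 20)
  g[g > 2] <- 2L
  gd <- gd_from_geno(g)
  got <- ldPrune(gd, windowSnps = 8L, stepSnps = 2L, r2Max = 0.2)
  want <- oracle_ld_prune(g, 8L, 2L, 0.2)
  expect_equal(got, want)
  ## two identical sites in one window: the later one is dropped
  dup <- gd_from_geno(rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L)))
  expect_equal(ldPrune(dup), 1L)
  ## mutually independent sites are all retained
  set.seed(42)
  ind <- gd_from_geno(matrix(rbinom(500 * 2, 2, 0.5), 2, 500))
  expect_equal(ldPrune(ind), c(1L, 2L))
})

test_that("pruned output never contains a within-window pair above r2Max", {
  sim <- simulateCohort(simConfig(nSites = 400L, chromLengthBp = 40000L,
                                  tract = NULL, sweep = NULL,
                                  bsLoci = list(), seed = 9L))
  keep <- ldPrune(sim$genotypes, windowSnps = 50L, stepSnps = 5L,
                  r2Max = 0.2)
  g <- genotypes(sim$genotypes)
  for (s in seq(1, nSites(sim$genotypes), by = 5)) {
    idx <- keep[keep >= s & keep <= s + 49]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(t(g[idx, , drop = FALSE]),
                               use = "pairwise.complete.obs"))^2
    diag(r2) <- 0
    expect_true(all(r2 <= 0.2 + 1e-12, na.rm = TRUE))
  }
})

test_that("window and site tables round-trip with BED conventions", {
  df <- data.frame(chrom = "chr1", start = 0L, end = 10000L,
                   value = c(0.123456789))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeWindowTable(df, f)
  first <- strsplit(readLines(f), "\t")
  expect_equal(first[[1]], c("chrom", "start", "end", "value"))
  expect_equal(first[[2]][1:3], c("chr1", "0", "10000"))
  back <- readWindowTable(f)
  expect_equal(back$value, signif(df$value, 6))
  ## empty table -> header-only file
  writeWindowTable(df[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  ## site-table round trip
  st <- data.frame(chrom = "chr2", pos = c(1L, 77L), x = c(1.5, 2.25))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeSiteTable(st, f2)
  expect_equal(readSiteTable(f2), st)
})

test_that("population map round-trips with roles and donors", {
  pm <- PopMap(c("a", "b", "c"), c("p1", "p1", "p2"),
               roles = list(p1 = c("hybrid", "P2"), p2 = c("donorB", "P3")),
               donors = list(p1 = c(donorA = "p2", donorB = "p2")))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writePopMap(pm, f1, f2)
  back <- readPopMap(f1, f2)
  expect_equal(popOf(back, c("a", "c")), c("p1", "p2"))
  expect_equal(samplesOf(back, "p1"), c("a", "b"))
  expect_equal(sort(popsWithRole(back, "P3")), "p2")
  expect_equal(unname(hybridDonors(back, "p1")["donorB"]), "p2")
})

test_that("PopMap validity rejects overlapping four-taxon roles", {
  expect_error(PopMap("a", "p1", roles = list(p1 = c("P1", "P2"))),
               "disjoint")
})
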