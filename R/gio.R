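## Format I/O and site-level filtering.
##
## Coordinate conventions used throughout the package: site positions are
## 1-based (VCF convention); window and tract coordinates are 0-based
## half-open (BED convention).  Every function that crosses the boundary
## says which convention it uses.

#' Read biallelic SNP genotypes from a VCF file
#'
#' Reads a VCF 4.x file (via vcfR), keeping only biallelic SNP records;
#' multi-allelic and indel records are dropped with a message reporting
#' the count.  Phase is preserved per genotype: haplotype alleles are
#' stored wherever the GT separator is `|`, and are NA for unphased or
#' missing genotypes.
#'
#' @param path VCF file.
#' @param region optional region `"chrom"` or `"chrom:start-end"`
#'   (1-based inclusive).  A region containing no records yields an empty
#'   object, not an error.
#' @return a [GenotypeData-class] object.  The number of dropped
#'   non-SNP/multi-allelic records is attached as attribute `"dropped"`.
#' @examples
#' f <- system.file("extdata", "toy.vcf", package = "admixscan")
#' gd <- readVcfGT(f)
#' genotypes(gd)
#' @export
readVcfGT <- function(path, region = NULL) {
  if (!file.exists(path)) .stopf("VCF file not found: %s", path)
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) .stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = length(fix) > 0, byrow = TRUE,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (nrow(fix) == 0L) {
    gm <- matrix(integer(), 0, length(samples),
                 dimnames = list(NULL, samples))
    out <- GenotypeData(gm, character(), integer(), character(), character())
    attr(out, "dropped") <- 0L
    return(out)
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos)) .stopf("malformed VCF '%s': non-numeric POS at record %d",
                         path, which(is.na(pos))[1])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  dropped <- sum(!snp)
  if (dropped) message(sprintf("readVcfGT: dropped %d non-SNP/multi-allelic record(s)",
                               dropped))
  keep <- snp
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(m)) .stopf("bad region '%s'", region)
    keep <- keep & chrom == m[2]
    if (nzchar(m[3]))
      keep <- keep & pos >= as.integer(m[4]) & pos <= as.integer(m[5])
  }
  gt <- vcf@gt[keep, -1, drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  ## strip any trailing FORMAT fields, keep the GT token
  gt[] <- sub(":.*$", "", gt)
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  a1i <- suppressWarnings(matrix(as.integer(a1), nrow(gt), ncol(gt)))
  a2i <- suppressWarnings(matrix(as.integer(a2), nrow(gt), ncol(gt)))
  gm <- a1i + a2i
  colnames(gm) <- samples
  phased <- sep == "|" & !is.na(a1i) & !is.na(a2i)
  hap <- NULL
  if (any(phased)) {
    hap <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
    hap[, seq(1L, ncol(hap), by = 2L)][phased] <- a1i[phased]
    hap[, seq(2L, ncol(hap), by = 2L)][phased] <- a2i[phased]
    colnames(hap) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  }
  out <- GenotypeData(gm, chrom, pos, ref, alt, haplotypes = hap)
  attr(out, "dropped") <- dropped
  out
}

#' Write genotypes to a plain-text VCF 4.2 file
#'
#' Emits phased GT fields (`a|b`) wherever haplotypes are stored and
#' unphased dosage-derived GT (`0/0`, `0/1`, `1/1`, `./.`) elsewhere.
#' Output is deterministic: equal inputs give byte-identical files.
#'
#' @param gd a [GenotypeData-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVcfGT <- function(gd, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(gd)), collapse = "\t"), con)
  n <- nSites(gd)
  if (n == 0L) return(invisible(path))
  g <- genotypes(gd)
  if (hasPhase(gd)) {
    h <- haplotypes(gd)
    a1 <- h[, seq(1L, ncol(h), by = 2L), drop = FALSE]
    a2 <- h[, seq(2L, ncol(h), by = 2L), drop = FALSE]
    gt <- matrix(NA_character_, n, ncol(g))
    ph <- !is.na(a1) & !is.na(a2)
    gt[ph] <- paste0(a1[ph], "|", a2[ph])
    un <- !ph & !is.na(g)
    gt[un] <- c("0/0", "0/1", "1/1")[g[un] + 1L]
    gt[is.na(gt)] <- "./."
  } else {
    gt <- matrix("./.", n, ncol(g))
    ok <- !is.na(g)
    gt[ok] <- c("0/0", "0/1", "1/1")[g[ok] + 1L]
  }
  rows <- paste(chroms(gd), positions(gd), ".", refAllele(gd), altAllele(gd),
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Site filter configuration
#'
#' @param max_missing_fraction drop sites missing in more than this
#'   fraction of samples (default 0.30).
#' @param min_maf drop sites with pooled minor-allele frequency below
#'   this (default 0.05).
#' @param excess_het_fdr drop sites whose one-sided heterozygote-excess
#'   exact-test q-value (Benjamini-Hochberg across all tested sites)
#'   falls below this (default 0.01).
#' @param require_biallelic kept for completeness; [GenotypeData-class]
#'   already guarantees biallelic sites.
#' @return a `filter_config` list.
#' @export
filterConfig <- function(max_missing_fraction = 0.30, min_maf = 0.05,
                         excess_het_fdr = 0.01, require_biallelic = TRUE) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 1,
            excess_het_fdr >= 0, excess_het_fdr <= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 min_maf = min_maf, excess_het_fdr = excess_het_fdr,
                 require_biallelic = isTRUE(require_biallelic)),
            class = "filter_config")
}

#' One-sided exact test for heterozygote excess
#'
#' Conditional exact test of Hardy-Weinberg equilibrium against the
#' one-sided alternative of heterozygote excess: given the minor-allele
#' count, the p-value is the probability of observing at least as many
#' heterozygotes as seen.
#'
#' @param gd a [GenotypeData-class] object.
#' @return numeric vector of p-values, one per site (NA where fewer than
#'   two samples are genotyped).
#' @export
excessHetPValues <- function(gd) {
  g <- genotypes(gd)
  nHet <- rowSums(g == 1L, na.rm = TRUE)
  nHomA <- rowSums(g == 0L, na.rm = TRUE)
  nHomB <- rowSums(g == 2L, na.rm = TRUE)
  vapply(seq_len(nrow(g)), function(i)
    .het_excess_p(nHomA[i], nHet[i], nHomB[i]), numeric(1))
}

## P(het >= observed | nA, n) under HWE; log-space for stability.
.het_excess_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (n < 2L) return(NA_real_)
  nA <- 2L * nAA + nAB
  nB <- 2L * n - nA
  hmax <- min(nA, nB)
  hs <- seq.int(nAB, hmax, by = 2L)   # parity of het count is fixed by nA
  if (!length(hs)) return(1)
  all_h <- seq.int(nA %% 2L, hmax, by = 2L)
  logp <- function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    h * log(2) + lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) -
      lgamma(nbb + 1) - lchoose(2 * n, nA)
  }
  lall <- logp(all_h)
  lall <- lall - max(lall)
  denom <- sum(exp(lall))
  num <- sum(exp(lall[all_h >= nAB]))
  min(1, num / denom)
}

#' Apply site-level filters
#'
#' Removes sites failing any of: missingness above
#' `max_missing_fraction`, pooled minor-allele frequency below `min_maf`,
#' or heterozygote-excess exact-test q-value (BH across all sites tested
#' together, genome-wide) below `excess_het_fdr`.  Per-rule counts report
#' how many sites fail each rule (a site can fail several).
#'
#' @param gd a non-empty [GenotypeData-class] object.
#' @param cfg a [filterConfig()] list.
#' @return list with elements `data` (the filtered [GenotypeData-class]),
#'   `removed` (named counts per rule), `nInput` and `nKept`.
#' @export
applySiteFilters <- function(gd, cfg = filterConfig()) {
  if (!is(gd, "GenotypeData")) .stopf("gd must be a GenotypeData object")
  if (nSites(gd) == 0L) .stopf("applySiteFilters: input has no sites")
  g <- genotypes(gd)
  nmiss <- rowSums(is.na(g))
  missFrac <- nmiss / ncol(g)
  nChrom <- 2 * (ncol(g) - nmiss)
  ac <- rowSums(g, na.rm = TRUE)
  p <- ifelse(nChrom > 0, ac / nChrom, NA_real_)
  maf <- pmin(p, 1 - p)
  failMiss <- missFrac > cfg$max_missing_fraction
  failMaf <- is.na(maf) | maf < cfg$min_maf
  q <- .bh(excessHetPValues(gd))
  failHet <- !is.na(q) & q < cfg$excess_het_fdr
  keep <- !(failMiss | failMaf | failHet)
  if (!any(keep)) .warnf("applySiteFilters: all %d sites removed", nSites(gd))
  list(data = gd[which(keep), ],
       removed = c(missingness = sum(failMiss), maf = sum(failMaf),
                   excess_het = sum(failHet)),
       nInput = nSites(gd), nKept = sum(keep))
}

#' Greedy LD pruning
#'
#' plink-style `--indep-pairwise` pruning on genotype dosages: sliding
#' windows of `windowSnps` sites advanced by `stepSnps`; within a window,
#' whenever a retained pair has squared correlation above `r2Max`, the
#' later site (higher position) is dropped.  r^2 uses pairwise-complete
#' observations.  Deterministic for fixed input.
#'
#' @param gd a [GenotypeData-class] object.
#' @param windowSnps,stepSnps,r2Max pruning parameters
#'   (defaults 100, 10, 0.2).
#' @return integer vector of retained site indices.
#' @export
ldPrune <- function(gd, windowSnps = 100L, stepSnps = 10L, r2Max = 0.2) {
  S <- nSites(gd)
  if (S <= 1L) return(seq_len(S))
  g <- genotypes(gd)
  keep <- rep(TRUE, S)
  starts <- seq.int(1L, S, by = as.integer(stepSnps))
  for (s in starts) {
    e <- min(s + windowSnps - 1L, S)
    idx <- s:e
    idx <- idx[keep[idx]]
    if (length(idx) <= 1L) next
    sub <- t(g[idx, , drop = FALSE])
    r2 <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))^2
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (is.finite(r2[a, b]) && r2[a, b] > r2Max) keep[idx[b]] <- FALSE
      }
    }
    if (e == S) break
  }
  which(keep)
}

#' Write / read window and site tables
#'
#' Window tables are written BED-like: the first three columns are
#' `chrom`, `start`, `end` in 0-based half-open coordinates, with a
#' header line naming all columns.  Site tables carry 1-based `pos`.
#' Floating-point values are written at 6 significant digits.
#'
#' @param df data.frame; for windows it must contain `chrom`, `start`,
#'   `end`; for sites `chrom` and `pos`.
#' @param path output/input file.
#' @return `path` invisibly (writers); a data.frame (readers).
#' @export
writeWindowTable <- function(df, path) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("window table needs columns %s", paste(need, collapse = ", "))
  df <- df[, c(need, setdiff(names(df), need)), drop = FALSE]
  write.table(.fmt_num_cols(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowTable
#' @export
readWindowTable <- function(path) read.delim(path, check.names = FALSE)

#' @rdname writeWindowTable
#' @export
writeSiteTable <- function(df, path) {
  need <- c("chrom", "pos")
  if (!all(need %in% names(df)))
    .stopf("site table needs columns %s", paste(need, collapse = ", "))
  df <- df[, c(need, setdiff(names(df), need)), drop = FALSE]
  write.table(.fmt_num_cols(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowTable
#' @export
readSiteTable <- function(path) read.delim(path, check.names = FALSE)

#' Read / write a sample-to-population map
#'
#' The map file is TSV `sample<TAB>population` with a header; the
#' optional roles file is TSV `population<TAB>role` (roles separated by
#' commas when a population carries several) with optional `donorA` and
#' `donorB` columns for hybrid populations.
#'
#' @param path map TSV.
#' @param rolesPath optional roles TSV.
#' @return a [PopMap-class] object.
#' @export
readPopMap <- function(path, rolesPath = NULL) {
  m <- read.delim(path)
  if (!all(c("sample", "population") %in% names(m)))
    .stopf("population map needs 'sample' and 'population' columns")
  roles <- list(); donors <- list()
  if (!is.null(rolesPath)) {
    r <- read.delim(rolesPath)
    for (i in seq_len(nrow(r))) {
      roles[[r$population[i]]] <- strsplit(r$role[i], ",", fixed = TRUE)[[1]]
      if (all(c("donorA", "donorB") %in% names(r)) &&
          !is.na(r$donorA[i]) && nzchar(r$donorA[i]))
        donors[[r$population[i]]] <- c(donorA = r$donorA[i],
                                       donorB = r$donorB[i])
    }
  }
  PopMap(m$sample, m$population, roles = roles, donors = donors)
}

#' @rdname readPopMap
#' @param popmap a [PopMap-class] object.
#' @param mapPath,rolesPathOut output files (roles skipped when NULL).
#' @export
writePopMap <- function(popmap, mapPath, rolesPathOut = NULL) {
  write.table(data.frame(sample = names(popmap@assignments),
                         population = unname(popmap@assignments)),
              mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rolesPathOut) && length(popmap@roles)) {
    pops <- names(popmap@roles)
    df <- data.frame(population = pops,
                     role = vapply(popmap@roles, paste, "", collapse = ","),
                     donorA = vapply(pops, function(p)
                       if (!is.null(popmap@donors[[p]]))
                         popmap@donors[[p]][["donorA"]] else "", ""),
                     donorB = vapply(pops, function(p)
                       if (!is.null(popmap@donors[[p]]))
                         popmap@donors[[p]][["donorB"]] else "", ""))
    write.table(df, rolesPathOut, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(mapPath)
}
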