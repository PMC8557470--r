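## Hand-built fixtures and independent brute-force oracles used across
## the suite.  Oracles are deliberately naive (double loops, exhaustive
## enumeration) and never share code with the implementation.

## GenotypeData from a haplotype matrix (2N x S, rows = haplotypes)
gd_from_haps <- function(hapRows, pos = NULL, chrom = "chr1",
                         samples = NULL) {
  stopifnot(nrow(hapRows) %% 2 == 0)
  n <- nrow(hapRows) / 2
  S <- ncol(hapRows)
  samples <- samples %||% sprintf("s%02d", seq_len(n))
  pos <- pos %||% seq(10L, by = 10L, length.out = S)
  a1 <- t(hapRows[seq(1, nrow(hapRows), 2), , drop = FALSE])
  a2 <- t(hapRows[seq(2, nrow(hapRows), 2), , drop = FALSE])
  g <- a1 + a2
  colnames(g) <- samples
  hap <- matrix(NA_integer_, S, 2 * n)
  hap[, seq(1, 2 * n, 2)] <- a1
  hap[, seq(2, 2 * n, 2)] <- a2
  colnames(hap) <- paste0(rep(samples, each = 2), c("_1", "_2"))
  GenotypeData(g, rep(chrom, S), pos, rep("A", S), rep("G", S),
               haplotypes = hap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## GenotypeData from a genotype matrix (sites x samples), unphased
gd_from_geno <- function(g, pos = NULL, chrom = "chr1") {
  if (is.null(colnames(g))) colnames(g) <- sprintf("s%02d", seq_len(ncol(g)))
  pos <- pos %||% seq(10L, by = 10L, length.out = nrow(g))
  GenotypeData(g, rep(chrom, nrow(g)), pos, rep("A", nrow(g)),
               rep("G", nrow(g)))
}

popmap_even <- function(gd, pops) {
  stopifnot(nSamples(gd) %% length(pops) == 0)
  PopMap(sampleIds(gd), rep(pops, each = nSamples(gd) / length(pops)))
}

## ---- oracles --------------------------------------------------------

## all-pairs pi over a haplotype matrix (rows = haplotypes)
oracle_pi <- function(hapRows, lengthBp) {
  n <- nrow(hapRows)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(hapRows[i, ] != hapRows[j, ])
    np <- np + 1
  }
  tot / np / lengthBp
}

## all-pairs dxy between two haplotype matrices
oracle_dxy <- function(h1, h2, lengthBp) {
  tot <- 0; np <- 0
  for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
    tot <- tot + sum(h1[i, ] != h2[j, ])
    np <- np + 1
  }
  tot / np / lengthBp
}

## Hudson FST, ratio of sums from per-site frequencies and hap counts
oracle_hudson_fst <- function(h1, h2) {
  num <- den <- 0
  for (m in seq_len(ncol(h1))) {
    p1 <- mean(h1[, m]); p2 <- mean(h2[, m])
    n1 <- nrow(h1); n2 <- nrow(h2)
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

## Benjamini-Hochberg step-up, literal
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= alpha * i / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

## greedy LD pruning, literal re-implementation with direct r2
oracle_ld_prune <- function(g, windowSnps, stepSnps, r2Max) {
  S <- nrow(g)
  keep <- rep(TRUE, S)
  r2 <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) return(NA_real_)
    suppressWarnings(cor(a[ok], b[ok]))^2
  }
  s <- 1
  repeat {
    e <- min(s + windowSnps - 1, S)
    idx <- (s:e)[keep[s:e]]
    if (length(idx) > 1) {
      for (ai in seq_along(idx)) {
        i <- idx[ai]
        if (!keep[i]) next
        for (bi in seq_along(idx)) {
          j <- idx[bi]
          if (bi <= ai || !keep[j]) next
          v <- r2(g[i, ], g[j, ])
          if (is.finite(v) && v > r2Max) keep[j] <- FALSE
        }
      }
    }
    if (e == S) break
    s <- s + stepSnps
  }
  which(keep)
}

## HAF via explicit double loop
oracle_haf <- function(hapRows) {
  n <- nrow(hapRows)
  out <- numeric(n)
  for (h in seq_len(n)) {
    acc <- 0
    for (m in seq_len(ncol(hapRows))) {
      if (hapRows[h, m] == 1) acc <- acc + sum(hapRows[, m])
    }
    out[h] <- acc
  }
  out
}

## SAFE via the definition, using oracle_haf
oracle_safe <- function(hapRows) {
  haf <- oracle_haf(hapRows)
  keys <- apply(hapRows, 1, paste, collapse = "")
  distinct <- unique(keys)
  out <- data.frame(phi = numeric(ncol(hapRows)),
                    kappa = numeric(ncol(hapRows)),
                    safe = numeric(ncol(hapRows)))
  for (m in seq_len(ncol(hapRows))) {
    carriers <- hapRows[, m] == 1
    phi <- sum(haf[carriers]) / sum(haf)
    kap <- length(unique(keys[carriers])) / length(distinct)
    out$phi[m] <- phi
    out$kappa[m] <- kap
    out$safe[m] <- if (kap <= 0 || kap >= 1) 0 else
      (phi - kap) / sqrt(kap * (1 - kap))
  }
  out
}

## exhaustive 2-state HMM posterior for one haplotype chain
oracle_hmm_posterior <- function(alleles, fA, fB, pos, g, r, eps, prior) {
  S <- length(alleles)
  states <- as.matrix(expand.grid(rep(list(1:2), S)))  # 1 = A, 2 = B
  emis <- function(a, st, i) {
    if (is.na(a)) return(1)
    f <- if (st == 1) fA[i] else fB[i]
    e <- eps + f * (1 - 2 * eps)
    if (a == 1) e else 1 - e
  }
  trans <- function(s1, s2, d) {
    th <- 1 - exp(-g * r * d)
    stay <- if (s2 == 1) th * prior else th * (1 - prior)
    if (s1 == s2) 1 - th + stay else stay
  }
  probs <- apply(states, 1, function(st) {
    p <- if (st[1] == 1) prior else 1 - prior
    p <- p * emis(alleles[1], st[1], 1)
    for (i in seq_len(S - 1)) {
      p <- p * trans(st[i], st[i + 1], pos[i + 1] - pos[i]) *
        emis(alleles[i + 1], st[i + 1], i + 1)
    }
    p
  })
  vapply(seq_len(S), function(i)
    sum(probs[states[, i] == 2]) / sum(probs), numeric(1))
}

## direct beta: similarity-weighted flank count minus Watterson-shaped
## expectation (mirrors the documented definition, independent code path)
oracle_beta <- function(pos, folded, core, halfwidth, maxDiff, nHap,
                        density) {
  ks <- seq_len(nHap %/% 2)
  psi <- (1 / ks + 1 / (nHap - ks)) / ifelse(ks == nHap - ks, 2, 1)
  fk <- ks / nHap
  mk <- sum(pmax(0, 1 - abs(fk - folded[core]) / maxDiff) * psi) / sum(psi)
  sw <- 0
  for (j in seq_along(pos)) {
    if (j == core) next
    if (abs(pos[j] - pos[core]) <= halfwidth)
      sw <- sw + max(0, 1 - abs(folded[j] - folded[core]) / maxDiff)
  }
  sw - density * 2 * halfwidth * mk
}
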