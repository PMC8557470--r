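## Haplotype-allele-frequency (HAF) based positive-selection scan:
## per-haplotype HAF scores, per-variant SAFE scores in 50%-overlapping
## windows, and an aggregated iSAFE-style score with the > 0.1
## significance rule and an optional case/control contrast.
##
## Haplotype matrices here are haplotypes x variants with entries 1 where
## the haplotype carries the derived allele.  All computations are
## deterministic and invariant to haplotype/sample order.

#' Per-haplotype HAF scores
#'
#' `HAF(h)` is the sum, over the derived alleles carried by haplotype h,
#' of each allele's derived count in the sample.
#'
#' @param hap haplotypes x variants 0/1 matrix (derived coding, phased).
#' @return numeric HAF score per haplotype (0 for a monomorphic region).
#' @export
hafScores <- function(hap) {
  if (anyNA(hap))
    .stopf("hafScores requires phased, complete haplotypes; phase or simulate phased data upstream")
  if (ncol(hap) == 0L) return(numeric(nrow(hap)))
  counts <- colSums(hap)
  as.numeric(hap %*% counts)
}

#' Per-variant SAFE scores in one window
#'
#' For variant m: `phi(m)` is the fraction of the window's total HAF
#' mass carried by the haplotypes bearing m; `kappa(m)` is the fraction
#' of distinct window haplotypes among the carriers;
#' `SAFE(m) = (phi - kappa) / sqrt(kappa (1 - kappa))`, defined as 0 when
#' kappa is 0 or 1 (e.g. a variant carried by every haplotype).
#'
#' @param hap haplotypes x variants 0/1 matrix for the window (needs
#'   >= 2 distinct haplotypes).
#' @return data.frame with `variant` (column index), `phi`, `kappa`,
#'   `safe`; empty when the window carries no derived alleles (HAF all
#'   zero).
#' @export
safeScores <- function(hap) {
  haf <- hafScores(hap)
  tot <- sum(haf)
  if (tot == 0) {
    message("safeScores: no derived alleles in window; SAFE undefined")
    return(data.frame(variant = integer(), phi = numeric(),
                      kappa = numeric(), safe = numeric()))
  }
  key <- apply(hap, 1L, paste, collapse = "")
  uniq <- !duplicated(key)
  nDistinct <- sum(uniq)
  if (nDistinct < 2L)
    .stopf("safeScores: window must contain >= 2 distinct haplotypes")
  phi <- as.numeric(crossprod(hap, haf)) / tot
  kappa <- colSums(hap[uniq, , drop = FALSE]) / nDistinct
  safe <- ifelse(kappa <= 0 | kappa >= 1, 0,
                 (phi - kappa) / sqrt(kappa * (1 - kappa)))
  data.frame(variant = seq_len(ncol(hap)), phi = phi, kappa = kappa,
             safe = safe)
}

## window starts over variant indices with ~overlap fraction shared;
## the final window is anchored at the end so every variant is covered
## by a full-size window
.isafe_windows <- function(nVar, windowSize) {
  w <- min(windowSize, nVar)
  step <- max(1L, as.integer(floor(w / 2)))
  starts <- seq.int(1L, max(1L, nVar - w + 1L), by = step)
  if (starts[length(starts)] + w - 1L < nVar)
    starts <- c(starts, nVar - w + 1L)
  lapply(starts, function(s) s:(s + w - 1L))
}

#' iSAFE-style aggregated sweep scan
#'
#' Computes SAFE scores in 50%-overlapping windows across the region and
#' aggregates them per variant into an iSAFE score on a [0, 1] scale:
#' within each window every variant contributes its positive SAFE
#' numerator `max(phi - kappa, 0)` (the excess of HAF mass over distinct
#' carriers, a [0, 1] quantity that orders variants like SAFE does
#' within a frequency class), and contributions are averaged across the
#' windows containing the variant, weighted by each window's total
#' positive SAFE mass (its sweep evidence).  A variant is flagged
#' significant when its score is strictly greater than `threshold`.
#'
#' In case/control mode the scan runs on the pooled case + control
#' haplotypes and each variant's score is damped by
#' `max(0, fCase - fControl) / fCase`, down-weighting variants at
#' similar frequency in the controls (shared, non-sweep variation).
#'
#' @param hap haplotypes x variants 0/1 derived-coded matrix (phased).
#'   In contrast mode, the case haplotypes; controls given separately.
#' @param pos 1-based position per variant.
#' @param windowSize window size (default 300), in `unit` = "variants"
#'   (default) or "bp".
#' @param unit `"variants"` or `"bp"`; with "bp" the window is converted
#'   to the equivalent variant count at the region's SNP density.
#' @param overlap fraction of window shared by consecutive windows
#'   (fixed design: 0.5).
#' @param threshold significance rule, strict: score > threshold flags a
#'   variant (default 0.1).
#' @param control optional control haplotypes x variants matrix (same
#'   variants) enabling case/control mode.
#' @return data.frame with `pos`, `isafe`, `significant`, plus
#'   `f_case`/`f_control` in contrast mode.  A region shorter than one
#'   window falls back to a single window with a warning.
#' @export
isafeScan <- function(hap, pos, windowSize = 300L,
                      unit = c("variants", "bp"), overlap = 0.5,
                      threshold = 0.1, control = NULL) {
  unit <- match.arg(unit)
  stopifnot(ncol(hap) == length(pos))
  pool <- if (is.null(control)) hap else rbind(hap, control)
  if (anyNA(pool)) .stopf("isafeScan requires phased, complete haplotypes")
  ## restrict to variants segregating in the pool
  cnt <- colSums(pool)
  keep <- cnt > 0L
  pool <- pool[, keep, drop = FALSE]
  kpos <- pos[keep]
  nVar <- ncol(pool)
  out <- data.frame(pos = pos, isafe = 0, significant = FALSE)
  if (nVar == 0L) return(out)
  if (unit == "bp") {
    span <- max(kpos) - min(kpos) + 1
    nPerWin <- max(2L, as.integer(round(nVar * windowSize / span)))
  } else nPerWin <- as.integer(windowSize)
  if (nVar < nPerWin)
    .warnf("isafeScan: region shorter than one window; single-window fallback")
  wins <- .isafe_windows(nVar, nPerWin)
  num <- den <- numeric(nVar)
  for (w in wins) {
    sf <- safeScores(pool[, w, drop = FALSE])
    if (!nrow(sf)) next
    evidence <- sum(pmax(sf$safe, 0))
    if (evidence <= 0) next
    num[w] <- num[w] + evidence * pmax(sf$phi - sf$kappa, 0)
    den[w] <- den[w] + evidence
  }
  isafe <- ifelse(den > 0, num / den, 0)
  if (!is.null(control)) {
    fCase <- colMeans(hap[, keep, drop = FALSE])
    fCtrl <- colMeans(control[, keep, drop = FALSE])
    damp <- ifelse(fCase > 0, pmax(0, fCase - fCtrl) / fCase, 0)
    isafe <- isafe * damp
    out$f_case <- out$f_control <- NA_real_
    out$f_case[keep] <- fCase
    out$f_control[keep] <- fCtrl
  }
  out$isafe[keep] <- isafe
  out$significant <- out$isafe > threshold
  out
}

#' Extract derived-coded haplotypes for a sample set
#'
#' Builds the haplotypes x variants matrix used by the sweep scan from a
#' phased [GenotypeData-class]: restricts to outgroup-polarized sites,
#' recodes alleles so 1 means derived, and returns the haplotypes of the
#' requested samples.
#'
#' @param gd a phased [GenotypeData-class].
#' @param popmap a [PopMap-class] (for the outgroup polarization).
#' @param samples sample ids whose haplotypes to extract.
#' @param outgroup optional outgroup label (default: role "O").
#' @return list with `hap` (haplotypes x variants), `pos`, and
#'   `siteIdx` (indices into `gd` of the polarized sites used).
#' @export
derivedHaplotypes <- function(gd, popmap, samples, outgroup = NULL) {
  if (!hasPhase(gd)) .stopf("derivedHaplotypes requires phased input")
  fr <- alleleFreqs(gd, popmap, outgroup = outgroup)
  idx <- which(fr$polarized)
  h <- haplotypes(gd)
  cols <- as.vector(vapply(samples, function(s)
    match(paste0(s, c("_1", "_2")), colnames(h)), integer(2)))
  hm <- t(h[idx, cols, drop = FALSE])
  flip <- !fr$altIsDerived[idx]
  hm[, flip] <- 1L - hm[, flip]
  rownames(hm) <- colnames(h)[cols]
  list(hap = hm, pos = positions(gd)[idx], siteIdx = idx)
}
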