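## Supervised global ancestry, local-ancestry dosage HMM, and the allele
## dosage difference (ADD).
##
## The local-ancestry model is a deliberately transparent single-layer
## panel-frequency HMM (a surrogate for two-layer haplotype-cluster
## models): hidden state = donor ancestry per haplotype, emissions
## Bernoulli(panel frequency) with error epsilon, transitions
## 1 - exp(-g * r * distance).  It is small enough to be validated
## against exhaustive path enumeration.

#' Supervised global admixture proportions
#'
#' Per-sample ancestry proportions over donor panels, obtained by
#' least squares: minimize || g/2 - F q || over the probability simplex,
#' where g are the sample's genotype dosages and F the donor panels'
#' allele frequencies.  With K donor panels the exact simplex optimum is
#' found by enumerating active sets (K is small).
#'
#' @param gd a [GenotypeData-class].
#' @param popmap a [PopMap-class].
#' @param donorPops >= 2 donor population labels (each needs >= 5
#'   samples).
#' @param samples samples to decompose (default: all samples in `gd`).
#' @param siteIdx optional site subset (e.g. an LD-pruned set).
#' @return matrix samples x donors of proportions (rows sum to 1).
#' @export
supervisedAdmixture <- function(gd, popmap, donorPops, samples = NULL,
                                siteIdx = NULL) {
  if (length(donorPops) < 2L) .stopf("need at least two donor panels")
  for (d in donorPops)
    if (length(samplesOf(popmap, d)) < 5L)
      .stopf("donor panel '%s' has fewer than 5 samples", d)
  if (!is.null(siteIdx)) gd <- gd[siteIdx, ]
  g <- genotypes(gd)
  Fm <- sapply(donorPops, function(d) {
    sub <- g[, samplesOf(popmap, d), drop = FALSE]
    nm <- rowSums(!is.na(sub))
    ifelse(nm > 0, rowSums(sub, na.rm = TRUE) / (2 * nm), NA_real_)
  })
  informative <- rowSums(!is.finite(Fm)) == 0 &
    apply(Fm, 1, function(x) max(x) - min(x)) > 0
  if (!any(informative))
    .stopf("donor panels are monomorphic/identical at every usable site")
  Fm <- Fm[informative, , drop = FALSE]
  samples <- samples %||% sampleIds(gd)
  out <- matrix(NA_real_, length(samples), length(donorPops),
                dimnames = list(samples, donorPops))
  for (s in samples) {
    y <- g[informative, s] / 2
    ok <- is.finite(y)
    out[s, ] <- .simplex_lsq(Fm[ok, , drop = FALSE], y[ok])
  }
  out
}

## exact least squares on the probability simplex by active-set
## enumeration (K small): for every non-empty donor subset solve the
## sum-to-one equality-constrained problem and keep the feasible optimum.
.simplex_lsq <- function(X, y) {
  K <- ncol(X)
  best <- NULL; bestObj <- Inf
  subsets <- unlist(lapply(seq_len(K), function(k)
    utils::combn(K, k, simplify = FALSE)), recursive = FALSE)
  for (ss in subsets) {
    Xs <- X[, ss, drop = FALSE]
    k <- length(ss)
    A <- rbind(cbind(crossprod(Xs), rep(1, k)), c(rep(1, k), 0))
    b <- c(crossprod(Xs, y), 1)
    q <- tryCatch(solve(A, b)[seq_len(k)], error = function(e) NULL)
    if (is.null(q) || any(q < -1e-9)) next
    obj <- sum((y - Xs %*% q)^2)
    if (obj < bestObj - 1e-12) {
      bestObj <- obj
      best <- numeric(K); best[ss] <- pmax(q, 0)
    }
  }
  if (is.null(best)) best <- rep(1 / K, K)
  best / sum(best)
}

#' Local-ancestry HMM configuration
#'
#' @param g generations since admixture (default 100).
#' @param recombRate recombination rate per bp used to scale transitions
#'   (default 3e-7; with g = 100 this matches ancestry segments of a few
#'   tens of kb, the scale of the package's reference simulations).
#' @param eps allele-emission error in (0, 0.5) (default 0.02).
#' @param prior prior (stationary) probability of donor-A ancestry.
#' @return an `hmm_config` list.
#' @export
hmmConfig <- function(g = 100L, recombRate = 3e-7, eps = 0.02, prior = 0.5) {
  stopifnot(g >= 1, eps > 0, eps < 0.5, prior > 0, prior < 1, recombRate > 0)
  structure(list(g = as.integer(g), recombRate = recombRate, eps = eps,
                 prior = prior), class = "hmm_config")
}

#' Local-ancestry dosage via a two-donor HMM
#'
#' Posterior donor dosages per site for each sample of a hybrid
#' population.  Phased input runs a 2-state chain per haplotype;
#' unphased input runs the 4-state product chain over composite diploid
#' states (equivalently the 3 unordered states AA/AB/BB with binomial
#' emissions).  Emission probability of a derived allele under donor k is
#' `eps + f_k (1-2 eps)` with `f_k` the donor-panel frequency; sites
#' where either panel frequency is unavailable get uninformative
#' emissions, so their dosage is interpolated through the transition
#' model.  Transitions between adjacent sites at distance d:
#' switch probability `1 - exp(-g * r * d)` toward the stationary prior.
#' Per-sample dosage is the mean posterior donor-B probability of the
#' two haplotypes; per-site ADD is `|mean dosage A - mean dosage B|`
#' over the population.
#'
#' @param gd a [GenotypeData-class].
#' @param popmap a [PopMap-class].
#' @param hybridPop hybrid population to decode.
#' @param donors c(donorA, donorB) population labels; default: the
#'   panels recorded for `hybridPop` in the map.
#' @param cfg an [hmmConfig()].
#' @param usePhase use phased haplotypes when present (default TRUE).
#' @return a [DosageTrack-class].
#' @export
ancestryDosageHmm <- function(gd, popmap, hybridPop, donors = NULL,
                              cfg = hmmConfig(), usePhase = TRUE) {
  donors <- donors %||% unname(hybridDonors(popmap, hybridPop))
  stopifnot(length(donors) == 2L)
  g <- genotypes(gd)
  panelFreq <- function(d) {
    sub <- g[, samplesOf(popmap, d), drop = FALSE]
    nm <- rowSums(!is.na(sub))
    ifelse(nm > 0, rowSums(sub, na.rm = TRUE) / (2 * nm), NA_real_)
  }
  fA <- panelFreq(donors[1]); fB <- panelFreq(donors[2])
  eps <- cfg$eps
  eA <- eps + fA * (1 - 2 * eps)
  eB <- eps + fB * (1 - 2 * eps)
  informative <- is.finite(eA) & is.finite(eB)
  hy <- samplesOf(popmap, hybridPop)
  pos <- positions(gd)
  theta <- 1 - exp(-cfg$g * cfg$recombRate * diff(pos))
  theta[diff(pos) <= 0] <- 0.5   # chromosome change: reset to stationary
  if (usePhase && hasPhase(gd)) {
    h <- haplotypes(gd)
    cols <- as.vector(vapply(hy, function(s)
      match(paste0(s, c("_1", "_2")), colnames(h)), integer(2)))
    A <- h[, cols, drop = FALSE]
    post <- .fb_2state(A, eA, eB, informative, theta, cfg$prior)
    dosB <- (post[, seq(1, ncol(post), 2), drop = FALSE] +
             post[, seq(2, ncol(post), 2), drop = FALSE]) / 2
  } else {
    G <- g[, hy, drop = FALSE]
    dosB <- .fb_diploid(G, eA, eB, informative, theta, cfg$prior)
  }
  colnames(dosB) <- hy
  meanB <- rowMeans(dosB)
  meanA <- 1 - meanB
  new("DosageTrack", chrom = chroms(gd), pos = as.integer(pos), samples = hy,
      donors = donors, dosageB = dosB, meanA = meanA, meanB = meanB,
      add = abs(meanA - meanB))
}

## scaled forward-backward over 2 states (A, B), vectorised across
## haplotype chains; returns sites x chains posterior P(state = B)
.fb_2state <- function(A, eA, eB, informative, theta, prior) {
  S <- nrow(A); n <- ncol(A)
  ## precomputed emission likelihoods, sites x chains, per state
  EA <- matrix(1, S, n); EB <- matrix(1, S, n)
  obs <- !is.na(A) & informative
  one <- obs & A == 1L; zero <- obs & A == 0L
  EA[one] <- rep(eA, n)[one]; EA[zero] <- rep(1 - eA, n)[zero]
  EB[one] <- rep(eB, n)[one]; EB[zero] <- rep(1 - eB, n)[zero]
  piv <- c(prior, 1 - prior)
  fA <- matrix(0, S, n); fB_ <- matrix(0, S, n)
  aA <- piv[1] * EA[1, ]; aB <- piv[2] * EB[1, ]
  sc <- aA + aB; aA <- aA / sc; aB <- aB / sc
  fA[1, ] <- aA; fB_[1, ] <- aB
  if (S > 1) for (i in 2:S) {
    th <- theta[i - 1]
    pA <- aA * (1 - th + th * piv[1]) + aB * th * piv[1]
    pB <- aA * th * piv[2] + aB * (1 - th + th * piv[2])
    aA <- pA * EA[i, ]; aB <- pB * EB[i, ]
    sc <- aA + aB; aA <- aA / sc; aB <- aB / sc
    fA[i, ] <- aA; fB_[i, ] <- aB
  }
  bA <- rep(1, n); bB <- rep(1, n)
  post <- matrix(0, S, n)
  post[S, ] <- fB_[S, ] * bB / (fA[S, ] * bA + fB_[S, ] * bB)
  if (S > 1) for (i in (S - 1):1) {
    th <- theta[i]
    eAn <- EA[i + 1, ] * bA; eBn <- EB[i + 1, ] * bB
    nbA <- (1 - th + th * piv[1]) * eAn + th * piv[2] * eBn
    nbB <- th * piv[1] * eAn + (1 - th + th * piv[2]) * eBn
    sc <- nbA + nbB; bA <- nbA / sc; bB <- nbB / sc
    num <- fB_[i, ] * bB
    post[i, ] <- num / (fA[i, ] * bA + num)
  }
  post
}

## 4-state (ordered haplotype-pair) product chain for unphased input;
## returns sites x samples posterior donor-B dosage
.fb_diploid <- function(G, eA, eB, informative, theta, prior) {
  S <- nrow(G); n <- ncol(G)
  piv <- c(prior, 1 - prior)
  pi4 <- c(piv[1] * piv[1], piv[1] * piv[2], piv[2] * piv[1], piv[2] * piv[2])
  stateP <- function(i) rbind(c(eA[i], eA[i]), c(eA[i], eB[i]),
                              c(eB[i], eA[i]), c(eB[i], eB[i]))
  emis <- function(i) {
    gi <- G[i, ]
    out <- matrix(1, n, 4)
    if (!informative[i]) return(out)
    sp <- stateP(i)
    for (k in 1:4) {
      p1 <- sp[k, 1]; p2 <- sp[k, 2]
      lik <- ifelse(is.na(gi), 1,
                    ifelse(gi == 0L, (1 - p1) * (1 - p2),
                           ifelse(gi == 1L, p1 * (1 - p2) + p2 * (1 - p1),
                                  p1 * p2)))
      out[, k] <- lik
    }
    out
  }
  hapT <- function(th) matrix(c(1 - th + th * piv[1], th * piv[2],
                                th * piv[1], 1 - th + th * piv[2]),
                              2, 2, byrow = TRUE)
  T4 <- function(th) {
    t2 <- hapT(th)
    kronecker(t2, t2)
  }
  fwd <- array(0, c(S, n, 4))
  a <- sweep(emis(1), 2, pi4, `*`)
  a <- a / rowSums(a)
  fwd[1, , ] <- a
  if (S > 1) for (i in 2:S) {
    tm <- T4(theta[i - 1])
    a <- (a %*% tm) * emis(i)
    a <- a / rowSums(a)
    fwd[i, , ] <- a
  }
  dosOf <- c(0, 0.5, 0.5, 1)
  post <- matrix(0, S, n)
  b <- matrix(1, n, 4)
  pi_ <- fwd[S, , , drop = TRUE]
  if (n == 1) pi_ <- matrix(pi_, 1, 4)
  post[S, ] <- (pi_ * b) %*% dosOf / rowSums(pi_ * b)
  if (S > 1) for (i in (S - 1):1) {
    tm <- T4(theta[i])
    b <- (emis(i + 1) * b) %*% t(tm)
    b <- b / rowSums(b)
    f <- fwd[i, , , drop = TRUE]
    if (n == 1) f <- matrix(f, 1, 4)
    w <- f * b
    post[i, ] <- (w %*% dosOf) / rowSums(w)
  }
  post
}

#' ADD quantile threshold and high-ADD mask
#'
#' Empirical quantile (linear interpolation, type 7) of the ADD values
#' with a `>=` tie rule at the threshold.
#'
#' @param add finite ADD values (or a [DosageTrack-class]).
#' @param q quantile (default 0.75).
#' @return list with `threshold` and logical `mask`.
#' @export
addQuantileMask <- function(add, q = 0.75) {
  if (is(add, "DosageTrack")) add <- addScores(add)
  if (!length(add)) .stopf("addQuantileMask: empty input")
  if (any(!is.finite(add))) .stopf("addQuantileMask: ADD must be finite")
  thr <- quantile(add, q, type = 7, names = FALSE)
  list(threshold = thr, mask = add >= thr)
}
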