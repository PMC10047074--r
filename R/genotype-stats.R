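#' Per-locus genotype summaries for a single population
#'
#' Expected heterozygosity is the plug-in quantity `1 - sum(p^2)` from the
#' typed individuals; observed heterozygosity is the fraction of typed
#' individuals that are heterozygous; `fis` is the Weir-Cockerham (1984)
#' single-population f, reported `NA` at monomorphic loci; the null-allele
#' frequency column applies [brookfieldNullFreq()] per locus.
#'
#' @param table a [GenotypeTable-class].
#' @return list with `loci` (data.frame of per-locus summaries) and
#'   `overall` (mean expected heterozygosity with a normal-theory 95 percent
#'   CI across loci, and mean allele number).
#' @export
locusSummaries <- function(table) {
  L <- nLoci(table)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    a1 <- table@allele1[, l]; a2 <- table@allele2[, l]
    keep <- !is.na(a1)
    nTyped <- sum(keep)
    a1 <- a1[keep]; a2 <- a2[keep]
    nAll <- length(table@alleleRegistry[[l]])
    cnt <- tabulate(c(a1, a2), nbins = nAll)
    p <- cnt / sum(cnt)
    he <- 1 - sum(p^2)
    ho <- mean(a1 != a2)
    out[[l]] <- data.frame(
      locus = locusNames(table)[l], n_typed = nTyped, n_alleles = nAll,
      expected_het = he, observed_het = ho,
      fis = .wcF(a1, a2, nAll),
      null_allele_freq = brookfieldNullFreq(he, ho),
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, out)
  he <- loci$expected_het
  se <- sd(he) / sqrt(length(he))
  overall <- list(
    mean_expected_het = mean(he),
    ci_expected_het = mean(he) + c(-1, 1) * qnorm(0.975) * se,
    mean_n_alleles = mean(loci$n_alleles),
    fis_overall = .wcFOverall(table))
  list(loci = loci, overall = overall)
}

# Weir & Cockerham (1984) single-population f for one locus.
# With one population only the within (b) and between-gamete (c) components
# remain: c_m = hbar_m / 2, b_m = n/(n-1) * (p_m (1-p_m) - (2n-1)/(4n) hbar_m),
# f = 1 - sum(c) / sum(b + c).
.wcComponents <- function(a1, a2, nAll) {
  n <- length(a1)
  cnt <- tabulate(c(a1, a2), nbins = nAll)
  p <- cnt / (2 * n)
  hbar <- vapply(seq_len(nAll), function(m)
    mean((a1 == m) != (a2 == m)), numeric(1))
  cm <- hbar / 2
  bm <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
  c(b = sum(bm), c = sum(cm))
}

.wcF <- function(a1, a2, nAll) {
  if (nAll < 2 || length(a1) < 2) return(NA_real_)
  bc <- .wcComponents(a1, a2, nAll)
  denom <- bc[["b"]] + bc[["c"]]
  if (abs(denom) < 1e-12) return(NA_real_)
  1 - bc[["c"]] / denom
}

.wcFOverall <- function(table) {
  b <- 0; cc <- 0
  for (l in seq_len(nLoci(table))) {
    a1 <- table@allele1[, l]; a2 <- table@allele2[, l]
    keep <- !is.na(a1)
    nAll <- length(table@alleleRegistry[[l]])
    if (sum(keep) < 2 || nAll < 2) next
    bc <- .wcComponents(a1[keep], a2[keep], nAll)
    b <- b + bc[["b"]]; cc <- cc + bc[["c"]]
  }
  if (abs(b + cc) < 1e-12) return(NA_real_)
  1 - cc / (b + cc)
}

#' Brookfield (1996) estimator 1 of null-allele frequency
#'
#' For a locus with no observed null homozygotes the estimated frequency
#' is `(He - Ho) / (1 + He)`, clamped at zero when there is a
#' heterozygote excess.
#'
#' @param expectedHet,observedHet proportions in `[0, 1]`.
#' @return estimated null-allele frequency.
#' @export
brookfieldNullFreq <- function(expectedHet, observedHet) {
  stopifnot(expectedHet >= 0, expectedHet <= 1,
            observedHet >= 0, observedHet <= 1)
  max(0, (expectedHet - observedHet) / (1 + expectedHet))
}

#' Multilocus homozygosity of one individual
#'
#' Fraction of typed loci at which both allele labels are identical;
#' missing calls are excluded.
#'
#' @param table a [GenotypeTable-class].
#' @param individual individual id.
#' @return proportion in `[0, 1]`.
#' @export
multilocusHomozygosity <- function(table, individual) {
  i <- match(individual, individualIds(table))
  if (is.na(i)) stop("unknown individual: ", individual)
  a1 <- table@allele1[i, ]; a2 <- table@allele2[i, ]
  keep <- !is.na(a1)
  if (!any(keep))
    stop("individual '", individual, "' has no typed loci")
  mean(a1[keep] == a2[keep])
}

# g2 point estimate from a heterozygosity matrix (1 het, 0 hom, NA missing).
# David et al. (2007) multilocus estimator restricted, per locus pair, to
# the individuals typed at both loci: the ratio of the mean within-individual
# product of heterozygosities to the unbiased cross-individual product,
# summed over ordered locus pairs, minus one.
.g2Point <- function(h) {
  t1 <- (!is.na(h)) * 1
  h0 <- h; h0[is.na(h)] <- 0
  N <- crossprod(t1)            # jointly typed individuals per locus pair
  S <- crossprod(h0)            # sum_i h_il h_ik (only jointly typed survive)
  R <- crossprod(h0, t1)        # sum_i h_il t_ik: het sums within the pair
  ok <- N >= 2
  diag(ok) <- FALSE
  if (!any(ok)) return(NA_real_)
  num <- sum((S / N)[ok])
  den <- sum(((R * t(R) - S) / (N * (N - 1)))[ok])
  if (den <= 0) return(NA_real_)
  num / den - 1
}

#' Identity disequilibrium g2 for microsatellite data
#'
#' Multilocus g2 (David et al. 2007 estimator with missing-data handling):
#' the standardised excess covariance in heterozygosity across loci caused
#' by variance in inbreeding among individuals. The p-value permutes each
#' locus's heterozygosity column independently across individuals (the null
#' of no identity disequilibrium); the confidence interval bootstraps
#' individuals.
#'
#' @param table a [GenotypeTable-class] with at least 2 loci and 2
#'   individuals.
#' @param nPerm,nBoot permutation and bootstrap replicates (both >= 1).
#' @param seed integer seed (required for reproducibility).
#' @param level confidence level for the bootstrap interval.
#' @return list with `g2`, `p_value`, `ci`, `nPerm`, `nBoot`.
#' @export
g2Microsats <- function(table, nPerm = 1000, nBoot = 1000, seed, level = 0.95) {
  if (nPerm < 1 || nBoot < 1) stop("nPerm and nBoot must be >= 1")
  if (missing(seed)) stop("seed is required")
  stopifnot(nLoci(table) >= 2, nIndividuals(table) >= 2)
  set.seed(seed)
  h <- .hetMatrix(table)
  n <- nrow(h)
  obs <- .g2Point(h)
  permVals <- vapply(seq_len(nPerm), function(b) {
    hp <- h
    for (l in seq_len(ncol(h))) hp[, l] <- h[sample.int(n), l]
    .g2Point(hp)
  }, numeric(1))
  pval <- (1 + sum(permVals >= obs, na.rm = TRUE)) / (1 + nPerm)
  bootVals <- vapply(seq_len(nBoot), function(b)
    .g2Point(h[sample.int(n, replace = TRUE), , drop = FALSE]),
    numeric(1))
  alpha <- (1 - level) / 2
  ci <- quantile(bootVals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(g2 = obs, p_value = pval, ci = ci, nPerm = nPerm, nBoot = nBoot)
}

#' Correlation between multilocus homozygosity and estimated F
#'
#' Pearson correlation of per-individual multilocus homozygosity against
#' point estimates of the inbreeding coefficient.
#'
#' @param table a [GenotypeTable-class].
#' @param fEstimates named numeric vector of F point estimates covering the
#'   table's individuals.
#' @return correlation, or `NA` with a warning when either vector is
#'   constant.
#' @export
hetFCorrelation <- function(table, fEstimates) {
  ids <- individualIds(table)
  if (!all(ids %in% names(fEstimates)))
    stop("fEstimates must be named and cover all individuals")
  hom <- vapply(ids, function(id) multilocusHomozygosity(table, id),
                numeric(1))
  f <- fEstimates[ids]
  if (sd(hom) < 1e-12 || sd(f) < 1e-12) {
    warning("zero variance in homozygosity or F; correlation undefined")
    return(NA_real_)
  }
  cor(hom, f)
}
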