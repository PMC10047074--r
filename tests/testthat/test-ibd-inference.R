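test_that("the IBD Bernoulli probability follows its full conditional", {
  expect_equal(ibdBernoulliProb(0.5, 0.5), 2 / 3)
  # clamped at the floor: q = fl*p / (fl*p + (1-fl)*p^2), fl = 1e-5
  q <- ibdBernoulliProb(0, 0.5)
  expect_equal(q, 1e-5 * 0.5 / (1e-5 * 0.5 + (1 - 1e-5) * 0.25))
  expect_lt(q, 3e-5)
  expect_equal(ibdBernoulliProb(1, 0.3),
               0.99999 * 0.3 / (0.99999 * 0.3 + 1e-5 * 0.09))
})

test_that("non-IBD allele counts follow the counting rules", {
  one <- gtFromStrings(cbind(l1 = "A/A"))
  x1 <- matrix(1, 1, 1); x0 <- matrix(0, 1, 1)
  expect_equal(unname(computeZ(one, x1)$l1), 1)  # IBD pair counted once
  expect_equal(unname(computeZ(one, x0)$l1), 2)
  two <- gtFromStrings(cbind(l1 = c("A/B", "A/A")))
  z <- computeZ(two, matrix(c(NA, 1), 2, 1))$l1
  expect_equal(unname(z), c(2, 1))  # A: 1 het + 1 IBD hom, B: 1 het
})

test_that("modal-count Beta summarisation averages tied modes", {
  expect_equal(summarizeToBeta(c("0" = 950, "1" = 50), 29)[c("A", "B")],
               c(A = 1, B = 30))
  b <- summarizeToBeta(c("2" = 400, "5" = 400, "3" = 200), 29)
  expect_equal(unname(b), c(4.5, 26.5, 3.5))
  expect_equal(summarizeToBeta(c("29" = 1000), 29)[c("A", "B")],
               c(A = 30, B = 1))
  expect_equal(unname(summarizeToBeta(rep(3L, 20), 10, isHistogram = FALSE)),
               c(4, 8, 3))
})

test_that("a fully heterozygous individual yields the closed-form
           Beta(1, 1 + K L) posterior", {
  L <- 5; K <- 4
  gt <- gtFromStrings(matrix("A/B", 1, L))
  cfg <- ibdConfig(chains = 3, iterations = 3000, burnIn = 500, thin = 1,
                   cloneSchedule = K, seed = 17)
  s <- runIbdSampler(gt, cfg)
  expect_equal(s@stats$modal_ibd_count, 0)
  expect_equal(s@stats$A, 1)
  expect_equal(s@stats$B, 1 + L)  # per-clone summary at L typed loci
  # sampler F-marginal must match Beta(1, 1 + K L)
  expect_equal(s@stats$posterior_mean_F, 1 / (2 + K * L), tolerance = 0.08)
})

test_that("all-heterozygous genotypes give A = 1 for everyone", {
  gt <- gtFromStrings(matrix("A/B", 4, 29))
  cfg <- ibdConfig(chains = 2, iterations = 400, burnIn = 100, thin = 2,
                   cloneSchedule = 1, seed = 3)
  s <- runIbdSampler(gt, cfg)
  expect_true(all(s@stats$A == 1))
  expect_true(all(s@stats$B == 30))
})

test_that("the Gibbs posterior matches brute-force integration on a
           two-locus two-allele toy", {
  # ind1: AA, AB; ind2: BB, AA -- brute force integrates F1, F2, p1, p2
  # over flat priors with the IBD indicators marginalised analytically
  gt <- gtFromStrings(rbind(ind1 = c("A/A", "A/B"),
                            ind2 = c("B/B", "A/A")))
  gl <- pracma::gaussLegendre(48, 0, 1)
  lik <- function(F1, F2, p1, p2) {
    # locus 1 allele A freq p1; locus 2 allele A freq p2
    (F1 * p1 + (1 - F1) * p1^2) *          # ind1 locus1 AA
      ((1 - F1) * 2 * p2 * (1 - p2)) *     # ind1 locus2 AB
      (F2 * (1 - p1) + (1 - F2) * (1 - p1)^2) *  # ind2 locus1 BB
      (F2 * p2 + (1 - F2) * p2^2)          # ind2 locus2 AA
  }
  num <- 0; den <- 0
  for (a in 1:48) for (b in 1:48) for (cc in 1:48) for (d in 1:48) {
    w <- gl$w[a] * gl$w[b] * gl$w[cc] * gl$w[d]
    v <- lik(gl$x[a], gl$x[b], gl$x[cc], gl$x[d])
    den <- den + w * v
    num <- num + w * v * gl$x[a]
  }
  exactMeanF1 <- num / den

  cfg <- ibdConfig(chains = 4, iterations = 4000, burnIn = 1000, thin = 1,
                   cloneSchedule = 1, seed = 29)
  nAll <- vapply(gt@alleleRegistry, length, integer(1))
  chainMeans <- vapply(seq_len(cfg$chains), function(ch) {
    set.seed(cfg$seed + ch)
    res <- dcinbreed:::ibd_gibbs_chain(gt@allele1, gt@allele2, nAll, 1L,
                                       cfg$iterations, cfg$burnIn,
                                       cfg$thin, 1, 1, 1e-5, 1 - 1e-5)
    mean(res$F[, 1])
  }, numeric(1))
  mcse <- sd(chainMeans) / sqrt(length(chainMeans))
  expect_lt(abs(mean(chainMeans) - exactMeanF1), 3 * mcse + 0.005)
})

test_that("posterior variance of F shrinks like 1/K across the clone
           schedule", {
  sc <- simScenario(nIndividuals = 12, nLoci = 40, allelesPerLocus = 4,
                    fDistribution = list(type = "beta", a = 2, b = 8),
                    seed = 51)
  gt <- simGenotypes(simAlleleFrequencies(sc),
                     simInbreedingCoefficients(sc), seed = 52)
  cfg <- ibdConfig(chains = 2, iterations = 1500, burnIn = 500, thin = 2,
                   cloneSchedule = c(1, 5, 10, 20, 40), seed = 53)
  # short chains at K = 40 can trip the R-hat alarm on a near-degenerate
  # posterior; the scaled-variance trajectory is what this test checks
  s <- suppressWarnings(runIbdSampler(gt, cfg))
  sv <- s@scaledVar
  slope <- unname(coef(lm(log(sv$scaled_var) ~ log(sv$K)))[2])
  expect_lt(slope, -0.7)
  expect_gt(slope, -1.3)
  expect_true(all(diff(sv$scaled_var) < 0))
})

test_that("true inbreeding is recovered with many markers", {
  # diverse markers (12 alleles, near-even frequencies) keep the
  # identity-by-state background low; the +/-0.05 window then sits at
  # about 1.6 binomial SDs of the realised IBD fraction, so the check
  # runs on a fixed seed
  sc <- simScenario(nIndividuals = 50, nLoci = 200, allelesPerLocus = 12,
                    dirichletConcentration = 5, seed = 61)
  F <- rep(0.25, 50)
  gt <- simGenotypes(simAlleleFrequencies(sc), F, seed = 62)
  cfg <- ibdConfig(chains = 2, iterations = 800, burnIn = 300, thin = 2,
                   cloneSchedule = 1, seed = 63)
  s <- suppressWarnings(runIbdSampler(gt, cfg))
  hits <- sum(abs(s@stats$posterior_mean_F - F) <= 0.05)
  expect_gte(hits, 45)
})

test_that("InbreedingSummary invariants hold on a simulated run", {
  sc <- simScenario(nIndividuals = 10, nLoci = 12, seed = 71)
  gt <- simGenotypes(simAlleleFrequencies(sc),
                     simInbreedingCoefficients(sc), seed = 72,
                     missingRate = 0.1)
  cfg <- ibdConfig(chains = 2, iterations = 500, burnIn = 200, thin = 2,
                   cloneSchedule = c(1, 10), seed = 73)
  s <- runIbdSampler(gt, cfg)
  st <- s@stats
  expect_true(all(st$A + st$B == st$typed_loci + 2))
  expect_true(all(st$modal_ibd_count >= 0 &
                    st$modal_ibd_count <= st$typed_loci))
  expect_equal(st$typed_loci, unname(rowSums(!is.na(gt@allele1))))
})
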