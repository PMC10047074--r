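test_that("GenePop files parse: 2-digit, missing, and 3-digit dialects", {
  p <- writeGenepopText(c("toy population", "locA", "Pop",
                          "ind1 , 0101", "ind2 , 0102"))
  gt <- readGenepop(p)
  expect_equal(nIndividuals(gt), 2)
  expect_equal(nLoci(gt), 1)
  expect_equal(gt@alleleRegistry[[1]], c("01", "02"))
  expect_equal(multilocusHomozygosity(gt, "ind1"), 1)
  expect_equal(multilocusHomozygosity(gt, "ind2"), 0)

  p2 <- writeGenepopText(c("with missing", "locA, locB", "Pop",
                           "ind1 , 0101 0000", "ind2 , 0102 0203"))
  gt2 <- readGenepop(p2)
  expect_true(is.na(gt2@allele1[1, 2]))
  expect_false(is.na(gt2@allele1[2, 2]))

  p3 <- writeGenepopText(c("3-digit", "locA", "Pop", "ind1 , 001002"))
  gt3 <- readGenepop(p3)
  expect_equal(gt3@alleleRegistry[[1]], c("001", "002"))
  expect_equal(multilocusHomozygosity(gt3, "ind1"), 0)
})

test_that("GenePop parse errors name the offending line or id", {
  bad <- writeGenepopText(c("odd codes", "locA", "Pop", "ind1 , 010"))
  expect_error(readGenepop(bad), "line")
  dup <- writeGenepopText(c("dup ids", "locA", "Pop",
                            "ind1 , 0101", "ind1 , 0102"))
  expect_error(readGenepop(dup), "duplicate")
})

test_that("GenePop round trip preserves the table", {
  sc <- simScenario(nIndividuals = 12, nLoci = 5, seed = 301)
  gt <- simGenotypes(simAlleleFrequencies(sc),
                     simInbreedingCoefficients(sc), seed = 302,
                     missingRate = 0.05)
  p <- tempfile(fileext = ".gen")
  writeGenepop(gt, p)
  rt <- readGenepop(p)
  expect_equal(individualIds(rt), individualIds(gt))
  expect_equal(is.na(rt@allele1), is.na(gt@allele1),
               ignore_attr = TRUE)
  for (i in seq_len(nIndividuals(gt)))
    expect_equal(multilocusHomozygosity(rt, individualIds(gt)[i]),
                 multilocusHomozygosity(gt, individualIds(gt)[i]))
})

test_that("locus summaries match hand counts", {
  gt <- gtFromStrings(cbind(l1 = c("A/A", "A/B", "B/B", "A/B")))
  s <- locusSummaries(gt)$loci
  expect_equal(s$expected_het, 0.5)
  expect_equal(s$observed_het, 0.5)
  # Weir-Cockerham single-population f, hand-computed:
  # c = 0.5, b = (4/3)(0.25 - (7/16)/2) * 2 alleles = 1/12; f = 1/7
  expect_equal(s$fis, 1 / 7)

  allHet <- gtFromStrings(cbind(l1 = rep("A/B", 6)))
  s2 <- locusSummaries(allHet)$loci
  expect_equal(s2$observed_het, 1)
  expect_equal(s2$expected_het, 0.5)

  mono <- gtFromStrings(cbind(l1 = rep("A/A", 4),
                              l2 = c("A/B", "A/A", "B/B", "A/B")))
  s3 <- locusSummaries(mono)$loci
  expect_equal(s3$expected_het[1], 0)
  expect_equal(s3$observed_het[1], 0)
  expect_true(is.na(s3$fis[1]))
})

test_that("expected heterozygosity is invariant to allele relabelling and
           observed het and hom sum to one", {
  sc <- simScenario(nIndividuals = 25, nLoci = 6, seed = 311)
  gt <- simGenotypes(simAlleleFrequencies(sc),
                     simInbreedingCoefficients(sc), seed = 312)
  s <- locusSummaries(gt)$loci
  # relabel: reverse registry order per locus
  perm <- gt
  for (l in seq_len(nLoci(gt))) {
    nAll <- length(gt@alleleRegistry[[l]])
    map <- rev(seq_len(nAll))
    a <- map[gt@allele1[, l]]; b <- map[gt@allele2[, l]]
    perm@allele1[, l] <- pmin(a, b)
    perm@allele2[, l] <- pmax(a, b)
  }
  s2 <- locusSummaries(perm)$loci
  expect_equal(s2$expected_het, s$expected_het)
  # per-individual het + hom = 1 over typed loci
  for (id in individualIds(gt))
    expect_equal(multilocusHomozygosity(gt, id) +
                   mean(gt@allele1[id == individualIds(gt), ] !=
                          gt@allele2[id == individualIds(gt), ],
                        na.rm = TRUE), 1)
})

test_that("Brookfield null-allele estimator follows its formula", {
  expect_equal(brookfieldNullFreq(0.7, 0.7), 0)
  expect_equal(brookfieldNullFreq(0.799, 0.713), 0.04780434, tolerance = 1e-6)
  expect_equal(brookfieldNullFreq(0.5, 0.6), 0)   # clamped
  # monotone increasing in He - Ho at fixed He
  vals <- vapply(seq(0, 0.5, by = 0.05), function(d)
    brookfieldNullFreq(0.6, 0.6 - d), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("multilocus homozygosity counts typed loci only", {
  gt <- gtFromStrings(rbind(ind1 = c("A/B", "A/B", "A/B"),
                            ind2 = c("A/A", "A/B", NA)))
  expect_equal(multilocusHomozygosity(gt, "ind1"), 0)
  expect_equal(multilocusHomozygosity(gt, "ind2"), 0.5)
  expect_error(multilocusHomozygosity(gt, "nope"), "unknown")
  calls <- rbind(ind1 = c(rep("A/A", 7), rep("A/B", 21), NA),
                 ind2 = rep("A/B", 29))
  gt2 <- gtFromStrings(calls)
  expect_equal(multilocusHomozygosity(gt2, "ind1"), 0.25)
})

test_that("g2 matches an independent direct-summation oracle", {
  set.seed(41)
  for (rep in 1:4) {
    n <- sample(4:8, 1); L <- sample(2:4, 1)
    calls <- matrix(sample(c("A/A", "A/B", "B/B", NA), n * L,
                           replace = TRUE, prob = c(.3, .4, .2, .1)),
                    n, L)
    # ensure each locus typed at least twice and some variation
    calls[1, ] <- "A/B"; calls[2, ] <- "A/A"
    gt <- gtFromStrings(calls)
    h <- (gt@allele1 != gt@allele2) * 1
    expect_equal(dcinbreed:::.g2Point(h), g2BruteForce(h), tolerance = 1e-12)
  }
})

test_that("g2 is zero with a permutation p-value >= 0.5 when everyone is
           heterozygous", {
  gt <- gtFromStrings(matrix("A/B", 8, 4))
  res <- g2Microsats(gt, nPerm = 50, nBoot = 20, seed = 5)
  expect_equal(res$g2, 0)
  expect_gte(res$p_value, 0.5)
})

test_that("g2 detects identity disequilibrium generated by variance in F", {
  hits <- 0
  seeds <- 100 + seq_len(20)
  for (s in seeds) {
    sc <- simScenario(nIndividuals = 80, nLoci = 200,
                      allelesPerLocus = 6,
                      fDistribution = list(type = "mixture", p = 0.5,
                                           f = 0.25), seed = s)
    F <- simInbreedingCoefficients(sc)
    gt <- simGenotypes(simAlleleFrequencies(sc), F, seed = s + 1)
    res <- g2Microsats(gt, nPerm = 99, nBoot = 1, seed = s + 2)
    if (res$g2 > 0 && res$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("homozygosity-F correlation behaves at the degenerate corners", {
  calls <- rbind(i1 = c("A/A", "A/B"), i2 = c("A/B", "A/B"))
  gt <- gtFromStrings(calls)
  hom <- vapply(individualIds(gt), function(id)
    multilocusHomozygosity(gt, id), numeric(1))
  expect_equal(hetFCorrelation(gt, hom), 1)
  expect_warning(r <- hetFCorrelation(gt, setNames(c(.2, .2),
                                                   individualIds(gt))),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("homozygosity-F correlation is -1 for perfectly reversed inputs", {
  # 5 individuals with homozygosity 0.1 .. 0.5 over 10 loci
  calls <- t(vapply(1:5, function(k)
    c(rep("A/A", k), rep("A/B", 10 - k)), character(10)))
  rownames(calls) <- paste0("i", 1:5)
  gt <- gtFromStrings(calls)
  f <- setNames(c(0.5, 0.4, 0.3, 0.2, 0.1), paste0("i", 1:5))
  expect_equal(hetFCorrelation(gt, f), -1)
})
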