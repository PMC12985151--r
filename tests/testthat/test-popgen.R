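test_that("allele frequencies count gene copies and skip null homozygotes", {
  tab <- makeTable(list(a = list(M = c(100, 100)),
                        b = list(M = c(100, 104))))
  p <- alleleFrequencies(tab, "M")
  expect_equal(as.numeric(p), c(0.75, 0.25))
  expect_equal(attr(p, "nCopies"), 4L)
  tab2 <- makeTable(list(a = list(M = c(100, 100)),
                         b = list(M = c(0, 0))))
  p2 <- alleleFrequencies(tab2, "M")
  expect_equal(as.numeric(p2), 1)
  expect_equal(attr(p2, "nCopies"), 2L)
  expect_error(alleleFrequencies(tab, "NOPE"), "not in table")
  tabNA <- makeTable(list(a = list(M = c(NA, NA))))
  expect_error(alleleFrequencies(tabNA, "M"), "no called")
})

test_that("observed heterozygosity is the fraction of unequal pairs", {
  tab <- makeTable(list(a = list(M = c(100, 104)), b = list(M = c(100, 104)),
                        c = list(M = c(104, 104)), d = list(M = c(100, 100))))
  expect_equal(observedHeterozygosity(tab, "M"), 0.5)
})

test_that("He, PIC, Ae, PI and Shannon match their closed forms", {
  p <- c(0.5, 0.5)
  expect_equal(expectedHeterozygosity(p), 0.5)
  expect_equal(expectedHeterozygosity(p, unbiased = TRUE, nCopies = 4),
               0.5 * 4 / 3)
  expect_error(expectedHeterozygosity(p, unbiased = TRUE, nCopies = 1),
               "nCopies")
  expect_equal(pic(1), 0)
  expect_equal(pic(p), 0.375)        # 1 - 0.5 - 2 * 0.25 * 0.25
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  expect_equal(effectiveAlleles(p), 2)
  expect_equal(effectiveAlleles(c(0.9, 0.1)), 1 / 0.82)
  expect_equal(probabilityIdentity(1), 1)
  expect_equal(probabilityIdentity(p), 0.375) # 0.25^2 + 0.5^2 + 0.25^2
  expect_equal(probabilityIdentity(rep(0.25, 4)), 0.109375)
  expect_equal(shannonIndex(1), 0)
  expect_equal(shannonIndex(p), log(2))
  expect_equal(shannonIndex(rep(0.25, 4)), log(4))
})

test_that("probability of identity equals brute-force genotype enumeration", {
  set.seed(42)
  for (rep in 1:200) {
    p <- randomFreqs(sample(2:6, 1))
    expect_equal(probabilityIdentity(p), bruteForcePI(p),
                 tolerance = 1e-12)
  }
})

test_that("null-allele estimators behave at and around Ho = He", {
  expect_equal(nullAlleleEstimate(0.6, 0.6), 0)
  expect_equal(nullAlleleEstimate(0.6, 0.65), 0.05 / 1.25)
  expect_lt(nullAlleleEstimate(0.7, 0.65), 0)   # excess heterozygotes
  expect_true(is.na(nullAlleleEstimate(0, 0)))
  expect_equal(nullAlleleEstimate(0.6, 0.65, method = "brookfield"),
               0.05 / 1.65)
})

test_that("allelic richness rarefies hypergeometrically", {
  tab <- makeTable(list(a = list(M = c(100, 100)),
                        b = list(M = c(104, 104))))
  expect_equal(allelicRichness(tab, "M"), 2)        # g = N gives k
  expect_equal(allelicRichness(tab, "M", g = 1), 1)
  # N = 4 copies {A:2, B:2}, g = 2: enumerate all 6 subsamples -> 5/3
  expect_equal(allelicRichness(tab, "M", g = 2), 2 - 2 * 1 / 6)
  cmb <- combn(c(100, 100, 104, 104), 2)
  expect_equal(mean(apply(cmb, 2, function(s) length(unique(s)))),
               allelicRichness(tab, "M", g = 2))
  expect_error(allelicRichness(tab, "M", g = 5), "exceeds")
})

test_that("marker and panel summaries aggregate consistently", {
  mono <- makeTable(list(a = list(M = c(100, 100)),
                         b = list(M = c(100, 100))))
  st <- markerStats(mono, "M")
  expect_equal(st$k, 1)
  expect_equal(st$Ho, 0); expect_equal(st$He, 0); expect_equal(st$PIC, 0)
  expect_equal(st$Ae, 1); expect_equal(st$PI, 1)
  # HWE-exact toy sample at {0.5, 0.5}: 1 AA, 2 AB, 1 BB
  hwe <- makeTable(list(a = list(M = c(100, 100)), b = list(M = c(100, 104)),
                        c = list(M = c(100, 104)), d = list(M = c(104, 104))))
  st2 <- markerStats(hwe, "M")
  expect_equal(st2$He, 0.5); expect_equal(st2$PIC, 0.375)
  expect_equal(st2$PI, 0.375); expect_equal(st2$Ae, 2)
  two <- makeTable(list(
    a = list(M1 = c(100, 100), M2 = c(200, 200)),
    b = list(M1 = c(100, 104), M2 = c(200, 204)),
    c = list(M1 = c(100, 104), M2 = c(200, 204)),
    d = list(M1 = c(104, 104), M2 = c(204, 204))))
  ps <- panelSummary(two)
  expect_equal(ps$PIt, 0.375^2)
  expect_equal(unname(ps$averages["PIC"]), 0.375)
  one <- panelSummary(two, markers = "M1")
  expect_equal(one$PIt, one$perMarker$PI[1])
})

test_that("PI_t weakly decreases as markers are appended", {
  set.seed(7)
  freqs <- lapply(1:5, function(i) {
    p <- randomFreqs(4); names(p) <- 100 + 2 * (0:3); p
  })
  names(freqs) <- paste0("M", 1:5)
  tab <- simulatePopulation(freqs, 40, seed = 7)
  pits <- vapply(1:5, function(m)
    panelSummary(tab, markers = paste0("M", 1:m))$PIt, numeric(1))
  expect_true(all(diff(pits) <= 1e-12))
})

test_that("diversity orderings and merge monotonicity hold", {
  set.seed(11)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    p <- randomFreqs(k)
    he <- expectedHeterozygosity(p)
    expect_lte(pic(p), he + 1e-12)
    expect_lte(he, 1 - 1 / k + 1e-12)
    expect_lte(effectiveAlleles(p), k + 1e-12)
    expect_gte(probabilityIdentity(p), sum(p^2)^2 - 1e-12)
    expect_equal(effectiveAlleles(p), 1 / (1 - he))
    # merging two alleles never increases He/PIC/Ae, never decreases PI
    q <- c(p[1] + p[2], p[-(1:2)])
    expect_lte(expectedHeterozygosity(q), he + 1e-12)
    expect_lte(pic(q), pic(p) + 1e-12)
    expect_lte(effectiveAlleles(q), effectiveAlleles(p) + 1e-12)
    expect_gte(probabilityIdentity(q), probabilityIdentity(p) - 1e-12)
  }
})

test_that("subset statistics reflect allele loss", {
  set.seed(3)
  freqs <- list(M1 = setNames(c(0.4, 0.3, 0.2, 0.1), c(100, 102, 104, 106)),
                M2 = setNames(c(0.5, 0.5), c(200, 204)))
  tab <- simulatePopulation(freqs, 60, seed = 3)
  full <- subsetStats(tab, sampleIds(tab))
  ref <- panelSummary(tab)
  expect_equal(full$stats$PIt, ref$PIt)
  expect_true(all(full$alleleLoss$lost == 0))
  # drop every carrier of allele 106 at M1: k must fall
  carriers <- sampleIds(tab)[alleleMatrix(tab, "A")[, "M1"] == 106 |
                             alleleMatrix(tab, "B")[, "M1"] == 106]
  keep <- setdiff(sampleIds(tab), carriers)
  sub <- subsetStats(tab, keep)
  expect_lt(sub$alleleLoss$k_subset[1], full$alleleLoss$k_subset[1])
  expect_error(subsetStats(tab, character(0)), "empty")
  expect_error(subsetStats(tab, "nobody"), "not in table")
})

test_that("spectra reconstructed from (k, He, PIC) reproduce the summary", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    p <- randomFreqs(k)
    he <- expectedHeterozygosity(p)
    pv <- pic(p)
    q <- frequenciesFromSummary(k, he, pv)
    expect_equal(expectedHeterozygosity(q), he, tolerance = 1e-5)
    expect_equal(pic(q), pv, tolerance = 1e-5)
    expect_equal(probabilityIdentity(q), probabilityIdentity(p),
                 tolerance = 1e-5)
  }
  expect_error(frequenciesFromSummary(2, 0.8, 0.79), "converge|spectrum")
})
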