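test_that("frequency simulation is seeded, lattice-valued and targetable", {
  p1 <- simulateFrequencies(5, seed = 1)
  p2 <- simulateFrequencies(5, seed = 1)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)
  expect_equal(as.integer(names(simulateFrequencies(4, motifLength = 3,
                                                    baseLength = 120,
                                                    seed = 2))),
               c(120, 123, 126, 129))
  expect_equal(as.numeric(simulateFrequencies(1, seed = 3)), 1)
  # PIC 0.375 is the 2-allele maximum: only near-equifrequent pairs qualify
  pt <- simulateFrequencies(2, targetPic = 0.375, seed = 4)
  expect_true(all(abs(pt - 0.5) < 0.15))
  expect_equal(pic(as.numeric(pt)), 0.375, tolerance = 0.02)
  expect_error(simulateFrequencies(2, targetPic = 0.8, seed = 5),
               "maximum")
})

test_that("simulated populations sit in Hardy-Weinberg proportions", {
  freqs <- list(M = stats::setNames(c(0.5, 0.5), c(100, 102)))
  tab <- simulatePopulation(freqs, 10000, seed = 6)
  ho <- observedHeterozygosity(tab, "M")
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(ho - 0.5), 3 * se)
  # recovered allele frequencies converge with n
  truth <- c(0.6, 0.25, 0.1, 0.05)
  freqs2 <- list(M = stats::setNames(truth, c(100, 102, 104, 106)))
  err <- vapply(c(100, 1000, 10000), function(n) {
    p <- alleleFrequencies(simulatePopulation(freqs2, n, seed = 8), "M")
    max(abs(p[as.character(c(100, 102, 104, 106))] - truth))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.02)
})

test_that("empirical genotype-match frequency reproduces the PI formula", {
  p <- c(0.45, 0.3, 0.15, 0.1)
  freqs <- list(M = stats::setNames(p, c(100, 102, 104, 106)))
  tab <- simulatePopulation(freqs, 4000, seed = 9)
  a <- alleleMatrix(tab, "A")[, 1]; b <- alleleMatrix(tab, "B")[, 1]
  g <- paste(a, b)
  # match probability of two random distinct individuals
  counts <- table(g)
  n <- length(g)
  match <- sum(counts * (counts - 1)) / (n * (n - 1))
  # U-statistic s.e. at n = 4000 is about 0.0026 here; 0.05 relative ~ 3 s.e.
  expect_equal(match, probabilityIdentity(p), tolerance = 0.05)
})

test_that("crosses are Mendelian and selfing segregates 1:2:1", {
  tab <- makeTable(list(P = list(M = c(100, 100)),
                        Q = list(M = c(104, 104))))
  kids <- simulateCross(tab, "P", "Q", nOffspring = 20, seed = 10)
  expect_true(all(alleleMatrix(kids, "A")[, 1] == 100))
  expect_true(all(alleleMatrix(kids, "B")[, 1] == 104))
  het <- makeTable(list(P = list(M = c(100, 104))))
  selfed <- simulateCross(het, "P", "P", nOffspring = 4000, seed = 11)
  g <- paste(alleleMatrix(selfed, "A")[, 1], alleleMatrix(selfed, "B")[, 1])
  frac <- table(g) / 4000
  expect_equal(unname(frac["100 100"]), 0.25, tolerance = 0.1)
  expect_equal(unname(frac["100 104"]), 0.50, tolerance = 0.1)
  expect_equal(unname(frac["104 104"]), 0.25, tolerance = 0.1)
})

test_that("error-free trios never mismatch; mutations create exclusions", {
  freqs <- lapply(1:8, function(i) {
    p <- randomFreqs(5); names(p) <- 100 + 2 * (0:4); p
  })
  names(freqs) <- paste0("M", 1:8)
  tab <- simulatePopulation(freqs, 10, seed = 12)
  kids <- simulateCross(tab, 1, 2, nOffspring = 50, seed = 13)
  for (i in 1:50) {
    all <- GenotypeTable(
      rbind(alleleMatrix(tab, "A"), alleleMatrix(kids, "A")[i, , drop = FALSE]),
      rbind(alleleMatrix(tab, "B"), alleleMatrix(kids, "B")[i, , drop = FALSE]),
      panel(tab))
    expect_equal(as.integer(trioMismatch(all, 11, 1, 2)), 0L)
  }
  # heavy mutation pressure must produce some exclusions
  mutKids <- simulateCross(tab, 1, 2, nOffspring = 50, mutationRate = 0.2,
                           seed = 14)
  mism <- vapply(1:50, function(i) {
    all <- GenotypeTable(
      rbind(alleleMatrix(tab, "A"), alleleMatrix(mutKids, "A")[i, , drop = FALSE]),
      rbind(alleleMatrix(tab, "B"), alleleMatrix(mutKids, "B")[i, , drop = FALSE]),
      panel(tab))
    as.integer(trioMismatch(all, 11, 1, 2))
  }, integer(1))
  expect_gt(sum(mism), 0)
})

test_that("founder populations lose diversity down the generations", {
  freqs <- lapply(1:10, function(i) {
    p <- randomFreqs(8); names(p) <- 100 + 2 * (0:7); p
  })
  names(freqs) <- paste0("M", 1:10)
  for (seed in 101:103) {
    founders <- simulatePopulation(freqs, 4, seed = seed)
    sim <- simulateFounderPopulation(founders, nGenerations = 4,
                                     popSize = 30, seed = seed + 50)
    base <- panelSummary(sim$table[sim$generation == 0, ])
    deep <- panelSummary(sim$table[sim$generation == 4, ])
    expect_lte(deep$averages[["PIC"]], base$averages[["PIC"]] + 1e-9)
    expect_lte(deep$averages[["Ae"]], base$averages[["Ae"]] + 1e-9)
    # allele conservation: k per marker never exceeds the founder pool
    for (m in markerNames(founders)) {
      fk <- length(alleleFrequencies(sim$table[sim$generation == 0, ], m))
      dk <- length(alleleFrequencies(sim$table[sim$generation == 4, ], m))
      expect_lte(dk, fk)
    }
    # recorded pedigree trios are all Mendelian-consistent
    ped <- sim$pedigree
    some <- ped[sample(nrow(ped), 10), ]
    for (r in seq_len(nrow(some)))
      expect_equal(as.integer(trioMismatch(sim$table, some$child[r],
                                           some$parent_a[r],
                                           some$parent_b[r])), 0L)
  }
  # two founders bound k at 4 everywhere
  two <- simulatePopulation(freqs, 2, seed = 104)
  sim2 <- simulateFounderPopulation(two, nGenerations = 3, popSize = 20,
                                    seed = 105)
  for (m in markerNames(two))
    expect_lte(length(alleleFrequencies(sim2$table, m)), 4L)
})

test_that("artifact injection is inert at zero rates and logged otherwise", {
  freqs <- lapply(1:6, function(i) {
    p <- randomFreqs(5); names(p) <- 100 + 2 * (0:4); p
  })
  names(freqs) <- paste0("M", 1:6)
  tab <- simulatePopulation(freqs, 40, seed = 15)
  same <- injectArtifacts(tab, seed = 16)
  expect_identical(alleleMatrix(same$table, "A"), alleleMatrix(tab, "A"))
  # hidden nulls reduce observed heterozygosity on average and push the
  # Chakraborty estimator positive
  withNull <- injectArtifacts(tab, nullAlleleRate = 0.15, seed = 17)
  hoBefore <- mean(vapply(markerNames(tab), function(m)
    observedHeterozygosity(tab, m), numeric(1)))
  hoAfter <- mean(vapply(markerNames(tab), function(m)
    observedHeterozygosity(withNull$table, m), numeric(1)))
  expect_lt(hoAfter, hoBefore)
  est <- mean(vapply(markerNames(tab), function(m) {
    st <- markerStats(withNull$table, m)
    st$null_rate
  }, numeric(1)))
  expect_gt(est, 0)
  expect_gt(nrow(withNull$truth$nullCarriers), 0)
  # typos are logged
  withTypo <- injectArtifacts(tab, replicateErrorRate = 0.05, seed = 18)
  expect_gt(nrow(withTypo$truth$typos), 0)
  expect_false(identical(alleleMatrix(withTypo$table, "A"),
                         alleleMatrix(tab, "A")))
})

test_that("the study-scale collection has the published structure", {
  sc <- simulateStudyCollection(seed = 7, nUnique = 60, nOffspring = 20,
                                nClones = 5)
  expect_equal(nSamples(sc$table), 65L)
  dd <- deduplicate(sc$table)
  expect_equal(nSamples(dd), 60L)
  expect_equal(nrow(sc$pedigree), 20L)
  # pedigree children resolve to their recorded parents
  hits <- searchParentPairs(dd, sc$pedigree$child[1])
  pair <- sort(c(sc$pedigree$parent_a[1], sc$pedigree$parent_b[1]))
  expect_true(any(hits$parent_a == pair[1] & hits$parent_b == pair[2] |
                  hits$parent_a == pair[2] & hits$parent_b == pair[1]))
})
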