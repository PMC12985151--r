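test_that("locus compatibility matches explicit gamete enumeration", {
  expect_true(locusCompatible(c(150, 154), c(150, 152), c(154, 156)))
  expect_false(locusCompatible(c(150, 150), c(152, 154), c(150, 156)))
  expect_true(locusCompatible(c(150, 152), c(150, 152), c(150, 152)))
  set.seed(13)
  for (rep in 1:200) {
    alleles <- 100 + 2 * (0:3)
    o <- sort(sample(alleles, 2, replace = TRUE))
    p <- sample(alleles, 2, replace = TRUE)
    q <- sample(alleles, 2, replace = TRUE)
    expect_equal(locusCompatible(o, p, q), gameteCompatible(o, p, q))
  }
})

test_that("trio mismatch counts incompatible complete loci only", {
  tab <- makeTable(list(
    P = list(M1 = c(100, 104), M2 = c(200, 202), M3 = c(300, 302)),
    Q = list(M1 = c(106, 108), M2 = c(204, 206), M3 = c(304, 306)),
    O = list(M1 = c(100, 106), M2 = c(202, 204), M3 = c(300, 304)),
    O2 = list(M1 = c(110, 112), M2 = c(202, 204), M3 = c(300, 304)),
    O3 = list(M1 = c(NA, NA), M2 = c(202, 204), M3 = c(300, 304))))
  expect_equal(as.integer(trioMismatch(tab, "O", "P", "Q")), 0L)
  expect_equal(as.integer(trioMismatch(tab, "O2", "P", "Q")), 1L)
  # missing locus skipped, not a mismatch
  m3 <- trioMismatch(tab, "O3", "P", "Q")
  expect_equal(as.integer(m3), 0L)
  expect_equal(attr(m3, "lociUsed"), 2L)
  # symmetric in the parents
  expect_equal(as.integer(trioMismatch(tab, "O2", "Q", "P")), 1L)
})

test_that("null alleles in a trio member exclude the locus", {
  tab <- makeTable(list(
    P = list(M1 = c(0, 0), M2 = c(200, 202)),
    Q = list(M1 = c(106, 108), M2 = c(204, 206)),
    O = list(M1 = c(100, 106), M2 = c(202, 204))))
  m <- trioMismatch(tab, "O", "P", "Q")
  expect_equal(as.integer(m), 0L)
  expect_equal(attr(m, "lociUsed"), 1L)
})

test_that("adding loci never decreases the trio mismatch", {
  set.seed(17)
  freqs <- lapply(1:8, function(i) {
    p <- randomFreqs(4); names(p) <- 100 + 2 * (0:3); p
  })
  names(freqs) <- paste0("M", 1:8)
  tab <- simulatePopulation(freqs, 12, seed = 17)
  for (rep in 1:10) {
    trio <- sample(12, 3)
    counts <- vapply(1:8, function(m)
      as.integer(trioMismatch(tab[, paste0("M", 1:m)],
                              trio[1], trio[2], trio[3])), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("a simulated cross is found as the unique parent pair", {
  freqs <- lapply(1:10, function(i) {
    p <- randomFreqs(8); names(p) <- 100 + 2 * (0:7); p
  })
  names(freqs) <- paste0("M", 1:10)
  tab <- simulatePopulation(freqs, 20, seed = 31)
  kid <- simulateCross(tab, 1, 2, nOffspring = 1, seed = 32, ids = "kid")
  all <- GenotypeTable(rbind(alleleMatrix(tab, "A"), alleleMatrix(kid, "A")),
                       rbind(alleleMatrix(tab, "B"), alleleMatrix(kid, "B")),
                       panel(tab))
  hits <- searchParentPairs(all, "kid", allowSelfing = TRUE)
  expect_true(any(hits$parent_a == sampleIds(tab)[1] &
                  hits$parent_b == sampleIds(tab)[2] |
                  hits$parent_a == sampleIds(tab)[2] &
                  hits$parent_b == sampleIds(tab)[1]))
  expect_equal(nrow(hits), 1L)
})

test_that("an offspring with a private allele has no parent pair", {
  tab <- makeTable(list(
    A = list(M1 = c(100, 104), M2 = c(200, 202)),
    B = list(M1 = c(104, 106), M2 = c(204, 206)),
    O = list(M1 = c(100, 999), M2 = c(200, 204))))
  expect_equal(nrow(searchParentPairs(tab, "O")), 0L)
})

test_that("LOD scores follow the Mendelian/HWE likelihood ratio", {
  tab <- makeTable(list(
    O = list(M1 = c(100, 104)),
    P = list(M1 = c(100, 100)),
    Q = list(M1 = c(104, 104))))
  freqs <- list(M1 = setNames(c(0.5, 0.5), c(100, 104)))
  # transmission certain (1); HWE prob of het = 2 * 0.25 = 0.5
  expect_equal(lodScore(tab, "O", "P", "Q", freqs), log10(2))
  # uninformative locus: all homozygous for a p = 1 allele
  tab2 <- makeTable(list(O = list(M1 = c(100, 100)),
                         P = list(M1 = c(100, 100)),
                         Q = list(M1 = c(100, 100))))
  expect_equal(lodScore(tab2, "O", "P", "Q",
                        list(M1 = setNames(1, 100))), 0)
  expect_error(lodScore(tab, "O", "P", "Q",
                        list(M1 = setNames(1, 100))), "absent")
})

test_that("true parents outscore random compatible pairs by LOD", {
  set.seed(41)
  freqs <- lapply(1:12, function(i) {
    p <- randomFreqs(3); names(p) <- 100 + 2 * (0:2); p
  })
  names(freqs) <- paste0("M", 1:12)
  wins <- 0; tries <- 0
  for (rep in 1:15) {
    tab <- simulatePopulation(freqs, 30, seed = 41 + rep)
    kid <- simulateCross(tab, 1, 2, seed = 100 + rep, ids = "kid")
    all <- GenotypeTable(
      rbind(alleleMatrix(tab, "A"), alleleMatrix(kid, "A")),
      rbind(alleleMatrix(tab, "B"), alleleMatrix(kid, "B")), panel(tab))
    hits <- searchParentPairs(all, "kid", freqs = freqs)
    truth <- hits$parent_a %in% sampleIds(tab)[1:2] &
      hits$parent_b %in% sampleIds(tab)[1:2]
    if (nrow(hits) >= 2 && any(truth)) {
      tries <- tries + 1
      if (max(hits$lod[truth]) >= max(hits$lod[!truth])) wins <- wins + 1
    }
  }
  expect_gte(tries, 3)
  expect_gt(wins / tries, 0.5)
})

test_that("parentage summary collapses clonal parent pairs", {
  freqs <- lapply(1:10, function(i) {
    p <- randomFreqs(8); names(p) <- 100 + 2 * (0:7); p
  })
  names(freqs) <- paste0("M", 1:10)
  tab <- simulatePopulation(freqs, 15, seed = 51)
  kid <- simulateCross(tab, 1, 2, seed = 52, ids = "kid")
  a <- rbind(alleleMatrix(tab, "A"), alleleMatrix(kid, "A"),
             P1clone = alleleMatrix(tab, "A")[1, ])
  b <- rbind(alleleMatrix(tab, "B"), alleleMatrix(kid, "B"),
             P1clone = alleleMatrix(tab, "B")[1, ])
  all <- GenotypeTable(a, b, panel(tab))
  hits <- searchParentPairs(all, "kid")
  expect_equal(nrow(hits), 2L)  # (P1, P2) and (P1clone, P2)
  summ <- parentageSummary(
    all, cloneClusters = list(c(sampleIds(tab)[1], "P1clone")))
  perKid <- summ$perOffspring[summ$perOffspring$sample == "kid", ]
  expect_equal(perKid$n_pairs, 2L)
  expect_equal(perKid$n_pairs_collapsed, 1L)
})

test_that("unrelated collections yield a histogram massed at zero", {
  freqs <- lapply(1:12, function(i) {
    p <- randomFreqs(8); names(p) <- 100 + 2 * (0:7); p
  })
  names(freqs) <- paste0("M", 1:12)
  tab <- simulatePopulation(freqs, 25, seed = 61)
  summ <- parentageSummary(tab)
  expect_equal(summ$nResolved, 0L)
  expect_equal(unname(summ$histogram["0"]), 25L)
})
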