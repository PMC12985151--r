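# Fixture builders used across the suite. Genotypes are written as
# length-2 vectors per marker; NA NA = missing, 0 0 = homozygous null.

# makeTable(list(s1 = list(M1 = c(100, 104), M2 = c(200, 200)), ...))
makeTable <- function(calls, panel = NULL) {
  samples <- names(calls)
  markers <- names(calls[[1]])
  a <- matrix(NA_integer_, length(samples), length(markers),
              dimnames = list(samples, markers))
  b <- a
  for (s in seq_along(calls)) for (m in seq_along(markers)) {
    g <- calls[[s]][[m]]
    a[s, m] <- g[1]; b[s, m] <- g[2]
  }
  GenotypeTable(a, b, panel)
}

# independent oracle for the locus probability of identity: enumerate all
# unordered genotypes under HWE and sum squared probabilities
bruteForcePI <- function(p) {
  k <- length(p)
  total <- 0
  for (i in seq_len(k)) for (j in i:k) {
    gp <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + gp^2
  }
  total
}

# independent oracle for allele mismatches between two genotype profiles:
# literal multiset intersection per locus
bruteForceMismatch <- function(rowA, rowB) {
  mism <- 0L; loci <- 0L
  for (l in seq_along(rowA)) {
    ga <- rowA[[l]]; gb <- rowB[[l]]
    if (anyNA(ga) || anyNA(gb)) next
    loci <- loci + 1L
    inter <- 0L
    gbLeft <- gb
    for (al in ga) {
      hit <- match(al, gbLeft)
      if (!is.na(hit)) { inter <- inter + 1L; gbLeft <- gbLeft[-hit] }
    }
    mism <- mism + 2L - inter
  }
  c(mism, loci)
}

# independent oracle for trio compatibility at one locus: enumerate the
# four gamete combinations explicitly
gameteCompatible <- function(o, p, q) {
  for (x in p) for (y in q)
    if (setequal2(sort(c(x, y)), sort(o))) return(TRUE)
  FALSE
}
setequal2 <- function(a, b) length(a) == length(b) && all(a == b)

randomFreqs <- function(k) {
  g <- rgamma(k, 1)
  p <- g / sum(g)
  while (any(p <= 0)) { g <- rgamma(k, 1); p <- g / sum(g) }
  p
}
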