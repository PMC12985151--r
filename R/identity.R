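# Shared pairwise machinery: per sample pair, the number of alleles shared
# (multiset intersection, summed over loci scored in both samples) and the
# number of loci compared. Null homozygotes compare as a genotype in its own
# right (two samples both failing to amplify a marker match there).
.pairwiseShared <- function(x) {
  n <- nSamples(x)
  m <- nMarkers(x)
  npair <- n * (n - 1) / 2
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  shared <- integer(npair)
  compared <- integer(npair)
  for (k in seq_len(m)) {
    a1 <- x@alleleA[ij[, 1], k]; a2 <- x@alleleB[ij[, 1], k]
    b1 <- x@alleleA[ij[, 2], k]; b2 <- x@alleleB[ij[, 2], k]
    ok <- !is.na(a1) & !is.na(b1)
    s <- integer(npair)
    # canonical sorted pairs: multiset intersection size from 4 comparisons
    s[ok] <- ifelse(a1[ok] == b1[ok] & a2[ok] == b2[ok], 2L,
                    (a1[ok] == b1[ok] | a1[ok] == b2[ok] |
                     a2[ok] == b1[ok] | a2[ok] == b2[ok]) * 1L)
    shared <- shared + s
    compared <- compared + as.integer(ok)
  }
  list(i = ij[, 1], j = ij[, 2], shared = shared, compared = compared)
}

#' Allele mismatches between two genotype profiles
#'
#' Per locus the mismatch contribution is \code{2 - |multiset intersection|}
#' of the two allele pairs (0 for identical genotypes, 1 for one shared
#' allele, 2 for none). Loci missing in either sample are skipped and counted
#' in neither tally.
#'
#' @param x a \code{GenotypeTable}.
#' @param a,b sample identifiers or row indices.
#' @return named integer vector \code{c(mismatch, lociCompared)}.
#' @export
genotypeMismatch <- function(x, a, b) {
  stopifnot(is(x, "GenotypeTable"))
  idx <- function(s) {
    if (is.character(s)) s <- match(s, sampleIds(x))
    if (is.na(s) || s < 1 || s > nSamples(x)) stop("sample not in table")
    s
  }
  a <- idx(a); b <- idx(b)
  a1 <- x@alleleA[a, ]; a2 <- x@alleleB[a, ]
  b1 <- x@alleleA[b, ]; b2 <- x@alleleB[b, ]
  ok <- !is.na(a1) & !is.na(b1)
  s <- ifelse(a1[ok] == b1[ok] & a2[ok] == b2[ok], 2L,
              (a1[ok] == b1[ok] | a1[ok] == b2[ok] |
               a2[ok] == b1[ok] | a2[ok] == b2[ok]) * 1L)
  c(mismatch = sum(2L - s), lociCompared = sum(ok))
}

#' Find clones, synonyms and near-identical genotypes
#'
#' Single-linkage clusters over all sample pairs whose allele-level mismatch
#' count does not exceed \code{maxMismatch}. At threshold 0 the clusters are
#' exact-identity classes (clones/synonyms); thresholds 1-2 additionally
#' catch "varieties/clones" separated by only one or two alleles, which are
#' reported for human judgment rather than merged automatically. Pairs with
#' fewer than half their loci comparable are flagged low-confidence.
#'
#' @param x a consolidated \code{GenotypeTable} (one row per accession).
#' @param maxMismatch maximum allele mismatches linking a pair (0, 1 or 2
#'   in routine use).
#' @return list with \code{clusters} (list of character vectors of members,
#'   each with the representative first in input order), \code{pairs}
#'   (data.frame sample_a, sample_b, mismatch, loci_compared, class,
#'   low_confidence for all pairs at or below the threshold) and
#'   \code{membership} (integer vector: cluster id per sample, NA when
#'   unclustered).
#' @export
findDuplicates <- function(x, maxMismatch = 0) {
  stopifnot(is(x, "GenotypeTable"), maxMismatch >= 0)
  n <- nSamples(x)
  ids <- sampleIds(x)
  pw <- .pairwiseShared(x)
  mism <- 2L * pw$compared - pw$shared
  hit <- which(mism <= maxMismatch & pw$compared > 0L)
  cls <- c("identical", "near-1", "near-2")
  pairs <- data.frame(
    sample_a = ids[pw$i[hit]], sample_b = ids[pw$j[hit]],
    mismatch = mism[hit], loci_compared = pw$compared[hit],
    class = ifelse(mism[hit] <= 2, cls[mism[hit] + 1L], "distinct"),
    low_confidence = pw$compared[hit] < nMarkers(x) / 2,
    stringsAsFactors = FALSE)
  # union-find over linked pairs (single linkage at this threshold)
  parent <- seq_len(n)
  for (h in hit) {
    ri <- pw$i[h]; rj <- pw$j[h]
    while (parent[ri] != ri) ri <- parent[ri]
    while (parent[rj] != rj) rj <- parent[rj]
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, integer(1))
  sizes <- table(root)
  multi <- as.integer(names(sizes)[sizes > 1])
  clusters <- lapply(multi, function(r) ids[root == r])
  membership <- rep(NA_integer_, n)
  for (c in seq_along(multi)) membership[root == multi[c]] <- c
  names(membership) <- ids
  list(clusters = clusters, pairs = pairs, membership = membership)
}

#' Reduce a table to unique genotypes
#'
#' Collapses exact-identity clusters (zero allele mismatches) to one row
#' each, keeping the first member in input order as the representative.
#' Near-identical pairs (one or two differing alleles) remain distinct rows;
#' they are reported via the attached scan so a curator can judge them.
#' Deduplication is idempotent.
#'
#' @param x a consolidated \code{GenotypeTable}.
#' @return a \code{GenotypeTable} of unique genotypes, with attributes
#'   \code{clusters} (the exact-identity clusters that were collapsed) and
#'   \code{removed} (character vector of dropped sample ids).
#' @export
deduplicate <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  dup <- findDuplicates(x, maxMismatch = 0)
  drop <- unlist(lapply(dup$clusters, function(members)
    members[-1]), use.names = FALSE)
  keep <- !(sampleIds(x) %in% drop)
  out <- x[keep, ]
  attr(out, "clusters") <- dup$clusters
  attr(out, "removed") <- sampleIds(x)[!keep]
  out
}
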