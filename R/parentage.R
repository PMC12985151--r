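#' Mendelian compatibility of one trio at one locus
#'
#' TRUE iff the offspring's unordered allele pair can be split as one allele
#' contributed by each candidate parent. A homozygous offspring needs the
#' allele from both parents; selfing is the case \code{p} = \code{q}.
#'
#' @param o,p,q length-2 numeric vectors: the offspring's and the two
#'   candidate parents' allele pairs.
#' @return logical.
#' @examples
#' locusCompatible(c(150, 154), c(150, 152), c(154, 156)) # TRUE
#' locusCompatible(c(150, 150), c(152, 154), c(150, 156)) # FALSE
#' @export
locusCompatible <- function(o, p, q) {
  (o[1] %in% p && o[2] %in% q) || (o[1] %in% q && o[2] %in% p)
}

# loci usable for a trio: complete, no null alleles in any member
.trioLociOk <- function(x, i, j, k) {
  a <- x@alleleA; b <- x@alleleB
  ok <- !is.na(a[i, ]) & !is.na(a[j, ]) & !is.na(a[k, ]) &
    a[i, ] > 0L & a[j, ] > 0L & a[k, ] > 0L &
    b[i, ] > 0L & b[j, ] > 0L & b[k, ] > 0L
  ok
}

#' Trio mismatch count
#'
#' Number of loci, complete in all three samples (no missing data, no null
#' alleles), at which the offspring genotype cannot be produced by one allele
#' from each candidate parent. The paper-grade criterion for accepting a
#' parent pair is a count of zero.
#'
#' @param x a \code{GenotypeTable}.
#' @param offspring,p,q sample identifiers or row indices.
#' @return integer mismatch count with attribute \code{lociUsed}.
#' @export
trioMismatch <- function(x, offspring, p, q) {
  stopifnot(is(x, "GenotypeTable"))
  idx <- function(s) if (is.character(s)) match(s, sampleIds(x)) else s
  i <- idx(offspring); j <- idx(p); k <- idx(q)
  if (anyNA(c(i, j, k))) stop("sample not in table")
  ok <- .trioLociOk(x, i, j, k)
  a <- x@alleleA; b <- x@alleleB
  o1 <- a[i, ok]; o2 <- b[i, ok]
  c1p <- o1 == a[j, ok] | o1 == b[j, ok]
  c2p <- o2 == a[j, ok] | o2 == b[j, ok]
  c1q <- o1 == a[k, ok] | o1 == b[k, ok]
  c2q <- o2 == a[k, ok] | o2 == b[k, ok]
  compat <- (c1p & c2q) | (c1q & c2p)
  structure(sum(!compat), lociUsed = sum(ok))
}

#' Exhaustive zero-mismatch parent-pair search for one offspring
#'
#' Scans all unordered pairs of candidate parents (sex unknown; selfing,
#' i.e. \code{parent_a == parent_b}, optionally permitted) and returns every
#' pair with zero trio mismatches. Candidates are first pruned to those able
#' to supply at least one offspring allele at every complete locus, which
#' makes the quadratic pair scan cheap on polymorphic panels. When
#' \code{freqs} are supplied, pairs are ranked by LOD.
#'
#' @param x a deduplicated \code{GenotypeTable}.
#' @param offspring sample identifier or row index.
#' @param allowSelfing allow \code{parent_a == parent_b} (a single candidate
#'   explaining both gametes). The offspring itself is never a candidate.
#' @param exclude sample identifiers to exclude from candidacy.
#' @param freqs optional list of per-marker allele frequencies (as from
#'   \code{\link{alleleFrequencies}}) used to attach LOD scores.
#' @return data.frame with columns \code{offspring}, \code{parent_a},
#'   \code{parent_b}, \code{mismatch}, \code{loci_used}, \code{lod}
#'   (NA without \code{freqs}), sorted by decreasing LOD.
#' @export
searchParentPairs <- function(x, offspring, allowSelfing = TRUE,
                              exclude = character(), freqs = NULL) {
  stopifnot(is(x, "GenotypeTable"))
  ids <- sampleIds(x)
  i <- if (is.character(offspring)) match(offspring, ids) else offspring
  if (is.na(i)) stop("offspring not in table")
  cand <- setdiff(seq_len(nSamples(x)), c(i, match(exclude, ids)))
  a <- x@alleleA; b <- x@alleleB
  o1 <- a[i, ]; o2 <- b[i, ]
  oOk <- !is.na(o1) & o1 > 0L & o2 > 0L
  # per candidate and locus: can it supply o1 / o2?
  cm <- length(cand)
  m <- nMarkers(x)
  c1 <- matrix(FALSE, cm, m); c2 <- matrix(FALSE, cm, m); pOk <- c1
  for (l in which(oOk)) {
    pa <- a[cand, l]; pb <- b[cand, l]
    ok <- !is.na(pa) & pa > 0L & pb > 0L
    c1[, l] <- ok & (pa == o1[l] | pb == o1[l])
    c2[, l] <- ok & (pa == o2[l] | pb == o2[l])
    pOk[, l] <- ok
  }
  # Pruning: a candidate failing to supply either offspring allele at a
  # locus can only enter a zero-mismatch pair if the co-parent is incomplete
  # there (the locus is then skipped). So candidates failing at any locus
  # where every candidate is complete can never qualify; the survivors are
  # verified exhaustively below.
  fails <- pOk & !(c1 | c2)
  lociAllComplete <- which(colSums(!pOk) == 0L & oOk)
  feasible <- which(rowSums(fails[, lociAllComplete, drop = FALSE]) == 0L)
  res <- list()
  if (length(feasible)) {
    # enumerate unordered pairs among feasible candidates (incl. selfing)
    pairsIdx <- which(upper.tri(diag(length(feasible))), arr.ind = TRUE)
    combos <- rbind(
      if (allowSelfing) cbind(feasible, feasible) else NULL,
      if (nrow(pairsIdx)) cbind(feasible[pairsIdx[, 1]],
                                feasible[pairsIdx[, 2]]) else NULL)
    if (!is.null(combos) && nrow(combos)) {
      for (r in seq_len(nrow(combos))) {
        # combos hold row indices of the candidate matrices
        mu <- combos[r, 1]; mv <- combos[r, 2]
        use <- pOk[mu, ] & pOk[mv, ]
        compat <- (c1[mu, ] & c2[mv, ]) | (c1[mv, ] & c2[mu, ])
        if (all(compat[use])) {
          res[[length(res) + 1L]] <- data.frame(
            offspring = ids[i], parent_a = ids[cand[mu]],
            parent_b = ids[cand[mv]], mismatch = 0L,
            loci_used = sum(use), lod = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(offspring = character(), parent_a = character(),
                    parent_b = character(), mismatch = integer(),
                    loci_used = integer(), lod = numeric(),
                    stringsAsFactors = FALSE)
  if (!is.null(freqs) && nrow(out)) {
    out$lod <- vapply(seq_len(nrow(out)), function(r)
      lodScore(x, out$offspring[r], out$parent_a[r], out$parent_b[r],
               freqs), numeric(1))
    out <- out[order(-out$lod), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Mendelian transmission probability of the offspring's unordered genotype
# given two parental genotypes: fraction of the four equiprobable gamete
# combinations reproducing it.
.transmissionProb <- function(o1, o2, p1, p2, q1, q2) {
  fromP <- c(p1, p1, p2, p2)
  fromQ <- c(q1, q2, q1, q2)
  hits <- (fromP == o1 & fromQ == o2) | (fromP == o2 & fromQ == o1)
  mean(hits)
}

#' LOD score of a candidate trio
#'
#' Base-10 log likelihood ratio of Mendelian transmission from the candidate
#' parent pair versus a random Hardy-Weinberg draw, summed over loci
#' complete in all three samples: \eqn{\sum_l \log_{10} [ T_l / H_l ]} with
#' \eqn{T_l} the gamete-enumeration transmission probability and \eqn{H_l}
#' the HWE genotype probability of the offspring call. No genotyping-error
#' model is applied; the trio must already be zero-mismatch for a finite
#' score.
#'
#' @param x a \code{GenotypeTable}.
#' @param offspring,p,q sample identifiers or row indices.
#' @param freqs named list of per-marker allele frequency vectors.
#' @return numeric LOD.
#' @export
lodScore <- function(x, offspring, p, q, freqs) {
  stopifnot(is(x, "GenotypeTable"))
  idx <- function(s) if (is.character(s)) match(s, sampleIds(x)) else s
  i <- idx(offspring); j <- idx(p); k <- idx(q)
  ok <- .trioLociOk(x, i, j, k)
  a <- x@alleleA; b <- x@alleleB
  total <- 0
  for (l in which(ok)) {
    mk <- markerNames(x)[l]
    f <- freqs[[mk]]
    if (is.null(f)) stop("no frequencies for marker ", mk)
    o1 <- a[i, l]; o2 <- b[i, l]
    tp <- .transmissionProb(o1, o2, a[j, l], b[j, l], a[k, l], b[k, l])
    p1 <- f[as.character(o1)]; p2 <- f[as.character(o2)]
    if (anyNA(c(p1, p2)) || p1 <= 0 || p2 <= 0)
      stop("offspring allele absent from supplied frequencies at ", mk)
    hwe <- if (o1 == o2) p1^2 else 2 * p1 * p2
    total <- total + log10(tp / hwe)
  }
  as.numeric(total)
}

#' Collection-level parentage summary
#'
#' Runs the zero-mismatch search for every sample and summarizes: pair
#' counts per offspring before and after collapsing pairs that differ only
#' by clone-cluster membership (clonal parents count once), the histogram of
#' per-offspring pair counts, the number of offspring with at least one
#' compatible pair, and the mean pairs per resolved offspring.
#'
#' @param x a deduplicated \code{GenotypeTable}.
#' @param allowSelfing allow selfed parent pairs.
#' @param cloneClusters optional list of character vectors (from
#'   \code{\link{findDuplicates}} on the pre-deduplication table): members of
#'   one cluster are treated as a single parent for pair counting.
#' @param freqs optional frequency list for LOD ranking.
#' @return list with \code{pairs} (data.frame of all zero-mismatch trios),
#'   \code{perOffspring} (data.frame sample, n_pairs, n_pairs_collapsed),
#'   \code{histogram} (table of collapsed pair counts incl. zero),
#'   \code{nResolved}, \code{meanPairsPerResolved} and \code{nPairsTotal}.
#' @export
parentageSummary <- function(x, allowSelfing = TRUE, cloneClusters = NULL,
                             freqs = NULL) {
  stopifnot(is(x, "GenotypeTable"))
  ids <- sampleIds(x)
  cloneOf <- ids
  names(cloneOf) <- ids
  if (!is.null(cloneClusters))
    for (cl in cloneClusters)
      cloneOf[cl[cl %in% ids]] <- cl[1]
  allPairs <- list()
  nPairs <- integer(length(ids))
  nPairsColl <- integer(length(ids))
  for (s in seq_along(ids)) {
    hits <- searchParentPairs(x, s, allowSelfing = allowSelfing,
                              freqs = freqs)
    nPairs[s] <- nrow(hits)
    if (nrow(hits)) {
      key <- apply(cbind(cloneOf[hits$parent_a], cloneOf[hits$parent_b]),
                   1, function(v) paste(sort(v), collapse = "|"))
      nPairsColl[s] <- length(unique(key))
      hits$pair_key <- key
      allPairs[[length(allPairs) + 1L]] <- hits
    }
  }
  pairs <- if (length(allPairs)) do.call(rbind, allPairs)
    else data.frame(offspring = character(), parent_a = character(),
                    parent_b = character(), mismatch = integer(),
                    loci_used = integer(), lod = numeric(),
                    pair_key = character(), stringsAsFactors = FALSE)
  resolved <- nPairsColl > 0
  list(pairs = pairs,
       perOffspring = data.frame(sample = ids, n_pairs = nPairs,
                                 n_pairs_collapsed = nPairsColl,
                                 stringsAsFactors = FALSE),
       histogram = table(factor(nPairsColl, levels = 0:max(nPairsColl, 1))),
       nResolved = sum(resolved),
       meanPairsPerResolved = if (any(resolved))
         mean(nPairsColl[resolved]) else NA_real_,
       nPairsTotal = sum(nPairsColl))
}
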