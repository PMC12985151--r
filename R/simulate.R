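#' Simulate an allele-frequency spectrum for one SSR marker
#'
#' Draws k frequencies from a symmetric Dirichlet and assigns allele lengths
#' on a motif-length lattice (\code{base + motif * 0:(k-1)}), resembling a
#' real SSR allele ladder. With \code{targetPic}, spectra are
#' rejection-sampled until the PIC is within \code{tol} of the target; a
#' target above the k-allele maximum (attained at equifrequency) is an
#' error.
#'
#' @param k number of alleles.
#' @param concentration Dirichlet concentration (1 = flat; large values give
#'   near-equifrequent spectra).
#' @param targetPic optional PIC to hit within \code{tol}.
#' @param motifLength repeat-unit length in nt (allele spacing).
#' @param baseLength length of the shortest allele in nt.
#' @param seed integer seed (mandatory for reproducibility).
#' @param tol tolerance around \code{targetPic}.
#' @param maxTries rejection-sampling cap.
#' @return named numeric frequency vector (names = allele lengths).
#' @export
simulateFrequencies <- function(k, concentration = 1, targetPic = NULL,
                                motifLength = 2, baseLength = 100,
                                seed, tol = 0.02, maxTries = 20000) {
  stopifnot(k >= 1)
  set.seed(seed)
  lengths <- baseLength + motifLength * (seq_len(k) - 1L)
  if (k == 1) {
    p <- stats::setNames(1, lengths)
    if (!is.null(targetPic) && targetPic > tol)
      stop("a single allele has PIC 0; target unattainable")
    return(p)
  }
  if (!is.null(targetPic)) {
    maxPic <- pic(rep(1 / k, k))
    if (targetPic > maxPic + tol)
      stop("target PIC ", targetPic, " exceeds the k-allele maximum ",
           round(maxPic, 4), " at k = ", k)
  }
  for (try in seq_len(maxTries)) {
    g <- stats::rgamma(k, shape = concentration)
    p <- g / sum(g)
    if (any(p <= 0)) next
    if (is.null(targetPic) || abs(pic(p) - targetPic) <= tol) {
      p <- sort(p, decreasing = TRUE)
      names(p) <- lengths
      return(p)
    }
  }
  stop("no spectrum within tolerance after ", maxTries, " draws")
}

#' Simulate a Hardy-Weinberg population
#'
#' Each genotype is two independent allele draws per marker from the given
#' spectra, the sampling model under which the probability-of-identity
#' formula is exact.
#'
#' @param freqs named list of per-marker frequency vectors (names of each
#'   vector are allele lengths in nt).
#' @param n number of individuals.
#' @param seed integer seed.
#' @param prefix sample-identifier prefix.
#' @param panel optional \code{SSRPanel} (defaults to a minimal panel over
#'   the marker names).
#' @return a \code{GenotypeTable}.
#' @export
simulatePopulation <- function(freqs, n, seed, prefix = "S", panel = NULL) {
  stopifnot(is.list(freqs), n >= 1, !is.null(names(freqs)))
  set.seed(seed)
  m <- length(freqs)
  a <- matrix(NA_integer_, n, m)
  b <- matrix(NA_integer_, n, m)
  for (k in seq_len(m)) {
    lens <- as.integer(names(freqs[[k]]))
    a[, k] <- sample(lens, n, replace = TRUE, prob = freqs[[k]])
    b[, k] <- sample(lens, n, replace = TRUE, prob = freqs[[k]])
  }
  rownames(a) <- rownames(b) <- sprintf("%s%0*d", prefix,
                                        nchar(as.character(n)), seq_len(n))
  colnames(a) <- colnames(b) <- names(freqs)
  GenotypeTable(a, b, panel)
}

#' Simulate offspring of a cross
#'
#' Each offspring receives one uniformly chosen allele from each parent per
#' locus (Mendelian segregation); with \code{p == q} this is selfing. An
#' optional single-step mutation model perturbs a transmitted allele by one
#' motif length at rate \code{mutationRate} per allele.
#'
#' @param x a \code{GenotypeTable} containing both parents.
#' @param p,q parent sample identifiers or row indices (equal for selfing).
#' @param nOffspring number of offspring rows to generate.
#' @param mutationRate per-allele single-step mutation probability.
#' @param motifLength mutation step in nt.
#' @param seed integer seed.
#' @param ids optional offspring identifiers.
#' @return a \code{GenotypeTable} of the offspring (same panel).
#' @export
simulateCross <- function(x, p, q, nOffspring = 1, mutationRate = 0,
                          motifLength = 2, seed, ids = NULL) {
  stopifnot(is(x, "GenotypeTable"))
  idx <- function(s) if (is.character(s)) match(s, sampleIds(x)) else s
  j <- idx(p); k <- idx(q)
  if (anyNA(c(j, k))) stop("parent not in table")
  if (anyNA(x@alleleA[c(j, k), ])) stop("parents must be fully genotyped")
  set.seed(seed)
  m <- nMarkers(x)
  a <- matrix(NA_integer_, nOffspring, m)
  b <- matrix(NA_integer_, nOffspring, m)
  for (l in seq_len(m)) {
    fromP <- ifelse(stats::runif(nOffspring) < 0.5,
                    x@alleleA[j, l], x@alleleB[j, l])
    fromQ <- ifelse(stats::runif(nOffspring) < 0.5,
                    x@alleleA[k, l], x@alleleB[k, l])
    if (mutationRate > 0) {
      mut <- stats::runif(nOffspring) < mutationRate
      fromP[mut] <- fromP[mut] +
        sample(c(-motifLength, motifLength), sum(mut), replace = TRUE)
      mut <- stats::runif(nOffspring) < mutationRate
      fromQ[mut] <- fromQ[mut] +
        sample(c(-motifLength, motifLength), sum(mut), replace = TRUE)
    }
    a[, l] <- fromP
    b[, l] <- fromQ
  }
  if (is.null(ids)) ids <- sprintf("off%d", seq_len(nOffspring))
  rownames(a) <- rownames(b) <- ids
  colnames(a) <- colnames(b) <- markerNames(x)
  GenotypeTable(a, b, panel(x))
}

#' Simulate generations descending from few founders
#'
#' Starting from the founder rows, each generation is produced by crosses
#' between individuals drawn from the previous generation (selfing
#' optionally allowed). The descendant allele pool can only shrink relative
#' to the founders, emulating a breeding bottleneck / founder effect:
#' diversity statistics (k, PIC, Ae) weakly decrease down the generations
#' while the probability of identity rises.
#'
#' @param founders a \code{GenotypeTable} of fully genotyped founders.
#' @param nGenerations number of descendant generations.
#' @param popSize individuals per generation.
#' @param selfing allow a parent to be drawn twice for one cross.
#' @param seed integer seed.
#' @return list with \code{table} (founders plus all descendants),
#'   \code{pedigree} (data.frame child, parent_a, parent_b, generation) and
#'   \code{generation} (integer per row of \code{table}; founders are 0).
#' @export
simulateFounderPopulation <- function(founders, nGenerations, popSize,
                                      selfing = TRUE, seed) {
  stopifnot(is(founders, "GenotypeTable"), nSamples(founders) >= 1)
  set.seed(seed)
  a <- founders@alleleA; b <- founders@alleleB
  gen <- rep(0L, nrow(a))
  ped <- list()
  prev <- seq_len(nrow(a))
  for (g in seq_len(nGenerations)) {
    newA <- matrix(NA_integer_, popSize, ncol(a))
    newB <- newA
    ids <- sprintf("g%d_%d", g, seq_len(popSize))
    for (i in seq_len(popSize)) {
      pq <- sample(prev, 2, replace = selfing)
      pick <- function(parent)
        ifelse(stats::runif(ncol(a)) < 0.5, a[parent, ], b[parent, ])
      newA[i, ] <- pick(pq[1])
      newB[i, ] <- pick(pq[2])
      ped[[length(ped) + 1L]] <- data.frame(
        child = ids[i], parent_a = rownames(a)[pq[1]],
        parent_b = rownames(a)[pq[2]], generation = g,
        stringsAsFactors = FALSE)
    }
    rownames(newA) <- rownames(newB) <- ids
    prev <- nrow(a) + seq_len(popSize)
    a <- rbind(a, newA); b <- rbind(b, newB)
    gen <- c(gen, rep(g, popSize))
  }
  colnames(a) <- colnames(b) <- markerNames(founders)
  list(table = GenotypeTable(a, b, panel(founders)),
       pedigree = do.call(rbind, ped), generation = gen)
}

#' Inject genotyping artifacts into a table
#'
#' Emulates the blemishes of real fragment-analysis data: a hidden null
#' allele per marker (a heterozygote carrying it appears homozygous for its
#' visible allele; a null homozygote appears as no-amplification
#' \code{(0,0)}), duplicated rows under new names (clones/synonyms), and
#' random allele typos at a per-call rate. A truth log of every change is
#' returned for planted-truth recovery tests.
#'
#' @param x a \code{GenotypeTable}.
#' @param nullAlleleRate per-gene-copy probability of carrying the hidden
#'   null allele, per marker.
#' @param replicateErrorRate per-call probability of a one-step allele typo.
#' @param cloneSpec data.frame with columns \code{source} (existing sample
#'   id) and \code{newId}, or an integer count of clones of random samples.
#' @param motifLength typo step in nt.
#' @param seed integer seed.
#' @return list with \code{table} and \code{truth} (list with
#'   \code{nullCarriers}, \code{typos}, \code{clones}).
#' @export
injectArtifacts <- function(x, nullAlleleRate = 0, replicateErrorRate = 0,
                            cloneSpec = NULL, motifLength = 2, seed) {
  stopifnot(is(x, "GenotypeTable"),
            nullAlleleRate >= 0, nullAlleleRate <= 1,
            replicateErrorRate >= 0, replicateErrorRate <= 1)
  set.seed(seed)
  a <- x@alleleA; b <- x@alleleB
  truth <- list(nullCarriers = NULL, typos = NULL, clones = NULL)
  if (nullAlleleRate > 0) {
    hits <- list()
    for (l in seq_len(ncol(a))) {
      carryA <- stats::runif(nrow(a)) < nullAlleleRate
      carryB <- stats::runif(nrow(a)) < nullAlleleRate
      both <- carryA & carryB & !is.na(a[, l])
      one <- xor(carryA, carryB) & !is.na(a[, l])
      # null homozygote: no amplification at all
      a[both, l] <- 0L; b[both, l] <- 0L
      # null heterozygote: only the visible allele amplifies -> apparent hom
      visible <- ifelse(carryA[one], b[one, l], a[one, l])
      a[one, l] <- visible; b[one, l] <- visible
      if (any(both | one))
        hits[[length(hits) + 1L]] <- data.frame(
          sample = rownames(a)[both | one],
          marker = colnames(a)[l],
          kind = ifelse(both[both | one], "homozygous-null",
                        "masked-heterozygote"),
          stringsAsFactors = FALSE)
    }
    truth$nullCarriers <- if (length(hits)) do.call(rbind, hits)
  }
  if (replicateErrorRate > 0) {
    hit <- !is.na(a) & stats::runif(length(a)) < replicateErrorRate & a > 0L
    step <- matrix(sample(c(-motifLength, motifLength), length(a),
                          replace = TRUE), nrow(a))
    useB <- matrix(stats::runif(length(a)) < 0.5, nrow(a))
    ia <- hit & !useB; ib <- hit & useB & b > 0L
    a[ia] <- a[ia] + step[ia]
    b[ib] <- b[ib] + step[ib]
    idx <- which(ia | ib, arr.ind = TRUE)
    if (nrow(idx))
      truth$typos <- data.frame(sample = rownames(a)[idx[, 1]],
                                marker = colnames(a)[idx[, 2]],
                                stringsAsFactors = FALSE)
  }
  if (!is.null(cloneSpec)) {
    if (is.numeric(cloneSpec)) {
      src <- sample(rownames(a), cloneSpec, replace = FALSE)
      cloneSpec <- data.frame(source = src,
                              newId = paste0(src, "_syn"),
                              stringsAsFactors = FALSE)
    }
    rows <- match(cloneSpec$source, rownames(a))
    if (anyNA(rows)) stop("clone source sample(s) not in table")
    ca <- a[rows, , drop = FALSE]; cb <- b[rows, , drop = FALSE]
    rownames(ca) <- rownames(cb) <- cloneSpec$newId
    a <- rbind(a, ca); b <- rbind(b, cb)
    truth$clones <- cloneSpec
  }
  list(table = GenotypeTable(a, b, panel(x)), truth = truth)
}
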