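#' Allele frequencies at one marker
#'
#' Counts every called allele once per gene copy. Null alleles (the \code{0}
#' sentinel) are unobservable products and are excluded from both numerator
#' and denominator, so a homozygous-null call contributes nothing.
#'
#' @param x a \code{GenotypeTable}.
#' @param marker marker name.
#' @return named numeric vector of proportions (names are allele lengths),
#'   summing to 1, with attributes \code{nCopies} (number of gene copies
#'   counted) and \code{marker}.
#' @examples
#' tab <- GenotypeTable(matrix(c(100, 100), 2, 1, dimnames = list(c("a","b"), "M")),
#'                      matrix(c(100, 104), 2, 1, dimnames = list(c("a","b"), "M")))
#' alleleFrequencies(tab, "M")
#' @export
alleleFrequencies <- function(x, marker) {
  stopifnot(is(x, "GenotypeTable"))
  k <- match(marker, markerNames(x))
  if (is.na(k)) stop("marker not in table: ", marker)
  alleles <- c(x@alleleA[, k], x@alleleB[, k])
  alleles <- alleles[!is.na(alleles) & alleles > 0L]
  if (!length(alleles))
    stop("no called (non-null) alleles at marker ", marker)
  counts <- table(alleles)
  p <- as.numeric(counts) / sum(counts)
  names(p) <- names(counts)
  structure(p, nCopies = sum(counts), marker = marker,
            counts = as.integer(counts))
}

.checkFreqs <- function(p) {
  if (any(p <= 0)) stop("allele frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  as.numeric(p)
}

#' Observed heterozygosity at one marker
#'
#' Fraction of fully scored individuals (both alleles called, non-null)
#' whose two alleles differ.
#'
#' @inheritParams alleleFrequencies
#' @return proportion in \code{[0, 1]}.
#' @export
observedHeterozygosity <- function(x, marker) {
  stopifnot(is(x, "GenotypeTable"))
  k <- match(marker, markerNames(x))
  if (is.na(k)) stop("marker not in table: ", marker)
  a <- x@alleleA[, k]; b <- x@alleleB[, k]
  keep <- !is.na(a) & a > 0L & b > 0L
  if (!any(keep)) stop("no scored calls at marker ", marker)
  mean(a[keep] != b[keep])
}

#' Expected heterozygosity (Nei's gene diversity)
#'
#' Default is the biased form \eqn{H_e = 1 - \sum p_i^2}; with
#' \code{unbiased = TRUE} it is multiplied by \eqn{n/(n-1)} where \eqn{n} is
#' the number of gene copies.
#'
#' @param p allele-frequency vector (e.g. from
#'   \code{\link{alleleFrequencies}}).
#' @param unbiased apply the small-sample correction.
#' @param nCopies gene-copy count; taken from \code{attr(p, "nCopies")} when
#'   absent.
#' @return proportion in \code{[0, 1)}.
#' @export
expectedHeterozygosity <- function(p, unbiased = FALSE, nCopies = NULL) {
  he <- 1 - sum(.checkFreqs(p)^2)
  if (!unbiased) return(he)
  if (is.null(nCopies)) nCopies <- attr(p, "nCopies")
  if (is.null(nCopies) || nCopies < 2)
    stop("unbiased He needs nCopies >= 2")
  he * nCopies / (nCopies - 1)
}

#' Polymorphic information content (Botstein)
#'
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2}.
#'
#' @inheritParams expectedHeterozygosity
#' @return value in \code{[0, He]}.
#' @export
pic <- function(p) {
  p <- .checkFreqs(p)
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Effective number of alleles
#'
#' \eqn{A_e = 1 / \sum p_i^2}: the number of equifrequent alleles giving the
#' same homozygosity; equals \eqn{1/(1 - H_e)} for biased \eqn{H_e}.
#'
#' @inheritParams expectedHeterozygosity
#' @return value in \code{[1, k]}.
#' @export
effectiveAlleles <- function(p) 1 / sum(.checkFreqs(p)^2)

#' Probability of identity at one locus
#'
#' The chance that two unrelated individuals drawn from a Hardy-Weinberg
#' population share the same genotype at the locus:
#' \eqn{PI = \sum_i p_i^4 + \sum_i \sum_{j>i} (2 p_i p_j)^2}.
#'
#' @inheritParams expectedHeterozygosity
#' @return probability in \code{(0, 1]}.
#' @export
probabilityIdentity <- function(p) {
  p <- .checkFreqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_i p^4 + 4 * sum_{i<j} p_i^2 p_j^2, with 2*sum_{i<j} = s2^2 - s4
  s4 + 2 * (s2^2 - s4)
}

#' Shannon's information index
#'
#' \eqn{I = -\sum p_i \ln p_i} (natural log).
#'
#' @inheritParams expectedHeterozygosity
#' @return nonnegative value.
#' @export
shannonIndex <- function(p) {
  p <- .checkFreqs(p)
  -sum(p * log(p))
}

#' Null-allele probability estimate
#'
#' Heterozygote-deficit estimators: Chakraborty's
#' \eqn{r = (H_e - H_o) / (H_e + H_o)} (default) or Brookfield's first
#' estimator \eqn{r = (H_e - H_o) / (1 + H_e)}. Either may be negative when
#' heterozygotes exceed expectation.
#'
#' @param ho,he observed and expected heterozygosity in \code{[0, 1]}.
#' @param method \code{"chakraborty"} or \code{"brookfield"}.
#' @return estimated rate, or \code{NA} when undefined (\code{ho + he = 0}).
#' @export
nullAlleleEstimate <- function(ho, he,
                               method = c("chakraborty", "brookfield")) {
  stopifnot(ho >= 0, ho <= 1, he >= 0, he <= 1)
  method <- match.arg(method)
  if (method == "chakraborty") {
    if (ho + he == 0) return(NA_real_)
    (he - ho) / (he + ho)
  } else {
    (he - ho) / (1 + he)
  }
}

#' Rarefied allelic richness at one marker
#'
#' Expected number of distinct alleles in a random subsample of \code{g}
#' gene copies, by hypergeometric rarefaction:
#' \eqn{k - \sum_a \binom{N - N_a}{g} / \binom{N}{g}} with \eqn{N} total
#' copies and \eqn{N_a} copies of allele \eqn{a}.
#'
#' @inheritParams alleleFrequencies
#' @param g rarefaction size in gene copies; default is all copies at the
#'   marker (richness then equals the raw allele count).
#' @return expected allele count (real).
#' @export
allelicRichness <- function(x, marker, g = NULL) {
  p <- alleleFrequencies(x, marker)
  counts <- attr(p, "counts")
  N <- sum(counts)
  if (is.null(g)) g <- N
  if (g > N) stop("rarefaction size g exceeds available gene copies (", N, ")")
  if (g < 1) stop("g must be >= 1")
  # lchoose is stable for the sizes seen here
  absent <- exp(lchoose(N - counts, g) - lchoose(N, g))
  length(counts) - sum(absent)
}

#' Per-marker diversity statistics
#'
#' Computes the locus summary from a single frequency pass: allele count k,
#' Ho, He, PIC, Ae, the per-locus probability of identity, Shannon's index,
#' rarefied allelic richness, the null-allele estimate and the allele-length
#' extremes.
#'
#' @inheritParams alleleFrequencies
#' @param unbiased use the small-sample-corrected He.
#' @param richnessG rarefaction size for allelic richness (gene copies);
#'   default all copies at the marker.
#' @return one-row data.frame with columns \code{marker}, \code{n},
#'   \code{k}, \code{Ho}, \code{He}, \code{PIC}, \code{Ae}, \code{PI},
#'   \code{shannon}, \code{richness}, \code{null_rate}, \code{min_len},
#'   \code{max_len}.
#' @export
markerStats <- function(x, marker, unbiased = FALSE, richnessG = NULL) {
  p <- alleleFrequencies(x, marker)
  ho <- observedHeterozygosity(x, marker)
  he <- expectedHeterozygosity(p, unbiased = unbiased)
  lens <- as.integer(names(p))
  data.frame(
    marker = marker,
    n = as.integer(attr(p, "nCopies") / 2),
    k = length(p),
    Ho = ho,
    He = he,
    PIC = pic(p),
    Ae = effectiveAlleles(p),
    PI = probabilityIdentity(p),
    shannon = shannonIndex(p),
    richness = allelicRichness(x, marker, g = richnessG),
    null_rate = nullAlleleEstimate(ho, he),
    min_len = min(lens),
    max_len = max(lens),
    stringsAsFactors = FALSE)
}

#' Panel-level diversity summary
#'
#' Per-marker statistics plus their arithmetic means and the total
#' probability of identity \eqn{PI_t = \prod_i PI_i} over the panel.
#'
#' @inheritParams markerStats
#' @param markers marker names to include (default: whole panel).
#' @return list with \code{perMarker} (data.frame), \code{averages} (named
#'   numeric means over markers) and \code{PIt}.
#' @export
panelSummary <- function(x, markers = markerNames(x), unbiased = FALSE,
                         richnessG = NULL) {
  stopifnot(is(x, "GenotypeTable"), length(markers) >= 1)
  per <- do.call(rbind, lapply(markers, function(m)
    markerStats(x, m, unbiased = unbiased, richnessG = richnessG)))
  rownames(per) <- NULL
  num <- c("k", "Ho", "He", "PIC", "Ae", "PI", "shannon", "richness",
           "null_rate")
  averages <- vapply(per[num], mean, numeric(1))
  structure(list(perMarker = per, averages = averages,
                 PIt = prod(per$PI)),
            class = "ssrPanelSummary")
}

#' @export
print.ssrPanelSummary <- function(x, ...) {
  cat("Panel diversity summary over", nrow(x$perMarker), "markers\n")
  print(cbind(x$perMarker[c("marker", "k")],
              round(x$perMarker[c("Ho", "He", "PIC", "Ae")], 3),
              PI = signif(x$perMarker$PI, 3)), row.names = FALSE)
  cat("Averages: ", paste(names(x$averages[1:5]),
                          round(x$averages[1:5], 3),
                          sep = "=", collapse = "  "), "\n")
  cat("PI_t =", format(x$PIt, digits = 3), "\n")
  invisible(x)
}

#' Diversity statistics of a sample subset
#'
#' Recomputes the panel summary on a subset of samples (for example the
#' members of an inbred family inferred from a population-structure run) and
#' reports per-marker allele losses relative to the full table. Under a
#' founder effect, k, PIC and Ae drop while PI rises.
#'
#' @inheritParams panelSummary
#' @param samples character vector of sample identifiers, or logical/integer
#'   row index.
#' @return list with \code{stats} (the subset \code{panelSummary}),
#'   \code{alleleLoss} (data.frame marker, k_full, k_subset, lost) and
#'   \code{n} (subset size).
#' @export
subsetStats <- function(x, samples, unbiased = FALSE, richnessG = NULL) {
  stopifnot(is(x, "GenotypeTable"))
  if (is.character(samples)) {
    missing <- setdiff(samples, sampleIds(x))
    if (length(missing))
      stop("sample(s) not in table: ", paste(missing, collapse = ", "))
    idx <- which(sampleIds(x) %in% samples)
  } else idx <- samples
  if (length(idx) == 0 || nrow(x@alleleA[idx, , drop = FALSE]) == 0)
    stop("empty sample subset")
  sub <- x[idx, ]
  stats <- panelSummary(sub, unbiased = unbiased, richnessG = richnessG)
  loss <- do.call(rbind, lapply(markerNames(x), function(m) {
    full <- alleleFrequencies(x, m)
    subp <- alleleFrequencies(sub, m)
    data.frame(marker = m, k_full = length(full), k_subset = length(subp),
               lost = length(setdiff(names(full), names(subp))),
               stringsAsFactors = FALSE)
  }))
  rownames(loss) <- NULL
  list(stats = stats, alleleLoss = loss, n = length(idx))
}

#' Reconstruct an allele-frequency spectrum from summary statistics
#'
#' Given a published locus summary (allele count k, expected heterozygosity
#' He and PIC), finds a frequency vector with those statistics. He and PIC
#' jointly fix \eqn{\sum p^2} and \eqn{\sum p^4}, which in turn determine
#' Ae and the probability of identity, so any exact solution reproduces a
#' table's PI even though the full spectrum is unpublished. The spectrum is
#' found by simplex-constrained least squares on \eqn{(\sum p^2, \sum p^4)}
#' from multiple deterministic starts.
#'
#' @param k number of alleles.
#' @param he expected heterozygosity (biased form, \eqn{1 - \sum p^2}).
#' @param picValue polymorphic information content.
#' @param lengths optional allele lengths to name the result (length k).
#' @param tol maximum tolerated relative residual on each moment (default
#'   2e-3). Statistics printed to three decimals can make the exact pair
#'   marginally infeasible on the simplex; the nearest feasible spectrum is
#'   then returned, which perturbs the derived PI by at most the same
#'   relative order.
#' @return named numeric frequency vector of length \code{k}.
#' @export
frequenciesFromSummary <- function(k, he, picValue, lengths = NULL,
                                   tol = 2e-3) {
  stopifnot(k >= 1, he >= 0, he < 1, picValue >= 0, picValue <= he)
  if (k == 1) {
    p <- 1
  } else {
    t2 <- 1 - he
    t4 <- picValue - 1 + t2 + t2^2
    if (t4 <= 0 || t4 > t2^2)
      stop("no frequency spectrum matches this (He, PIC) pair")
    obj <- function(theta) {
      w <- exp(theta - max(theta))
      p <- w / sum(w)
      ((sum(p^2) - t2) / t2)^2 + ((sum(p^4) - t4) / t4)^2
    }
    best <- NULL
    for (s in seq(0.2, 4, by = 0.4)) {
      start <- -s * (seq_len(k) - 1)
      fit <- stats::optim(start, obj, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-16))
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-16))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-24) break
    }
    w <- exp(best$par - max(best$par))
    p <- w / sum(w)
    if (sqrt(best$value) > tol)
      stop("frequency reconstruction did not converge for k=", k,
           " He=", he, " PIC=", picValue)
    p <- sort(p, decreasing = TRUE)
  }
  if (!is.null(lengths)) {
    stopifnot(length(lengths) == k)
    names(p) <- lengths
  } else names(p) <- seq_len(k)
  structure(p, nCopies = NA_integer_)
}
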