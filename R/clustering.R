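#' Allele-sharing genetic distance
#'
#' For each sample pair, \eqn{d = 1 - S / (2 L)} where \eqn{S} is the total
#' number of alleles shared (multiset intersection per locus) and \eqn{L}
#' the number of loci scored in both samples (Dps-style distance for
#' codominant data). Loci missing in either sample are skipped pairwise; a
#' pair with no comparable locus is an error.
#'
#' @param x a consolidated \code{GenotypeTable}.
#' @return a \code{\link[stats]{dist}} object with sample labels.
#' @export
alleleSharingDistance <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  n <- nSamples(x)
  pw <- .pairwiseShared(x)
  if (any(pw$compared == 0L))
    stop("sample pair(s) share no scored locus; distance undefined")
  d <- 1 - pw$shared / (2 * pw$compared)
  m <- matrix(0, n, n, dimnames = list(sampleIds(x), sampleIds(x)))
  m[cbind(pw$i, pw$j)] <- d
  m[cbind(pw$j, pw$i)] <- d
  stats::as.dist(m)
}

#' UPGMA dendrogram
#'
#' Standard size-weighted average-linkage agglomeration on a distance
#' matrix, returned as a rooted ultrametric \code{\link[ape]{phylo}} tree
#' (every leaf equidistant from the root; a pair joined at distance
#' \eqn{d} sits at height \eqn{d/2}).
#'
#' @param d a \code{dist} or symmetric matrix with labels.
#' @return an ultrametric \code{phylo}; the underlying \code{hclust} is
#'   attached as attribute \code{"hclust"}.
#' @export
upgmaTree <- function(d) {
  d <- stats::as.dist(d)
  hc <- stats::hclust(d, method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

#' Cophenetic correlation between a distance matrix and a dendrogram
#'
#' Pearson correlation between the lower triangle of \code{d} and the
#' cophenetic distances of the tree, aligned by label (not by index).
#' Equals 1 when \code{d} is already ultrametric.
#'
#' @param d a \code{dist} or labelled symmetric matrix.
#' @param tree a \code{phylo} from \code{\link{upgmaTree}} or an
#'   \code{hclust}.
#' @return correlation in \code{[-1, 1]}.
#' @export
copheneticCorrelation <- function(d, tree) {
  d <- stats::as.dist(d)
  labs <- attr(d, "Labels")
  if (inherits(tree, "phylo")) {
    hc <- attr(tree, "hclust")
    cp <- if (!is.null(hc)) stats::cophenetic(hc)
      else stats::as.dist(ape::cophenetic.phylo(tree))
  } else cp <- stats::cophenetic(tree)
  cpm <- as.matrix(cp)
  if (!all(labs %in% rownames(cpm))) stop("tree and matrix labels differ")
  cpAligned <- stats::as.dist(cpm[labs, labs])
  v1 <- as.vector(d); v2 <- as.vector(cpAligned)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distances; cophenetic correlation undefined")
  stats::cor(v1, v2)
}

#' Mantel test between two genetic distance matrices
#'
#' Pearson correlation of the lower triangles with a one-sided
#' ("greater") permutation p-value,
#' \eqn{p = (1 + \#\{r^* \ge r\}) / (1 + n_{perm})}, permuting the rows and
#' columns of the second matrix jointly. The two matrices must carry the
#' same label set; the second is aligned to the first by label before
#' testing. The permutation stream is seeded for reproducibility.
#'
#' @param d1,d2 \code{dist} objects or labelled symmetric matrices.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with \code{r}, \code{p}, \code{nPerm} and \code{seed}.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = 1) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (is.null(l1) || is.null(l2) || !setequal(l1, l2))
    stop("distance matrices must carry the same label set")
  m2 <- as.matrix(d2)[l1, l1]
  set.seed(seed)
  fit <- vegan::mantel(d1, stats::as.dist(m2), method = "pearson",
                       permutations = nPerm)
  list(r = unname(fit$statistic), p = unname(fit$signif), nPerm = nPerm,
       seed = seed)
}
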