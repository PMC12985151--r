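#' Simulate a study-scale genotyping collection
#'
#' Composes a synthetic germplasm collection with the structure of a large
#' varietal survey genotyped on the published 16-marker panel: per-marker
#' allele-frequency spectra reconstructed from the published (k, He, PIC)
#' summaries (see \code{\link{frequenciesFromSummary}}), a set of unrelated
#' founder-type accessions in Hardy-Weinberg proportions, a subset of
#' accessions that are true offspring of crosses between collection members
#' (recorded in the returned pedigree), and extra rows that duplicate
#' existing genotypes under new names (synonyms/clones). Defaults mirror
#' the published collection: 294 unique genotypes of which 123 are
#' pedigree offspring, plus 21 synonym rows for 315 samples in total.
#'
#' @param seed integer seed driving every random choice.
#' @param nUnique number of unique genotypes.
#' @param nOffspring how many of the unique genotypes are offspring of
#'   crosses between other collection members.
#' @param nClones extra duplicated rows under synonym names.
#' @param stats published per-marker summary table (default
#'   \code{publishedPanelStats("16in1")}).
#' @return list with \code{table} (the full collection,
#'   \code{nUnique + nClones} rows), \code{pedigree} (data.frame child,
#'   parent_a, parent_b), \code{clones} (data.frame source, newId),
#'   \code{freqs} (the per-marker spectra used) and \code{founders}
#'   (identifiers of the non-offspring accessions).
#' @export
simulateStudyCollection <- function(seed, nUnique = 294, nOffspring = 123,
                                    nClones = 21,
                                    stats = publishedPanelStats("16in1")) {
  stopifnot(nOffspring < nUnique, nClones >= 0)
  layout <- sixteenInOnePanel()
  spacing <- ifelse(is.na(layout$motif), 2L, nchar(layout$motif))
  freqs <- lapply(seq_len(nrow(stats)), function(i) {
    j <- match(stats$marker[i], layout$name)
    base <- if (!is.na(j)) layout$size_min[j] else 100L
    step <- if (!is.na(j)) spacing[j] else 2L
    frequenciesFromSummary(stats$k[i], stats$He[i], stats$PIC[i],
                           lengths = base + step * (seq_len(stats$k[i]) - 1))
  })
  names(freqs) <- stats$marker
  nFounders <- nUnique - nOffspring
  pan <- SSRPanel(data.frame(
    name = stats$marker,
    chromosome = layout$chromosome[match(stats$marker, layout$name)],
    position_bp = layout$position_bp[match(stats$marker, layout$name)],
    motif = layout$motif[match(stats$marker, layout$name)],
    dye = layout$dye[match(stats$marker, layout$name)],
    window_min = layout$window_min[match(stats$marker, layout$name)],
    window_max = layout$window_max[match(stats$marker, layout$name)],
    stringsAsFactors = FALSE))
  founders <- simulatePopulation(freqs, nFounders, seed = seed,
                                 prefix = "acc", panel = pan)
  set.seed(seed + 1L)
  pa <- sample(nFounders, nOffspring, replace = TRUE)
  pb <- vapply(pa, function(i) {
    j <- sample(nFounders, 1)
    while (j == i) j <- sample(nFounders, 1)
    j
  }, integer(1))
  offIds <- sprintf("cross%03d", seq_len(nOffspring))
  offs <- vector("list", nOffspring)
  for (i in seq_len(nOffspring))
    offs[[i]] <- simulateCross(founders, pa[i], pb[i], nOffspring = 1,
                               mutationRate = 0, seed = seed + 1L + i,
                               ids = offIds[i])
  a <- do.call(rbind, c(list(founders@alleleA),
                        lapply(offs, function(o) o@alleleA)))
  b <- do.call(rbind, c(list(founders@alleleB),
                        lapply(offs, function(o) o@alleleB)))
  tab <- GenotypeTable(a, b, pan)
  pedigree <- data.frame(child = offIds,
                         parent_a = sampleIds(founders)[pa],
                         parent_b = sampleIds(founders)[pb],
                         stringsAsFactors = FALSE)
  clones <- NULL
  if (nClones > 0) {
    set.seed(seed + 1000L)
    src <- sample(sampleIds(tab), nClones, replace = FALSE)
    clones <- data.frame(source = src,
                         newId = sprintf("syn%03d", seq_len(nClones)),
                         stringsAsFactors = FALSE)
    art <- injectArtifacts(tab, cloneSpec = clones, seed = seed + 1001L)
    tab <- art$table
  }
  list(table = tab, pedigree = pedigree,
       clones = if (is.null(clones))
         data.frame(source = character(), newId = character()) else clones,
       freqs = freqs, founders = sampleIds(founders))
}
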