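#' @import methods
NULL

#' SSRPanel: a set of SSR marker definitions
#'
#' An \code{SSRPanel} holds the marker metadata needed to interpret a
#' fragment-analysis genotype table and to validate a multiplex layout:
#' marker name, chromosome, 1-based position on the reference genome, repeat
#' motif, fluorescent dye channel, and the expected amplicon size window in
#' nucleotides. Any field other than the name may be \code{NA} when unknown
#' (legacy markers often have no reference position).
#'
#' @slot markers data.frame with columns \code{name}, \code{chromosome},
#'   \code{position_bp}, \code{motif}, \code{dye}, \code{window_min},
#'   \code{window_max}.
#' @aliases SSRPanel-class
#' @export
setClass("SSRPanel", representation(markers = "data.frame"))

.panelColumns <- c("name", "chromosome", "position_bp", "motif", "dye",
                   "window_min", "window_max")

setValidity("SSRPanel", function(object) {
  m <- object@markers
  msg <- character()
  if (!all(.panelColumns %in% names(m)))
    msg <- c(msg, paste("markers must contain columns:",
                        paste(.panelColumns, collapse = ", ")))
  else {
    if (anyNA(m$name) || any(!nzchar(m$name)))
      msg <- c(msg, "marker names must be non-empty")
    if (anyDuplicated(m$name))
      msg <- c(msg, "marker names must be unique")
    bad <- !is.na(m$position_bp) & m$position_bp < 1
    if (any(bad)) msg <- c(msg, "position_bp must be >= 1")
    mot <- m$motif[!is.na(m$motif)]
    if (length(mot) && any(!nchar(mot) %in% 2:6))
      msg <- c(msg, "motif length must be 2-6 nt")
    both <- !is.na(m$window_min) & !is.na(m$window_max)
    if (any(m$window_min[both] >= m$window_max[both]))
      msg <- c(msg, "window_min must be < window_max")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeTable: diploid multilocus SSR genotypes
#'
#' A sample-by-marker table of unordered diploid allele-length pairs as scored
#' by fragment analysis. Each call is stored canonically with
#' \code{alleleA <= alleleB}. The allele value \code{0} is the null sentinel
#' (no amplification: a homozygous-null genotype is \code{(0, 0)}), which is
#' distinct from missing data (\code{NA} in both matrices). Row names are
#' sample identifiers and may repeat for biological replicates of the same
#' accession (see \code{\link{consolidateReplicates}}).
#'
#' @slot alleleA integer matrix, the smaller allele length per call.
#' @slot alleleB integer matrix, the larger allele length per call.
#' @slot panel an \code{\linkS4class{SSRPanel}} whose marker names match the
#'   matrix columns.
#' @aliases GenotypeTable-class
#' @export
setClass("GenotypeTable",
         representation(alleleA = "matrix", alleleB = "matrix",
                        panel = "SSRPanel"))

setValidity("GenotypeTable", function(object) {
  a <- object@alleleA; b <- object@alleleB
  msg <- character()
  if (!identical(dim(a), dim(b)))
    return("alleleA and alleleB must have identical dimensions")
  if (!identical(dimnames(a), dimnames(b)))
    return("alleleA and alleleB must have identical dimnames")
  if (is.null(rownames(a)) && nrow(a) > 0)
    msg <- c(msg, "sample identifiers (row names) are required")
  if (!identical(colnames(a), object@panel@markers$name))
    msg <- c(msg, "column names must equal the panel marker names, in order")
  if (!all(is.na(a) == is.na(b)))
    msg <- c(msg, "a call must have both alleles present or both missing")
  ok <- is.na(a) | a <= b
  if (!all(ok)) msg <- c(msg, "calls must be stored with alleleA <= alleleB")
  neg <- !is.na(a) & (a < 0 | b < 0)
  if (any(neg)) msg <- c(msg, "allele lengths must be >= 0 (0 = null)")
  if (length(msg)) msg else TRUE
})
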