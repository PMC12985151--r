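#' Construct a GenotypeTable
#'
#' Builds the canonical diploid genotype container from two allele-length
#' matrices. Calls are stored as unordered pairs: the two matrices are swapped
#' elementwise where needed so that \code{alleleA <= alleleB}. Use \code{NA}
#' in both matrices for missing data and \code{0} for a null
#' (non-amplifying) allele; a homozygous-null call is \code{(0, 0)}.
#'
#' @param alleleA,alleleB numeric matrices (samples x markers) of allele
#'   lengths in nt; row names are sample identifiers (replicates may share a
#'   name), column names must match the panel markers.
#' @param panel an \code{\linkS4class{SSRPanel}}; if omitted, a minimal panel
#'   is derived from the column names.
#' @return a \code{\linkS4class{GenotypeTable}}.
#' @examples
#' a <- matrix(c(246, 100), 1, 2, dimnames = list("Van", c("M1", "M2")))
#' b <- matrix(c(257, 100), 1, 2, dimnames = list("Van", c("M1", "M2")))
#' GenotypeTable(a, b)
#' @export
GenotypeTable <- function(alleleA, alleleB, panel = NULL) {
  alleleA <- as.matrix(alleleA); alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"; storage.mode(alleleB) <- "integer"
  if (is.null(panel)) {
    if (is.null(colnames(alleleA)))
      stop("marker names are required (column names or a panel)")
    panel <- SSRPanel(colnames(alleleA))
  }
  if (is.null(colnames(alleleA))) {
    colnames(alleleA) <- colnames(alleleB) <- markerNames(panel)
  }
  swap <- !is.na(alleleA) & !is.na(alleleB) & alleleA > alleleB
  if (any(swap)) {
    tmp <- alleleA[swap]
    alleleA[swap] <- alleleB[swap]
    alleleB[swap] <- tmp
  }
  new("GenotypeTable", alleleA = alleleA, alleleB = alleleB, panel = panel)
}

#' @rdname GenotypeTable-class
#' @export
setMethod("sampleIds", "GenotypeTable", function(x) rownames(x@alleleA))

#' @rdname GenotypeTable-class
#' @export
setMethod("nSamples", "GenotypeTable", function(x) nrow(x@alleleA))

#' @rdname GenotypeTable-class
#' @export
setMethod("nMarkers", "GenotypeTable", function(x) ncol(x@alleleA))

#' @rdname GenotypeTable-class
#' @export
setMethod("markerNames", "GenotypeTable", function(x) colnames(x@alleleA))

#' @rdname GenotypeTable-class
#' @export
setMethod("panel", "GenotypeTable", function(x) x@panel)

#' Allele matrices of a GenotypeTable
#'
#' @param x a \code{GenotypeTable}.
#' @param which \code{"A"} (smaller allele) or \code{"B"} (larger allele).
#' @return integer matrix of allele lengths.
#' @export
alleleMatrix <- function(x, which = c("A", "B")) {
  stopifnot(is(x, "GenotypeTable"))
  if (match.arg(which) == "A") x@alleleA else x@alleleB
}

setMethod("show", "GenotypeTable", function(object) {
  a <- object@alleleA
  miss <- sum(is.na(a))
  nullhom <- sum(!is.na(a) & a == 0 & object@alleleB == 0)
  cat("GenotypeTable:", nrow(a), "samples x", ncol(a), "markers\n")
  cat("  missing calls:", miss, " homozygous-null calls:", nullhom, "\n")
  cat("  markers:", paste(utils::head(colnames(a), 5), collapse = ", "),
      if (ncol(a) > 5) "..." else "", "\n")
})

setMethod("[", signature("GenotypeTable", "ANY", "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@alleleA))
  if (missing(j)) j <- seq_len(ncol(x@alleleA))
  if (is.character(j)) j <- match(j, colnames(x@alleleA))
  new("GenotypeTable",
      alleleA = x@alleleA[i, j, drop = FALSE],
      alleleB = x@alleleB[i, j, drop = FALSE],
      panel = x@panel[j])
})

.genotypeHeader <- function(markers)
  c("sample", paste0(rep(markers, each = 2), c("_1", "_2")))

#' Read a wide genotype table
#'
#' Parses the fragment-analysis export dialect used throughout the package: a
#' delimited text file whose first column is the sample identifier, followed
#' by two columns per marker named \code{<marker>_1} and \code{<marker>_2}.
#' An empty cell in both columns is missing data; the null token (default
#' \code{"0"}) denotes a null allele, so \code{0,0} is a homozygous-null
#' call. Allele order within a call is irrelevant; calls are canonicalized.
#'
#' @param path file path.
#' @param panel optional \code{SSRPanel}; when given, the file columns must
#'   cover exactly its markers (any unknown marker column is an error).
#' @param sep field separator, \code{","} (default) or \code{"\t"}.
#' @param nullToken token standing for a null allele (default \code{"0"}).
#' @return a \code{\linkS4class{GenotypeTable}}.
#' @export
readGenotypeTable <- function(path, panel = NULL, sep = ",",
                              nullToken = "0") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 1L) stop("empty genotype file")
  cols <- names(df)[-1]
  if (length(cols) %% 2L != 0L)
    stop("odd number of allele columns; two per marker are required")
  base <- sub("_[12]$", "", cols)
  suffix <- sub("^.*_([12])$", "\\1", cols)
  odd <- seq(1, length(cols), by = 2)
  markers <- base[odd]
  if (!all(base[odd + 1] == markers) ||
      !all(suffix[odd] == "1" & suffix[odd + 1] == "2"))
    stop("allele columns must come in adjacent pairs <marker>_1, <marker>_2")
  if (!is.null(panel)) {
    unknown <- setdiff(markers, markerNames(panel))
    if (length(unknown))
      stop("unknown marker column(s): ", paste(unknown, collapse = ", "))
    absent <- setdiff(markerNames(panel), markers)
    if (length(absent))
      stop("panel marker(s) absent from file: ",
           paste(absent, collapse = ", "))
    ord <- match(markerNames(panel), markers)
  } else {
    panel <- SSRPanel(markers)
    ord <- seq_along(markers)
  }
  parseCol <- function(v) {
    v <- trimws(v)
    out <- rep(NA_integer_, length(v))
    isNull <- !is.na(v) & v == nullToken
    out[isNull] <- 0L
    rest <- !is.na(v) & nzchar(v) & !isNull
    num <- suppressWarnings(as.numeric(v[rest]))
    if (anyNA(num) || any(num != round(num)))
      stop("non-integer allele value(s): ",
           paste(unique(v[rest][is.na(num) | num != round(num)]),
                 collapse = ", "))
    out[rest] <- as.integer(num)
    out
  }
  n <- nrow(df)
  m <- length(markers)
  a <- matrix(NA_integer_, n, m)
  b <- matrix(NA_integer_, n, m)
  for (k in seq_len(m)) {
    a[, k] <- parseCol(df[[2 * ord[k]]])
    b[, k] <- parseCol(df[[2 * ord[k] + 1]])
  }
  halfMissing <- xor(is.na(a), is.na(b))
  if (any(halfMissing))
    stop("call(s) with exactly one allele present; ",
         "a call needs both alleles or neither")
  rownames(a) <- rownames(b) <- df[[1]]
  colnames(a) <- colnames(b) <- markerNames(panel)
  GenotypeTable(a, b, panel)
}

#' Write a genotype table
#'
#' Inverse of \code{\link{readGenotypeTable}} (bit-stable round trip):
#' missing calls become empty cells and null alleles the null token.
#'
#' @param x a \code{GenotypeTable}.
#' @param path output file path.
#' @param sep field separator.
#' @param nullToken token written for a null allele.
#' @return the path, invisibly.
#' @export
writeGenotypeTable <- function(x, path, sep = ",", nullToken = "0") {
  stopifnot(is(x, "GenotypeTable"))
  fmt <- function(m) {
    v <- ifelse(is.na(m), "", ifelse(m == 0L, nullToken, as.character(m)))
    matrix(v, nrow(m), ncol(m))
  }
  a <- fmt(x@alleleA); b <- fmt(x@alleleB)
  out <- matrix("", nSamples(x), 1 + 2 * nMarkers(x))
  out[, 1] <- sampleIds(x)
  if (nMarkers(x)) {
    out[, 1 + 2 * seq_len(nMarkers(x)) - 1] <- a
    out[, 1 + 2 * seq_len(nMarkers(x))] <- b
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.genotypeHeader(markerNames(x)), collapse = sep), con)
  if (nrow(out))
    writeLines(apply(out, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Consolidate biological replicates to the prevailing genotype
#'
#' Rows sharing a sample label are treated as replicates of one accession.
#' Per marker, the consensus is the majority ("prevailing") call among
#' non-missing replicate calls; on a tie the call of the earliest replicate
#' in file order wins and the group is flagged unresolved. Conflicting calls
#' are reported, never silently dropped, and the consensus never contains an
#' allele absent from the replicates.
#'
#' @param x a \code{GenotypeTable} (replicates share a row name).
#' @return a list with elements \code{table} (one row per label, file
#'   order of first appearance), \code{groups} (data.frame label, n
#'   replicates, unresolved flag) and \code{conflicts} (data.frame label,
#'   marker, allele_a, allele_b, count, consensus flag).
#' @export
consolidateReplicates <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  ids <- sampleIds(x)
  labels <- unique(ids)
  m <- nMarkers(x)
  a <- matrix(NA_integer_, length(labels), m,
              dimnames = list(labels, markerNames(x)))
  b <- a
  groups <- data.frame(label = labels, n = 0L, unresolved = FALSE,
                       stringsAsFactors = FALSE)
  conflicts <- list()
  for (g in seq_along(labels)) {
    rows <- which(ids == labels[g])
    groups$n[g] <- length(rows)
    for (k in seq_len(m)) {
      ca <- x@alleleA[rows, k]; cb <- x@alleleB[rows, k]
      keep <- !is.na(ca)
      if (!any(keep)) next
      key <- paste(ca[keep], cb[keep])
      tab <- table(key)
      best <- max(tab)
      winners <- names(tab)[tab == best]
      # tie-break: earliest replicate whose call is among the winners
      winner <- key[match(TRUE, key %in% winners)]
      pick <- match(winner, key)
      a[g, k] <- ca[keep][pick]; b[g, k] <- cb[keep][pick]
      if (length(tab) > 1L) {
        if (length(winners) > 1L) groups$unresolved[g] <- TRUE
        parts <- do.call(rbind, strsplit(names(tab), " "))
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          label = labels[g], marker = markerNames(x)[k],
          allele_a = as.integer(parts[, 1]),
          allele_b = as.integer(parts[, 2]),
          count = as.integer(tab),
          consensus = names(tab) == winner,
          stringsAsFactors = FALSE)
      }
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts)
    else data.frame(label = character(), marker = character(),
                    allele_a = integer(), allele_b = integer(),
                    count = integer(), consensus = logical())
  rownames(conflicts) <- NULL
  list(table = GenotypeTable(a, b, panel(x)), groups = groups,
       conflicts = conflicts)
}
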