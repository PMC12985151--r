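#' Construct an SSR marker panel
#'
#' @param name character vector of unique marker names, or a data.frame that
#'   already carries the panel columns (\code{name}, \code{chromosome},
#'   \code{position_bp}, \code{motif}, \code{dye}, \code{window_min},
#'   \code{window_max}); missing columns are filled with \code{NA}.
#' @param chromosome chromosome label per marker (character, coerced).
#' @param position_bp 1-based position on the reference genome, in bp.
#' @param motif repeat-unit string (2-6 nt), e.g. \code{"AG"}.
#' @param dye fluorescent channel label, e.g. \code{"6-FAM"}.
#' @param window_min,window_max expected amplicon size window in nt.
#' @return an \code{\linkS4class{SSRPanel}}.
#' @examples
#' SSRPanel(c("M1", "M2"), chromosome = c("1", "2"))
#' @export
SSRPanel <- function(name, chromosome = NA, position_bp = NA, motif = NA,
                     dye = NA, window_min = NA, window_max = NA) {
  if (is.data.frame(name)) {
    df <- name
    for (col in .panelColumns)
      if (!col %in% names(df)) df[[col]] <- NA
    df <- df[, .panelColumns, drop = FALSE]
  } else {
    df <- data.frame(name = as.character(name),
                     chromosome = as.character(chromosome),
                     position_bp = as.numeric(position_bp),
                     motif = as.character(motif),
                     dye = as.character(dye),
                     window_min = as.numeric(window_min),
                     window_max = as.numeric(window_max),
                     stringsAsFactors = FALSE)
  }
  df$name <- as.character(df$name)
  df$chromosome <- as.character(df$chromosome)
  rownames(df) <- NULL
  new("SSRPanel", markers = df)
}

#' @rdname SSRPanel-class
#' @param object,x an \code{SSRPanel}
#' @export
setMethod("markerNames", "SSRPanel", function(x) x@markers$name)

#' @rdname SSRPanel-class
#' @export
setMethod("nMarkers", "SSRPanel", function(x) nrow(x@markers))

#' Marker metadata of a panel
#'
#' @param x an \code{SSRPanel} or \code{GenotypeTable}.
#' @return data.frame of marker definitions.
#' @export
markerTable <- function(x) {
  if (is(x, "GenotypeTable")) x <- x@panel
  stopifnot(is(x, "SSRPanel"))
  x@markers
}

setMethod("show", "SSRPanel", function(object) {
  m <- object@markers
  cat("SSRPanel with", nrow(m), "markers on",
      length(unique(m$chromosome[!is.na(m$chromosome)])), "chromosome(s)\n")
  if (nrow(m)) {
    shown <- utils::head(m$name, 6)
    cat(" ", paste(shown, collapse = ", "),
        if (nrow(m) > 6) "..." else "", "\n")
  }
})

setMethod("[", signature("SSRPanel", "ANY", "missing"),
          function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@markers$name)
  new("SSRPanel", markers = x@markers[i, , drop = FALSE])
})

#' Read or write a panel definition file
#'
#' The on-disk format is a tab-separated table with columns \code{name},
#' \code{chromosome}, \code{position_bp}, \code{motif}, \code{dye},
#' \code{window_min}, \code{window_max}; empty cells are \code{NA}.
#'
#' @param path file path.
#' @return \code{readPanelFile}: an \code{SSRPanel};
#'   \code{writePanelFile}: the path, invisibly.
#' @export
readPanelFile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(.panelColumns, names(df))
  if (length(missing))
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "))
  SSRPanel(df)
}

#' @rdname readPanelFile
#' @param panel an \code{SSRPanel}.
#' @export
writePanelFile <- function(panel, path) {
  stopifnot(is(panel, "SSRPanel"))
  utils::write.table(panel@markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
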