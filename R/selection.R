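#' Selection criteria for candidate SSR markers
#'
#' Defaults encode the screening rules used for genome-wide SSR candidate
#' tables: at most 2 mapping failures in the cohort, at least 3 alleles, a
#' repeat tract of at most 60 nt (to limit stutter), no allele above
#' frequency 0.5, and motif-length-dependent minimum sequence-based PIC
#' (0.8 for dinucleotide, 0.7 for trinucleotide, 0.6 for longer units).
#'
#' @param maxMapFailures maximum samples whose sequence failed to map.
#' @param minAlleles minimum distinct alleles.
#' @param maxRepeatLength maximum repeat tract length, nt.
#' @param maxAlleleFreq maximum allowed frequency of any single allele.
#' @param picThresholds named numeric: minimum PIC by motif length; names
#'   \code{"2"}, \code{"3"} and \code{"4"} (the last applies to all longer
#'   units).
#' @return list of criteria for \code{\link{filterCandidates}}.
#' @export
selectionCriteria <- function(maxMapFailures = 2, minAlleles = 3,
                              maxRepeatLength = 60, maxAlleleFreq = 0.5,
                              picThresholds = c("2" = 0.8, "3" = 0.7,
                                                "4" = 0.6)) {
  stopifnot(all(picThresholds >= 0), all(picThresholds <= 1))
  list(maxMapFailures = maxMapFailures, minAlleles = minAlleles,
       maxRepeatLength = maxRepeatLength, maxAlleleFreq = maxAlleleFreq,
       picThresholds = picThresholds)
}

.picThreshold <- function(motif, thresholds) {
  len <- pmin(nchar(motif), 4L)
  unname(thresholds[as.character(pmax(len, 2L))])
}

#' Filter candidate SSRs
#'
#' Applies the conjunction of all criteria to a candidate table; a candidate
#' passes iff every criterion holds, and the verdict lists every failed
#' criterion by name. Columns not present in \code{candidates} are not
#' judged (their criteria are skipped), so partially annotated tables can be
#' screened on what is known.
#'
#' @param candidates data.frame with (any of) columns \code{name},
#'   \code{motif}, \code{pic_seq} (sequence-based PIC),
#'   \code{map_failures}, \code{n_alleles}, \code{repeat_length_nt},
#'   \code{max_allele_freq}.
#' @param criteria a list from \code{\link{selectionCriteria}}.
#' @return list with \code{pass} (the passing subset of
#'   \code{candidates}) and \code{verdicts} (data.frame name, pass,
#'   failed: comma-separated failed criteria).
#' @export
filterCandidates <- function(candidates, criteria = selectionCriteria()) {
  stopifnot(is.data.frame(candidates), "name" %in% names(candidates))
  n <- nrow(candidates)
  failed <- vector("list", n)
  addFail <- function(which, label) {
    for (i in which(which)) failed[[i]] <<- c(failed[[i]], label)
  }
  if ("map_failures" %in% names(candidates))
    addFail(candidates$map_failures > criteria$maxMapFailures,
            "map_failures")
  if ("n_alleles" %in% names(candidates))
    addFail(candidates$n_alleles < criteria$minAlleles, "min_alleles")
  if ("repeat_length_nt" %in% names(candidates))
    addFail(candidates$repeat_length_nt > criteria$maxRepeatLength,
            "repeat_length")
  if ("max_allele_freq" %in% names(candidates))
    addFail(candidates$max_allele_freq > criteria$maxAlleleFreq,
            "max_allele_freq")
  if (all(c("motif", "pic_seq") %in% names(candidates)))
    addFail(candidates$pic_seq <
              .picThreshold(candidates$motif, criteria$picThresholds),
            "pic")
  nFailed <- lengths(failed)
  verdicts <- data.frame(
    name = candidates$name, pass = nFailed == 0L,
    failed = vapply(failed, function(f)
      paste(f, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  list(pass = candidates[nFailed == 0L, , drop = FALSE],
       verdicts = verdicts)
}

#' Flag physically close same-chromosome marker pairs
#'
#' Lists every pair of markers on the same chromosome closer than the
#' linkage threshold (default 1 Mbp) on the reference coordinates. Markers
#' without a position are skipped.
#'
#' @param markers an \code{SSRPanel} or a data.frame with columns
#'   \code{name}, \code{chromosome}, \code{position_bp}.
#' @param minDistance minimum tolerated distance in bp.
#' @return data.frame marker_a, marker_b, chromosome, distance_bp for each
#'   violation (zero rows when none).
#' @export
checkLinkageDistance <- function(markers, minDistance = 1e6) {
  if (is(markers, "SSRPanel")) markers <- markers@markers
  m <- markers[!is.na(markers$position_bp) & !is.na(markers$chromosome), ]
  out <- list()
  for (chr in unique(m$chromosome)) {
    sub <- m[m$chromosome == chr, ]
    if (nrow(sub) < 2) next
    cmb <- utils::combn(nrow(sub), 2)
    for (c in seq_len(ncol(cmb))) {
      i <- cmb[1, c]; j <- cmb[2, c]
      d <- abs(sub$position_bp[i] - sub$position_bp[j])
      if (d < minDistance)
        out[[length(out) + 1L]] <- data.frame(
          marker_a = sub$name[i], marker_b = sub$name[j],
          chromosome = chr, distance_bp = d, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(marker_a = character(), marker_b = character(),
                  chromosome = character(), distance_bp = numeric(),
                  stringsAsFactors = FALSE)
}

.windowLabel <- function(w) paste0(w[1], "-", w[2])

#' Validate a multiplex panel layout
#'
#' Checks a dye/size-window assignment for single-reaction fragment
#' analysis: at most one marker per (dye, window) slot, no overlapping
#' expected size ranges within a dye channel (the requirement for
#' unambiguous allele calling), at most two markers per chromosome with
#' same-chromosome pairs at least \code{minDistance} apart (markers lacking
#' a position are skipped by the distance rule), and each marker's expected
#' range inside its nominal window shrunk by \code{guardMargin}. Nominal
#' windows are approximate, so a range excursion beyond its window is a
#' warning rather than a violation as long as ranges within the dye stay
#' disjoint.
#'
#' @param layout data.frame with columns \code{name}, \code{chromosome},
#'   \code{position_bp}, \code{dye}, \code{window_min}, \code{window_max},
#'   \code{size_min}, \code{size_max} (expected amplicon range).
#' @param minDistance linkage threshold in bp.
#' @param guardMargin nt kept clear between a range and its window edge.
#' @param maxPerChromosome maximum markers per chromosome.
#' @return list with \code{ok} (no violations), \code{violations} and
#'   \code{warnings} (character vectors).
#' @export
validatePanelDesign <- function(layout, minDistance = 1e6, guardMargin = 5,
                                maxPerChromosome = 2) {
  need <- c("name", "dye", "window_min", "window_max", "size_min",
            "size_max")
  stopifnot(is.data.frame(layout), all(need %in% names(layout)))
  violations <- character()
  warnings <- character()
  slot <- paste(layout$dye, layout$window_min, layout$window_max)
  dup <- duplicated(slot)
  if (any(dup))
    violations <- c(violations, paste("slot carries several markers:",
                                      unique(slot[dup])))
  for (d in unique(layout$dye)) {
    sub <- layout[layout$dye == d, ]
    if (nrow(sub) < 2) next
    ord <- order(sub$size_min)
    sub <- sub[ord, ]
    for (i in seq_len(nrow(sub) - 1))
      if (sub$size_max[i] >= sub$size_min[i + 1])
        violations <- c(violations, sprintf(
          "overlapping size ranges in dye %s: %s and %s", d,
          sub$name[i], sub$name[i + 1]))
  }
  inWin <- layout$size_min >= layout$window_min + guardMargin &
    layout$size_max <= layout$window_max - guardMargin
  excur <- which(!inWin)
  for (i in excur) {
    over <- max(layout$window_min[i] + guardMargin - layout$size_min[i],
                layout$size_max[i] - (layout$window_max[i] - guardMargin))
    warnings <- c(warnings, sprintf(
      "%s range %g-%g exceeds window %g-%g (guard %g) by %g nt",
      layout$name[i], layout$size_min[i], layout$size_max[i],
      layout$window_min[i], layout$window_max[i], guardMargin, over))
  }
  if ("chromosome" %in% names(layout)) {
    perChr <- table(layout$chromosome[!is.na(layout$chromosome)])
    over <- perChr[perChr > maxPerChromosome]
    if (length(over))
      violations <- c(violations, paste("more than", maxPerChromosome,
                                        "markers on chromosome:",
                                        paste(names(over), collapse = ", ")))
    if ("position_bp" %in% names(layout)) {
      viol <- checkLinkageDistance(layout, minDistance)
      if (nrow(viol))
        violations <- c(violations, sprintf(
          "%s and %s only %g bp apart on chromosome %s",
          viol$marker_a, viol$marker_b, viol$distance_bp,
          viol$chromosome))
    }
  }
  list(ok = length(violations) == 0L, violations = violations,
       warnings = warnings)
}

#' Design a one-reaction multiplex panel
#'
#' Assigns markers to (dye x size-window) slots maximizing total quality
#' under the panel constraints: one marker per slot, the marker's expected
#' size range inside the window (shrunk by the guard margin), at most two
#' markers per chromosome, and same-chromosome pairs at least
#' \code{minDistance} apart. Assignment is greedy in decreasing quality with
#' local repair (a lower-quality marker never displaces a placed one unless
#' a free compatible slot exists for both); fixed pre-assignments (e.g.
#' proven legacy markers) are honored first and the designer fills around
#' them. Infeasible markers are reported with reasons, and an instance
#' without enough feasible slots yields an explicit infeasibility flag.
#'
#' @param markers data.frame with columns \code{name}, \code{chromosome},
#'   \code{position_bp}, \code{size_min}, \code{size_max}, \code{quality}
#'   (e.g. PIC; higher is better).
#' @param dyes character vector of dye labels (default four channels).
#' @param windows numeric matrix with one row per size window and columns
#'   min, max (default the four windows 100-150, 200-250, 300-350,
#'   400-450).
#' @param minDistance linkage threshold in bp.
#' @param guardMargin nt kept clear at window edges.
#' @param maxPerChromosome maximum markers per chromosome.
#' @param fixed optional data.frame like \code{markers} plus columns
#'   \code{dye}, \code{window_min}, \code{window_max}: markers pinned to
#'   slots before optimization.
#' @param nSlotsRequired slots that must be filled for feasibility
#'   (default: all).
#' @return list with \code{layout} (assignment data.frame suitable for
#'   \code{\link{validatePanelDesign}}), \code{unassigned} (data.frame name,
#'   reason), \code{feasible} flag and \code{validation} (the validator's
#'   verdict on the layout).
#' @export
designMultiplex <- function(markers, dyes = c("6-FAM", "VIC", "NED", "PET"),
                            windows = cbind(c(100, 200, 300, 400),
                                            c(150, 250, 350, 450)),
                            minDistance = 1e6, guardMargin = 5,
                            maxPerChromosome = 2, fixed = NULL,
                            nSlotsRequired = NULL) {
  need <- c("name", "chromosome", "size_min", "size_max", "quality")
  stopifnot(is.data.frame(markers), all(need %in% names(markers)))
  if (!"position_bp" %in% names(markers)) markers$position_bp <- NA_real_
  slots <- expand.grid(dyeIdx = seq_along(dyes),
                       winIdx = seq_len(nrow(windows)))
  slots$dye <- dyes[slots$dyeIdx]
  slots$window_min <- windows[slots$winIdx, 1]
  slots$window_max <- windows[slots$winIdx, 2]
  slots$marker <- NA_character_
  layout <- list()
  chrCount <- integer(0)
  placed <- function() do.call(rbind, layout)

  okChromosome <- function(row) {
    chr <- as.character(row$chromosome)
    if (is.na(chr)) return(TRUE)
    cur <- placed()
    if (is.null(cur)) return(TRUE)
    same <- cur[!is.na(cur$chromosome) & cur$chromosome == chr, ,
                drop = FALSE]
    if (!is.null(same) && nrow(same) >= maxPerChromosome) return(FALSE)
    if (!is.null(same) && nrow(same) && !is.na(row$position_bp)) {
      d <- abs(same$position_bp - row$position_bp)
      if (any(!is.na(d) & d < minDistance)) return(FALSE)
    }
    TRUE
  }
  fitsWindow <- function(row, s)
    row$size_min >= slots$window_min[s] + guardMargin &
    row$size_max <= slots$window_max[s] - guardMargin
  place <- function(row, s) {
    slots$marker[s] <<- row$name
    layout[[length(layout) + 1L]] <<- data.frame(
      name = row$name, chromosome = as.character(row$chromosome),
      position_bp = row$position_bp, dye = slots$dye[s],
      window_min = slots$window_min[s], window_max = slots$window_max[s],
      size_min = row$size_min, size_max = row$size_max,
      quality = row$quality, stringsAsFactors = FALSE)
  }

  if (!is.null(fixed)) {
    for (r in seq_len(nrow(fixed))) {
      row <- fixed[r, ]
      s <- which(slots$dye == row$dye & slots$window_min == row$window_min &
                 slots$window_max == row$window_max)
      if (!length(s) || !is.na(slots$marker[s]))
        stop("fixed marker ", row$name, " pinned to an unknown or taken slot")
      if (!"quality" %in% names(row) || is.na(row$quality)) row$quality <- NA
      place(row, s)
    }
  }

  pool <- markers[!markers$name %in% slots$marker, , drop = FALSE]
  pool <- pool[order(-pool$quality), , drop = FALSE]
  unassigned <- list()
  for (r in seq_len(nrow(pool))) {
    row <- pool[r, ]
    if (!okChromosome(row)) {
      unassigned[[length(unassigned) + 1L]] <- data.frame(
        name = row$name,
        reason = "chromosome occupancy or linkage-distance constraint",
        stringsAsFactors = FALSE)
      next
    }
    free <- which(is.na(slots$marker))
    fit <- free[vapply(free, function(s) fitsWindow(row, s), logical(1))]
    if (length(fit)) {
      # prefer the tightest feasible window to keep options open
      waste <- slots$window_max[fit] - slots$window_min[fit] -
        (row$size_max - row$size_min)
      place(row, fit[which.min(waste)])
    } else {
      unassigned[[length(unassigned) + 1L]] <- data.frame(
        name = row$name, reason = "no free compatible (dye, window) slot",
        stringsAsFactors = FALSE)
    }
  }
  layoutDf <- placed()
  if (is.null(layoutDf))
    layoutDf <- data.frame(name = character(), chromosome = character(),
                           position_bp = numeric(), dye = character(),
                           window_min = numeric(), window_max = numeric(),
                           size_min = numeric(), size_max = numeric(),
                           quality = numeric(), stringsAsFactors = FALSE)
  unassigned <- if (length(unassigned)) do.call(rbind, unassigned)
    else data.frame(name = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (is.null(nSlotsRequired)) nSlotsRequired <- nrow(slots)
  feasible <- nrow(layoutDf) >= min(nSlotsRequired,
                                    nrow(markers) +
                                      if (is.null(fixed)) 0 else nrow(fixed))
  list(layout = layoutDf, unassigned = unassigned, feasible = feasible,
       validation = validatePanelDesign(layoutDf, minDistance = minDistance,
                                        guardMargin = guardMargin,
                                        maxPerChromosome = maxPerChromosome))
}
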