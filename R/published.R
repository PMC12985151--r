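# Printed reference data for the sweet-cherry one-reaction SSR assay:
# the 30 genome-derived candidate markers, the published 16-marker
# multiplex layout, and the per-marker statistics reported for the
# 294-genotype collection under both the new panel and the legacy ECPGR
# panel. These tables are inputs for validation and reconstruction; the
# legacy markers' positions and size ranges were not published, so their
# entries are NA / nominal.

#' Published candidate SSR markers
#'
#' The 30 genome-derived sweet-cherry candidate markers: reference
#' coordinates on the 'Tieton' v2.0 genome, repeat motif, sequence-based
#' PIC from whole-genome calling (\code{pic_seq}), and the
#' fragment-analysis statistics observed on the 49-cultivar screening
#' cohort (k, Ho, He, length-based PIC, Ae, allele-length extremes).
#' \code{in_panel} marks the 12 that entered the published one-reaction
#' panel; \code{note} records why the others were left out.
#'
#' @return data.frame, one row per candidate.
#' @export
publishedCandidates <- function() {
  name <- c("Pav_chr1_028", "Pav_chr1_073", "Pav_chr2_274", "Pav_chr2_995",
            "Pav_chr3_002", "Pav_chr3_706", "Pav_chr3_765", "Pav_chr4_217",
            "Pav_chr4_499", "Pav_chr5_059", "Pav_chr5_144", "Pav_chr5_198",
            "Pav_chr5_903", "Pav_chr6_178", "Pav_chr6_363", "Pav_chr6_387",
            "Pav_chr6_418", "Pav_chr6_505", "Pav_chr6_641", "Pav_chr6_989",
            "Pav_chr7_259", "Pav_chr7_286", "Pav_chr7_444", "Pav_chr7_737",
            "Pav_chr7_798", "Pav_chr7_863", "Pav_chr7_867", "Pav_chr7_906",
            "Pav_chr8_224", "Pav_chr8_438")
  chromosome <- c("1", "1", "2", "2", "3", "3", "3", "4", "4", "5", "5",
                  "5", "5", "6", "6", "6", "6", "6", "6", "6", "7", "7",
                  "7", "7", "7", "7", "7", "7", "8", "8")
  position_bp <- c(56439028, 52114073, 44310274, 44515995, 24943002,
                   21366706, 5316765, 3209217, 275499, 16156059, 32811144,
                   16788198, 32741903, 10235178, 37421363, 25964387,
                   29689418, 3361505, 25614641, 35139989, 23664259,
                   13399286, 19590444, 29755737, 12815798, 28148863,
                   23682867, 6627906, 29212224, 25182438)
  motif <- c("AAT", "AT", "CT", "AG", "CT", "AG", "TAT", "GT", "TCTAGT",
             "AT", "CT", "TTGC", "AG", "AG", "AGA", "AG", "AGTT", "AG",
             "ATT", "AG", "CT", "AT", "CT", "AAAG", "AG", "ATAA", "CT",
             "ATGT", "AAT", "CT")
  pic_seq <- c(0.721, 0.829, 0.833, 0.855, 0.902, 0.835, 0.711, 0.810,
               0.734, 0.853, 0.856, 0.640, 0.846, 0.825, 0.749, 0.830,
               0.691, 0.829, 0.812, 0.854, 0.832, 0.825, 0.821, 0.786,
               0.850, 0.648, 0.846, 0.666, 0.762, 0.836)
  k <- c(4, 8, 7, 8, 11, 10, 7, 5, 4, 11, 9, 3, 8, 7, 7, 7, 5, 7, 9, 6,
         8, 9, 6, 8, 8, 3, 9, 3, 10, 8)
  Ho <- c(0.796, 0.776, 0.878, 0.898, 0.898, 0.918, 0.735, 0.898, 0.755,
          0.816, 0.796, 0.755, 0.837, 0.878, 0.816, 0.837, 0.816, 0.857,
          0.915, 0.857, 0.878, 0.851, 0.714, 0.837, 0.837, 0.571, 0.878,
          0.735, 0.796, 0.776)
  He <- c(0.736, 0.807, 0.837, 0.790, 0.850, 0.827, 0.736, 0.747, 0.712,
          0.846, 0.826, 0.712, 0.830, 0.820, 0.760, 0.763, 0.711, 0.798,
          0.798, 0.720, 0.828, 0.826, 0.713, 0.771, 0.831, 0.608, 0.838,
          0.661, 0.790, 0.831)
  PIC <- c(0.686, 0.780, 0.816, 0.762, 0.833, 0.804, 0.696, 0.709, 0.657,
           0.828, 0.804, 0.657, 0.808, 0.797, 0.724, 0.728, 0.655, 0.769,
           0.769, 0.682, 0.806, 0.805, 0.671, 0.741, 0.809, 0.540, 0.818,
           0.587, 0.763, 0.808)
  Ae <- c(3.784, 5.175, 6.125, 4.754, 6.651, 5.772, 3.790, 3.952, 3.477,
          6.507, 5.744, 3.477, 5.892, 5.545, 4.168, 4.227, 3.460, 4.951,
          4.953, 3.570, 5.828, 5.753, 3.480, 4.361, 5.928, 2.553, 6.180,
          2.953, 4.759, 5.907)
  size_min <- c(209, 115, 415, 124, 300, 221, 235, 406, 227, 215, 332,
                395, 290, 104, 121, 127, 177, 304, 410, 250, 112, 132,
                417, 89, 308, 187, 423, 279, 197, 386)
  size_max <- c(221, 133, 438, 167, 324, 247, 264, 433, 245, 243, 362,
                425, 312, 126, 141, 155, 208, 323, 465, 281, 128, 152,
                455, 117, 330, 195, 460, 292, 255, 416)
  in_panel <- name %in% c("Pav_chr1_073", "Pav_chr2_274", "Pav_chr3_002",
                          "Pav_chr3_706", "Pav_chr4_217", "Pav_chr4_499",
                          "Pav_chr5_144", "Pav_chr6_178", "Pav_chr6_505",
                          "Pav_chr7_798", "Pav_chr7_867", "Pav_chr8_438")
  note <- rep("", 30)
  note[name %in% c("Pav_chr1_028", "Pav_chr5_059", "Pav_chr6_641",
                   "Pav_chr7_286", "Pav_chr8_224")] <- "multiplex-failure"
  note[name %in% c("Pav_chr2_995", "Pav_chr5_903")] <- "close-proximity"
  note[name %in% c("Pav_chr5_198", "Pav_chr6_989", "Pav_chr7_259",
                   "Pav_chr7_737")] <- "lower-diversity"
  data.frame(name, chromosome, position_bp, motif, pic_seq, k, Ho, He,
             PIC, Ae, size_min, size_max, in_panel, note,
             stringsAsFactors = FALSE)
}

#' The published one-reaction 16-marker panel layout
#'
#' Dye and size-window assignment of the published 16-marker single-PCR
#' sweet-cherry panel: 12 genome-derived markers (coordinates and observed
#' size ranges as printed) plus 4 legacy markers (EMPA005, UCD-CH11,
#' BPPCT037, CPPCT006) whose reference positions were not published
#' (\code{position_bp = NA}) and whose expected ranges are set to their
#' nominal windows. Channel membership follows the published
#' fragment-analysis trace; nominal windows are 100-150, 200-250, 300-350
#' and 400-450 nt per dye.
#'
#' @return data.frame suitable for \code{\link{validatePanelDesign}}, with
#'   columns \code{name}, \code{chromosome}, \code{position_bp},
#'   \code{motif}, \code{dye}, \code{window_min}, \code{window_max},
#'   \code{size_min}, \code{size_max}, \code{legacy}.
#' @export
sixteenInOnePanel <- function() {
  cand <- publishedCandidates()
  rows <- list(
    list("BPPCT037",     "5", NA,  "6-FAM", 100, 150, NA, NA, TRUE),
    list("EMPA005",      "1", NA,  "6-FAM", 200, 250, NA, NA, TRUE),
    list("Pav_chr6_505", "6", NA,  "6-FAM", 300, 350, NA, NA, FALSE),
    list("Pav_chr4_217", "4", NA,  "6-FAM", 400, 450, NA, NA, FALSE),
    list("Pav_chr1_073", "1", NA,  "VIC",   100, 150, NA, NA, FALSE),
    list("Pav_chr3_706", "3", NA,  "VIC",   200, 250, NA, NA, FALSE),
    list("Pav_chr5_144", "5", NA,  "VIC",   300, 350, NA, NA, FALSE),
    list("Pav_chr2_274", "2", NA,  "VIC",   400, 450, NA, NA, FALSE),
    list("UCD-CH11",     "2", NA,  "NED",   100, 150, NA, NA, TRUE),
    list("Pav_chr4_499", "4", NA,  "NED",   200, 250, NA, NA, FALSE),
    list("Pav_chr3_002", "3", NA,  "NED",   300, 350, NA, NA, FALSE),
    list("Pav_chr8_438", "8", NA,  "NED",   400, 450, NA, NA, FALSE),
    list("Pav_chr6_178", "6", NA,  "PET",   100, 150, NA, NA, FALSE),
    list("CPPCT006",     "8", NA,  "PET",   200, 250, NA, NA, TRUE),
    list("Pav_chr7_798", "7", NA,  "PET",   300, 350, NA, NA, FALSE),
    list("Pav_chr7_867", "7", NA,  "PET",   400, 450, NA, NA, FALSE))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], chromosome = r[[2]], position_bp = r[[3]],
               dye = r[[4]], window_min = r[[5]], window_max = r[[6]],
               size_min = r[[7]], size_max = r[[8]], legacy = r[[9]],
               stringsAsFactors = FALSE)))
  idx <- match(df$name, cand$name)
  known <- !is.na(idx)
  df$position_bp[known] <- cand$position_bp[idx[known]]
  df$motif <- NA_character_
  df$motif[known] <- cand$motif[idx[known]]
  df$size_min[known] <- cand$size_min[idx[known]]
  df$size_max[known] <- cand$size_max[idx[known]]
  # legacy markers: nominal window as expected range (unpublished)
  df$size_min[!known] <- df$window_min[!known]
  df$size_max[!known] <- df$window_max[!known]
  df[, c("name", "chromosome", "position_bp", "motif", "dye",
         "window_min", "window_max", "size_min", "size_max", "legacy")]
}

#' Published per-marker statistics of the 294-genotype collection
#'
#' The per-marker allele counts and diversity statistics reported for the
#' 294 unique genotypes under the new 16-marker panel (\code{"16in1"}) and
#' under the legacy ECPGR 16-marker recommendation (\code{"ecpgr"}).
#' k is the allele count; Ho/He observed/expected heterozygosity; PIC the
#' polymorphic information content; Ae the effective allele number.
#'
#' @param set \code{"16in1"} or \code{"ecpgr"}.
#' @return data.frame with columns \code{marker}, \code{k}, \code{Ho},
#'   \code{He}, \code{PIC}, \code{Ae}.
#' @export
publishedPanelStats <- function(set = c("16in1", "ecpgr")) {
  set <- match.arg(set)
  if (set == "16in1") {
    data.frame(
      marker = c("BPPCT037", "EMPA005", "Pav_chr4_217", "Pav_chr6_505",
                 "Pav_chr1_073", "Pav_chr3_706", "Pav_chr5_144",
                 "Pav_chr2_274", "UCD-CH11", "Pav_chr4_499",
                 "Pav_chr3_002", "Pav_chr8_438", "Pav_chr6_178",
                 "CPPCT006", "Pav_chr7_798", "Pav_chr7_867"),
      k = c(11, 10, 5, 9, 11, 13, 10, 11, 11, 4, 13, 9, 10, 9, 12, 10),
      Ho = c(0.867, 0.633, 0.759, 0.786, 0.827, 0.884, 0.891, 0.837,
             0.810, 0.776, 0.867, 0.857, 0.816, 0.748, 0.847, 0.898),
      He = c(0.804, 0.647, 0.702, 0.806, 0.825, 0.824, 0.845, 0.823,
             0.799, 0.735, 0.862, 0.825, 0.829, 0.718, 0.842, 0.841),
      PIC = c(0.775, 0.606, 0.662, 0.779, 0.802, 0.802, 0.826, 0.799,
              0.769, 0.685, 0.846, 0.802, 0.806, 0.676, 0.822, 0.821),
      Ae = c(5.101, 2.832, 3.352, 5.160, 5.705, 5.677, 6.457, 5.642,
             4.980, 3.770, 7.223, 5.724, 5.850, 3.550, 6.323, 6.291),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      marker = c("EMPaS12", "EMPA003", "EMPaS02", "EMPA017", "EMPaS10",
                 "EMPaS14", "UDP98-412", "EMPaS06", "UDP98-410",
                 "EMPaS01", "UDP98-411", "EMPA026", "EMPA002",
                 "CPPCT006", "BPPCT037", "CPPCT022"),
      k = c(7, 4, 8, 7, 14, 5, 8, 10, 8, 8, 7, 3, 4, 10, 12, 11),
      Ho = c(0.765, 0.466, 0.701, 0.245, 0.588, 0.663, 0.643, 0.860,
             0.527, 0.674, 0.762, 0.609, 0.609, 0.748, 0.867, 0.704),
      He = c(0.754, 0.436, 0.679, 0.248, 0.598, 0.577, 0.623, 0.828,
             0.525, 0.654, 0.708, 0.581, 0.493, 0.718, 0.804, 0.650),
      PIC = c(0.713, 0.342, 0.650, 0.235, 0.562, 0.491, 0.595, 0.806,
              0.476, 0.592, 0.666, 0.491, 0.373, 0.676, 0.775, 0.587),
      Ae = c(4.068, 1.773, 3.118, 1.329, 2.488, 2.367, 2.656, 5.813,
             2.104, 2.891, 3.419, 2.387, 1.971, 3.550, 5.101, 2.856),
      stringsAsFactors = FALSE)
  }
}

#' Recompute panel-level identity statistics from published summaries
#'
#' For each marker of a published statistics table, reconstructs an
#' allele-frequency spectrum matching the printed (k, He, PIC) via
#' \code{\link{frequenciesFromSummary}} and evaluates the per-locus
#' probability of identity with \code{\link{probabilityIdentity}}; the
#' panel-level \eqn{PI_t} is the product over markers. He and PIC fix the
#' second and fourth frequency moments, so the reconstructed PI is exact up
#' to the rounding of the printed values.
#'
#' @param stats data.frame as from \code{\link{publishedPanelStats}}.
#' @return list with \code{perMarker} (marker, PI, freqs in a list column
#'   dropped: marker and PI only), \code{PIt}, \code{avgPIC}, \code{avgK}.
#' @export
panelIdentityFromSummary <- function(stats) {
  stopifnot(all(c("marker", "k", "He", "PIC") %in% names(stats)))
  PI <- vapply(seq_len(nrow(stats)), function(i) {
    p <- frequenciesFromSummary(stats$k[i], stats$He[i], stats$PIC[i])
    probabilityIdentity(p)
  }, numeric(1))
  list(perMarker = data.frame(marker = stats$marker, PI = PI,
                              stringsAsFactors = FALSE),
       PIt = prod(PI),
       avgPIC = mean(stats$PIC),
       avgK = mean(stats$k))
}
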