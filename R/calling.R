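# Fragment sizing and germline allele calling. Raw migration positions
# are mapped to bp against the co-electrophoresed size standard, bp sizes
# are converted to integer repeat units, and the two germline alleles are
# called from the repeat-space profile: the modal (highest) peak anchors
# allele one, and the second allele is the tallest peak not attributable
# to stutter (left window) or expansion mosaicism (right side).

#' Calibrate raw peak positions against a size standard
#'
#' After dropping ladder peaks below `min_height`, the remaining ladder
#' peaks must match the standard's fragments one-to-one; the calibration
#' is the monotone piecewise-linear map through those (raw, bp) knots,
#' extended linearly beyond the terminal knots using the end-segment
#' slopes.
#'
#' @param ladder_peaks Data.frame with `position` and `height` for the
#'   ladder rows of one sample.
#' @param standard A [size_standard()].
#' @param min_height Ladder peaks below this height are ignored.
#' @return Object of class `"calibration"` with a `knots` data.frame
#'   (`raw`, `bp`).
#' @seealso [map_to_bp()]
#' @export
calibrate <- function(ladder_peaks, standard = size_standard(),
                      min_height = 50) {
  stopifnot(is.data.frame(ladder_peaks), inherits(standard, "size_standard"))
  pk <- ladder_peaks[ladder_peaks$height >= min_height, , drop = FALSE]
  pk <- pk[order(pk$position), , drop = FALSE]
  frag <- standard$fragment_sizes
  if (nrow(pk) != length(frag)) {
    stop_httcag("calibration error: %d ladder peaks vs %d standard fragments",
                nrow(pk), length(frag))
  }
  if (any(diff(pk$position) <= 0)) {
    stop_httcag("ladder peak positions are not strictly increasing")
  }
  structure(list(knots = data.frame(raw = pk$position, bp = frag),
                 standard = standard$name),
            class = "calibration")
}

#' Apply a calibration: raw position to bp
#'
#' Piecewise-linear interpolation through the calibration knots; outside
#' the knot range the terminal segment slopes are extended (linear, not
#' constant, extrapolation).
#'
#' @param calibration A [calibrate()] result.
#' @param position Numeric raw positions.
#' @return Numeric bp sizes.
#' @export
map_to_bp <- function(calibration, position) {
  stopifnot(inherits(calibration, "calibration"))
  r <- calibration$knots$raw
  b <- calibration$knots$bp
  y <- stats::approx(r, b, xout = position, rule = 1)$y
  k <- length(r)
  lo <- !is.na(position) & position < r[1L]
  hi <- !is.na(position) & position > r[k]
  if (any(lo)) {
    y[lo] <- b[1L] + (b[2L] - b[1L]) / (r[2L] - r[1L]) * (position[lo] - r[1L])
  }
  if (any(hi)) {
    y[hi] <- b[k] + (b[k] - b[k - 1L]) / (r[k] - r[k - 1L]) *
      (position[hi] - r[k])
  }
  y
}

#' Convert a fragment size in bp to an integer CAG repeat count
#'
#' `round((size_bp - flank_bp) / 3)` with R's default ties-to-even
#' rounding; the integer conversion mirrors diagnostic reporting, which
#' states whole repeat units.
#'
#' @param size_bp Numeric bp size(s), each strictly greater than
#'   `flank_bp`.
#' @param flank_bp Non-repeat amplicon length in bp.
#' @return Integer repeat count(s).
#' @examples
#' bp_to_repeat(105, 54)  # 17
#' bp_to_repeat(106, 54)  # 17 (17.33 rounds down)
#' @export
bp_to_repeat <- function(size_bp, flank_bp) {
  stopifnot(flank_bp > 0)
  if (any(size_bp <= flank_bp)) {
    stop_httcag("fragment size (%.1f bp) at or below flank length (%.1f bp)",
                min(size_bp), flank_bp)
  }
  as.integer(round((size_bp - flank_bp) / 3))
}

#' Call the two germline CAG alleles from a repeat-space peak table
#'
#' Allele one is the modal (highest) peak; a height tie resolves to the
#' larger repeat and is flagged. Candidate peaks are masked as stutter
#' when they lie within `stutter_depth` repeats left of the modal allele
#' with height below `stutter_cut` times the modal height, and as
#' expansion mosaicism when they lie right of the modal allele with
#' height below `expansion_cut` times the modal height. Allele two is the
#' tallest unmasked peak; if none survives, the call is homozygous (both
#' alleles equal to the modal repeat) with a flag, since a true
#' homozygote cannot be distinguished from single-allele dropout at the
#' peak level. QC flags also record masked peaks close to their masking
#' threshold and second alleles close enough to the modal allele that
#' they could be tall stutter.
#'
#' @param peaks Data.frame with integer `position` (repeat units) and
#'   positive `height` for one sample; optional `sample_id`.
#' @param stutter_cut,expansion_cut Relative height cuts (defaults 0.5).
#' @param stutter_depth Stutter window in repeats (default 3).
#' @param sample_id Overrides the sample id recorded in the call.
#' @return One-row data.frame: `sample_id`, `allele_a`, `allele_b`,
#'   `modal_repeat`, `zygosity` (`"het"`/`"hom"`), `qc_flags`
#'   (semicolon-joined, `""` when clean).
#' @examples
#' call_alleles(data.frame(position = c(17, 20), height = c(980, 1000)))
#' @export
call_alleles <- function(peaks, stutter_cut = 0.5, expansion_cut = 0.5,
                         stutter_depth = 3L, sample_id = NULL) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) stop_httcag("empty peak table: nothing to call")
  stopifnot(all(peaks$height > 0))
  sid <- sample_id %||% (if ("sample_id" %in% names(peaks))
    peaks$sample_id[1L] else NA_character_)
  pos <- as.integer(round(peaks$position))
  h <- as.numeric(peaks$height)
  flags <- character(0)

  hmax <- max(h)
  modal_cand <- pos[h == hmax]
  modal <- max(modal_cand)
  if (length(modal_cand) > 1L) flags <- c(flags, "modal-height-tie")
  h1 <- hmax

  other <- which(pos != modal)
  ratio <- h / h1
  in_stutter_win <- pos >= modal - stutter_depth & pos < modal
  stutter_masked <- in_stutter_win & ratio < stutter_cut
  expansion_masked <- pos > modal & ratio < expansion_cut
  masked <- stutter_masked | expansion_masked
  # flag masked peaks sitting just under their cut (possible true allele)
  near <- masked & ((stutter_masked & ratio >= 0.8 * stutter_cut) |
                    (expansion_masked & ratio >= 0.8 * expansion_cut))
  if (any(near)) {
    flags <- c(flags, sprintf("masked-peak-near-threshold@%d", pos[near]))
  }

  cand <- setdiff(which(!masked), which(pos == modal))
  if (length(cand) > 0L) {
    best <- max(h[cand])
    a2 <- max(pos[cand][h[cand] == best])
    zyg <- "het"
    # a second allele inside the stutter window that is not far above the
    # cut could itself be tall stutter
    if (a2 < modal && a2 >= modal - stutter_depth &&
        best / h1 < stutter_cut + 0.2) {
      flags <- c(flags, "adjacent-allele-ambiguity")
    }
  } else {
    a2 <- modal
    zyg <- "hom"
    flags <- c(flags, "homozygous-or-dropout")
  }

  data.frame(
    sample_id = sid,
    allele_a = min(modal, a2),
    allele_b = max(modal, a2),
    modal_repeat = modal,
    zygosity = zyg,
    qc_flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Convert a cohort peak table to repeat space
#'
#' For each sample, raw positions are calibrated to bp against the
#' sample's own ladder rows (suffix `".ladder"`); bp positions are used
#' as-is. Sizes are then converted with [bp_to_repeat()] and heights of
#' peaks falling in the same repeat bin are summed.
#'
#' @param peaks Cohort peak table (as from [simulate_cohort_traces()] or
#'   [read_peaks()]).
#' @param standard A [size_standard()] (for raw-space input).
#' @param flank_bp Non-repeat amplicon length in bp.
#' @return Repeat-space peak table: `sample_id`, `space = "repeat"`,
#'   `position`, `height`.
#' @export
convert_cohort_peaks <- function(peaks, standard = size_standard(),
                                 flank_bp = flank_profiles()[["bochum"]]) {
  stopifnot(is.data.frame(peaks))
  is_ladder <- grepl("\\.ladder$", peaks$sample_id)
  samples <- unique(peaks$sample_id[!is_ladder])
  parts <- lapply(samples, function(sid) {
    pk <- peaks[peaks$sample_id == sid, , drop = FALSE]
    space <- pk$space[1L]
    if (space == "repeat") {
      rep_pos <- as.integer(round(pk$position))
    } else {
      bp <- pk$position
      if (space == "raw") {
        lad <- peaks[peaks$sample_id == paste0(sid, ".ladder"), , drop = FALSE]
        if (nrow(lad) == 0L) {
          stop_httcag("sample '%s': raw-space peaks but no ladder rows", sid)
        }
        cal <- calibrate(lad, standard)
        bp <- map_to_bp(cal, bp)
      }
      rep_pos <- bp_to_repeat(bp, flank_bp)
    }
    hh <- tapply(pk$height, rep_pos, sum)
    data.frame(sample_id = sid, space = "repeat",
               position = as.integer(names(hh)), height = as.numeric(hh),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Call germline alleles for every sample in a cohort peak table
#'
#' Converts to repeat space (see [convert_cohort_peaks()]) when needed,
#' then applies [call_alleles()] per sample.
#'
#' @inheritParams convert_cohort_peaks
#' @inheritParams call_alleles
#' @return Data.frame of per-sample calls.
#' @export
call_cohort <- function(peaks, standard = size_standard(),
                        flank_bp = flank_profiles()[["bochum"]],
                        stutter_cut = 0.5, expansion_cut = 0.5,
                        stutter_depth = 3L) {
  rs <- if (all(peaks$space == "repeat")) peaks else
    convert_cohort_peaks(peaks, standard, flank_bp)
  samples <- unique(rs$sample_id)
  out <- do.call(rbind, lapply(samples, function(sid) {
    call_alleles(rs[rs$sample_id == sid, , drop = FALSE],
                 stutter_cut = stutter_cut, expansion_cut = expansion_cut,
                 stutter_depth = stutter_depth)
  }))
  rownames(out) <- NULL
  out
}
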