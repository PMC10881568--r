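# Peak-level electropherogram simulation. Simulation starts at the peak
# table (GeneMapper-export level), not at raw fluorescence: stutter
# appears left of each allele with geometric decay, somatic expansion
# peaks appear to the right, heights in the same repeat bin superpose
# additively, and an internal size-standard ladder is co-emitted for
# calibration.

#' Named flank-length profiles for the CAG amplicon
#'
#' Total non-repeat amplicon length in bp depends on the primer set; two
#' named profiles stand in for the two assays the package emulates. The
#' published amplicon offsets are not fixed constants here: both values
#' are configuration, not biology.
#' @return Named numeric vector of flank lengths in bp.
#' @export
flank_profiles <- function() c(bochum = 54, lund = 79)

#' Capillary-electrophoresis size standard
#'
#' @param name Standard name.
#' @param fragment_sizes Strictly increasing bp sizes, at least 4. The
#'   default mirrors a GeneScan-500-style ladder.
#' @return Object of class `"size_standard"`.
#' @export
size_standard <- function(name = "GS500",
                          fragment_sizes = c(35, 50, 75, 100, 139, 150,
                                             160, 200, 250, 300, 340,
                                             350, 400, 450, 490, 500)) {
  stopifnot(is.character(name), length(fragment_sizes) >= 4L)
  if (any(diff(fragment_sizes) <= 0)) {
    stop_httcag("size standard fragments must be strictly increasing")
  }
  structure(list(name = name, fragment_sizes = as.numeric(fragment_sizes)),
            class = "size_standard")
}

#' Simulation parameters for synthetic peak profiles
#'
#' @param stutter_ratio Per-repeat geometric decay of minus-strand PCR
#'   stutter peaks, in `[0, 1)`. A stutter peak k repeats left of an
#'   allele has height `main_height * stutter_ratio^k`.
#' @param stutter_depth Maximum number of stutter positions (default 3).
#' @param expansion_ratio Per-repeat geometric decay of somatic expansion
#'   peaks right of each allele, in `[0, 1)`.
#' @param expansion_load Height of the +1 expansion peak relative to its
#'   allele peak (>= 0). The +k peak has height
#'   `main_height * expansion_load * expansion_ratio^(k-1)`; the series
#'   is truncated when it drops below 1 height unit.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian
#'   height noise (applied per peak, then clipped to `(0, saturation]`;
#'   peaks pushed to zero or below are dropped).
#' @param main_height Nominal height of one allele's main peak. Equal
#'   alleles superpose to twice this height.
#' @param flank_bp Total non-repeat amplicon length in bp; default taken
#'   from `profile` via [flank_profiles()].
#' @param profile Name of a flank profile, used when `flank_bp` is NULL.
#' @param saturation Maximum reportable height (detector saturation).
#' @param ladder_height Height given to size-standard ladder peaks
#'   (noise-free).
#' @param raw_slope,raw_offset Affine map applied when emitting peaks in
#'   `"raw"` migration units: `raw = raw_slope * bp + raw_offset`.
#' @return Object of class `"trace_params"`.
#' @export
trace_params <- function(stutter_ratio = 0.3, stutter_depth = 3L,
                         expansion_ratio = 0.45, expansion_load = 0.25,
                         noise_sd = 15, main_height = 1000,
                         flank_bp = NULL, profile = "bochum",
                         saturation = 32000, ladder_height = 800,
                         raw_slope = 1, raw_offset = 0) {
  if (is.null(flank_bp)) {
    profs <- flank_profiles()
    if (!profile %in% names(profs)) {
      stop_httcag("unknown flank profile '%s' (have: %s)", profile,
                  paste(names(profs), collapse = ", "))
    }
    flank_bp <- profs[[profile]]
  }
  stopifnot(stutter_ratio >= 0, stutter_ratio < 1,
            expansion_ratio >= 0, expansion_ratio < 1,
            expansion_load >= 0, noise_sd >= 0,
            main_height > 0, flank_bp > 0, saturation > 0,
            is_count(stutter_depth), raw_slope > 0)
  structure(
    list(stutter_ratio = stutter_ratio,
         stutter_depth = as.integer(stutter_depth),
         expansion_ratio = expansion_ratio,
         expansion_load = expansion_load,
         noise_sd = noise_sd, main_height = main_height,
         flank_bp = flank_bp, saturation = saturation,
         ladder_height = ladder_height,
         raw_slope = raw_slope, raw_offset = raw_offset),
    class = "trace_params"
  )
}

#' Convert a CAG repeat count to a fragment size in bp
#'
#' `bp = flank_bp + 3 * cag`. Inverse of [bp_to_repeat()] on exact sizes.
#'
#' @param cag Integer CAG count(s), >= 1.
#' @param flank_bp Non-repeat amplicon length in bp.
#' @return Numeric bp size(s).
#' @examples
#' repeat_to_bp(17, flank_bp = 54)  # 105
#' @export
repeat_to_bp <- function(cag, flank_bp) {
  if (any(cag < 1) || any(cag != round(cag))) {
    stop_httcag("CAG counts must be integers >= 1")
  }
  stopifnot(flank_bp > 0)
  flank_bp + 3 * cag
}

#' Simulate one sample's fragment-analysis peak table
#'
#' Builds the repeat-space height profile of a biallelic genotype: one
#' main peak per distinct allele (heights summed if the alleles are
#' equal), geometric stutter at -1..-`stutter_depth` repeats, geometric
#' somatic expansion peaks at +1, +2, ... (truncated below 1 height
#' unit), additive Gaussian height noise, and clipping to
#' `(0, saturation]`. Artifacts landing in the same repeat bin are merged
#' by height addition. Peaks can be emitted in repeat units, in bp
#' (`flank_bp + 3 * repeat`), or in raw migration units (an affine map of
#' bp); in bp/raw space a size-standard ladder is appended as rows with
#' sample id suffix `".ladder"`.
#'
#' @param genotype List or one-row data.frame with `sample_id`,
#'   `allele_a`, `allele_b`.
#' @param params A [trace_params()].
#' @param space One of `"bp"`, `"repeat"`, `"raw"`.
#' @param standard A [size_standard()] to co-emit as ladder rows, or
#'   `NULL` for no ladder (required `NULL` for `"repeat"` space).
#' @return Peak table data.frame: `sample_id`, `space`, `position`,
#'   `height`, ordered by position (ladder rows last, also ordered).
#' @examples
#' g <- list(sample_id = "s1", allele_a = 17, allele_b = 20)
#' p <- trace_params(noise_sd = 0)
#' simulate_trace(g, p, space = "repeat")
#' @export
simulate_trace <- function(genotype, params = trace_params(),
                           space = c("bp", "repeat", "raw"),
                           standard = if (space[1] != "repeat") size_standard()) {
  space <- match.arg(space)
  stopifnot(inherits(params, "trace_params"))
  a <- as.integer(genotype$allele_a)
  b <- as.integer(genotype$allele_b)
  sid <- as.character(genotype$sample_id)
  if (any(c(a, b) < 1)) stop_httcag("alleles must be >= 1 repeat")

  bins <- accumulate_profile(c(a, b), params)
  reps <- bins$reps
  h <- bins$height
  if (params$noise_sd > 0) {
    h <- h + stats::rnorm(length(h), 0, params$noise_sd)
  }
  keep <- h > 0
  reps <- reps[keep]
  h <- pmin(h[keep], params$saturation)

  pos <- switch(space,
    "repeat" = as.numeric(reps),
    "bp"     = repeat_to_bp(reps, params$flank_bp),
    "raw"    = params$raw_slope * repeat_to_bp(reps, params$flank_bp) +
               params$raw_offset
  )
  ord <- order(pos)
  out <- data.frame(sample_id = sid, space = space,
                    position = pos[ord], height = h[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(standard) && space != "repeat") {
    lpos <- standard$fragment_sizes
    if (space == "raw") lpos <- params$raw_slope * lpos + params$raw_offset
    ladder <- data.frame(sample_id = paste0(sid, ".ladder"), space = space,
                         position = lpos, height = params$ladder_height,
                         stringsAsFactors = FALSE)
    out <- rbind(out, ladder)
  }
  rownames(out) <- NULL
  out
}

# Deterministic (pre-noise) repeat-space profile for a set of alleles.
accumulate_profile <- function(alleles, params) {
  acc <- new.env(parent = emptyenv())
  add <- function(r, h) {
    key <- as.character(r)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + h
  }
  for (al in alleles) {
    add(al, params$main_height)
    if (params$stutter_ratio > 0 && params$stutter_depth > 0) {
      for (k in seq_len(params$stutter_depth)) {
        if (al - k >= 1L) add(al - k, params$main_height * params$stutter_ratio^k)
      }
    }
    if (params$expansion_load > 0) {
      k <- 1L
      repeat {
        hk <- params$main_height * params$expansion_load *
          params$expansion_ratio^(k - 1L)
        if (hk < 1) break
        add(al + k, hk)
        k <- k + 1L
        if (k > 1000L) break
      }
    }
  }
  reps <- sort(as.integer(ls(acc)))
  list(reps = reps,
       height = vapply(as.character(reps), function(k) acc[[k]], numeric(1),
                       USE.NAMES = FALSE))
}

#' Simulate peak tables for a whole cohort
#'
#' One [simulate_trace()] call per genotype under a fixed seed; traces
#' are drawn in sample order so the output is reproducible.
#'
#' @param genotypes Genotype data.frame (`sample_id`, `allele_a`,
#'   `allele_b`).
#' @param params A [trace_params()].
#' @param space,standard Passed to [simulate_trace()].
#' @param seed Integer seed for the height-noise stream.
#' @return Combined peak table data.frame.
#' @export
simulate_cohort_traces <- function(genotypes, params = trace_params(),
                                   space = "bp",
                                   standard = if (space != "repeat") size_standard(),
                                   seed = 1L) {
  stopifnot(is.data.frame(genotypes))
  with_seed(derive_seed(seed, "traces"), {
    parts <- lapply(seq_len(nrow(genotypes)), function(i) {
      simulate_trace(genotypes[i, ], params, space = space,
                     standard = standard)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a peak table CSV
#'
#' Columns `sample_id`, `space`, `position`, `height`; ladder rows are
#' flagged by the `".ladder"` sample-id suffix. Row order is
#' deterministic (sample order, then position).
#'
#' @param peaks Peak table data.frame.
#' @param path CSV path.
#' @param tag Optional `#` comment line content.
#' @return `path` invisibly / the peak table.
#' @export
write_peaks <- function(peaks, path, tag = NULL) {
  write_tagged_table(peaks, path, sep = ",", tag = tag)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
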