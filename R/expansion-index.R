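# Somatic CAG expansion index (EI). The per-sample statistic considers
# only expansion peaks to the right of the highest (modal allele) peak:
# peaks at larger repeat counts are retained when their height reaches a
# fraction of the modal height, and the EI is the retained-height-weighted
# mean repeat distance from the modal allele, with the modal peak included
# in the normalizing denominator (so EI = 0 exactly when no expansion peak
# is retained).

#' Compute the somatic expansion index for one sample
#'
#' With modal peak height `H` at repeat `m`, the retained set is the
#' modal peak plus every peak at repeat `> m` with height `>= threshold
#' * H`. Then
#' `EI = sum_i h_i * (r_i - m) / sum_i h_i` over the retained set (the
#' modal term contributes 0 distance but does enter the denominator). A
#' height tie for the modal peak resolves to the larger repeat — the
#' conservative, EI-reducing choice — and is flagged.
#'
#' @param peaks Data.frame with `position` (repeat units) and positive
#'   `height` for one sample; optional `sample_id`.
#' @param threshold Relative height threshold `c` in `[0, 1)`; default
#'   0.20 of the modal height.
#' @param sample_id Overrides the recorded sample id.
#' @return Object of class `"ei_result"`: list with `sample_id`,
#'   `modal_repeat`, `threshold`, `retained` (data.frame `position`,
#'   `height`), `n_retained_expansion` and `ei`.
#' @examples
#' pk <- data.frame(position = c(20, 21, 22, 23),
#'                  height   = c(1000, 300, 250, 100))
#' compute_expansion_index(pk, threshold = 0.20)$ei  # 800/1550 = 0.516
#' @export
compute_expansion_index <- function(peaks, threshold = 0.20,
                                    sample_id = NULL) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) stop_httcag("empty peak table: cannot compute EI")
  stopifnot(threshold >= 0, threshold < 1, all(peaks$height > 0))
  sid <- sample_id %||% (if ("sample_id" %in% names(peaks))
    peaks$sample_id[1L] else NA_character_)
  pos <- as.numeric(peaks$position)
  h <- as.numeric(peaks$height)

  hmax <- max(h)
  modal_cand <- pos[h == hmax]
  modal <- max(modal_cand)
  tie <- length(modal_cand) > 1L

  keep <- pos > modal & h >= threshold * hmax
  retained <- data.frame(position = c(modal, pos[keep]),
                         height = c(hmax, h[keep]))
  retained <- retained[order(retained$position), , drop = FALSE]
  ei <- sum(retained$height * (retained$position - modal)) /
    sum(retained$height)

  structure(
    list(sample_id = sid, modal_repeat = modal, threshold = threshold,
         retained = retained, n_retained_expansion = sum(keep),
         ei = ei, modal_tie = tie),
    class = "ei_result"
  )
}

#' @export
print.ei_result <- function(x, ...) {
  cat(sprintf("<ei_result> %s: modal %g, %d expansion peak(s) retained (c = %.2f), EI = %.4f\n",
              x$sample_id, x$modal_repeat, x$n_retained_expansion,
              x$threshold, x$ei))
  invisible(x)
}

#' Expansion index for every sample in a cohort peak table
#'
#' When germline calls are supplied, each sample's profile is first
#' restricted to repeats at or beyond the larger called allele, so the
#' modal anchor is that allele's main peak and the short allele of a
#' heterozygote is never mistaken for an expansion peak of the modal
#' allele. Without calls the full profile is used (appropriate for
#' single-allele profiles).
#'
#' @param peaks Repeat-space cohort peak table (see
#'   [convert_cohort_peaks()]).
#' @param calls Optional data.frame of [call_cohort()] results
#'   (`sample_id`, `allele_b`).
#' @param threshold Relative height threshold, as in
#'   [compute_expansion_index()].
#' @return Data.frame: `sample_id`, `modal_repeat`, `threshold`,
#'   `n_retained_expansion_peaks`, `ei`.
#' @export
ei_cohort <- function(peaks, calls = NULL, threshold = 0.20) {
  stopifnot(is.data.frame(peaks), all(peaks$space == "repeat"))
  samples <- unique(peaks$sample_id[!grepl("\\.ladder$", peaks$sample_id)])
  anchor <- NULL
  if (!is.null(calls)) {
    anchor <- stats::setNames(calls$allele_b, calls$sample_id)
  }
  out <- do.call(rbind, lapply(samples, function(sid) {
    pk <- peaks[peaks$sample_id == sid, , drop = FALSE]
    if (!is.null(anchor) && sid %in% names(anchor)) {
      pk <- pk[pk$position >= anchor[[sid]], , drop = FALSE]
    }
    r <- compute_expansion_index(pk, threshold = threshold, sample_id = sid)
    data.frame(sample_id = sid, modal_repeat = r$modal_repeat,
               threshold = threshold,
               n_retained_expansion_peaks = r$n_retained_expansion,
               ei = r$ei, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-group mean expansion index
#'
#' @param results Data.frame with `sample_id` and `ei` (as from
#'   [ei_cohort()]).
#' @param grouping Data.frame mapping `sample_id` to `group`; groups
#'   present in `grouping` but absent from `results` are omitted with a
#'   warning.
#' @return Data.frame: `group`, `n`, `mean_ei` (group order follows
#'   first appearance in `grouping`).
#' @export
summarize_ei <- function(results, grouping) {
  stopifnot(is.data.frame(results), is.data.frame(grouping))
  m <- merge(results[, c("sample_id", "ei")],
             grouping[, c("sample_id", "group")], by = "sample_id")
  groups <- unique(grouping$group)
  present <- groups[groups %in% m$group]
  missing <- setdiff(groups, present)
  if (length(missing) > 0L) {
    warning(sprintf("omitting empty group(s): %s",
                    paste(missing, collapse = ", ")))
  }
  out <- do.call(rbind, lapply(present, function(g) {
    v <- m$ei[m$group == g]
    data.frame(group = g, n = length(v), mean_ei = mean(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
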