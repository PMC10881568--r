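# Cohort statistical layer: clinical CAG band classification, the
# per-individual sum of repeats (used because the MMR-cosegregating HTT
# allele is unknown), group summaries, pooled two-sample t tests with
# Bonferroni threshold adjustment, intermediate-allele carrier tallies
# and the carrier-exclusion sensitivity re-analysis.

#' Classify CAG alleles into the clinical bands
#'
#' Normal <= 26, intermediate 27-35, incomplete penetrance 36-39, full
#' penetrance >= 40. The bands partition all positive integers.
#'
#' @param cag Integer CAG count(s), >= 1.
#' @return Factor with levels `normal`, `intermediate`,
#'   `incomplete_penetrance`, `full_penetrance`.
#' @examples
#' classify_allele(c(26, 27, 35, 36, 39, 40))
#' @export
classify_allele <- function(cag) {
  if (any(!is.finite(cag)) || any(cag < 1) || any(cag != round(cag))) {
    stop_httcag("CAG counts must be positive integers")
  }
  cut(cag, breaks = c(0, 26, 35, 39, Inf),
      labels = c("normal", "intermediate", "incomplete_penetrance",
                 "full_penetrance"),
      right = TRUE)
}

#' Per-individual sum of CAG repeats
#'
#' The sum of both alleles is the per-person statistic used throughout
#' the group comparisons, since which HTT allele cosegregates with the
#' Lynch syndrome variant is unknown; a homozygote's allele counts twice.
#'
#' @param genotypes Data.frame with `allele_a` and `allele_b`, or an
#'   integer vector of first alleles.
#' @param allele_b Second alleles when `genotypes` is a vector.
#' @return Integer vector of sums.
#' @export
sum_of_repeats <- function(genotypes, allele_b = NULL) {
  if (is.data.frame(genotypes)) {
    return(as.integer(genotypes$allele_a + genotypes$allele_b))
  }
  as.integer(genotypes + allele_b)
}

#' Summarize one group's sum-of-repeats values
#'
#' @param values Numeric values (n >= 2).
#' @param label Group label.
#' @return Object of class `"group_summary"`: `label`, `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator).
#' @export
summarize_group <- function(values, label = "group") {
  if (length(values) < 2L) {
    stop_httcag("group '%s': need at least 2 values to summarize (got %d)",
                label, length(values))
  }
  structure(list(label = label, n = length(values),
                 mean = mean(values), sd = stats::sd(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n = %d, %.2f ± %.1f\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Bonferroni per-comparison significance threshold
#'
#' Implements threshold adjustment: raw p-values are compared against
#' `alpha / m`, rather than inflating the p-values themselves. With
#' `alpha = 0.05` and `m = 3` the threshold is 0.0167, i.e. 0.017 at
#' three decimals.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  stopifnot(alpha > 0, alpha < 1, is_count(m), m >= 1)
  alpha / m
}

#' Pooled-variance two-sample Student t test from group summaries
#'
#' Classic pooled form (not Welch):
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))`, two-sided p from the t
#' distribution on `n1 + n2 - 2` degrees of freedom, and a 95% CI for
#' the mean difference. The raw p-value is reported unadjusted and
#' compared against the Bonferroni threshold `alpha / m`.
#'
#' Degenerate inputs: zero pooled variance with equal means gives t = 0,
#' p = 1 (flagged); zero pooled variance with unequal means is flagged
#' degenerate with `p = NA`.
#'
#' @param a,b [summarize_group()] objects (or lists with `label`, `n`,
#'   `mean`, `sd`), each with n >= 2.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m_comparisons Number of comparisons in the family (default 1).
#' @param conf_level Confidence level of the mean-difference CI.
#' @return Object of class `"pooled_t_test"`: `t`, `df`, `p`, `estimate`
#'   (mean difference a - b), `ci_low`, `ci_high`, `alpha_adjusted`,
#'   `significant` (p < alpha_adjusted), `note`.
#' @examples
#' mlh1 <- summarize_group_values(n = 60, mean = 35.40, sd = 3.6, "MLH1")
#' ctrl <- summarize_group_values(n = 559, mean = 36.89, sd = 4.5, "controls")
#' pooled_t_test(mlh1, ctrl, alpha = 0.05, m_comparisons = 3)
#' @export
pooled_t_test <- function(a, b, alpha = 0.05, m_comparisons = 1L,
                          conf_level = 0.95) {
  for (g in list(a, b)) {
    stopifnot(is.list(g), g$n >= 2, g$sd >= 0)
  }
  n1 <- a$n; n2 <- b$n
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * a$sd^2 + (n2 - 1) * b$sd^2) / df
  est <- a$mean - b$mean
  alpha_adj <- bonferroni_threshold(alpha, m_comparisons)
  note <- ""
  if (sp2 <= 0) {
    if (est == 0) {
      t_stat <- 0; p <- 1; ci <- c(0, 0)
      note <- "zero pooled variance, equal means"
    } else {
      t_stat <- sign(est) * Inf; p <- NA_real_; ci <- c(NA_real_, NA_real_)
      note <- "degenerate: zero pooled variance, unequal means"
    }
  } else {
    se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
    t_stat <- est / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- est + c(-1, 1) * tq * se
  }
  structure(
    list(t = t_stat, df = df, p = p, estimate = est,
         ci_low = ci[1L], ci_high = ci[2L],
         alpha = alpha, m_comparisons = as.integer(m_comparisons),
         alpha_adjusted = alpha_adj,
         significant = if (is.na(p)) NA else p < alpha_adj,
         labels = c(a$label %||% "a", b$label %||% "b"),
         note = note),
    class = "pooled_t_test"
  )
}

#' @export
print.pooled_t_test <- function(x, ...) {
  cat(sprintf(
    "<pooled_t_test> %s vs %s: t = %.3f, df = %d, p = %.4g\n  diff = %.3f [%.3f, %.3f], threshold %.4g (alpha %.2f / %d)%s\n",
    x$labels[1L], x$labels[2L], x$t, x$df, x$p, x$estimate, x$ci_low,
    x$ci_high, x$alpha_adjusted, x$alpha, x$m_comparisons,
    if (nzchar(x$note)) paste0("\n  note: ", x$note) else ""))
  invisible(x)
}

#' Build a group summary directly from n, mean and sd
#'
#' Convenience constructor for summary statistics taken from a published
#' table rather than raw values.
#'
#' @param n,mean,sd Summary statistics (n >= 2, sd >= 0).
#' @param label Group label.
#' @return A `"group_summary"` object.
#' @export
summarize_group_values <- function(n, mean, sd, label = "group") {
  stopifnot(is_count(n), n >= 2, sd >= 0)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

# carrier = at least one allele in the intermediate band (27-35)
is_intermediate_carrier <- function(genotypes) {
  classify_allele(genotypes$allele_a) == "intermediate" |
    classify_allele(genotypes$allele_b) == "intermediate"
}

#' Tally intermediate-allele carriers per group
#'
#' A carrier is an individual with at least one allele of 27-35 CAG
#' repeats.
#'
#' @param genotypes Genotype data.frame with `group`, `allele_a`,
#'   `allele_b`.
#' @return Data.frame: `group`, `carriers`, `n`, `percent` (one
#'   decimal), in order of first appearance.
#' @export
intermediate_carrier_tally <- function(genotypes) {
  stopifnot(is.data.frame(genotypes))
  carrier <- is_intermediate_carrier(genotypes)
  groups <- unique(genotypes$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- genotypes$group == g
    k <- sum(carrier[sel]); n <- sum(sel)
    data.frame(group = g, carriers = k, n = n,
               percent = round(100 * k / n, 1), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Remove intermediate-allele carriers ("without IA" re-analysis)
#'
#' Drops every individual carrying at least one allele in 27-35 CAG,
#' decrementing group sizes accordingly.
#'
#' @inheritParams intermediate_carrier_tally
#' @return The reduced genotype data.frame.
#' @export
exclude_intermediate_carriers <- function(genotypes) {
  stopifnot(is.data.frame(genotypes))
  out <- genotypes[!is_intermediate_carrier(genotypes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare every group against a reference with pooled t tests
#'
#' Each non-reference group's sum-of-repeats values are compared to the
#' reference group; the Bonferroni family size defaults to the number of
#' comparisons performed.
#'
#' @param genotypes Genotype data.frame (`group`, `allele_a`,
#'   `allele_b`).
#' @param reference Reference group label (default `"controls"`).
#' @param alpha Family-wise significance level.
#' @param m_comparisons Bonferroni family size; defaults to the number
#'   of non-reference groups.
#' @return Data.frame with one row per comparison: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `df`, `p`, `ci_low`,
#'   `ci_high`, `alpha_adjusted`, `significant`.
#' @export
compare_groups <- function(genotypes, reference = "controls",
                           alpha = 0.05, m_comparisons = NULL) {
  stopifnot(is.data.frame(genotypes))
  if (!reference %in% genotypes$group) {
    stop_httcag("reference group '%s' not present", reference)
  }
  sums <- sum_of_repeats(genotypes)
  others <- setdiff(unique(genotypes$group), reference)
  m <- m_comparisons %||% length(others)
  ref_sum <- summarize_group(sums[genotypes$group == reference], reference)
  out <- do.call(rbind, lapply(others, function(g) {
    gs <- summarize_group(sums[genotypes$group == g], g)
    tt <- pooled_t_test(gs, ref_sum, alpha = alpha, m_comparisons = m)
    data.frame(group_a = g, group_b = reference,
               n_a = gs$n, n_b = ref_sum$n,
               mean_a = gs$mean, mean_b = ref_sum$mean,
               t = tt$t, df = tt$df, p = tt$p,
               ci_low = tt$ci_low, ci_high = tt$ci_high,
               alpha_adjusted = tt$alpha_adjusted,
               significant = tt$significant, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort summary table (one row per group)
#'
#' Per group: n, mean and SD of the per-individual sum of CAG repeats,
#' intermediate-allele carrier count and percentage, and (when supplied)
#' the mean somatic expansion index.
#'
#' @param genotypes Genotype data.frame (`sample_id`, `group`,
#'   `allele_a`, `allele_b`).
#' @param ei Optional per-sample EI data.frame (`sample_id`, `ei`).
#' @return Data.frame: `group`, `n`, `mean_sum`, `sd_sum`, `carriers`,
#'   `carrier_pct`, `mean_ei` (NA when `ei` is absent).
#' @export
cohort_summary_table <- function(genotypes, ei = NULL) {
  sums <- sum_of_repeats(genotypes)
  tal <- intermediate_carrier_tally(genotypes)
  ei_by_group <- NULL
  if (!is.null(ei)) {
    ei_by_group <- summarize_ei(ei, genotypes[, c("sample_id", "group")])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tal)), function(i) {
    g <- tal$group[i]
    v <- sums[genotypes$group == g]
    mean_ei <- NA_real_
    if (!is.null(ei_by_group) && g %in% ei_by_group$group) {
      mean_ei <- ei_by_group$mean_ei[ei_by_group$group == g]
    }
    data.frame(group = g, n = tal$n[i],
               mean_sum = mean(v), sd_sum = stats::sd(v),
               carriers = tal$carriers[i], carrier_pct = tal$percent[i],
               mean_ei = mean_ei, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format a cohort summary table for display
#'
#' Renders `mean_sum`/`sd_sum` in the conventional "mean ± SD" form
#' (two decimals / one decimal) and carriers as "k/n (pct)".
#'
#' @param summary_table A [cohort_summary_table()] result.
#' @return Character data.frame for printing.
#' @export
format_summary_table <- function(summary_table) {
  data.frame(
    group = summary_table$group,
    sum_of_repeats = sprintf("%.2f ± %.1f", summary_table$mean_sum,
                             summary_table$sd_sum),
    intermediate_carriers = ifelse(
      summary_table$carriers > 0,
      sprintf("%d/%d (%.1f)", summary_table$carriers, summary_table$n,
              summary_table$carrier_pct),
      sprintf("0/%d", summary_table$n)),
    mean_ei = ifelse(is.na(summary_table$mean_ei), "NA",
                     sprintf("%.3f", summary_table$mean_ei)),
    stringsAsFactors = FALSE
  )
}
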