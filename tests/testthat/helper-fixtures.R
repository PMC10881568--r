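# Shared fixture builders. All fixtures are generated in code.

point_model <- function(value) allele_model(support = value, weights = 1)

peak_tab <- function(position, height, sample_id = "s1") {
  data.frame(sample_id = rep(sample_id, length(position)),
             space = rep("repeat", length(position)),
             position = position, height = height,
             stringsAsFactors = FALSE)
}

unrowname <- function(d) {
  rownames(d) <- NULL
  d
}

# Cohort design of the larger (Bochum-style) study: exact group sizes
# and intermediate-allele carrier counts.
bochum_spec <- function(seed = 1L, mlh1_shift = 0) {
  cohort_spec(list(
    cohort_group("controls", 559, intermediate_carriers = 29),
    cohort_group("MLH1", 60, intermediate_carriers = 1,
                 mean_shift = mlh1_shift),
    cohort_group("MSH2", 88, intermediate_carriers = 3),
    cohort_group("MSH6", 23, intermediate_carriers = 1)
  ), seed = seed)
}

lund_spec <- function(seed = 1L) {
  cohort_spec(list(
    cohort_group("controls", 19, intermediate_carriers = 1),
    cohort_group("MLH1", 12, intermediate_carriers = 1),
    cohort_group("MSH2", 15, intermediate_carriers = 1),
    cohort_group("MSH6", 21, intermediate_carriers = 0)
  ), seed = seed)
}

# Independent brute-force expansion index: finds the modal peak by
# explicit scan (ties to the larger repeat), enumerates retained
# expansion peaks one by one, and accumulates the weighted distances.
# Deliberately loop-based and separate from the package implementation.
brute_force_ei <- function(position, height, threshold) {
  modal_i <- 1L
  for (i in seq_along(position)) {
    if (height[i] > height[modal_i] ||
        (height[i] == height[modal_i] && position[i] > position[modal_i])) {
      modal_i <- i
    }
  }
  m <- position[modal_i]
  hm <- height[modal_i]
  num <- 0
  den <- hm
  for (i in seq_along(position)) {
    if (position[i] > m && height[i] >= threshold * hm) {
      num <- num + height[i] * (position[i] - m)
      den <- den + height[i]
    }
  }
  num / den
}

# A raw vector with exactly the requested mean and sd (for cross-checking
# the summary-based pooled t test against stats::t.test on raw data).
vector_with_summary <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}
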