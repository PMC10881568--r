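test_that("calibration against the ladder is exact at and between knots", {
  std <- size_standard()
  # identity: ladder already in bp
  lad <- data.frame(position = std$fragment_sizes, height = 800)
  cal <- calibrate(lad, std)
  probe <- c(40, 105, 123.4, 499)
  expect_equal(map_to_bp(cal, probe), probe, tolerance = 1e-9)

  # affine migration raw = 2*bp + 7 is exactly representable
  lad2 <- data.frame(position = 2 * std$fragment_sizes + 7, height = 800)
  cal2 <- calibrate(lad2, std)
  bp <- c(35, 62.5, 105, 250, 500, 520)  # includes extrapolation beyond 500
  expect_equal(map_to_bp(cal2, 2 * bp + 7), bp, tolerance = 1e-9)
})

test_that("ladder peak / fragment count mismatch is a calibration error", {
  std <- size_standard()
  lad <- data.frame(position = std$fragment_sizes[-1], height = 800)
  expect_error(calibrate(lad, std), "15 ladder peaks vs 16")
  # sub-threshold ladder peaks are dropped before counting
  lad3 <- rbind(data.frame(position = 20, height = 10),
                data.frame(position = std$fragment_sizes, height = 800))
  expect_s3_class(calibrate(lad3, std), "calibration")
})

test_that("bp -> repeat conversion rounds to integers, ties to even", {
  expect_equal(bp_to_repeat(105, 54), 17L)
  expect_equal(bp_to_repeat(106, 54), 17L)   # 17.33 rounds down
  expect_equal(bp_to_repeat(107, 54), 18L)   # 17.67 rounds up
  expect_error(bp_to_repeat(54, 54), "flank")
})

test_that("allele calling follows the modal-anchor + masking rules", {
  # clean heterozygote
  call <- call_alleles(peak_tab(c(17, 20), c(980, 1000)))
  expect_equal(c(call$allele_a, call$allele_b), c(17, 20))
  expect_equal(call$zygosity, "het")
  expect_equal(call$modal_repeat, 20)
  expect_false(grepl("adjacent-allele-ambiguity", call$qc_flags))

  # stuttered homozygote: both stutter peaks under the cut
  call2 <- call_alleles(peak_tab(c(18, 19, 20), c(90, 300, 1000)),
                        stutter_cut = 0.5, stutter_depth = 3)
  expect_equal(c(call2$allele_a, call2$allele_b), c(20, 20))
  expect_equal(call2$zygosity, "hom")
  expect_true(grepl("homozygous-or-dropout", call2$qc_flags))

  # tall adjacent peak above the cut: called het, flagged ambiguous
  call3 <- call_alleles(peak_tab(c(19, 20), c(550, 1000)),
                        stutter_cut = 0.5)
  expect_equal(c(call3$allele_a, call3$allele_b), c(19, 20))
  expect_equal(call3$zygosity, "het")
  expect_true(grepl("adjacent-allele-ambiguity", call3$qc_flags))

  expect_error(call_alleles(peak_tab(numeric(0), numeric(0))), "empty")
})

test_that("expansion peaks right of the modal allele are not called", {
  call <- call_alleles(peak_tab(c(20, 21, 22), c(1000, 300, 150)),
                       expansion_cut = 0.5)
  expect_equal(call$zygosity, "hom")
  expect_equal(call$allele_b, 20)
})

test_that("calling is invariant to uniform height scaling", {
  pk <- peak_tab(c(16, 17, 18, 19, 20, 21), c(90, 300, 1000, 300, 995, 250))
  c1 <- call_alleles(pk)
  pk2 <- pk; pk2$height <- pk2$height * 7.3
  c2 <- call_alleles(pk2)
  expect_equal(c1[, c("allele_a", "allele_b", "zygosity", "qc_flags")],
               c2[, c("allele_a", "allele_b", "zygosity", "qc_flags")])
})

test_that("noiseless simulation -> calibration -> calling is the identity", {
  params <- trace_params(noise_sd = 0, raw_slope = 2.5, raw_offset = 40)
  grid <- expand.grid(a = c(9, 15, 17, 22, 30, 35), b = c(17, 20, 36, 44))
  grid <- grid[grid$a <= grid$b, ]
  for (i in seq_len(nrow(grid))) {
    g <- list(sample_id = "x", allele_a = grid$a[i], allele_b = grid$b[i])
    pk <- simulate_trace(g, params, space = "raw", standard = size_standard())
    rs <- convert_cohort_peaks(pk, size_standard(), flank_bp = params$flank_bp)
    call <- call_alleles(rs)
    expect_equal(c(call$allele_a, call$allele_b),
                 c(grid$a[i], grid$b[i]),
                 info = sprintf("alleles (%d, %d)", grid$a[i], grid$b[i]))
  }
})
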