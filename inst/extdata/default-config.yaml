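# Default httcag pipeline configuration.
# Cohort structure mirrors the larger (Bochum-style) study design:
# exact group sizes and intermediate-allele carrier counts, and a
# -0.75 per-allele mean shift in the MLH1 group (echoing the observed
# ~-1.5 difference in the per-individual sum of CAG repeats).
seed: 20240221
output_dir: httcag-results
cohort:
  allele_model:
    support_min: 9
    support_max: 55
    center_repeat: 17     # log-normal median, in repeat units
    sdlog: 0.30           # ~6% of alleles fall in the 27-35 band
  groups:
    - label: controls
      n: 559
      intermediate_carriers: 29
    - label: MLH1
      n: 60
      intermediate_carriers: 1
      mean_shift: -0.75
    - label: MSH2
      n: 88
      intermediate_carriers: 3
    - label: MSH6
      n: 23
      intermediate_carriers: 1
trace:
  profile: bochum         # flank_bp profile (bochum: 54 bp, lund: 79 bp)
  space: bp
  stutter_ratio: 0.3
  stutter_depth: 3
  expansion_ratio: 0.45
  expansion_load: 0.25
  noise_sd: 15
  main_height: 1000
calling:
  stutter_cut: 0.5
  expansion_cut: 0.5
  stutter_depth: 3
ei:
  threshold: 0.20
  reference_subset_n: 250
stats:
  reference: controls
  alpha: 0.05
  m_comparisons: 3
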