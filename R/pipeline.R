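# Pipeline orchestration: simulate -> call -> EI -> stats, driven by one
# YAML configuration and a single seed. Every stage can also be run on
# its own against the intermediate files.

#' Default pipeline configuration
#'
#' Mirrors the larger of the two cohort designs the package emulates:
#' groups controls (n = 559, 29 intermediate carriers), MLH1 (60, 1),
#' MSH2 (88, 3) and MSH6 (23, 1), with a -0.75 per-allele mean shift in
#' the MLH1 group echoing the observed group difference of about -1.5 in
#' the per-individual sum of repeats. Stored as YAML at
#' `system.file("extdata", "default-config.yaml", package = "httcag")`.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  read_run_config(system.file("extdata", "default-config.yaml",
                              package = "httcag"))
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file with sections `seed`, `output_dir`, `cohort`
#'   (allele model + groups), `trace`, `calling`, `ei`, `stats`. Missing
#'   scalar entries fall back to the package defaults.
#' @return Validated configuration list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_httcag("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohort$groups) || length(cfg$cohort$groups) == 0L) {
    stop_httcag("config must define at least one cohort group")
  }
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
  cfg$cohort$groups <- lapply(cfg$cohort$groups, function(g) {
    names(g)[names(g) %in% c("FALSE", "no")] <- "n"
    g
  })
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "httcag-results"
  am <- cfg$cohort$allele_model %||% list()
  cfg$cohort$allele_model <- list(
    support_min = am$support_min %||% 9L,
    support_max = am$support_max %||% 55L,
    center_repeat = am$center_repeat %||% 17,
    sdlog = am$sdlog %||% 0.30
  )
  tr <- cfg$trace %||% list()
  cfg$trace <- list(
    profile = tr$profile %||% "bochum",
    flank_bp = tr$flank_bp,
    stutter_ratio = tr$stutter_ratio %||% 0.3,
    stutter_depth = tr$stutter_depth %||% 3L,
    expansion_ratio = tr$expansion_ratio %||% 0.45,
    expansion_load = tr$expansion_load %||% 0.25,
    noise_sd = tr$noise_sd %||% 15,
    main_height = tr$main_height %||% 1000,
    space = tr$space %||% "bp"
  )
  cl <- cfg$calling %||% list()
  cfg$calling <- list(
    stutter_cut = cl$stutter_cut %||% 0.5,
    expansion_cut = cl$expansion_cut %||% 0.5,
    stutter_depth = cl$stutter_depth %||% 3L
  )
  ei <- cfg$ei %||% list()
  cfg$ei <- list(
    threshold = ei$threshold %||% 0.20,
    reference_subset_n = ei$reference_subset_n %||% 250L
  )
  st <- cfg$stats %||% list()
  cfg$stats <- list(
    reference = st$reference %||% "controls",
    alpha = st$alpha %||% 0.05,
    m_comparisons = st$m_comparisons
  )
  class(cfg) <- "run_config"
  cfg
}

# Build package objects from the config sections.
config_allele_model <- function(cfg) {
  am <- cfg$cohort$allele_model
  allele_model(support = am$support_min:am$support_max,
               meanlog = log(am$center_repeat), sdlog = am$sdlog)
}

config_cohort_spec <- function(cfg, seed) {
  model <- config_allele_model(cfg)
  groups <- lapply(cfg$cohort$groups, function(g) {
    cohort_group(label = g$label, n = g$n,
                 intermediate_carriers = g$intermediate_carriers %||% NA,
                 mean_shift = g$mean_shift %||% 0,
                 model = model)
  })
  cohort_spec(groups, seed = seed)
}

config_trace_params <- function(cfg) {
  tr <- cfg$trace
  trace_params(stutter_ratio = tr$stutter_ratio,
               stutter_depth = tr$stutter_depth,
               expansion_ratio = tr$expansion_ratio,
               expansion_load = tr$expansion_load,
               noise_sd = tr$noise_sd, main_height = tr$main_height,
               flank_bp = tr$flank_bp, profile = tr$profile)
}

#' Run the full pipeline
#'
#' Simulates the configured cohort, synthesizes peak tables, calls
#' germline alleles, computes per-sample expansion indices anchored at
#' the larger called allele, and writes the statistical layer: a
#' one-row-per-group summary table, reference comparisons for the full
#' cohort and for the cohort with intermediate-allele carriers removed,
#' and a JSON run manifest. All outputs carry the configuration hash and
#' seed; re-running with the same config and seed reproduces the bundle
#' byte for byte.
#'
#' @param config A [read_run_config()] result (default:
#'   [default_run_config()]).
#' @param output_dir Overrides `config$output_dir`.
#' @param seed Overrides `config$seed`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory stage results and
#'   `files`, the named vector of written paths.
#' @export
run_all <- function(config = default_run_config(),
                    output_dir = NULL, seed = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(seed %||% config$seed)
  output_dir <- output_dir %||% config$output_dir
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  tag <- sprintf("httcag run %s seed %d", hash, seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(output_dir, f)

  say("[cohort] simulating genotypes (seed %d)", seed)
  cohort <- generate_cohort(config_cohort_spec(config, seed))
  write_cohort(cohort, path("cohort.tsv"), ledger_path = path("ledger.json"),
               tag = tag)

  say("[traces] simulating %d peak profiles", nrow(cohort$genotypes))
  params <- config_trace_params(config)
  peaks <- simulate_cohort_traces(cohort$genotypes, params,
                                  space = config$trace$space, seed = seed)
  write_peaks(peaks, path("peaks.csv"), tag = tag)

  say("[call] calibrating and calling alleles")
  rs_peaks <- convert_cohort_peaks(peaks, flank_bp = params$flank_bp)
  calls <- call_cohort(rs_peaks,
                       stutter_cut = config$calling$stutter_cut,
                       expansion_cut = config$calling$expansion_cut,
                       stutter_depth = config$calling$stutter_depth)
  write_tagged_table(calls, path("called.tsv"), sep = "\t", tag = tag)

  say("[ei] computing expansion indices (threshold %.2f)",
      config$ei$threshold)
  ei <- ei_cohort(rs_peaks, calls = calls, threshold = config$ei$threshold)
  write_tagged_table(ei, path("ei.tsv"), sep = "\t", tag = tag)

  say("[stats] group comparisons vs '%s'", config$stats$reference)
  called_geno <- merge(calls[, c("sample_id", "allele_a", "allele_b")],
                       cohort$genotypes[, c("sample_id", "group")],
                       by = "sample_id", sort = FALSE)
  summary_tab <- cohort_summary_table(called_geno, ei = ei)
  write_tagged_table(summary_tab, path("summary.tsv"), sep = "\t", tag = tag)

  comps <- compare_groups(called_geno, reference = config$stats$reference,
                          alpha = config$stats$alpha,
                          m_comparisons = config$stats$m_comparisons)
  comps$subset <- "all"
  no_ia <- exclude_intermediate_carriers(called_geno)
  comps_no_ia <- compare_groups(no_ia, reference = config$stats$reference,
                                alpha = config$stats$alpha,
                                m_comparisons = config$stats$m_comparisons)
  comps_no_ia$subset <- "without_ia"
  comparisons <- rbind(comps, comps_no_ia)
  write_tagged_table(comparisons, path("comparisons.tsv"), sep = "\t",
                     tag = tag)

  # EI comparison group: the named reference subset of the first
  # reference-group samples (emulating consecutively selected controls)
  ref_ids <- cohort$genotypes$sample_id[
    cohort$genotypes$group == config$stats$reference]
  ref_ids <- utils::head(ref_ids, config$ei$reference_subset_n)
  ei_ref <- ei[ei$sample_id %in% ref_ids, , drop = FALSE]

  files <- c(cohort = path("cohort.tsv"), ledger = path("ledger.json"),
             peaks = path("peaks.csv"), called = path("called.tsv"),
             ei = path("ei.tsv"), summary = path("summary.tsv"),
             comparisons = path("comparisons.tsv"),
             manifest = path("manifest.json"))
  manifest <- list(
    tool = "httcag",
    version = as.character(utils::packageVersion("httcag")),
    seed = seed, config_hash = hash,
    config = unclass(config),
    n_samples = nrow(cohort$genotypes),
    ei_reference_subset = list(n = length(ref_ids),
                               mean_ei = if (nrow(ei_ref)) mean(ei_ref$ei)
                                         else NA),
    files = as.list(basename(files))
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("[done] bundle written to %s", output_dir)

  invisible(list(config = config, seed = seed, hash = hash,
                 cohort = cohort, peaks = peaks, repeat_peaks = rs_peaks,
                 calls = calls, ei = ei, summary = summary_tab,
                 comparisons = comparisons, files = files))
}
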