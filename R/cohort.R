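#' Define one cohort group
#'
#' @param label Group label (e.g. `"controls"`, `"MLH1"`); must be unique
#'   within a [cohort_spec()].
#' @param n Number of individuals (>= 1).
#' @param intermediate_carriers Exact number of individuals that must
#'   carry precisely one intermediate allele (27-35 CAG) with the other
#'   allele in the normal range (<= 26). `NA` (default) leaves carrier
#'   status free, i.e. governed by the allele model alone.
#' @param mean_shift Per-allele mean shift in repeat units applied to the
#'   group's allele distribution (see [shift_allele_model()]); may be
#'   fractional.
#' @param model The group's [allele_model()].
#' @return A list of class `"cohort_group"`.
#' @export
cohort_group <- function(label, n, intermediate_carriers = NA,
                         mean_shift = 0, model = allele_model()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is_count(n) || n < 1) {
    stop_httcag("group '%s': n must be a positive integer", label)
  }
  if (!is.na(intermediate_carriers)) {
    if (!is_count(intermediate_carriers)) {
      stop_httcag("group '%s': intermediate_carriers must be a count or NA",
                  label)
    }
    if (intermediate_carriers > n) {
      stop_httcag(
        "group '%s': %d forced intermediate carriers exceed group size %d",
        label, as.integer(intermediate_carriers), as.integer(n))
    }
  }
  stopifnot(inherits(model, "allele_model"))
  structure(
    list(label = label, n = as.integer(n),
         intermediate_carriers = if (is.na(intermediate_carriers)) NA_integer_
                                 else as.integer(intermediate_carriers),
         mean_shift = mean_shift, model = model),
    class = "cohort_group"
  )
}

#' Define a cohort simulation
#'
#' @param groups List of [cohort_group()] objects with unique labels.
#' @param seed Integer parent seed. Each group draws from its own child
#'   stream derived from `seed` and the group label, so editing one
#'   group does not perturb the others.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups, seed) {
  if (inherits(groups, "cohort_group")) groups <- list(groups)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "cohort_group")))
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_httcag("duplicate group labels: %s",
                paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  stopifnot(is_count(abs(seed)))
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of biallelic CAG genotypes
#'
#' Draws `n` genotypes per group from the (mean-shifted) allele model.
#' When a group requests an exact number of intermediate-allele carriers,
#' carrier individuals receive one allele conditioned on the 27-35 band
#' and one conditioned on <= 26 repeats, while all remaining individuals
#' are conditioned to carry no allele in 27-35 (alleles of 36+ remain
#' possible if the model puts mass there). Carrier counts in the output
#' are therefore exact, not in expectation. Output is byte-reproducible
#' for a fixed spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `genotypes`, a data.frame with columns `sample_id`,
#'   `group`, `allele_a`, `allele_b` (`allele_a <= allele_b`), and
#'   `ledger`, a list echoing the spec, the parent and per-group child
#'   seeds, and the package version.
#' @examples
#' spec <- cohort_spec(list(
#'   cohort_group("controls", 50, intermediate_carriers = 3),
#'   cohort_group("MLH1", 10, intermediate_carriers = 1)
#' ), seed = 1)
#' cohort <- generate_cohort(spec)
#' table(cohort$genotypes$group)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", length(spec$groups))
  ledger_groups <- vector("list", length(spec$groups))
  for (i in seq_along(spec$groups)) {
    g <- spec$groups[[i]]
    gseed <- derive_seed(spec$seed, g$label)
    model <- if (g$mean_shift != 0) {
      shift_allele_model(g$model, g$mean_shift)
    } else {
      g$model
    }
    geno <- with_seed(gseed, sample_group_genotypes(g, model))
    geno$sample_id <- sprintf("%s_%04d", g$label, seq_len(g$n))
    out[[i]] <- data.frame(
      sample_id = geno$sample_id,
      group = g$label,
      allele_a = pmin(geno$a1, geno$a2),
      allele_b = pmax(geno$a1, geno$a2),
      stringsAsFactors = FALSE
    )
    ledger_groups[[i]] <- list(
      label = g$label, n = g$n,
      intermediate_carriers = g$intermediate_carriers,
      mean_shift = g$mean_shift,
      child_seed = gseed,
      model_support = range(g$model$support),
      model_intermediate_prob = g$model$intermediate_prob
    )
  }
  genotypes <- do.call(rbind, out)
  rownames(genotypes) <- NULL
  list(
    genotypes = genotypes,
    ledger = list(
      seed = spec$seed,
      groups = ledger_groups,
      package = "httcag",
      version = as.character(utils::packageVersion("httcag"))
    )
  )
}

# Draw one group's allele pairs; assumes the RNG is already seeded.
sample_group_genotypes <- function(g, model) {
  n <- g$n
  nc <- g$intermediate_carriers
  if (is.na(nc)) {
    return(list(a1 = sample_allele(model, n), a2 = sample_allele(model, n)))
  }
  band <- model$support >= 27L & model$support <= 35L
  normal <- model$support <= 26L
  a1 <- integer(n)
  a2 <- integer(n)
  if (nc > 0L) {
    band_model <- restrict_allele_model(model, band,
                                        "the intermediate band (27-35)")
    normal_model <- restrict_allele_model(model, normal,
                                          "the normal range (<= 26)")
    carrier_rows <- sort(sample.int(n, nc))
    a1[carrier_rows] <- sample_allele(band_model, nc)
    a2[carrier_rows] <- sample_allele(normal_model, nc)
  } else {
    carrier_rows <- integer(0)
  }
  rest <- setdiff(seq_len(n), carrier_rows)
  if (length(rest) > 0L) {
    clean_model <- restrict_allele_model(model, !band,
                                         "CAG counts outside 27-35")
    a1[rest] <- sample_allele(clean_model, length(rest))
    a2[rest] <- sample_allele(clean_model, length(rest))
  }
  list(a1 = a1, a2 = a2)
}

#' Write / read a cohort genotype table
#'
#' Tab-separated columns `sample_id`, `group`, `allele_a`, `allele_b`.
#' A leading `#` comment line carries the run tag when written by the
#' pipeline. The ledger is written alongside as JSON when supplied.
#'
#' @param cohort Result of [generate_cohort()] or a bare genotype
#'   data.frame.
#' @param path Output TSV path.
#' @param ledger_path Optional JSON path for the ground-truth ledger.
#' @param tag Optional comment line (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, ledger_path = NULL, tag = NULL) {
  genotypes <- if (is.data.frame(cohort)) cohort else cohort$genotypes
  write_tagged_table(genotypes, path, sep = "\t", tag = tag)
  if (!is.null(ledger_path) && !is.data.frame(cohort)) {
    jsonlite::write_json(cohort$ledger, ledger_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Shared writer: optional '# <tag>' first line, then a header'd table.
write_tagged_table <- function(df, path, sep, tag = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(tag)) writeLines(paste0("# ", tag), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
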