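# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a parent seed and a string label, so that
# per-group (or per-stage) RNG streams are keyed by label: editing one
# group's parameters never perturbs another group's draws. Plain
# polynomial hash kept below 2^31 so it is a valid set.seed() argument.
derive_seed <- function(parent, label) {
  stopifnot(is.numeric(parent), length(parent) == 1L, is.finite(parent))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(((abs(parent) %% 1000003) * 1000003 + h) %% 2147483647)
}

# Evaluate code under a fixed seed without clobbering the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

stop_httcag <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Small rolling hash of a configuration (or any R object) used to tag
# output files and the run manifest.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
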