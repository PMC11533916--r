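# Internal helpers shared across modules.

# C-11 physical decay constant, min^-1 (half-life 20.4 min). Used only by the
# noise model: TAC values themselves are decay-corrected.
lambda_c11 <- log(2) / 20.4

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "petsuvr_invalid_input", ...)
}

abort_undefined <- function(msg, ...) {
  rlang::abort(msg, class = "petsuvr_undefined_result", ...)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort_invalid(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream of sub-seeds (< 2^31) derived from a master seed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Write a tibble as TSV with a commented provenance header; byte-deterministic.
write_table_with_header <- function(x, path, header_lines) {
  body <- readr::format_tsv(x)
  writeLines(c(paste0("# ", header_lines), sub("\n$", "", body)), path, sep = "\n")
  invisible(path)
}

read_table_with_header <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
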