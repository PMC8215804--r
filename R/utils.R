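## Internal helpers shared across the pipeline.

#' @keywords internal
"_PACKAGE"

# Stage-tagged condition helpers: every warning/error names the pipeline
# stage so failures in `run_pipeline()` can be attributed.
np_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

np_warn <- function(stage, ...) {
  warning(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

np_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Derive an independent per-artifact RNG sub-seed from one root seed, so
# regenerating one artifact (e.g. more probes) never perturbs another.
# Lehmer step keeps the result a valid 32-bit seed.
derive_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  as.integer((abs(as.numeric(root_seed)) * 48271 + 7919 * stream) %% 2147483647)
}

# Run `expr` with a local RNG state seeded from (root, stream); restores the
# caller's RNG afterwards.
with_substream <- function(root_seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(root_seed, stream))
  expr
}

assert_scalar_prob <- function(x, name, stage = "config") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    np_stop(stage, sprintf("`%s` must be a single number in (0, 1), got %s",
                           name, deparse(x)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
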