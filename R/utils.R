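# Internal helpers shared across modules.

abort_config <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("Invalid `%s`: %s", field, msg)
  rlang::abort(msg, class = "redunet_config_error", field = field)
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "redunet_validation_error")
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards so library calls never clobber user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of child seeds from one parent seed without consuming the
# caller's RNG state. Keeps every artifact reproducible from a single seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_binary_adjacency <- function(A) {
  is.matrix(A) && nrow(A) == ncol(A) && all(A %in% c(0, 1)) &&
    all(A == t(A)) && all(diag(A) == 0)
}

check_adjacency <- function(A, arg = "adjacency") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    abort_validation(sprintf("`%s` must be a square matrix.", arg))
  if (!all(A %in% c(0, 1)))
    abort_validation(sprintf("`%s` must be binary (0/1 entries only).", arg))
  if (!isTRUE(all(A == t(A))))
    abort_validation(sprintf("`%s` must be symmetric.", arg))
  if (!all(diag(A) == 0))
    abort_validation(sprintf("`%s` must have a zero diagonal.", arg))
  invisible(A)
}

default_node_ids <- function(n) sprintf("ROI%03d", seq_len(n))
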