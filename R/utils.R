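# Internal helpers shared across the package.

PARAM_NAMES <- c("igf", "tumor", "comorbidity", "symptoms", "qol")
RATING_LEVELS <- c("S", "M-DA", "S-DA")

# Classed error so callers/tests can distinguish validation failures
# from programming errors.
abort_invalid <- function(msg, class = "acrodat_invalid") {
  stop(errorCondition(msg, class = c(class, "acrodat_error")))
}

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state.
# All stochastic code in the package funnels through this so that a
# single integer seed fully determines any simulated dataset.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_invalid("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Coerce a 5-column level input (vector, matrix or data.frame) to an
# integer matrix with one row per observation and the canonical column
# order. Accepts a bare length-5 vector for convenience.
as_level_matrix <- function(levels) {
  if (is.data.frame(levels)) {
    missing_cols <- setdiff(PARAM_NAMES, names(levels))
    if (length(missing_cols) > 0L) {
      abort_invalid(paste0(
        "level data is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ))
    }
    levels <- as.matrix(levels[, PARAM_NAMES, drop = FALSE])
  } else if (is.null(dim(levels))) {
    if (length(levels) != 5L) {
      abort_invalid("a level vector must have exactly 5 components")
    }
    levels <- matrix(levels, nrow = 1L)
  }
  if (ncol(levels) != 5L) {
    abort_invalid("a level matrix must have exactly 5 columns")
  }
  storage.mode(levels) <- "integer"
  if (anyNA(levels) || any(levels < 1L | levels > 3L)) {
    abort_invalid("severity levels must all be 1, 2 or 3")
  }
  colnames(levels) <- PARAM_NAMES
  levels
}
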