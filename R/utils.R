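`%||%` <- function(x, y) if (is.null(x)) y else x

# probability-vector validation shared by the statistical helpers
check_prob <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & (x < 0 | x > 1) else is.na(x) | x < 0 | x > 1
  if (any(bad)) {
    stop(sprintf("%s must lie in [0, 1]; offending value(s): %s",
                 name, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("%s must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# runs code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(seed)
  force(code)
}
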