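# Internal helpers shared across modules.

# round() in R rounds half to even; census percentages are reported with
# conventional half-up rounding (37/49 -> 76, 60/74 -> 81).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Run code with a local RNG seed, restoring the caller's RNG state afterwards
# so generators never perturb the global random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  force(code)
}

stop_riverval <- function(...) {
  stop(paste0(...), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Weight vectors must sum to 1; tolerance matches the hierarchy contract.
check_weights <- function(w, n = NULL, tol = 1e-9) {
  if (!is.numeric(w) || length(w) == 0L || anyNA(w)) {
    stop_riverval("weights must be a non-empty numeric vector without NA")
  }
  if (any(w < 0)) stop_riverval("weights must be non-negative")
  if (!is.null(n) && length(w) != n) {
    stop_riverval("length mismatch: ", length(w), " weights for ", n, " values")
  }
  if (abs(sum(w) - 1) > tol) {
    stop_riverval("weights must sum to 1 (got ", format(sum(w)), ")")
  }
  invisible(w)
}

check_values <- function(v) {
  if (!is.numeric(v) || length(v) == 0L || anyNA(v)) {
    stop_riverval("values must be a non-empty numeric vector without NA")
  }
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop_riverval("values must lie in [0, 1]")
  }
  invisible(pmin(pmax(v, 0), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
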