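
# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stageminer_config_error", "error")))
}

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stageminer_parse_error", "error")))
}

check_scalar_count <- function(x, name, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < minimum) {
    stop_config("'%s' must be a single integer >= %d (got %s)",
                name, minimum, deparse(x))
  }
  as.integer(x)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lower &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_config("'%s' must be a single number in [%s, %s%s (got %s)",
                name, format(lower), format(upper),
                if (open_upper) ")" else "]", deparse(x))
  }
  as.numeric(x)
}
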