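#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------
# All user-facing validation failures are classed conditions so callers (and
# the pipeline runner) can distinguish configuration mistakes from bad data.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "barreldev_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field '%s' %s", field, msg),
        "barreldev_config_error")
}

abort_data <- function(msg) abort(msg, "barreldev_data_error")
abort_schema <- function(msg) abort(msg, "barreldev_schema_error")
abort_insufficient <- function(msg) abort(msg, "barreldev_insufficient_data_error")
abort_geometry <- function(msg) abort(msg, "barreldev_geometry_error")
abort_bounds <- function(msg) abort(msg, "barreldev_bounds_error")

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort_config(field, "must be a single probability in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    abort_config(field, "must be a single positive number")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    abort_config(field, "must be a single non-negative number")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    abort_config(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

# Seed handling: every generator seeds explicitly and restores the caller's
# RNG state on exit, so synthetic data are reproducible without the package
# touching the global random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_config("seed", "must be a single integer or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
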