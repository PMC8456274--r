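# Internal utilities shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `code`, and
#' restores the previous state on exit, so seeded package functions never
#' disturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Stage offsets used to derive per-stage seeds from a single global seed.
# Recorded in pipeline manifests; keep stable across releases.
.seed_offsets <- c(
  panel = 101L, cohort = 211L, acquisition = 307L, stabilizer = 401L,
  ensemble = 503L, mk = 601L, split = 701L
)

stage_seed <- function(seed, stage) {
  off <- .seed_offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# sample() without the length-1 surprise
sample_exact <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean. An all-zero vector has CV 0
#' by convention (no signal, no spread); a zero mean with nonzero spread is
#' undefined and raises an error.
#'
#' @param values numeric vector, at least one element.
#' @return a single nonnegative number.
#' @examples
#' cv_stat(c(8, 12))   # 0.2828...
#' cv_stat(rep(1, 4))  # 0
#' @export
cv_stat <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop_invalid("cv_stat() needs a nonempty numeric vector")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (length(values) == 1L) s <- 0
  if (m == 0) {
    if (isTRUE(all.equal(s, 0)) || all(values == 0)) return(0)
    stop_invalid("coefficient of variation undefined: mean is 0 with nonzero spread")
  }
  s / m
}
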