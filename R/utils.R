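#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}

# Circular shift of a vector: positive k moves content toward larger indices.
roll_vec <- function(v, k) {
  n <- length(v)
  if (n == 0L) return(v)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(v)
  c(v[(n - k + 1L):n], v[1:(n - k)])
}

# Circular shift of matrix rows (axis 1); positive k moves content down.
roll_rows <- function(m, k) {
  n <- nrow(m)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(m)
  m[c((n - k + 1L):n, 1:(n - k)), , drop = FALSE]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

hann_window <- function(n) {
  stopifnot(n >= 2)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
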