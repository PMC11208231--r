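## Internal helpers: deterministic substreams, validation, small numerics.

#' Derive a deterministic substream seed
#'
#' Hashes a root seed together with an arbitrary set of string/numeric keys
#' into a 31-bit integer seed. Used so that every simulated entity (subject,
#' muscle, trial) has its own reproducible random stream: adding subjects to
#' a cohort never reshuffles the draws of existing ones.
#'
#' @param seed integer root seed.
#' @param ... further keys (coerced to character) identifying the entity.
#' @return an integer in [0, 2^31 - 2] suitable for `set.seed()`.
#' @keywords internal
substream_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## with_substream: evaluate expr under a local RNG state seeded from keys,
## restoring the caller's RNG afterwards.
with_substream <- function(seed, ..., expr) {
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
  set.seed(substream_seed(seed, ...))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a finite numeric scalar")
  }
  if (strict_lower && x <= lower) {
    stop_field(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && x < lower) {
    stop_field(field, sprintf("must be >= %g", lower))
  }
  if (strict_upper && x >= upper) {
    stop_field(field, sprintf("must be < %g", upper))
  }
  if (!strict_upper && x > upper) {
    stop_field(field, sprintf("must be <= %g", upper))
  }
  invisible(x)
}

## Shoelace area of a polygon given vertex coordinates in order.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Point-in-convex-polygon test (polygon vertices in counterclockwise order).
point_in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  n <- length(hx)
  j <- c(2:n, 1L)
  cross <- (hx[j] - hx) * (py - hy) - (hy[j] - hy) * (px - hx)
  all(cross >= -tol) || all(cross <= tol)
}
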