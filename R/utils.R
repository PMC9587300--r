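# Internal helpers shared across modules.

#' Wrap angles to (-pi, pi]
#'
#' Canonical angle representation used by every module (field heading,
#' controller error). Exact -pi maps to +pi.
#'
#' @param a numeric vector of angles, radians.
#' @return angles wrapped into (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Centered moving average with truncated windows at the edges.
# Window of length w covers indices i - floor((w-1)/2) .. i + floor(w/2),
# clipped to the series; each mean is over the pixels actually in range.
moving_average <- function(x, window) {
  if (window < 1) stop("`window` must be >= 1")
  n <- length(x)
  hl <- floor((window - 1) / 2)
  hr <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - hl)
  hi <- pmin(n, seq_len(n) + hr)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Evaluate `code` under a fixed RNG seed (restoring the caller's RNG state),
# or with the ambient RNG stream when seed is NULL.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Normal(0, sd) truncated below at `lower` (rejection sampling); used for
# multiplicative speed noise so 1 + eps stays positive.
rnorm_trunc <- function(n, sd, lower = -0.9) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- x < lower
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_num <- function(x, name, finite = TRUE, min = -Inf) {
  if (!is.numeric(x) || length(x) == 0) {
    stop("`", name, "` must be numeric", call. = FALSE)
  }
  if (finite && any(!is.finite(x))) {
    stop("`", name, "` must be finite", call. = FALSE)
  }
  if (any(x < min)) {
    stop("`", name, "` must be >= ", min, call. = FALSE)
  }
  invisible(x)
}
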