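# Heterogeneous mucus mobility field. Mucus is heterogeneous: concentrated
# mucin glycoproteins are present at random in solution, so identical
# particles in different regions move at noticeably different speeds. We
# model this as a smooth, strictly positive, mean-one multiplicative
# mobility field with a tunable coefficient of variation and correlation
# length, generated as a smoothed lognormal random field.

#' Generate a heterogeneous mucus mobility field
#'
#' Gaussian white noise on a regular grid is smoothed with a Gaussian kernel
#' of the requested correlation length, standardised, exponentiated to a
#' lognormal field, and rescaled to mean 1 with the requested coefficient of
#' variation. `cv = 0` yields the homogeneous field (all ones).
#'
#' @param extent length-2 field extent `(Lx, Ly)`, um; the field covers
#'   `[0, Lx] x [0, Ly]`.
#' @param step grid spacing, um (> 0).
#' @param correlation_length smoothing kernel sd, um.
#' @param cv target coefficient of variation of the mobility multiplier
#'   (>= 0).
#' @param seed integer seed; the field is a pure function of (parameters,
#'   seed).
#' @return object of class `fluid_field`: list with the node matrix `m`
#'   (`length(xs) x length(ys)`), node coordinates `xs`, `ys`, and the
#'   generating parameters.
#' @export
#' @examples
#' fl <- make_mucus_field(extent = c(100, 100), step = 2, cv = 0.3, seed = 1)
#' mean(fl$m)  # ~1
make_mucus_field <- function(extent = c(200, 200), step = 2,
                             correlation_length = 10, cv = 0.3, seed = 1) {
  stopifnot_num(extent, "extent", min = 0)
  if (length(extent) != 2 || any(extent <= 0)) {
    stop("`extent` must be two positive lengths")
  }
  if (step <= 0) stop("`step` must be > 0")
  stopifnot_num(cv, "cv", min = 0)
  xs <- seq(0, extent[1], by = step)
  ys <- seq(0, extent[2], by = step)
  if (cv == 0) {
    m <- matrix(1, length(xs), length(ys))
  } else {
    m <- with_seed_opt(seed, {
      z <- matrix(stats::rnorm(length(xs) * length(ys)),
                  length(xs), length(ys))
      sig_cells <- correlation_length / step
      z <- gaussian_smooth_matrix(z, sig_cells)
      z <- (z - mean(z)) / stats::sd(z)
      sig_l <- sqrt(log(1 + cv^2))
      f <- exp(-sig_l^2 / 2 + sig_l * z)
      f <- f / mean(f)
      samp_cv <- stats::sd(f) / mean(f)
      f <- 1 + (f - 1) * (cv / samp_cv)
      f[f < 0.05] <- 0.05   # strict positivity guard, rarely binds
      f / mean(f)
    })
  }
  structure(
    list(m = m, xs = xs, ys = ys, step = step, extent = extent,
         correlation_length = correlation_length, cv = cv, seed = seed),
    class = "fluid_field"
  )
}

# Separable Gaussian smoothing by row/column band matrices, with per-node
# kernel renormalisation at the edges.
gaussian_smooth_matrix <- function(z, sigma_cells) {
  if (sigma_cells <= 0) return(z)
  smoother <- function(n) {
    idx <- seq_len(n)
    S <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sigma_cells))
    S / rowSums(S)
  }
  Sx <- smoother(nrow(z))
  Sy <- smoother(ncol(z))
  Sx %*% z %*% t(Sy)
}

#' @export
print.fluid_field <- function(x, ...) {
  cat(sprintf(
    "<fluid_field> %g x %g um, step %g um, corr. length %g um, cv %g (sample cv %.3f), seed %s\n",
    x$extent[1], x$extent[2], x$step, x$correlation_length, x$cv,
    stats::sd(x$m) / mean(x$m), format(x$seed)))
  invisible(x)
}

#' Sample the mobility field at a point
#'
#' Bilinear interpolation of the node grid; strictly positive. Queries
#' outside the field extent raise a bounds error.
#'
#' @param field a [make_mucus_field()] object.
#' @param x,y query position, um.
#' @return mobility multiplier, dimensionless (> 0).
#' @export
sample_mobility <- function(field, x, y) {
  stopifnot(inherits(field, "fluid_field"))
  if (x < 0 || x > field$extent[1] || y < 0 || y > field$extent[2]) {
    stop(sprintf("query (%g, %g) is outside the field extent [0, %g] x [0, %g]",
                 x, y, field$extent[1], field$extent[2]))
  }
  fx <- x / field$step
  fy <- y / field$step
  i0 <- min(floor(fx) + 1, length(field$xs) - 1)
  j0 <- min(floor(fy) + 1, length(field$ys) - 1)
  tx <- fx - (i0 - 1)
  ty <- fy - (j0 - 1)
  m <- field$m
  (1 - tx) * (1 - ty) * m[i0, j0] +
    tx * (1 - ty) * m[i0 + 1, j0] +
    (1 - tx) * ty * m[i0, j0 + 1] +
    tx * ty * m[i0 + 1, j0 + 1]
}

#' Export a mobility field as plain text
#'
#' Writes `<prefix>.tsv` (the node matrix, tab-separated) and
#' `<prefix>.json` (extent, step, correlation length, cv, seed).
#'
#' @param field a [make_mucus_field()] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_mucus_field <- function(field, prefix) {
  stopifnot(inherits(field, "fluid_field"))
  utils::write.table(field$m, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- field[c("step", "extent", "correlation_length", "cv", "seed")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a mobility field written by [write_mucus_field()]
#'
#' @param prefix path prefix used when writing.
#' @return a `fluid_field` object.
#' @export
read_mucus_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(m) <- NULL
  structure(
    list(m = m, xs = seq(0, meta$extent[1], by = meta$step),
         ys = seq(0, meta$extent[2], by = meta$step), step = meta$step,
         extent = meta$extent, correlation_length = meta$correlation_length,
         cv = meta$cv, seed = meta$seed),
    class = "fluid_field"
  )
}
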