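# Synthetic microscopy renderer: an anti-aliased dark disk (the 10 um
# microparticle) on a bright noisy background, one frame per trajectory
# sample. Used to exercise the tracking stage without any real video.

#' Rendering specification
#'
#' @param width,height frame size, px.
#' @param pixel_size pixel size, um/px.
#' @param radius_um particle radius, um (default 5: a 10 um diameter
#'   particle).
#' @param bg_intensity,particle_intensity background / particle intensities
#'   in 0..1 (particle darker by default).
#' @param noise_sd additive Gaussian intensity noise sd (>= 0).
#' @param seed integer seed; stacks are bit-identical per seed.
#' @return object of class `render_spec`.
#' @export
render_spec <- function(width = 256, height = 256, pixel_size = 0.5,
                        radius_um = 5, bg_intensity = 0.85,
                        particle_intensity = 0.15, noise_sd = 0, seed = 1) {
  if (width < 8 || height < 8) stop("frame must be at least 8 x 8 px")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (radius_um <= 0) stop("`radius_um` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  for (v in c(bg_intensity, particle_intensity)) {
    if (v < 0 || v > 1) stop("intensities must lie in [0, 1]")
  }
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 radius_um = radius_um, bg_intensity = bg_intensity,
                 particle_intensity = particle_intensity,
                 noise_sd = noise_sd, seed = seed),
            class = "render_spec")
}

# Draw one anti-aliased disk into a background matrix. Pixel (i, j) has its
# centre at (i - 0.5, j - 0.5) px; coverage ramps linearly over one pixel at
# the rim.
draw_disk <- function(frame, cx_px, cy_px, r_px, fg, bg) {
  i0 <- max(1L, floor(cx_px - r_px - 1)); i1 <- min(nrow(frame), ceiling(cx_px + r_px + 1))
  j0 <- max(1L, floor(cy_px - r_px - 1)); j1 <- min(ncol(frame), ceiling(cy_px + r_px + 1))
  ii <- i0:i1; jj <- j0:j1
  d <- sqrt(outer((ii - 0.5 - cx_px)^2, (jj - 0.5 - cy_px)^2, `+`))
  cov <- pmin(1, pmax(0, r_px + 0.5 - d))
  frame[ii, jj] <- frame[ii, jj] * (1 - cov) + fg * cov
  frame
}

#' Render a trajectory as a microscopy frame stack
#'
#' One frame per trajectory sample: an anti-aliased dark disk at the sample
#' position on a uniform bright background, plus seeded Gaussian intensity
#' noise clamped to [0, 1]. Deterministic per seed. Trajectories whose disk
#' would leave the frame are rejected.
#'
#' @param trajectory data frame with columns `t_s` (regularly sampled),
#'   `x_um`, `y_um` (e.g. from [simulate_propulsion()]).
#' @param spec a [render_spec()].
#' @return a [frame_stack()] with `fps = 1 / median(diff(t_s))`.
#' @export
render_frames <- function(trajectory, spec) {
  stopifnot(inherits(spec, "render_spec"))
  need <- c("t_s", "x_um", "y_um")
  if (!all(need %in% names(trajectory))) {
    stop("`trajectory` needs columns t_s, x_um, y_um")
  }
  if (nrow(trajectory) < 2) stop("trajectory needs at least 2 samples")
  ps <- spec$pixel_size
  r_px <- spec$radius_um / ps
  cx <- trajectory$x_um / ps
  cy <- trajectory$y_um / ps
  if (any(cx - r_px < 1) || any(cx + r_px > spec$width - 1) ||
      any(cy - r_px < 1) || any(cy + r_px > spec$height - 1)) {
    stop("trajectory leaves the frame (disk would touch or cross the border)")
  }
  fps <- 1 / stats::median(diff(trajectory$t_s))
  frames <- with_seed_opt(spec$seed, {
    lapply(seq_len(nrow(trajectory)), function(k) {
      fr <- matrix(spec$bg_intensity, spec$width, spec$height)
      fr <- draw_disk(fr, cx[k], cy[k], r_px,
                      spec$particle_intensity, spec$bg_intensity)
      if (spec$noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(length(fr), 0, spec$noise_sd),
                          nrow(fr), ncol(fr))
        fr[fr < 0] <- 0; fr[fr > 1] <- 1
      }
      fr
    })
  })
  frame_stack(frames, pixel_size = ps, fps = fps)
}

#' Write a frame stack as multi-page TIFF + JSON sidecar
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json` with `pixel_size_um` and `fps`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(stack$frames, path)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size, fps = stack$fps),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar next to it, or
#'   explicit `pixel_size` / `fps`).
#' @param pixel_size,fps overrides when no sidecar is present.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path, pixel_size = NULL, fps = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    fps <- fps %||% meta$fps
  }
  if (is.null(pixel_size) || is.null(fps)) {
    stop("no sidecar found; supply `pixel_size` and `fps`")
  }
  frame_stack(frames, pixel_size = pixel_size, fps = fps)
}
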