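# Image-analysis chain: Otsu thresholding + connected-component centroid
# tracking on grayscale frame stacks, instantaneous frame-to-frame
# velocities, the 60-point moving-average smoothing with the 3x-mean
# outlier rule, zero-intercept linear fits with R^2, and standard-error
# aggregation across trials.
#
# Image convention: a frame is a numeric matrix with intensities in [0, 1];
# the first index is x (px), the second y (px). Pixel (i, j) has its centre
# at (i - 0.5, j - 0.5) px, so centroids round-trip exactly with the
# renderer. The particle is darker than the background by default.

#' Frame stack
#'
#' @param frames list of >= 2 numeric matrices (equal dimensions,
#'   intensities in 0..1).
#' @param pixel_size pixel size, um/px.
#' @param fps frame rate, Hz (> 0).
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, fps) {
  if (!is.list(frames) || length(frames) < 2) {
    stop("`frames` must be a list of at least 2 matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions")
  }
  if (fps <= 0) stop("`fps` must be > 0")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size, fps = fps),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %g um/px, %g fps\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$fps))
  invisible(x)
}

#' Detect the particle centroid in one frame
#'
#' Thresholds the frame (Otsu), labels connected components, keeps the
#' component nearest the centre of `prior_bbox` (the largest component when
#' no prior is given) and returns its intensity-weighted centroid (weights
#' `1 - intensity` for a dark particle) together with a tight bounding box.
#'
#' @param frame numeric matrix, intensities in 0..1.
#' @param prior_bbox optional previous bounding box `c(x0, y0, x1, y1)` px,
#'   used to follow the same particle across frames.
#' @param polarity `"dark"` (default) for a particle darker than the
#'   background, `"bright"` for the reverse.
#' @param min_area minimum component area, px.
#' @return list with `centroid_px` (`c(x, y)`, pixel-centre coordinates) and
#'   `bbox` (`c(x0, y0, x1, y1)`, integer pixel indices). A component
#'   touching the image border raises a warning.
#' @export
detect_centroid <- function(frame, prior_bbox = NULL, polarity = "dark",
                            min_area = 9) {
  polarity <- match.arg(polarity, c("dark", "bright"))
  if (polarity == "bright") frame <- 1 - frame
  thr <- EBImage::otsu(EBImage::Image(frame), range = c(0, 1))
  mask <- frame < thr
  if (!any(mask)) stop("no particle detected: thresholded mask is empty")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) {
    stop("no particle detected: no component of at least ", min_area, " px")
  }
  if (!is.null(prior_bbox) && length(keep) > 1) {
    pc <- c((prior_bbox[1] + prior_bbox[3]) / 2,
            (prior_bbox[2] + prior_bbox[4]) / 2)
    cent <- vapply(keep, function(comp) {
      idx <- which(lab == comp, arr.ind = TRUE)
      c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5)
    }, numeric(2))
    comp <- keep[which.min(colSums((cent - pc)^2))]
  } else {
    comp <- keep[which.max(sizes[keep])]
  }
  idx <- which(lab == comp, arr.ind = TRUE)
  w <- 1 - frame[idx]
  if (sum(w) <= 0) w <- rep(1, nrow(idx))
  centroid <- c(x = sum(w * (idx[, 1] - 0.5)) / sum(w),
                y = sum(w * (idx[, 2] - 0.5)) / sum(w))
  bbox <- c(x0 = min(idx[, 1]), y0 = min(idx[, 2]),
            x1 = max(idx[, 1]), y1 = max(idx[, 2]))
  if (bbox[1] == 1 || bbox[2] == 1 ||
      bbox[3] == nrow(frame) || bbox[4] == ncol(frame)) {
    warning("detected component touches the image border")
  }
  list(centroid_px = centroid, bbox = bbox)
}

#' Track a particle across a frame stack
#'
#' Runs [detect_centroid()] on every frame, carrying each frame's bounding
#' box forward as the prior for the next, so the same particle is followed
#' even when several are present.
#'
#' @param stack a [frame_stack()].
#' @param polarity,min_area passed to [detect_centroid()].
#' @return data frame (class `swim_track`) with columns `frame`, `x_px`,
#'   `y_px`, `x_um`, `y_um`, `bbox_x0`, `bbox_y0`, `bbox_x1`, `bbox_y1`;
#'   attributes `pixel_size` and `fps`.
#' @export
track_frames <- function(stack, polarity = "dark", min_area = 9) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  out <- data.frame(frame = seq_len(n), x_px = NA_real_, y_px = NA_real_,
                    x_um = NA_real_, y_um = NA_real_,
                    bbox_x0 = NA_integer_, bbox_y0 = NA_integer_,
                    bbox_x1 = NA_integer_, bbox_y1 = NA_integer_)
  prior <- NULL
  for (i in seq_len(n)) {
    det <- detect_centroid(stack$frames[[i]], prior_bbox = prior,
                           polarity = polarity, min_area = min_area)
    out$x_px[i] <- det$centroid_px[1]
    out$y_px[i] <- det$centroid_px[2]
    out[i, c("bbox_x0", "bbox_y0", "bbox_x1", "bbox_y1")] <-
      as.list(det$bbox)
    prior <- det$bbox
  }
  out$x_um <- out$x_px * stack$pixel_size
  out$y_um <- out$y_px * stack$pixel_size
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "fps") <- stack$fps
  class(out) <- c("swim_track", "data.frame")
  out
}

#' Instantaneous frame-to-frame velocity
#'
#' \eqn{v_i = (p_{i+1} - p_i) \cdot fps} componentwise, with speed the
#' Euclidean norm. Times are placed at the midpoint between frames.
#'
#' @param track data frame with columns `x_um`, `y_um` (e.g. from
#'   [track_frames()]).
#' @param fps frame rate, Hz; defaults to the track's `fps` attribute.
#' @return data frame (class `velocity_series`) with columns `t_s`,
#'   `vx_um_s`, `vy_um_s`, `speed_um_s` and length `nrow(track) - 1`;
#'   attributes `cleaned = FALSE`, `smoothed = FALSE`.
#' @export
instantaneous_velocity <- function(track, fps = NULL) {
  fps <- fps %||% attr(track, "fps")
  if (is.null(fps) || fps <= 0) stop("`fps` must be supplied and > 0")
  n <- nrow(track)
  if (n < 2) stop("track needs at least 2 frames")
  vx <- diff(track$x_um) * fps
  vy <- diff(track$y_um) * fps
  out <- data.frame(
    t_s = (seq_len(n - 1) - 0.5) / fps,
    vx_um_s = vx, vy_um_s = vy,
    speed_um_s = sqrt(vx^2 + vy^2)
  )
  attr(out, "cleaned") <- FALSE
  attr(out, "smoothed") <- FALSE
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Outlier replacement and moving-average smoothing
#'
#' Two-stage conditioning of a speed series, in this order: (1) speeds
#' beyond `outlier_factor` times the series mean are set to that
#' (pre-replacement) mean; (2) a centered moving average of length `window`
#' is applied, with truncated windows at the edges. The rule is one-sided
#' (speeds are non-negative). Both stages are recorded in the `cleaned` /
#' `smoothed` attributes; `vx`/`vy` columns are left untouched.
#'
#' @param series a `velocity_series` from [instantaneous_velocity()].
#' @param window moving-average window, frames (>= 1). Default 60.
#' @param outlier_factor outlier threshold as a multiple of the mean speed.
#'   Default 3.
#' @return the series with `speed_um_s` conditioned; attributes `cleaned`,
#'   `smoothed`, `window`, `n_outliers` set.
#' @export
clean_and_smooth <- function(series, window = 60, outlier_factor = 3) {
  if (nrow(series) == 0) stop("empty velocity series")
  if (window < 1) stop("`window` must be >= 1")
  sp <- series$speed_um_s
  m <- mean(sp)
  out <- sp > outlier_factor * m
  sp[out] <- m
  sp <- moving_average(sp, window)
  series$speed_um_s <- sp
  attr(series, "cleaned") <- TRUE
  attr(series, "smoothed") <- TRUE
  attr(series, "window") <- window
  attr(series, "n_outliers") <- sum(out)
  series
}

#' Zero-intercept linear fit of a velocity profile
#'
#' Least-squares line through the origin, `U = slope * f`:
#' `slope = sum(f * U) / sum(f^2)`. The coefficient of determination is
#' `r2 = 1 - SS_res / SS_tot` with `SS_res` about the origin-constrained
#' line and `SS_tot` about the mean of `U` (so r2 <= 1, and a constant-`U`
#' profile, for which `SS_tot = 0`, yields `NA`).
#'
#' @param profile data frame with columns `f` (Hz) and `mean_v` (um/s), or a
#'   [aggregate_trials()] result. At least 2 frequencies, not all zero.
#' @return object of class `linear_fit`: list with `slope` (um/s per Hz),
#'   `r2`, `n`.
#' @export
#' @examples
#' fit_through_origin(data.frame(f = 1:10, mean_v = 2 * (1:10)))
fit_through_origin <- function(profile) {
  f <- profile$f
  U <- profile$mean_v %||% profile$v
  if (is.null(f) || is.null(U)) {
    stop("`profile` must have columns `f` and `mean_v`")
  }
  if (length(f) < 2) stop("need at least 2 frequencies")
  if (all(f == 0)) stop("all frequencies are zero")
  slope <- sum(f * U) / sum(f^2)
  ss_res <- sum((U - slope * f)^2)
  ss_tot <- sum((U - mean(U))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  structure(list(slope = slope, r2 = r2, n = length(f)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4g um/s per Hz, R^2 = %.4g (n = %d)\n",
              x$slope, x$r2, x$n))
  invisible(x)
}

#' Aggregate per-trial velocities into a profile
#'
#' Mean across trials per frequency with the standard error
#' `SE = sd / sqrt(n)`. A single trial is reported with `SE = 0` and flagged
#' via the `single_trial` attribute.
#'
#' @param f strictly increasing frequency grid, Hz.
#' @param trials list of per-trial velocity vectors (each `length(f)`), or a
#'   trials x frequencies matrix.
#' @return data frame (class `velocity_profile`) with columns `f`, `mean_v`,
#'   `se`, `n`.
#' @export
#' @examples
#' aggregate_trials(5, list(1, 2, 3))  # mean 2, se 1/sqrt(3)
aggregate_trials <- function(f, trials) {
  if (length(trials) == 0) stop("no trials supplied")
  if (is.list(trials)) trials <- do.call(rbind, trials)
  trials <- as.matrix(trials)
  if (ncol(trials) != length(f)) {
    stop("each trial must have one velocity per frequency")
  }
  if (length(f) > 1 && any(diff(f) <= 0)) {
    stop("`f` must be strictly increasing")
  }
  n <- nrow(trials)
  out <- data.frame(
    f = f,
    mean_v = colMeans(trials),
    se = if (n > 1) apply(trials, 2, stats::sd) / sqrt(n) else rep(0, length(f)),
    n = n
  )
  attr(out, "single_trial") <- n == 1
  class(out) <- c("velocity_profile", "data.frame")
  out
}

#' Write a velocity profile to CSV
#'
#' @param profile a `velocity_profile` from [aggregate_trials()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
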