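#' Rostro-caudal axis annotation for one sample
#'
#' Defines the coordinate system along which intensity is profiled: an
#' origin (the posterior reference point), a polyline running posterior to
#' anterior in pixel coordinates, and a unit length in pixels (typically
#' posterior tip to the most recent somite boundary).  Axial position of a
#' pixel is the arclength of its orthogonal projection onto the polyline,
#' measured from the origin's own projection, divided by `unit_length`.
#'
#' @param origin numeric length-2 pixel point (posterior reference).
#' @param polyline n x 2 numeric matrix of pixel points, posterior first.
#' @param unit_length positive scalar in pixels normalizing position to
#'   `[0, 1]`.
#' @return object of class `axis_spec`.
#' @export
axis_spec <- function(origin, polyline, unit_length) {
  polyline <- rbind(polyline)
  storage.mode(polyline) <- "double"
  stopifnot(length(origin) == 2, is.finite(origin),
            ncol(polyline) == 2, nrow(polyline) >= 2,
            is.finite(polyline),
            is.numeric(unit_length), length(unit_length) == 1,
            unit_length > 0)
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0))
    stop("consecutive polyline points must be distinct")
  structure(list(origin = as.numeric(origin), polyline = polyline,
                 unit_length = as.numeric(unit_length),
                 seg_lengths = seglen,
                 cum_lengths = c(0, cumsum(seglen))),
            class = "axis_spec")
}

#' Region-of-interest polygon mask
#'
#' @param polygon n x 2 numeric matrix of pixel vertices of a simple
#'   (non-self-intersecting) polygon; closure is implicit.
#' @param sample_id identifier string.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(polygon, sample_id = "sample") {
  polygon <- rbind(polygon)
  storage.mode(polygon) <- "double"
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3, is.finite(polygon))
  # drop an explicitly repeated closing vertex
  n <- nrow(polygon)
  if (all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  a <- polygon_area(polygon)
  if (a <= 0) stop("ROI polygon must have positive area")
  structure(list(polygon = polygon, sample_id = as.character(sample_id)),
            class = "roi_mask")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' One sample's intensity-versus-position profile
#'
#' @param sample_id identifier string.
#' @param channel channel name (e.g. `"Lfng_i"`, `"Dll1"`, `"Notch1"`).
#' @param positions strictly increasing bin centers on `[0, 1]`
#'   (0 = posterior, 1 = anterior).
#' @param intensities non-negative fluorescence values, same length.
#' @param normalized has [normalize_profile()] been applied?
#' @param interpolated_bins integer indices of bins whose value was
#'   filled by interpolation (empty bins during extraction).
#' @return object of class `spatial_profile`.
#' @export
spatial_profile <- function(sample_id, channel, positions, intensities,
                            normalized = FALSE,
                            interpolated_bins = integer(0)) {
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  stopifnot(length(positions) == length(intensities),
            length(positions) >= 2,
            all(diff(positions) > 0),
            all(is.finite(intensities)), all(intensities >= 0))
  structure(list(sample_id = as.character(sample_id),
                 channel = as.character(channel),
                 positions = positions, intensities = intensities,
                 normalized = isTRUE(normalized),
                 interpolated_bins = as.integer(interpolated_bins)),
            class = "spatial_profile")
}

#' @export
print.spatial_profile <- function(x, ...) {
  cat(sprintf("Spatial profile: sample %s, channel %s, %d bins%s\n",
              x$sample_id, x$channel, length(x$positions),
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  positions [%.3g, %.3g], intensity range [%.3g, %.3g]\n",
              min(x$positions), max(x$positions),
              min(x$intensities), max(x$intensities)))
  if (length(x$interpolated_bins))
    cat(sprintf("  %d bin(s) filled by interpolation\n",
                length(x$interpolated_bins)))
  invisible(x)
}

#' Project a z-stack to a single plane
#'
#' @param stack 3-D numeric array (y, x, z) or a 2-D matrix (returned
#'   unchanged).
#' @param method `"max"` (default; preserves thin expression bands),
#'   `"mean"` or `"sum"`.
#' @return 2-D numeric matrix with the stack's x-y shape.
#' @export
project_stack <- function(stack, method = c("max", "mean", "sum")) {
  method <- match.arg(method)
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (dim(stack)[3] < 1) stop("stack has no z-planes")
  if (dim(stack)[3] == 1) return(stack[, , 1])
  f <- switch(method, max = max, mean = mean, sum = sum)
  apply(stack, c(1, 2), f)
}

#' Subtract background and threshold to a control level
#'
#' Each pixel `p` maps to `max(p - control_level, 0)`: background is
#' removed and everything at or below the no-primary control level is
#' zeroed, so only signal exceeding the staining control survives.
#'
#' @param image 2-D numeric matrix.
#' @param control_level non-negative scalar background/threshold level,
#'   typically from [control_level()] on a no-primary control sample.
#' @return matrix of the same shape.
#' @export
subtract_background <- function(image, control_level) {
  stopifnot(is.numeric(image), length(control_level) == 1,
            is.finite(control_level))
  if (control_level < 0) stop("`control_level` must be non-negative")
  pmax(image - control_level, 0)
}

#' Summarize a no-primary control ROI into a scalar level
#'
#' @param image 2-D numeric matrix (the no-primary control image).
#' @param roi [roi_mask()] within the control image.
#' @param statistic `"mean"` (default) or `"percentile"`.
#' @param q percentile in `[0, 100]` when `statistic = "percentile"`.
#' @return non-negative scalar.
#' @export
control_level <- function(image, roi, statistic = c("mean", "percentile"),
                          q = 95) {
  statistic <- match.arg(statistic)
  px <- roi_pixels(image, roi)
  if (length(px$values) == 0) stop("ROI contains no pixel centers")
  switch(statistic,
         mean = mean(px$values),
         percentile = unname(stats::quantile(px$values, q / 100,
                                             type = 7)))
}

# Pixel centers inside the ROI polygon, with values.  Pixel (r, c) of the
# matrix has center (x, y) = (c - 0.5, r - 0.5): centers at integer + 0.5
# in a 0-based pixel grid; containment is center-in-polygon.
roi_pixels <- function(image, roi) {
  stopifnot(inherits(roi, "roi_mask"), is.matrix(image))
  poly <- roi$polygon
  rr <- max(1L, floor(min(poly[, 2]) + 0.5)):min(nrow(image),
                                                 ceiling(max(poly[, 2]) + 0.5))
  cc <- max(1L, floor(min(poly[, 1]) + 0.5)):min(ncol(image),
                                                 ceiling(max(poly[, 1]) + 0.5))
  if (length(rr) == 0 || length(cc) == 0)
    return(list(x = numeric(0), y = numeric(0), values = numeric(0)))
  grid <- expand.grid(r = rr, c = cc)
  x <- grid$c - 0.5
  y <- grid$r - 0.5
  bnd <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(bnd, cbind(x, y))
  list(x = x[inside], y = y[inside],
       values = image[cbind(grid$r[inside], grid$c[inside])])
}

# Arclength of the orthogonal projection of points onto an axis polyline,
# measured from the polyline start (pixels).
project_arclength <- function(x, y, axis) {
  pl <- axis$polyline
  nseg <- nrow(pl) - 1
  best_d2 <- rep(Inf, length(x))
  best_s <- rep(NA_real_, length(x))
  for (s in seq_len(nseg)) {
    p1 <- pl[s, ]; d <- pl[s + 1, ] - p1
    len2 <- sum(d^2)
    t <- pmin(pmax(((x - p1[1]) * d[1] + (y - p1[2]) * d[2]) / len2, 0), 1)
    fx <- p1[1] + t * d[1]; fy <- p1[2] + t * d[2]
    d2 <- (x - fx)^2 + (y - fy)^2
    take <- d2 < best_d2
    best_d2[take] <- d2[take]
    best_s[take] <- axis$cum_lengths[s] + t[take] * axis$seg_lengths[s]
  }
  best_s
}

#' Extract an intensity-versus-position profile from an annotated image
#'
#' Every pixel center inside the ROI is assigned the normalized arclength
#' coordinate of its orthogonal projection onto the axis polyline (offset
#' by the origin's projection, divided by `unit_length`); coordinates
#' outside `[0, 1]` are discarded.  The profile value in bin `i` is the
#' mean of pixel values assigned to the half-open bin
#' `[i/n, (i+1)/n)` (last bin closed).  Empty bins are filled by linear
#' interpolation between neighboring non-empty bins (nearest value at the
#' ends) and recorded in `interpolated_bins`.
#'
#' @param image 2-D numeric matrix (background-subtracted).
#' @param roi [roi_mask()].
#' @param axis [axis_spec()].
#' @param n_bins number of axial bins (>= 2).
#' @param sample_id,channel labels for the resulting profile.
#' @return a [spatial_profile()] on bin centers `(i - 0.5) / n_bins`.
#' @export
extract_profile <- function(image, roi, axis, n_bins = 100L,
                            sample_id = roi$sample_id, channel = "channel") {
  stopifnot(inherits(axis, "axis_spec"), n_bins >= 2)
  n_bins <- as.integer(n_bins)
  px <- roi_pixels(image, roi)
  if (length(px$values) == 0) stop("ROI contains no pixel centers")
  s0 <- project_arclength(axis$origin[1], axis$origin[2], axis)
  coord <- (project_arclength(px$x, px$y, axis) - s0) / axis$unit_length
  keep <- coord >= 0 & coord <= 1
  if (!any(keep))
    stop("no ROI pixel projects into [0, 1] along the axis")
  coord <- coord[keep]
  vals <- px$values[keep]
  bin <- pmin(floor(coord * n_bins), n_bins - 1L) + 1L
  means <- vapply(split(vals, factor(bin, levels = seq_len(n_bins))),
                  function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  empty <- which(is.na(means))
  if (length(empty) == n_bins) stop("all bins are empty")
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  if (length(empty)) {
    filled <- which(!is.na(means))
    means[empty] <- stats::approx(centers[filled], means[filled],
                                  xout = centers[empty], rule = 2)$y
  }
  spatial_profile(sample_id = sample_id, channel = channel,
                  positions = centers, intensities = pmax(means, 0),
                  interpolated_bins = empty)
}

#' Normalize an intensity profile
#'
#' `mode = "max"` (default) divides by the peak intensity so the maximum
#' becomes 1; `mode = "area"` divides by the trapezoidal integral of the
#' profile over its positions so the integral becomes 1.
#'
#' @param profile a [spatial_profile()] with at least one positive value.
#' @param mode `"max"` or `"area"`.
#' @return the normalized [spatial_profile()] (`normalized` flag set).
#' @export
normalize_profile <- function(profile, mode = c("max", "area")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "spatial_profile"))
  y <- profile$intensities
  if (all(y == 0)) stop("cannot normalize an all-zero profile")
  denom <- if (mode == "max") max(y) else trapezoid(profile$positions, y)
  if (denom <= 0) stop("normalization denominator is not positive")
  profile$intensities <- y / denom
  profile$normalized <- TRUE
  profile
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Classify a clock-gene profile into a phase of the clock cycle
#'
#' The expression band is the set of bins at or above
#' `threshold_fraction` times the profile maximum.  Its intensity-weighted
#' centroid `c` (on the `[0, 1]` axis, 0 = posterior) determines the
#' phase: `c < 1/3` is Phase 1 (posterior band), `1/3 <= c < 2/3` Phase 2,
#' `c >= 2/3` Phase 3 (anterior band).  The thirds are an explicit
#' convention mirroring the usual by-eye phase calls on *Lfng* band
#' position.
#'
#' @param profile a [spatial_profile()] with a positive maximum.
#' @param threshold_fraction band threshold as a fraction of the maximum,
#'   in `(0, 1)`; default 0.5.
#' @return object of class `phase_call`: list with integer `phase`
#'   (1, 2 or 3), band `centroid` and fractional band `width`.
#' @export
assign_phase <- function(profile, threshold_fraction = 0.5) {
  stopifnot(inherits(profile, "spatial_profile"),
            threshold_fraction > 0, threshold_fraction < 1)
  y <- profile$intensities
  if (max(y) <= 0) stop("profile has no positive intensity")
  band <- y >= threshold_fraction * max(y)
  centroid <- sum(profile$positions[band] * y[band]) / sum(y[band])
  width <- sum(band) / length(y)
  phase <- if (centroid < 1 / 3) 1L else if (centroid < 2 / 3) 2L else 3L
  structure(list(phase = phase, centroid = centroid, width = width,
                 sample_id = profile$sample_id),
            class = "phase_call")
}

#' @export
print.phase_call <- function(x, ...) {
  cat(sprintf("Phase %d (band centroid %.3f, width %.3f) - sample %s\n",
              x$phase, x$centroid, x$width, x$sample_id))
  invisible(x)
}
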