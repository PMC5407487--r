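#' Intensity matrix f(i, j) for one channel across a cohort
#'
#' Element `(i, j)` is the intensity at the i-th spatial bin of the j-th
#' sample; columns are samples, rows are positions along the normalized
#' rostro-caudal axis.
#'
#' @param values N x M numeric matrix, finite and non-negative.
#' @param bin_centers length-N strictly increasing vector on `[0, 1]`.
#' @param sample_ids length-M unique character vector naming the columns.
#' @param channel channel name.
#' @param normalized were the source profiles normalized?
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, bin_centers, sample_ids, channel,
                             normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  stopifnot(nrow(values) >= 2, ncol(values) >= 1,
            all(is.finite(values)), all(values >= 0),
            length(bin_centers) == nrow(values),
            all(diff(bin_centers) > 0),
            length(sample_ids) == ncol(values))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(values) <- list(NULL, sample_ids)
  structure(list(values = values, bin_centers = as.numeric(bin_centers),
                 sample_ids = sample_ids, channel = as.character(channel),
                 normalized = isTRUE(normalized)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("Intensity matrix: channel %s, %d bins x %d samples%s\n",
              x$channel, nrow(x$values), ncol(x$values),
              if (x$normalized) " (normalized profiles)" else ""))
  invisible(x)
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

# Piecewise-linear interpolation with *linear* extrapolation beyond the
# endpoints (using the terminal segment slopes), so resampling is exact
# for affine profiles on any grid pair.
lin_resample <- function(x, y, xout) {
  n <- length(x)
  if (n == 1) return(rep(y, length(xout)))
  idx <- findInterval(xout, x, all.inside = TRUE)
  x0 <- x[idx]; x1 <- x[idx + 1]
  y0 <- y[idx]; y1 <- y[idx + 1]
  y0 + (y1 - y0) * (xout - x0) / (x1 - x0)
}

#' Place profiles side by side as an intensity matrix
#'
#' Each profile is resampled by linear interpolation onto the common grid
#' of `n_bins` bin centers `(i - 0.5) / n_bins`; column j holds the j-th
#' profile in input order.  All profiles must share one channel and one
#' normalization state.
#'
#' @param profiles list of [spatial_profile()]s.
#' @param n_bins number of bins of the common grid.
#' @return an [intensity_matrix()].
#' @export
build_matrix <- function(profiles, n_bins = 100L) {
  stopifnot(length(profiles) >= 1, n_bins >= 2)
  ok <- vapply(profiles, inherits, logical(1), what = "spatial_profile")
  if (!all(ok)) stop("all inputs must be spatial_profile objects")
  chans <- unique(vapply(profiles, `[[`, character(1), "channel"))
  if (length(chans) != 1)
    stop("profiles mix channels: ", paste(chans, collapse = ", "))
  norm <- unique(vapply(profiles, `[[`, logical(1), "normalized"))
  if (length(norm) != 1)
    stop("profiles mix normalized and raw intensities")
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  vals <- vapply(profiles, function(p)
    lin_resample(p$positions, p$intensities, centers), numeric(n_bins))
  intensity_matrix(pmax(vals, 0), centers, ids, chans, normalized = norm)
}
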