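#' Ordered kymograph of snapshot profiles
#'
#' A kymograph stacks the one-dimensional spatial profiles of a cohort in
#' inferred temporal order: row r (temporal rank r, counted from 0 and
#' increasing downward when displayed) holds the profile of the sample at
#' rank r.  An n-cycle kymograph tiles the one-cycle stack to visualize
#' multiple simulated oscillations.
#'
#' @param values R x N numeric matrix, one profile per row.
#' @param bin_centers length-N axial bin centers on `[0, 1]`.
#' @param sample_ids length-R sample ids (repeating across cycles).
#' @param cycle length-R integer cycle index (1-based) of each row.
#' @param channel channel name.
#' @param n_cycles number of tiled cycles (1 = unextended).
#' @return object of class `kymograph`.
#' @export
kymograph <- function(values, bin_centers, sample_ids, cycle, channel,
                      n_cycles = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n_cycles <- as.integer(n_cycles)
  stopifnot(nrow(values) >= 1, length(bin_centers) == ncol(values),
            length(sample_ids) == nrow(values),
            length(cycle) == nrow(values), n_cycles >= 1,
            nrow(values) %% n_cycles == 0)
  structure(list(values = values, bin_centers = as.numeric(bin_centers),
                 sample_ids = as.character(sample_ids),
                 cycle = as.integer(cycle),
                 rank = seq_len(nrow(values)) - 1L,
                 channel = as.character(channel), n_cycles = n_cycles),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: channel %s, %d rows (%d samples x %d cycle%s), %d bins\n",
              x$channel, nrow(x$values), nrow(x$values) / x$n_cycles,
              x$n_cycles, if (x$n_cycles > 1) "s" else "",
              ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.kymograph <- function(x, ...) x$values

#' Build an ordered kymograph from an intensity matrix
#'
#' Row at rank r is the column of `matrix` for the sample at rank r of
#' the ordering (identity if `ordering` is `NULL`).
#'
#' @param matrix an [intensity_matrix()].
#' @param ordering a `snapshot_ordering` from [infer_order()], an integer
#'   permutation (rank -> column), or `NULL` for input order.
#' @return a [kymograph()] with `n_cycles = 1`.
#' @export
build_kymograph <- function(matrix, ordering = NULL) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  M <- ncol(matrix$values)
  perm <- if (is.null(ordering)) seq_len(M)
          else if (inherits(ordering, "snapshot_ordering")) {
            if (ordering$M != M)
              stop("ordering length does not match the matrix")
            match(ordering$sample_ids, matrix$sample_ids)
          } else as.integer(ordering)
  if (length(perm) != M || anyDuplicated(perm) || anyNA(perm) ||
      any(perm < 1) || any(perm > M))
    stop("`ordering` must be a permutation matching the matrix samples")
  kymograph(t(matrix$values[, perm, drop = FALSE]), matrix$bin_centers,
            matrix$sample_ids[perm], rep(1L, M), matrix$channel)
}

#' Periodic extension of a one-cycle kymograph
#'
#' Tiles the rows `n_cycles` times in order — exact repetition, no
#' resampling or smoothing — so the one inferred cycle is displayed as a
#' sustained oscillation.  The row of copy c at original rank r gets
#' rank `c*M + r`; sample ids are preserved per copy.
#'
#' @param kymo a [kymograph()] with `n_cycles = 1`.
#' @param n_cycles number of cycles (>= 1); 1 returns the input.
#' @return the extended [kymograph()].
#' @export
periodic_extension <- function(kymo, n_cycles) {
  stopifnot(inherits(kymo, "kymograph"))
  if (n_cycles < 1) stop("`n_cycles` must be >= 1")
  if (kymo$n_cycles != 1)
    stop("input kymograph is already extended")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles == 1) return(kymo)
  M <- nrow(kymo$values)
  idx <- rep(seq_len(M), n_cycles)
  kymograph(kymo$values[idx, , drop = FALSE], kymo$bin_centers,
            kymo$sample_ids[idx], rep(seq_len(n_cycles), each = M),
            kymo$channel, n_cycles = n_cycles)
}

# Resolve crop windows into row/column index vectors.
kymo_window <- function(kymo, crop_axial = NULL, crop_rank = NULL) {
  cols <- seq_along(kymo$bin_centers)
  if (!is.null(crop_axial)) {
    stopifnot(length(crop_axial) == 2)
    cols <- which(kymo$bin_centers >= crop_axial[1] &
                    kymo$bin_centers <= crop_axial[2])
    if (length(cols) == 0) stop("axial crop window contains no bins")
  }
  rows <- seq_len(nrow(kymo$values))
  if (!is.null(crop_rank)) {
    stopifnot(length(crop_rank) == 2)
    rows <- which(kymo$rank >= crop_rank[1] & kymo$rank <= crop_rank[2])
    if (length(rows) == 0) stop("rank crop window contains no rows")
  }
  list(rows = rows, cols = cols)
}

#' Render a kymograph to a PNG heat map
#'
#' Writes a raster image with x = normalized axial position (anterior to
#' the right) and y = temporal rank increasing downward.  Intensities
#' are mapped linearly onto the palette over the (cropped) value range;
#' optional per-row max-normalization highlights band position when
#' absolute levels differ between rows.  Rendering is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param kymo a [kymograph()].
#' @param path output PNG path.
#' @param palette vector of colors (default 256-step inferno).
#' @param crop_axial optional `c(lo, hi)` axial window on `[0, 1]`
#'   (bins with centers inside are kept), reproducing magnified views of
#'   e.g. the caudal PSM.
#' @param crop_rank optional `c(lo, hi)` window of temporal ranks.
#' @param per_row_norm divide each row by its own maximum before color
#'   mapping (off by default).
#' @param scale integer pixel-replication factor for display.
#' @return invisibly, the path.
#' @export
render_kymograph <- function(kymo, path,
                             palette = grDevices::hcl.colors(256, "Inferno"),
                             crop_axial = NULL, crop_rank = NULL,
                             per_row_norm = FALSE, scale = 1L) {
  stopifnot(inherits(kymo, "kymograph"), nrow(kymo$values) >= 1)
  w <- kymo_window(kymo, crop_axial, crop_rank)
  v <- kymo$values[w$rows, w$cols, drop = FALSE]
  if (per_row_norm) {
    mx <- apply(v, 1, max)
    v <- v / ifelse(mx > 0, mx, 1)
  }
  rng <- range(v)
  u <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
       else matrix(0, nrow(v), ncol(v))
  idx <- pmin(floor(u * length(palette)) + 1L, length(palette))
  rgb <- grDevices::col2rgb(palette[idx]) / 255
  img <- array(0, dim = c(nrow(v), ncol(v), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(v), ncol(v))
  img[, , 2] <- matrix(rgb[2, ], nrow(v), ncol(v))
  img[, , 3] <- matrix(rgb[3, ], nrow(v), ncol(v))
  scale <- as.integer(scale)
  if (scale > 1)
    img <- img[rep(seq_len(nrow(v)), each = scale),
               rep(seq_len(ncol(v)), each = scale), , drop = FALSE]
  png::writePNG(img, target = path)
  invisible(path)
}

#' Plot a kymograph on the current graphics device
#'
#' @param x a [kymograph()].
#' @param col color palette.
#' @param crop_axial,crop_rank optional windows as in
#'   [render_kymograph()].
#' @param per_row_norm per-row max normalization before display.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, col = grDevices::hcl.colors(256, "Inferno"),
                           crop_axial = NULL, crop_rank = NULL,
                           per_row_norm = FALSE, ...) {
  w <- kymo_window(x, crop_axial, crop_rank)
  v <- x$values[w$rows, w$cols, drop = FALSE]
  if (per_row_norm) {
    mx <- apply(v, 1, max)
    v <- v / ifelse(mx > 0, mx, 1)
  }
  # time runs downward: flip the rank axis
  graphics::image(x$bin_centers[w$cols], x$rank[w$rows],
                  t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = col, xlab = "axial position (P → A)",
                  ylab = "temporal rank", yaxt = "n",
                  main = sprintf("%s kymograph", x$channel), ...)
  at <- pretty(x$rank[w$rows])
  graphics::axis(2, at = at,
                 labels = rev(range(x$rank[w$rows]))[1] -
                   at + min(x$rank[w$rows]))
  invisible(x)
}
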