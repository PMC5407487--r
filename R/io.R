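# Deterministic float formatting for CSV writers: 17 significant digits
# round-trips doubles exactly and is stable across runs.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write profiles to a long-format CSV
#'
#' Columns: `sample_id, channel, position, intensity, normalized`.
#' Multiple profiles (and channels) may share one file.
#'
#' @param profiles a [spatial_profile()] or list of them.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "spatial_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(sample_id = p$sample_id, channel = p$channel,
               position = fmt_num(p$positions),
               intensity = fmt_num(p$intensities),
               normalized = p$normalized))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read profiles from a long-format CSV
#'
#' @param path CSV written by [write_profiles_csv()].
#' @return list of [spatial_profile()]s, one per (sample_id, channel),
#'   in order of first appearance.
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "channel", "position", "intensity", "normalized")
  if (!all(need %in% names(d)))
    stop("profile CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(d$sample_id, d$channel, sep = "\r")
  lapply(split(d, factor(key, levels = unique(key))), function(g)
    spatial_profile(g$sample_id[1], g$channel[1],
                    as.numeric(g$position), as.numeric(g$intensity),
                    normalized = isTRUE(as.logical(g$normalized[1]))))
}

#' Write an intensity matrix to CSV (plus sidecar JSON)
#'
#' First column `bin_center`, then one column per sample id.  The
#' sidecar (`<path minus .csv>.json`) records channel, normalization
#' state and provenance.
#'
#' @param m an [intensity_matrix()].
#' @param path output CSV path.
#' @param sidecar write the sidecar JSON next to the CSV?
#' @return invisibly, the path.
#' @export
write_matrix_csv <- function(m, path, sidecar = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  d <- data.frame(bin_center = fmt_num(m$bin_centers),
                  apply(m$values, 2, fmt_num),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (sidecar)
    jsonlite::write_json(
      list(channel = m$channel, normalized = m$normalized,
           n_bins = nrow(m$values), sample_ids = m$sample_ids,
           tool = paste0("kymoclock ", utils::packageVersion("kymoclock"))),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read an intensity matrix from CSV
#'
#' @param path CSV written by [write_matrix_csv()]; the sidecar JSON is
#'   consulted for the channel if present.
#' @param channel channel name override.
#' @return an [intensity_matrix()].
#' @export
read_matrix_csv <- function(path, channel = NULL) {
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) != 1)
    stop("ragged CSV: rows have differing field counts in ", path)
  d <- utils::read.csv(path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (names(d)[1] != "bin_center")
    stop("matrix CSV must start with a `bin_center` column")
  if (ncol(d) < 2) stop("matrix CSV contains no sample columns")
  normalized <- FALSE
  if (is.null(channel)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      channel <- meta$channel
      normalized <- isTRUE(meta$normalized)
    } else channel <- "unknown"
  }
  intensity_matrix(as.matrix(d[, -1, drop = FALSE]),
                   as.numeric(d$bin_center), names(d)[-1], channel,
                   normalized = normalized)
}

#' Write an ordering fit to JSON (and its trace to CSV)
#'
#' @param fit a `snapshot_ordering` from [infer_order()].
#' @param path output JSON path.
#' @param trace_path optional CSV path for the per-iteration trace
#'   (`iteration, current_g, best_g, temperature`).
#' @return invisibly, the path.
#' @export
write_ordering_json <- function(fit, path, trace_path = NULL) {
  stopifnot(inherits(fit, "snapshot_ordering"))
  if (!is.null(trace_path) && !is.null(fit$trace)) {
    tr <- as.data.frame(fit$trace)
    tr[] <- lapply(tr, fmt_num)
    utils::write.csv(tr, trace_path, row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(channel = fit$channel,
         permutation = fit$sample_ids,
         objective = fit$objective,
         n_admissible_rows = fit$n_admissible_rows,
         method = fit$method,
         lags = fit$lags, period = fit$period, seed = fit$seed,
         config = fit$control[c("iterations", "cooling_factor",
                                "proposal", "restarts")],
         trace_file = if (!is.null(trace_path)) basename(trace_path)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an ordering JSON
#'
#' @param path JSON written by [write_ordering_json()].
#' @return list with `channel`, `permutation` (sample ids in rank
#'   order), `objective` and the stored configuration.
#' @export
read_ordering_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a kymograph to CSV (plus sidecar JSON)
#'
#' Columns `rank, sample_id, cycle, bin_0 ... bin_{N-1}`; the sidecar
#' stores `bin_centers`, channel and cycle count.
#'
#' @param kymo a [kymograph()].
#' @param path output CSV path.
#' @param sidecar write the sidecar JSON?
#' @return invisibly, the path.
#' @export
write_kymograph_csv <- function(kymo, path, sidecar = TRUE) {
  stopifnot(inherits(kymo, "kymograph"))
  vals <- apply(kymo$values, 2, fmt_num)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- sprintf("bin_%d", seq_len(ncol(kymo$values)) - 1L)
  d <- data.frame(rank = kymo$rank, sample_id = kymo$sample_ids,
                  cycle = kymo$cycle, vals, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (sidecar)
    jsonlite::write_json(
      list(channel = kymo$channel, n_cycles = kymo$n_cycles,
           bin_centers = kymo$bin_centers),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph from CSV
#'
#' @param path CSV written by [write_kymograph_csv()].
#' @return a [kymograph()].
#' @export
read_kymograph_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  bins <- grep("^bin_", names(d))
  if (length(bins) == 0) stop("kymograph CSV has no bin_* columns")
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc))
    jsonlite::read_json(sc, simplifyVector = TRUE)
  else list(channel = "unknown", n_cycles = max(d$cycle),
            bin_centers = (seq_along(bins) - 0.5) / length(bins))
  kymograph(as.matrix(d[, bins, drop = FALSE]), meta$bin_centers,
            d$sample_id, d$cycle, meta$channel,
            n_cycles = meta$n_cycles)
}

#' Read a per-sample annotation JSON
#'
#' Expected keys: `sample_id`, `roi` (list of `[x, y]` pixel vertices),
#' `axis` (`origin`, `polyline`, `unit_length`), optional `control_of`
#' naming the no-primary control sample this annotation belongs to, and
#' optional `channels` (names for the image planes).
#'
#' @param path JSON path.
#' @return list with `sample_id`, `roi` ([roi_mask()]),
#'   `axis` ([axis_spec()]), `control_of`, `channels`.
#' @export
read_annotations <- function(path) {
  a <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sample_id", "roi", "axis")
  if (!all(need %in% names(a)))
    stop("annotation JSON must contain keys: ",
         paste(need, collapse = ", "))
  list(sample_id = a$sample_id,
       roi = roi_mask(rbind(a$roi), sample_id = a$sample_id),
       axis = axis_spec(unlist(a$axis$origin), rbind(a$axis$polyline),
                        a$axis$unit_length),
       control_of = a$control_of,
       channels = a$channels)
}

#' Parse channel metadata from an OME-XML description
#'
#' Extracts `SizeC`, `SizeZ`, `DimensionOrder` and channel names from
#' the `Pixels`/`Channel` elements of an OME-XML document (as embedded
#' in the ImageDescription tag of an OME-TIFF).
#'
#' @param xml OME-XML document as a string.
#' @return list with `size_c`, `size_z`, `dimension_order`,
#'   `channel_names`.
#' @export
parse_ome_channels <- function(xml) {
  doc <- xml2::read_xml(xml)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, "//Pixels")
  if (inherits(px, "xml_missing")) stop("no <Pixels> element in OME-XML")
  ch <- xml2::xml_find_all(doc, "//Channel")
  nm <- xml2::xml_attr(ch, "Name")
  id <- xml2::xml_attr(ch, "ID")
  nm[is.na(nm)] <- id[is.na(nm)]
  list(size_c = as.integer(xml2::xml_attr(px, "SizeC") %||% "1"),
       size_z = as.integer(xml2::xml_attr(px, "SizeZ") %||% "1"),
       dimension_order = xml2::xml_attr(px, "DimensionOrder") %||%
         "XYCZT",
       channel_names = nm)
}

#' Read a channel from a TIFF / OME-TIFF file
#'
#' Reads the requested channel as a z-stack (or single plane).  Channels
#' are located from OME-XML metadata when the file carries it (names and
#' plane layout), otherwise planes are assumed channel-interleaved with
#' `n_channels` channels (default 1, i.e. all planes are z).  A plane
#' with a third array dimension (e.g. RGB) is treated as
#' channel-in-plane.
#'
#' @param path TIFF path.
#' @param channel channel index (integer) or name (character; requires
#'   OME metadata or `channel_names`).
#' @param z_policy `"keep"` for the full stack, or `"project:max"`,
#'   `"project:mean"`, `"project:sum"` to z-project.
#' @param n_channels number of interleaved channels when no metadata is
#'   present.
#' @param channel_names optional names for the channels, overriding
#'   metadata (e.g. from an annotation sidecar).
#' @return 2-D matrix or 3-D array (y, x, z) of intensities, as stored
#'   (integer TIFFs are read as-is, not rescaled).
#' @export
read_image <- function(path, channel = 1L, z_policy = "keep",
                       n_channels = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("cannot read TIFF ", path, ": ",
                             conditionMessage(e)))
  desc <- attr(planes[[1]], "description")
  meta <- NULL
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE))
    meta <- tryCatch(parse_ome_channels(desc), error = function(e) NULL)
  size_c <- n_channels %||% meta$size_c %||% 1L
  names_c <- channel_names %||% meta$channel_names
  # RGB-style channel-in-plane files
  if (length(planes) == 1 && length(dim(planes[[1]])) == 3) {
    arr <- planes[[1]]
    size_c <- dim(arr)[3]
    ci <- resolve_channel(channel, size_c, names_c)
    stack <- array(arr[, , ci], dim = c(dim(arr)[1:2], 1L))
  } else {
    n_planes <- length(planes)
    if (n_planes %% size_c != 0)
      stop(n_planes, " planes not divisible by ", size_c, " channels")
    size_z <- n_planes / size_c
    ci <- resolve_channel(channel, size_c, names_c)
    order_cz <- (meta$dimension_order %||% "XYCZT")
    plane_idx <- if (grepl("^XYZ", order_cz))
      (ci - 1L) * size_z + seq_len(size_z)   # Z fastest
    else
      ci + size_c * (seq_len(size_z) - 1L)   # C fastest (XYCZT)
    stack <- array(0, dim = c(dim(planes[[1]])[1:2], size_z))
    for (z in seq_len(size_z)) stack[, , z] <- planes[[plane_idx[z]]]
  }
  if (identical(z_policy, "keep")) {
    if (dim(stack)[3] == 1) return(stack[, , 1]) else return(stack)
  }
  if (grepl("^project:", z_policy))
    return(project_stack(stack, sub("^project:", "", z_policy)))
  stop("unknown z_policy: ", z_policy)
}

resolve_channel <- function(channel, size_c, names_c) {
  if (is.character(channel)) {
    if (is.null(names_c))
      stop("channel requested by name but no channel names available")
    ci <- match(channel, names_c)
    if (is.na(ci))
      stop("channel '", channel, "' not found; available: ",
           paste(names_c, collapse = ", "))
  } else ci <- as.integer(channel)
  if (ci < 1 || ci > size_c)
    stop("channel index ", ci, " out of range; file has ", size_c,
         " channel(s)",
         if (!is.null(names_c))
           paste0(": ", paste(names_c, collapse = ", ")) else "")
  ci
}
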