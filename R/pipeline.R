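# Tag errors with the pipeline stage that raised them.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Write a simulated cohort to a directory
#'
#' Emits one long-format profile CSV per channel
#' (`profiles_<channel>.csv`) and a `truth.json` holding the ground
#' truth (phases in radians, sample ids in true temporal order, model
#' parameters, seed) for later scoring.
#'
#' @param cohort a `synthetic_cohort`, or a list of them (e.g. the
#'   `reference`/`partner` pair from [paired_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- list(cohort)
  stopifnot(all(vapply(cohort, inherits, logical(1), "synthetic_cohort")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in cohort) {
    ch <- co$profiles[[1]]$channel
    write_profiles_csv(co$profiles,
                       file.path(dir, sprintf("profiles_%s.csv", ch)))
  }
  ref <- cohort[[1]]
  jsonlite::write_json(
    list(sample_ids = ref$sample_ids,
         true_phases = ref$true_phases,
         true_order = ref$sample_ids[ref$true_order],
         model = unclass(ref$model), seed = ref$seed,
         channels = vapply(cohort, function(co)
           co$profiles[[1]]$channel, character(1))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full snapshot-ordering pipeline
#'
#' Reads per-channel profile CSVs from a directory, normalizes the
#' profiles, assembles per-channel intensity matrices, infers the
#' temporal order on the reference (clock) channel, transfers it to the
#' partnered channels, and writes ordered kymographs (CSV and PNG) with
#' periodic extension.  All randomness flows from `seed`; re-running
#' with the same inputs and seed reproduces every output byte for byte.
#'
#' @param input_dir directory containing `profiles_<channel>.csv` files
#'   (as written by [write_cohort()] or the `extract` step).
#' @param out_dir output directory (created if needed).
#' @param reference_channel channel the ordering is fitted on (the clock
#'   channel); default: the first channel found.
#' @param partner_channels channels to carry along; default: all others.
#' @param normalize per-profile normalization mode (`"max"`, `"area"`,
#'   or `NULL` for raw intensities).
#' @param n_bins common bin grid for the matrices.
#' @param lags,period objective parameters, see [infer_order()].
#' @param control an [anneal_control()].
#' @param seed integer seed for the annealing search.
#' @param cycles periodic-extension cycle count for the kymographs.
#' @param render also write PNG renderings?
#' @return invisibly, a list with the fitted `snapshot_ordering`, the
#'   per-channel matrices and kymographs, and the paths written.
#' @export
run_pipeline <- function(input_dir, out_dir, reference_channel = NULL,
                         partner_channels = NULL, normalize = "max",
                         n_bins = NULL, lags = NULL, period = NULL,
                         control = anneal_control(), seed = 1L,
                         cycles = 3L, render = TRUE) {
  profiles <- with_stage("read", {
    files <- list.files(input_dir, pattern = "^profiles_.*\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0)
      stop("no profiles_<channel>.csv files in ", input_dir)
    unlist(lapply(sort(files), read_profiles_csv), recursive = FALSE)
  })
  chans <- vapply(profiles, `[[`, character(1), "channel")
  reference_channel <- reference_channel %||% chans[[1]]
  if (!reference_channel %in% chans)
    stop(sprintf("[read] reference channel '%s' not found; available: %s",
                 reference_channel,
                 paste(unique(chans), collapse = ", ")), call. = FALSE)
  partner_channels <- partner_channels %||%
    setdiff(unique(chans), reference_channel)

  matrices <- with_stage("matrix", {
    by_chan <- split(profiles, chans)
    lapply(by_chan, function(ps) {
      if (!is.null(normalize))
        ps <- lapply(ps, normalize_profile, mode = normalize)
      build_matrix(ps, n_bins = n_bins %||%
                     length(ps[[1]]$positions))
    })
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(matrices))
    write_matrix_csv(matrices[[ch]],
                     file.path(out_dir, sprintf("matrix_%s.csv", ch)))

  fit <- with_stage("order",
    infer_order(matrices[[reference_channel]], lags = lags,
                period = period, control = control, seed = seed))
  write_ordering_json(fit, file.path(out_dir, "order.json"),
                      trace_path = file.path(out_dir, "trace.csv"))

  kymos <- with_stage("kymograph", {
    ks <- list()
    for (ch in c(reference_channel, partner_channels)) {
      ordered <- if (ch == reference_channel) {
        build_kymograph(matrices[[ch]], fit)
      } else {
        build_kymograph(apply_ordering(matrices[[ch]], fit))
      }
      k <- periodic_extension(ordered, cycles)
      write_kymograph_csv(k, file.path(out_dir,
                                       sprintf("kymo_%s.csv", ch)))
      if (render)
        render_kymograph(k, file.path(out_dir,
                                      sprintf("kymo_%s.png", ch)))
      ks[[ch]] <- k
    }
    ks
  })

  with_stage("provenance", {
    inputs <- list.files(input_dir, full.names = TRUE)
    jsonlite::write_json(
      list(tool = paste0("kymoclock ",
                         utils::packageVersion("kymoclock")),
           reference_channel = reference_channel,
           partner_channels = partner_channels,
           normalize = normalize, seed = as.integer(seed),
           cycles = as.integer(cycles),
           lags = fit$lags, period = fit$period,
           control = control[c("iterations", "cooling_factor",
                               "proposal", "restarts")],
           input_digests = as.list(tools::md5sum(sort(inputs)))),
      file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA)
  })

  invisible(list(fit = fit, matrices = matrices, kymographs = kymos,
                 out_dir = out_dir))
}
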