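#' Generative model of a traveling expression wave across the PSM
#'
#' Parameterizes the synthetic cohorts used to validate temporal ordering:
#' a periodic signal sweeping the normalized posterior (0) to anterior (1)
#' axis, superimposed on a static rostro-caudal gradient (Dll1/Notch1-like)
#' and a constant baseline, with additive Gaussian noise.
#'
#' Two signal shapes are available.  `"band"` (default) is a Gaussian band
#' of expression whose center sweeps posterior to anterior over one clock
#' cycle, emulating a nascent-transcription band such as *Lfng* intron
#' signal.  `"sinusoid"` is a spatial cosine whose phase advances with the
#' clock; its circular autocorrelation along the sample axis is exactly
#' cosine, which makes it the clean test bed for the ordering objective.
#'
#' @param mode signal shape, `"band"` or `"sinusoid"`.
#' @param amplitude peak signal amplitude above baseline (arbitrary
#'   fluorescence units); must be positive.
#' @param band_width standard deviation of the Gaussian band, as a fraction
#'   of the axis (band mode only).
#' @param wave_number number of spatial periods across the axis
#'   (sinusoid mode only).
#' @param gradient_slope slope of the static linear gradient; positive
#'   values are strongest at the anterior (rostral) end.
#' @param baseline constant non-negative offset.
#' @param noise_fraction standard deviation of additive Gaussian noise, as
#'   a fraction of `amplitude`; non-negative.
#' @param n_bins number of spatial bins profiles are evaluated on.
#' @return An object of class `wave_model`.
#' @seealso [simulate_cohort()], [wave_profile()]
#' @examples
#' m <- wave_model(mode = "band", noise_fraction = 0)
#' wave_profile(c(0, 0.25, 0.5), phase = pi, model = m)
#' @export
wave_model <- function(mode = c("band", "sinusoid"),
                       amplitude = 1,
                       band_width = 0.12,
                       wave_number = 1,
                       gradient_slope = 0.5,
                       baseline = 0.1,
                       noise_fraction = 0.1,
                       n_bins = 100L) {
  mode <- match.arg(mode)
  stopifnot(amplitude > 0, noise_fraction >= 0, baseline >= 0,
            n_bins >= 2)
  if (mode == "band" && band_width <= 0)
    stop("`band_width` must be positive in band mode")
  if (mode == "sinusoid" && wave_number <= 0)
    stop("`wave_number` must be positive in sinusoid mode")
  structure(list(mode = mode, amplitude = amplitude,
                 band_width = band_width, wave_number = wave_number,
                 gradient_slope = gradient_slope, baseline = baseline,
                 noise_fraction = noise_fraction,
                 n_bins = as.integer(n_bins)),
            class = "wave_model")
}

#' @export
print.wave_model <- function(x, ...) {
  cat(sprintf("Traveling-wave model (%s mode)\n", x$mode))
  cat(sprintf("  amplitude %.3g, baseline %.3g, gradient slope %.3g\n",
              x$amplitude, x$baseline, x$gradient_slope))
  if (x$mode == "band")
    cat(sprintf("  band width (sd) %.3g of axis\n", x$band_width))
  else
    cat(sprintf("  wave number %.3g periods across axis\n", x$wave_number))
  cat(sprintf("  noise %.3g x amplitude, %d bins\n",
              x$noise_fraction, x$n_bins))
  invisible(x)
}

#' Noise-free wave intensity at given axial positions and clock phase
#'
#' Evaluates the deterministic part of a [wave_model()] at positions
#' `x` in `[0, 1]` for a clock phase in `[0, 2*pi)`.  In band mode the
#' band center sits at `phase / (2*pi)`, so the band sweeps the whole
#' axis posterior to anterior over one cycle.  In sinusoid mode the
#' signal is `amplitude * (1 + cos(2*pi*wave_number*x - phase)) / 2`.
#' The static gradient and baseline are added and the result clipped at
#' zero.
#'
#' @param x numeric vector of normalized axial positions in `[0, 1]`
#'   (0 = posterior, 1 = anterior).
#' @param phase clock phase in radians.
#' @param model a [wave_model()].
#' @return numeric vector of non-negative intensities, same length as `x`.
#' @export
wave_profile <- function(x, phase, model) {
  stopifnot(inherits(model, "wave_model"), is.numeric(x),
            length(phase) == 1, is.finite(phase))
  if (any(x < 0 | x > 1))
    stop("positions `x` must lie in [0, 1]")
  base <- model$baseline + model$gradient_slope * x
  sig <- if (model$mode == "sinusoid") {
    model$amplitude * (1 + cos(2 * pi * model$wave_number * x - phase)) / 2
  } else {
    ctr <- (phase %% (2 * pi)) / (2 * pi)
    model$amplitude * exp(-(x - ctr)^2 / (2 * model$band_width^2))
  }
  pmax(base + sig, 0)
}

#' Simulate a cohort of snapshot profiles with known phases
#'
#' Draws `n_samples` clock phases, evaluates the wave model on the bin
#' centers `(i - 0.5) / n_bins`, adds clipped Gaussian noise, and records
#' the ground-truth temporal order.  With `shuffle = TRUE` the profiles
#' are presented in a seeded random order (as real snapshots would be),
#' while `true_order` still gives the rank-to-sample permutation sorting
#' phases ascending.
#'
#' @param model a [wave_model()].
#' @param n_samples number of snapshots M.
#' @param phase_scheme `"grid"` for evenly spaced phases `2*pi*m/M`,
#'   `"random"` for i.i.d. uniform phases.
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @param shuffle present profiles in random order (default `FALSE`).
#' @param channel channel label stored on each profile.
#' @return An object of class `synthetic_cohort`: a list with `profiles`
#'   (list of [spatial_profile()]), `true_phases` (radians, aligned with
#'   `profiles`), `true_order` (rank -> profile index), `sample_ids`,
#'   `model`, and `seed`.
#' @examples
#' co <- simulate_cohort(wave_model(noise_fraction = 0), n_samples = 6,
#'                       seed = 1)
#' co$true_order
#' @export
simulate_cohort <- function(model, n_samples,
                            phase_scheme = c("grid", "random"),
                            seed = 1L, shuffle = FALSE,
                            channel = "Lfng_i") {
  stopifnot(inherits(model, "wave_model"), n_samples >= 1)
  phase_scheme <- match.arg(phase_scheme)
  M <- as.integer(n_samples)
  local_seed(seed)
  phases <- if (phase_scheme == "grid") 2 * pi * (seq_len(M) - 1) / M
            else stats::runif(M, 0, 2 * pi)
  ids <- sprintf("S%03d", seq_len(M))
  pos <- (seq_len(model$n_bins) - 0.5) / model$n_bins
  sd_noise <- model$noise_fraction * model$amplitude
  profiles <- lapply(seq_len(M), function(m) {
    y <- wave_profile(pos, phases[m], model)
    if (sd_noise > 0)
      y <- pmax(y + stats::rnorm(length(y), sd = sd_noise), 0)
    spatial_profile(sample_id = ids[m], channel = channel,
                    positions = pos, intensities = y)
  })
  ord <- seq_len(M)
  if (shuffle) {
    ord <- sample.int(M)
    profiles <- profiles[ord]
    phases <- phases[ord]
    ids <- ids[ord]
  }
  structure(list(profiles = profiles,
                 true_phases = phases,
                 true_order = order(phases),
                 sample_ids = ids,
                 model = model, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic snapshot cohort: %d samples, %d bins, %s mode\n",
              length(x$profiles), x$model$n_bins, x$model$mode))
  cat(sprintf("  channel %s, noise %.3g x amplitude, seed %d\n",
              x$profiles[[1]]$channel, x$model$noise_fraction, x$seed))
  invisible(x)
}

#' Paired cohorts emulating contralateral explant halves
#'
#' One embryonic tail split along the midline gives two explants at the
#' same clock phase; one is stained for the clock gene (reference), the
#' other for a partner protein.  This generator draws one set of phases
#' and produces two cohorts sharing `sample_ids` and phases (partner
#' shifted by `phase_offset`), with independent noise per channel.
#'
#' @param reference_model,partner_model [wave_model()]s for the two
#'   channels.
#' @param phase_offset constant phase shift (radians) applied to the
#'   partner channel.
#' @param n_samples number of explant pairs.
#' @param seed integer seed; noise streams for the two channels are
#'   derived from it but independent.
#' @param phase_scheme,shuffle as in [simulate_cohort()].
#' @param channels length-2 character vector of channel labels.
#' @return list with elements `reference` and `partner`, both
#'   `synthetic_cohort`s presented in the same sample order.
#' @export
paired_cohort <- function(reference_model, partner_model,
                          phase_offset = 0, n_samples = 24L, seed = 1L,
                          phase_scheme = c("grid", "random"),
                          shuffle = FALSE,
                          channels = c("Lfng_i", "Dll1")) {
  phase_scheme <- match.arg(phase_scheme)
  stopifnot(length(channels) == 2)
  M <- as.integer(n_samples)
  local_seed(seed)
  phases <- if (phase_scheme == "grid") 2 * pi * (seq_len(M) - 1) / M
            else stats::runif(M, 0, 2 * pi)
  perm <- if (shuffle) sample.int(M) else seq_len(M)
  ids <- sprintf("S%03d", seq_len(M))[perm]
  phases <- phases[perm]
  build <- function(model, channel, offset, subseed) {
    local_seed(subseed)
    pos <- (seq_len(model$n_bins) - 0.5) / model$n_bins
    sd_noise <- model$noise_fraction * model$amplitude
    profiles <- lapply(seq_len(M), function(m) {
      y <- wave_profile(pos, (phases[m] + offset) %% (2 * pi), model)
      if (sd_noise > 0)
        y <- pmax(y + stats::rnorm(length(y), sd = sd_noise), 0)
      spatial_profile(sample_id = ids[m], channel = channel,
                      positions = pos, intensities = y)
    })
    structure(list(profiles = profiles, true_phases = phases,
                   true_order = order(phases), sample_ids = ids,
                   model = model, seed = as.integer(seed)),
              class = "synthetic_cohort")
  }
  # distinct sub-seeds keep the two noise streams independent
  s <- as.integer(seed) %% 1000000L
  list(reference = build(reference_model, channels[1], 0, 2L * s + 11L),
       partner   = build(partner_model,  channels[2], phase_offset,
                         2L * s + 12L))
}

#' Assemble a cohort's profiles into an intensity matrix
#'
#' Convenience wrapper: optionally normalizes each profile, then calls
#' [build_matrix()] on the cohort's bin grid.
#'
#' @param cohort a `synthetic_cohort`.
#' @param normalize `NULL` for raw intensities, or a mode accepted by
#'   [normalize_profile()] (`"max"` or `"area"`).
#' @param n_bins target bin count (default: the model's own grid).
#' @return An [intensity_matrix()].
#' @export
cohort_matrix <- function(cohort, normalize = NULL, n_bins = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  profs <- cohort$profiles
  if (!is.null(normalize))
    profs <- lapply(profs, normalize_profile, mode = normalize)
  build_matrix(profs, n_bins = n_bins %||% cohort$model$n_bins)
}

# Seed the RNG locally, restoring the caller's RNG state on exit.
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  do.call(on.exit, list(quote({
    if (is.null(.kc_old_seed))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", .kc_old_seed, envir = globalenv())
  }), add = TRUE), envir = envir)
  assign(".kc_old_seed", old, envir = envir)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
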