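#' Circular autocorrelation of a series
#'
#' Mean-removed, variance-normalized, wrap-around autocorrelation:
#' `A(k) = sum_j (s_j - sbar)(s_{(j+k) mod M} - sbar) / sum_j (s_j - sbar)^2`.
#' The wrap-around is what lets the objective enforce temporal
#' periodicity of an ordered cohort; `A(0) = 1` by construction, and for a
#' sampled sinusoid `s_j = cos(2*pi*j/M)` the identity
#' `A(k) = cos(2*pi*k/M)` holds exactly.
#'
#' @param series numeric vector of length M >= 2.
#' @param k integer lag, `0 <= k < M`.
#' @return scalar in `[-1, 1]`.
#' @export
circular_autocorr <- function(series, k) {
  M <- length(series)
  stopifnot(M >= 2, k >= 0, k < M)
  s <- series - mean(series)
  ss <- sum(s^2)
  if (ss == 0) stop("series has zero variance; autocorrelation undefined")
  sum(s * s[((seq_len(M) - 1 + k) %% M) + 1]) / ss
}

#' Target autocorrelation enforcing temporal periodicity
#'
#' `A_T(k) = cos(2*pi*k / period)`.  With `period = M` (the default used
#' throughout) the ordered cohort is asked to span exactly one clock
#' cycle: a spatial bin's intensity, read across the ordered samples,
#' should look like one period of a sinusoid.
#'
#' @param k integer lag(s), `k >= 0`.
#' @param period target period in units of sample count.
#' @return numeric vector in `[-1, 1]`.
#' @export
target_autocorr <- function(k, period) {
  stopifnot(all(k >= 0), period > 0)
  cos(2 * pi * k / period)
}

# Shared preprocessing for the objective: admissible (above-variance)
# rows, centered, with sums of squares, plus lag set and targets.
objective_setup <- function(values, lags, period, min_row_variance) {
  M <- ncol(values)
  if (M < 2) stop("need at least 2 samples to order")
  if (is.null(lags)) lags <- seq_len(max(1L, M %/% 2L))
  lags <- as.integer(lags)
  stopifnot(all(lags >= 1), all(lags < M))
  if (is.null(period)) period <- M
  stopifnot(period > 0)
  rv <- apply(values, 1, stats::var)
  adm <- which(rv > min_row_variance)
  if (length(adm) == 0)
    stop("no spatial row has variance above `min_row_variance`")
  Xc <- values[adm, , drop = FALSE] - rowMeans(values[adm, , drop = FALSE])
  list(Xc = Xc, ss = rowSums(Xc^2), lags = lags, period = period,
       AT = target_autocorr(lags, period), n_admissible = length(adm),
       M = M)
}

#' Periodicity objective of an ordering
#'
#' For a candidate temporal order `pi` of the M samples,
#' `g(pi) = sum_i sum_k (A(row_i under pi; k) - A_T(k))^2`, summing over
#' spatial rows with variance above `min_row_variance` and over the lag
#' set (default `1..floor(M/2)`).  `A` is the circular autocorrelation
#' along the ordered sample axis and `A_T(k) = cos(2*pi*k/period)`.
#' Minimizing g arranges the columns into a temporally periodic pattern;
#' g is invariant under cyclic rotation and reversal of the ordering, so
#' an order is recoverable only up to those symmetries.
#'
#' @param x an [intensity_matrix()] or plain numeric matrix
#'   (rows = spatial bins, columns = samples).
#' @param ordering integer permutation of `1..M` (rank -> column);
#'   default identity.
#' @param lags integer lags; default `1..floor(M/2)`.
#' @param period target period in samples; default `M`.
#' @param min_row_variance rows at or below this variance are excluded.
#' @return scalar g >= 0, with attributes `n_admissible_rows` and `lags`.
#' @export
periodicity_objective <- function(x, ordering = NULL, lags = NULL,
                                  period = NULL, min_row_variance = 1e-12) {
  values <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  M <- ncol(values)
  if (is.null(ordering)) ordering <- seq_len(M)
  ordering <- as.integer(ordering)
  if (length(ordering) != M || anyDuplicated(ordering) ||
      any(ordering < 1) || any(ordering > M))
    stop("`ordering` must be a permutation of 1..", M)
  st <- objective_setup(values, lags, period, min_row_variance)
  g <- g_value_cpp(st$Xc, st$ss, ordering - 1L, st$lags, st$AT)
  structure(g, n_admissible_rows = st$n_admissible, lags = st$lags)
}

#' Annealing schedule for the ordering search
#'
#' @param iterations Metropolis steps per chain.
#' @param initial_temperature `"auto"` (median absolute objective change
#'   over 100 random swap proposals) or a positive scalar.
#' @param cooling_factor geometric cooling multiplier per step, in (0,1).
#' @param proposal `"reverse-segment"` (default; mixes better on
#'   permutation spaces) or `"swap-two"`.
#' @param restarts independent chains from random starts; the best state
#'   across all chains is returned.
#' @param trace_every record the trace every this many iterations.
#' @return list of class `anneal_control`.
#' @export
anneal_control <- function(iterations = 20000L,
                           initial_temperature = "auto",
                           cooling_factor = 0.999,
                           proposal = c("reverse-segment", "swap-two"),
                           restarts = 5L, trace_every = 10L) {
  proposal <- match.arg(proposal)
  stopifnot(iterations >= 1, restarts >= 1, trace_every >= 1,
            cooling_factor > 0, cooling_factor < 1)
  if (!identical(initial_temperature, "auto"))
    stopifnot(is.numeric(initial_temperature), initial_temperature > 0)
  list(iterations = as.integer(iterations),
       initial_temperature = initial_temperature,
       cooling_factor = cooling_factor, proposal = proposal,
       restarts = as.integer(restarts),
       trace_every = as.integer(trace_every))
}

#' Infer the temporal order of snapshot samples
#'
#' Fits the ordering that minimizes the periodicity objective
#' [periodicity_objective()] over permutations of the samples, either by
#' Metropolis annealing (`method = "anneal"`, the workhorse) or by
#' exhaustive enumeration (`method = "exhaustive"`, the validation oracle
#' for small cohorts).  Because the objective is blind to cyclic rotation
#' and reversal, the returned permutation is canonicalized: the sample
#' with the lowest column index is placed at rank 1 and the direction is
#' chosen so the expression-band centroid drifts posterior to anterior
#' with increasing rank (the known direction of the traveling wave).
#' Canonicalization is cosmetic; the objective value is unaffected.
#'
#' @param x an [intensity_matrix()] (the reference/clock channel) or a
#'   plain numeric matrix with samples in columns.
#' @param lags integer lag set; default `1..floor(M/2)`.
#' @param period target period in samples; default `M` (the cohort spans
#'   one clock cycle).
#' @param method `"anneal"` or `"exhaustive"`.
#' @param control an [anneal_control()] (annealing only).
#' @param seed integer seed; the fit is bit-reproducible given the same
#'   seed and control.
#' @param min_row_variance variance floor below which spatial rows are
#'   excluded from the objective.
#' @param canonicalize rotate/reflect the minimizer into canonical form?
#' @param exhaustive_limit refuse exhaustive search above this M unless
#'   `full_enumeration` machinery is explicitly stress-tested; guards the
#'   factorial blow-up.
#' @param full_enumeration enumerate all M! permutations instead of
#'   fixing the first sample at rank 1 (result-equivalent; for testing).
#' @return object of class `snapshot_ordering` with components
#'   `permutation` (rank -> column index), `sample_ids` (rank order),
#'   `objective`, `n_admissible_rows`, `trace`, `restarts`, `centroids`,
#'   and the resolved configuration.
#' @examples
#' co <- simulate_cohort(wave_model(noise_fraction = 0), 8, seed = 3,
#'                       shuffle = TRUE)
#' fit <- infer_order(cohort_matrix(co), seed = 1)
#' ordering_distance(fit, co$true_order)
#' @export
infer_order <- function(x, lags = NULL, period = NULL,
                        method = c("anneal", "exhaustive"),
                        control = anneal_control(), seed = 1L,
                        min_row_variance = 1e-12, canonicalize = TRUE,
                        exhaustive_limit = 9L, full_enumeration = FALSE) {
  method <- match.arg(method)
  im <- if (inherits(x, "intensity_matrix")) x else
    intensity_matrix(as.matrix(x),
                     bin_centers = (seq_len(nrow(as.matrix(x))) - 0.5) /
                       nrow(as.matrix(x)),
                     sample_ids = colnames(as.matrix(x)) %||%
                       sprintf("S%03d", seq_len(ncol(as.matrix(x)))),
                     channel = "channel")
  values <- im$values
  M <- ncol(values)
  if (M == 1 && method == "exhaustive") {
    # a single sample is trivially ordered; the objective is an empty sum
    return(structure(list(permutation = 1L, sample_ids = im$sample_ids,
                          objective = 0, n_admissible_rows = 0L,
                          channel = im$channel, method = method,
                          lags = integer(0), period = 1,
                          min_row_variance = min_row_variance,
                          control = NULL, initial_temperature = NULL,
                          seed = as.integer(seed), M = 1L, trace = NULL,
                          restarts = NULL,
                          centroids = column_centroids(im),
                          call = match.call()),
                     class = "snapshot_ordering"))
  }
  if (M < 2) stop("need at least 2 samples to order")
  st <- objective_setup(values, lags, period, min_row_variance)

  if (method == "anneal") {
    local_seed(seed)
    t0 <- control$initial_temperature
    if (identical(t0, "auto")) t0 <- auto_temperature(st)
    best <- NULL
    restart_tab <- data.frame(restart = integer(0), best_g = numeric(0),
                              accept_rate = numeric(0))
    for (r in seq_len(control$restarts)) {
      perm0 <- sample.int(M) - 1L
      ch <- anneal_chain_cpp(st$Xc, st$ss, st$lags, st$AT, perm0,
                             control$iterations, t0,
                             control$cooling_factor,
                             if (control$proposal == "swap-two") 0L else 1L,
                             control$trace_every)
      restart_tab <- rbind(restart_tab,
                           data.frame(restart = r, best_g = ch$best_g,
                                      accept_rate = ch$accept_rate))
      if (is.null(best) || ch$best_g < best$best_g) best <- ch
    }
    perm <- best$best_perm + 1L
    g <- best$best_g
    trace <- best$trace
    colnames(trace) <- c("iteration", "current_g", "best_g", "temperature")
  } else {
    if (M > exhaustive_limit)
      stop("exhaustive search refused for M = ", M, " > ",
           exhaustive_limit, " (raise `exhaustive_limit` to override)")
    perms <- if (full_enumeration) permutations_of(seq_len(M))
             else cbind(1L, permutations_of(seq_len(M)[-1]))
    gs <- g_value_many_cpp(st$Xc, st$ss, perms - 1L, st$lags, st$AT)
    gmin <- min(gs)
    ties <- which(gs <= gmin + 1e-12 * (1 + abs(gmin)))
    cand <- lapply(ties, function(i)
      canonical_ordering(perms[i, ], im, canonicalize))
    perm <- cand[[which.min(vapply(cand, function(p)
      sum(p * (M + 1)^(rev(seq_len(M)) - 1)), numeric(1)))]]
    g <- gmin
    trace <- NULL
    restart_tab <- NULL
    t0 <- NA_real_
  }

  perm <- canonical_ordering(perm, im, canonicalize)
  g <- g_value_cpp(st$Xc, st$ss, perm - 1L, st$lags, st$AT)
  structure(list(permutation = perm,
                 sample_ids = im$sample_ids[perm],
                 objective = g,
                 n_admissible_rows = st$n_admissible,
                 channel = im$channel, method = method,
                 lags = st$lags, period = st$period,
                 min_row_variance = min_row_variance,
                 control = if (method == "anneal") control else NULL,
                 initial_temperature = if (method == "anneal") t0 else NULL,
                 seed = as.integer(seed), M = M,
                 trace = trace, restarts = restart_tab,
                 centroids = column_centroids(im),
                 call = match.call()),
            class = "snapshot_ordering")
}

# Median |delta g| over random swap proposals: a temperature at which
# about half the early uphill moves are accepted.
auto_temperature <- function(st, n_probe = 100L) {
  M <- st$M
  deltas <- vapply(seq_len(n_probe), function(i) {
    p <- sample.int(M) - 1L
    ij <- sample.int(M, 2)
    q <- p
    q[ij] <- q[rev(ij)]
    abs(g_value_cpp(st$Xc, st$ss, q, st$lags, st$AT) -
          g_value_cpp(st$Xc, st$ss, p, st$lags, st$AT))
  }, numeric(1))
  t0 <- stats::median(deltas)
  if (!is.finite(t0) || t0 <= 0) t0 <- 1e-8
  t0
}

# Expression-band centroid of each column: intensity-weighted mean
# position over the bins at or above half the column maximum (the same
# band definition assign_phase uses).  Unlike the whole-column centroid,
# this tracks the traveling band even on top of a static gradient.
column_centroids <- function(im) {
  vapply(seq_len(ncol(im$values)), function(j) {
    v <- im$values[, j]
    if (max(v) <= 0) return(0.5)
    band <- v >= 0.5 * max(v)
    sum(im$bin_centers[band] * v[band]) / sum(v[band])
  }, numeric(1))
}

# Rotate so the lexicographically smallest sample id sits at rank 1;
# reflect so the band centroid drifts posterior -> anterior with
# increasing rank (the known direction of the traveling wave).
canonical_ordering <- function(perm, im, canonicalize = TRUE) {
  if (!canonicalize) return(as.integer(perm))
  perm <- as.integer(perm)
  M <- length(perm)
  ctr <- column_centroids(im)[perm]
  d <- ((diff(c(ctr, ctr[1])) + 0.5) %% 1) - 0.5
  if (sum(d) < 0) perm <- rev(perm)
  shift <- which.min(match(im$sample_ids[perm], sort(im$sample_ids)))
  perm[((seq_len(M) + shift - 2) %% M) + 1]
}

# All permutations of a vector, one per row (small n only).
permutations_of <- function(v) {
  n <- length(v)
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  if (n == 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(v[i], permutations_of(v[-i]))))
}

#' Distance between orderings up to rotation and reflection
#'
#' The periodicity objective cannot distinguish an ordering from its
#' cyclic rotations or its reversal, so recovery is scored modulo that
#' dihedral symmetry: the minimum, over all `2M` compositions of `b` with
#' rotations and the reflection, of the normalized Kendall-tau distance
#' to `a`.  0 means `a` equals `b` up to the symmetry; 1 is maximal
#' discordance.
#'
#' @param a,b integer permutations of the same length, or
#'   `snapshot_ordering` objects.
#' @return scalar in `[0, 1]`.
#' @export
ordering_distance <- function(a, b) {
  if (inherits(a, "snapshot_ordering")) a <- a$permutation
  if (inherits(b, "snapshot_ordering")) b <- b$permutation
  a <- as.integer(a); b <- as.integer(b)
  M <- length(a)
  if (length(b) != M) stop("orderings have different lengths")
  if (M < 2) return(0)
  best <- Inf
  for (variant in list(b, rev(b))) {
    for (r in seq_len(M) - 1L) {
      rot <- variant[((seq_len(M) + r - 1L) %% M) + 1L]
      best <- min(best, kendall_distance(a, rot))
    }
  }
  best
}

# Normalized Kendall-tau distance between two permutations of the same
# elements: fraction of discordant pairs.
kendall_distance <- function(p, q) {
  pos <- integer(length(q))
  pos[q] <- seq_along(q)
  r <- pos[p]
  n <- length(r)
  disc <- 0L
  for (i in seq_len(n - 1))
    disc <- disc + sum(r[(i + 1):n] < r[i])
  disc / (n * (n - 1) / 2)
}

#' Transfer an inferred ordering to the partnered channel
#'
#' The ordering is inferred on the clock (reference) channel and applied
#' to the contralateral partner channel: columns of the partner matrix
#' are permuted so that rank r carries the sample at rank r of the
#' ordering, matched by `sample_id` (contralateral halves share an
#' embryo identifier), never by column position.
#'
#' @param partner an [intensity_matrix()] for the partnered channel.
#' @param ordering a `snapshot_ordering` fitted on the reference channel
#'   (or a character vector of sample ids in rank order).
#' @return the reordered [intensity_matrix()].
#' @export
apply_ordering <- function(partner, ordering) {
  stopifnot(inherits(partner, "intensity_matrix"))
  ids <- if (inherits(ordering, "snapshot_ordering")) ordering$sample_ids
         else as.character(ordering)
  if (!setequal(ids, partner$sample_ids) ||
      length(ids) != length(partner$sample_ids))
    stop("sample_ids of partner matrix do not match the ordering")
  idx <- match(ids, partner$sample_ids)
  intensity_matrix(partner$values[, idx, drop = FALSE],
                   partner$bin_centers, partner$sample_ids[idx],
                   partner$channel, normalized = partner$normalized)
}

#' @export
print.snapshot_ordering <- function(x, ...) {
  cat(sprintf("Snapshot temporal ordering (%s), channel %s\n",
              x$method, x$channel))
  cat(sprintf("  M = %d samples, g = %.6g over %d admissible rows\n",
              x$M, x$objective, x$n_admissible_rows))
  cat("  rank order: ", paste(utils::head(x$sample_ids, 8),
                              collapse = " "),
      if (x$M > 8) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.snapshot_ordering <- function(object, ...) {
  structure(list(fit = object), class = "summary.snapshot_ordering")
}

#' @export
print.summary.snapshot_ordering <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  lags: %s; target period: %g samples\n",
              paste(f$lags, collapse = ","), f$period))
  if (!is.null(f$control)) {
    cat(sprintf("  annealing: %d iterations x %d restarts, T0 = %.4g, cooling %.4g, %s proposal\n",
                f$control$iterations, f$control$restarts,
                f$initial_temperature, f$control$cooling_factor,
                f$control$proposal))
    print(f$restarts, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.snapshot_ordering <- function(object, ...) {
  stats::setNames(object$permutation, object$sample_ids)
}

#' Diagnostic plot for an ordering fit
#'
#' For annealed fits, the objective trace of the winning chain (current
#' and best-so-far g against iteration, log scale); for all fits, the
#' expression-band centroid against temporal rank, which should drift
#' monotonically for a well-ordered traveling wave.
#'
#' @param x a `snapshot_ordering`.
#' @param which `"trace"`, `"centroid"`, or `"both"` (default: both when
#'   a trace exists).
#' @param ... passed to [graphics::plot()].
#' @export
plot.snapshot_ordering <- function(x, which = NULL, ...) {
  has_trace <- !is.null(x$trace)
  which <- which %||% if (has_trace) "both" else "centroid"
  panels <- switch(which, trace = "trace", centroid = "centroid",
                   both = c(if (has_trace) "trace", "centroid"))
  if (length(panels) > 1) {
    op <- graphics::par(mfrow = c(1, length(panels)))
    on.exit(graphics::par(op))
  }
  for (p in panels) {
    if (p == "trace") {
      tr <- x$trace
      graphics::plot(tr[, "iteration"], pmax(tr[, "current_g"], 1e-12),
                     type = "l", log = "y", col = "grey60",
                     xlab = "iteration", ylab = "objective g",
                     main = "annealing trace", ...)
      graphics::lines(tr[, "iteration"], pmax(tr[, "best_g"], 1e-12),
                      col = "firebrick", lwd = 2)
      graphics::legend("topright", c("current", "best"), lwd = c(1, 2),
                       col = c("grey60", "firebrick"), bty = "n")
    } else {
      graphics::plot(seq_len(x$M) - 1, x$centroids[x$permutation],
                     xlab = "temporal rank", ylab = "band centroid (0=posterior)",
                     main = "centroid drift", pch = 19, ...)
    }
  }
  invisible(x)
}
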