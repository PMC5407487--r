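test_that("circular autocorrelation obeys its identities and matches the loop oracle", {
  set.seed(42)
  s <- runif(9, 1, 4)
  expect_equal(circular_autocorr(s, 0), 1)

  # sampled sinusoid: A(k) = cos(2*pi*k/M) exactly
  M <- 8
  sj <- cos(2 * pi * (seq_len(M) - 1) / M)
  expect_equal(circular_autocorr(sj, 2), 0, tolerance = 1e-12)
  expect_equal(circular_autocorr(sj, 4), -1, tolerance = 1e-12)

  s6 <- runif(6)
  for (k in 1:5)
    expect_equal(circular_autocorr(s6, k), oracle_autocorr(s6, k),
                 tolerance = 1e-12)

  expect_error(circular_autocorr(rep(3, 5), 1), "zero variance")
})

test_that("target autocorrelation is a cosine of the lag", {
  expect_equal(target_autocorr(0, 12), 1)
  expect_equal(target_autocorr(12, 12), 1)
  expect_equal(target_autocorr(3, 12), cos(pi / 2), tolerance = 1e-15)
})

test_that("periodicity objective matches an independent summation oracle", {
  set.seed(11)
  for (rep in 1:5) {
    im <- random_imatrix(5, 6, seed = 100 + rep)
    perm <- sample(6)
    lags <- 1:3
    expect_equal(as.numeric(periodicity_objective(im, perm, lags = lags)),
                 oracle_g(im$values, perm, lags, period = 6),
                 tolerance = 1e-10)
  }
})

test_that("objective vanishes for pure sampled sinusoid rows at the true period", {
  M <- 12; N <- 30
  set.seed(2)
  a <- runif(N, 2, 4); b <- runif(N, 0.5, 1.5)
  vals <- t(sapply(seq_len(N), function(i)
    a[i] + b[i] * cos(2 * pi * (seq_len(M) - 1) / M)))
  im <- intensity_matrix(vals, (seq_len(N) - 0.5) / N,
                         sprintf("S%02d", seq_len(M)), "test")
  expect_lt(as.numeric(periodicity_objective(im)), 1e-9)
})

test_that("objective excludes flat rows and errors when none are admissible", {
  im <- random_imatrix(4, 5, seed = 9)
  vals <- im$values
  vals[2, ] <- 1.5  # constant row carries no ordering signal
  im2 <- intensity_matrix(vals, im$bin_centers, im$sample_ids, "test")
  g <- periodicity_objective(im2)
  expect_identical(attr(g, "n_admissible_rows"), 3L)
  flat <- intensity_matrix(matrix(2, 3, 4), c(0.1, 0.5, 0.9),
                           letters[1:4], "test")
  expect_error(periodicity_objective(flat), "variance")
})

test_that("objective is invariant under rotation and reversal of the ordering", {
  im <- random_imatrix(6, 7, seed = 21)
  perm <- sample(7)
  g0 <- as.numeric(periodicity_objective(im, perm))
  for (r in 1:6) {
    rot <- perm[((seq_len(7) + r - 1) %% 7) + 1]
    expect_equal(as.numeric(periodicity_objective(im, rot)), g0,
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(periodicity_objective(im, rev(perm))), g0,
               tolerance = 1e-12)
})

test_that("annealed fit is deterministic and its best trace is non-increasing", {
  im <- random_imatrix(20, 8, seed = 5)
  ctl <- anneal_control(iterations = 2000, restarts = 2)
  f1 <- infer_order(im, control = ctl, seed = 99)
  f2 <- infer_order(im, control = ctl, seed = 99)
  expect_identical(f1$permutation, f2$permutation)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$restarts, f2$restarts)
  expect_true(all(diff(f1$trace[, "best_g"]) <= 0))
  f3 <- infer_order(im, control = ctl, seed = 100)
  expect_false(identical(f1$restarts, f3$restarts))
})

test_that("two-sample fits are exhaustive by construction", {
  im <- random_imatrix(10, 2, seed = 3)
  fit <- infer_order(im, control = anneal_control(iterations = 10,
                                                  restarts = 1), seed = 1)
  expect_setequal(fit$permutation, 1:2)
  # both orders are equivalent under reflection, so g matches either
  expect_equal(fit$objective,
               as.numeric(periodicity_objective(im, 1:2)),
               tolerance = 1e-12)
})

test_that("annealing attains the brute-force optimum on a noise-free cohort", {
  co <- simulate_cohort(wave_model(noise_fraction = 0), 8, seed = 17,
                        shuffle = TRUE)
  m <- cohort_matrix(co, normalize = "max")
  bf <- infer_order(m, method = "exhaustive")
  an <- infer_order(m, control = anneal_control(iterations = 5000,
                                                restarts = 3), seed = 4)
  expect_equal(an$objective, bf$objective, tolerance = 1e-9)
})

test_that("reduced enumeration equals full enumeration", {
  for (M in 4:5) {
    im <- random_imatrix(8, M, seed = 30 + M)
    full <- infer_order(im, method = "exhaustive", full_enumeration = TRUE)
    fixed <- infer_order(im, method = "exhaustive")
    expect_equal(full$objective, fixed$objective, tolerance = 1e-12)
    expect_identical(full$permutation, fixed$permutation)
  }
})

test_that("exhaustive search recovers the true order of a noise-free cohort", {
  co <- simulate_cohort(wave_model(noise_fraction = 0), 6, seed = 8,
                        shuffle = TRUE)
  bf <- infer_order(cohort_matrix(co, normalize = "max"),
                    method = "exhaustive")
  expect_equal(ordering_distance(bf, co$true_order), 0)
})

test_that("exhaustive search guards the factorial blow-up and handles M = 1", {
  im <- random_imatrix(5, 10, seed = 1)
  expect_error(infer_order(im, method = "exhaustive"), "exhaustive")
  one <- intensity_matrix(matrix(c(1, 2), 2, 1), c(0.25, 0.75), "S1", "x")
  fit1 <- infer_order(one, method = "exhaustive")
  expect_identical(fit1$permutation, 1L)
})

test_that("ordering distance is zero exactly on the dihedral orbit and matches the scan oracle", {
  a <- c(3L, 1L, 4L, 2L, 6L, 5L)
  expect_equal(ordering_distance(a, a), 0)
  expect_equal(ordering_distance(a, rev(a)), 0)
  expect_equal(ordering_distance(a, a[c(3:6, 1:2)]), 0)
  set.seed(77)
  for (rep in 1:5) {
    b <- sample(6)
    expect_equal(ordering_distance(a, b), oracle_dihedral_distance(a, b),
                 tolerance = 1e-12)
  }
  expect_gt(ordering_distance(1:6, c(1L, 3L, 5L, 2L, 6L, 4L)), 0)
  expect_error(ordering_distance(1:4, 1:5), "length")
})

test_that("orderings transfer to the partnered channel by sample id", {
  im <- random_imatrix(4, 5, seed = 55)
  partner <- intensity_matrix(im$values + 1, im$bin_centers,
                              im$sample_ids, "Dll1")
  expect_identical(apply_ordering(partner, im$sample_ids)$values,
                   partner$values)
  swapped <- im$sample_ids[c(2, 1, 3, 4, 5)]
  out <- apply_ordering(partner, swapped)
  expect_identical(out$values[, 1], partner$values[, 2])
  expect_identical(out$sample_ids, swapped)
  # id-tracking through a random ordering
  perm <- sample(5)
  out2 <- apply_ordering(partner, im$sample_ids[perm])
  for (r in seq_len(5))
    expect_identical(out2$values[, r],
                     partner$values[, perm[r]])
  bad <- intensity_matrix(partner$values, partner$bin_centers,
                          paste0("X", 1:5), "Dll1")
  expect_error(apply_ordering(bad, im$sample_ids), "sample_ids")
})

test_that("fit methods expose the permutation and draw diagnostics", {
  im <- random_imatrix(10, 6, seed = 14)
  fit <- infer_order(im, control = anneal_control(iterations = 500,
                                                  restarts = 1), seed = 2)
  cf <- coef(fit)
  expect_named(cf, fit$sample_ids)
  expect_setequal(unname(cf), 1:6)
  expect_output(print(fit), "Snapshot temporal ordering")
  expect_output(print(summary(fit)), "annealing")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  unlink(tf)
})
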