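test_that("a static fluorine gives the flat geometric value", {
  # one F fixed at 0.5 nm: P2(1)/r^6 = 1/0.5^6 = 64 nm^-6 at every lag
  tr <- make_hf_traj(matrix(rep(c(0.5, 0, 0), 10), ncol = 3, byrow = TRUE))
  corr <- dipolar_correlation(tr, max_lag = 50)
  expect_equal(corr$G, rep(64, 6), tolerance = 1e-12)
  expect_equal(corr$lag_ps[1], 0)
  expect_true(all(corr$n_eval >= 1))
})

test_that("a perpendicular reorientation gives P2(cos 90) = -1/2", {
  # F alternates between +x and +y at 0.5 nm: every single-lag pair is
  # perpendicular, so G(dt) = 64 * (-1/2) = -32
  off <- matrix(0, nrow = 12, ncol = 3)
  off[seq(1, 11, 2), 1] <- 0.5
  off[seq(2, 12, 2), 2] <- 0.5
  tr <- make_hf_traj(off)
  corr <- dipolar_correlation(tr, max_lag = 10)
  expect_equal(corr$G[1], 64, tolerance = 1e-12)
  expect_equal(corr$G[2], -32, tolerance = 1e-12)
})

test_that("G(0) equals the direct time-average of sum 1/r^6", {
  g <- small_free(n_hfip = 20, n_water = 0, box = 6, n_frames = 60,
                  seed = 21)
  tr <- g$trajectory
  corr <- dipolar_correlation(tr, max_lag = 100, cutoff = 2.9)
  f <- which(tr$atoms$role == "fluorine")
  d <- solvnoe:::.dist_to_ref_cpp(tr$coords, 0L, f - 1L, tr$box_edge)
  origins <- 1:(60 - 10)
  direct <- mean(vapply(origins, function(o) {
    r <- d[o, ]
    sum(1 / r[r <= 2.9]^6)
  }, 0))
  expect_equal(corr$G[1], direct, tolerance = 1e-10)
})

test_that("shell-resolved functions sum exactly to the all-solvent G(t)", {
  g <- small_free(n_hfip = 25, n_water = 0, box = 6, n_frames = 80,
                  seed = 22)
  shells <- shell_definition(0.556, 5)
  parts <- shell_resolved_correlation(g$trajectory, shells = shells,
                                      max_lag = 200)
  expect_length(parts, 5L)
  total <- sum_correlations(parts)
  all <- dipolar_correlation(g$trajectory, max_lag = 200, cutoff = 5 * 0.556)
  expect_equal(total$G, all$G, tolerance = 1e-12)
  one <- shell_resolved_correlation(g$trajectory,
                                    shells = shell_definition(2.78, 1),
                                    max_lag = 200)
  expect_equal(one[[1]]$G, all$G, tolerance = 1e-12)
})

test_that("shell-1 origins outweigh shell-3 as the r^-6 volume integrals", {
  g <- small_free(n_hfip = 100, n_water = 0, box = 6.7, b = 0.3,
                  n_frames = 2500, dt = 20, seed = 23,
                  substeps_per_snapshot = 30)
  parts <- shell_resolved_correlation(g$trajectory,
                                      shells = shell_definition(0.556, 3),
                                      max_lag = 40)
  # analytic: G0(shell) ~ int_l^u 4 pi r^2 r^-6 dr = (4pi/3)(l^-3 - u^-3),
  # with the inner shell truncated at the contact radius b
  gint <- function(lo, hi) (1 / max(lo, 0.3)^3 - 1 / hi^3)
  expected <- gint(0, 0.556) / gint(2 * 0.556, 3 * 0.556)
  observed <- parts[[1]]$G[1] / parts[[3]]$G[1]
  expect_lt(abs(observed / expected - 1), 0.30)
  expect_gt(observed, 10)
})

test_that("free-diffusion G(t) is statistically monotone non-increasing", {
  g <- small_free(n_hfip = 50, n_water = 0, box = 6, b = 0.3,
                  d_hfip = 21.8e-10, n_frames = 3000, dt = 5, seed = 24,
                  substeps_per_snapshot = 12)
  corr <- dipolar_correlation(g$trajectory, max_lag = 300,
                              origin_stride = 5)
  dg <- diff(corr$G)
  dse <- sqrt(corr$se[-1]^2 + corr$se[-nrow(corr)]^2)
  expect_true(all(dg <= 3 * dse))
})

test_that("G scales linearly with fluorine count", {
  G0 <- vapply(c(30, 60), function(n) {
    mean(vapply(1:3, function(k) {
      g <- small_free(n_hfip = n, n_water = 0, box = 6.7,
                      n_frames = 2000, dt = 20, seed = 25 + k,
                      substeps_per_snapshot = 30)
      dipolar_correlation(g$trajectory, max_lag = 40)$G[1]
    }, 0))
  }, 0)
  expect_lt(abs(G0[2] / G0[1] / 2 - 1), 0.25)
})

test_that("simulated G(t) follows the reflecting-propagator quadrature", {
  b <- 0.3; D <- 21.8e-10
  tau_b <- b^2 / (D * 1e6)
  corrs <- lapply(1:5, function(k) {
    g <- small_free(n_hfip = 80, n_water = 0, box = 6.7, b = b, d_hfip = D,
                    n_frames = 6000, dt = 5, seed = 30 + k,
                    substeps_per_snapshot = 12)
    dipolar_correlation(g$trajectory, max_lag = 3.2 * tau_b,
                        origin_stride = 4)
  })
  G <- rowMeans(vapply(corrs, `[[`, corrs[[1]]$G, "G"))
  se <- sqrt(rowMeans(vapply(corrs, `[[`, corrs[[1]]$se, "se")^2) / 5)
  lag <- corrs[[1]]$lag_ps
  p <- hard_sphere_params(b, D, 480 / 6.7^3)
  Gth <- ayant_correlation(p, lag)
  # the mean relative deviation over the early decay stays within 10%,
  # and every lag out to 3 tau_b is within 10% or 3 standard errors of
  # the quadrature curve, whichever is looser at that lag
  early <- lag <= tau_b
  expect_lt(abs(mean(G[early] / Gth[early] - 1)), 0.10)
  keep <- lag <= 3 * tau_b
  expect_true(all(abs(G - Gth)[keep] <=
                    pmax(0.10 * Gth[keep], 3 * se[keep])))
})

test_that("degenerate inputs are rejected", {
  tr <- make_hf_traj(matrix(rep(c(0.5, 0, 0), 5), ncol = 3, byrow = TRUE))
  expect_error(dipolar_correlation(tr, max_lag = 1000), "shorter than")
  far <- make_hf_traj(matrix(rep(c(3.5, 0, 0), 5), ncol = 3, byrow = TRUE),
                      box = 16)
  expect_error(dipolar_correlation(far, max_lag = 20, cutoff = 3),
               "no fluorines within")
})
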