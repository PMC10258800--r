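test_that("zero-diffusion particles stay put while others move", {
  g <- small_free(n_hfip = 5, n_water = 8, d_water = 0, n_frames = 20,
                  seed = 3)
  tr <- g$trajectory
  w <- which(tr$atoms$role == "water-O")
  expect_true(all(tr$coords[w, , ] == tr$coords[w, , rep(1L, 20)]))
  h <- which(tr$atoms$resname == "HFP")
  expect_gt(max(abs(tr$coords[h, , 20] - tr$coords[h, , 1])), 0)
})

test_that("the reflecting solute sphere excludes fluorine sites", {
  g <- small_free(n_hfip = 40, box = 5, b = 1.0, n_frames = 100, seed = 4)
  tr <- g$trajectory
  f <- which(tr$atoms$role == "fluorine")
  d <- solvnoe:::.dist_to_ref_cpp(tr$coords, 0L, f - 1L, tr$box_edge)
  expect_gte(min(d), 1.0 - 0.2)           # stated site-offset allowance
  expect_gte(min(d), 1.0 - 0.05 - 1e-9)   # actual default offset bound
  cen <- which(tr$atoms$role == "other")
  dc <- solvnoe:::.dist_to_ref_cpp(tr$coords, 0L, cen - 1L, tr$box_edge)
  expect_gte(min(dc), 1.0)
})

test_that("a too-coarse substep is rejected with the required count", {
  expect_error(
    simulation_spec(n_hfip = 1, n_water = 0, d_hfip = 500e-10,
                    closest_approach_b = 0.3, substeps_per_snapshot = 1),
    "substeps_per_snapshot to at least [0-9]+")
})

test_that("invalid specs are rejected", {
  expect_error(simulation_spec(box_edge = 0.5, closest_approach_b = 0.3),
               "twice the closest-approach")
  expect_error(simulation_spec(n_frames = 1), "at least 2")
  expect_error(simulation_spec(sticky = list(k_off = 1)), "sticky mode")
  expect_error(simulation_spec(sticky = list(k_off = 1, capture_shell = 0.5,
                                             bound_d_scale = 2)),
               "bound_d_scale")
  expect_error(simulation_spec(site_offset_max = 0.3), "site_offset_max")
})

test_that("identical spec and seed give a bit-identical trajectory", {
  g1 <- small_free(n_hfip = 10, n_water = 5, n_frames = 30, seed = 12)
  g2 <- small_free(n_hfip = 10, n_water = 5, n_frames = 30, seed = 12)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  g3 <- small_free(n_hfip = 10, n_water = 5, n_frames = 30, seed = 13)
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("snapshot displacements are Gaussian with variance 2 D dt", {
  # far from the solute (tiny b) with one substep per snapshot, the stored
  # displacements are the raw Brownian steps
  d_si <- 17e-10
  g <- small_free(n_hfip = 0, n_water = 200, d_water = d_si, d_hfip = 0,
                  box = 20, b = 0.7, n_frames = 501, dt = 10, seed = 5,
                  substeps_per_snapshot = 1)
  tr <- g$trajectory
  w <- which(tr$atoms$role == "water-O")
  unw <- unwrap_coords(tr)[w, , ]
  steps <- as.vector(unw[, , -1] - unw[, , -501])
  expect_gte(length(steps), 1e5)
  sigma <- sqrt(2 * d_si * 1e6 * 10)
  # rare rejected substeps at the distant solute sphere duplicate a few
  # values; the tie warning is expected and immaterial at this n
  ks <- suppressWarnings(stats::ks.test(steps, "pnorm", 0, sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run radial density outside the solute sphere is uniform", {
  # uniform density means r^3 is uniform beyond b^3; fast diffusion and a
  # wide snapshot spacing decorrelate successive frames
  g <- small_free(n_hfip = 100, n_water = 0, box = 5, b = 0.4,
                  d_hfip = 21.8e-10, n_frames = 300, dt = 50, seed = 1,
                  substeps_per_snapshot = 170)
  tr <- g$trajectory
  cen <- which(tr$atoms$role == "other")
  d <- solvnoe:::.dist_to_ref_cpp(tr$coords, 0L, cen - 1L, tr$box_edge)
  r3 <- d[d >= 0.4 & d <= 2.4]^3
  breaks <- seq(0.4^3, 2.4^3, length.out = 9)
  counts <- hist(r3, breaks = breaks, plot = FALSE)$counts
  n <- sum(counts); p <- 1 / (length(breaks) - 1)
  band <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= band),
              info = paste(counts, collapse = " "))
})

test_that("the Einstein estimator recovers the generator diffusion input", {
  devs <- vapply(1:5, function(s) {
    g <- small_free(n_hfip = 50, n_water = 0, box = 6, d_hfip = 4.8e-10,
                    n_frames = 1500, seed = s)
    einstein_diffusion(g$trajectory, "hfip")$d / 4.8e-10 - 1
  }, 0)
  expect_true(all(abs(devs) < 0.10))
})

test_that("sticky unbinding is exponential with the requested rate", {
  spec <- simulation_spec(box_edge = 3, n_hfip = 100, n_water = 0,
                          d_hfip = 4.8e-10, closest_approach_b = 0.3,
                          snapshot_dt = 10, n_frames = 3000, seed = 8,
                          sticky = list(k_off = 1, capture_shell = 0.5,
                                        bound_d_scale = 0.1))
  g <- generate_sticky_trajectory(spec)
  full <- g$events[!g$events$censored_end, ]
  expect_gte(nrow(full), 100)
  expect_lt(abs(mean(full$duration_ps) / 1000 - 1), 0.15)
})

test_that("sticky mode with instant unbinding matches free statistics", {
  base <- list(box_edge = 4, n_hfip = 60, n_water = 0, d_hfip = 10e-10,
               closest_approach_b = 0.3, snapshot_dt = 10, n_frames = 200,
               seed = 9)
  free <- generate_free_trajectory(do.call(simulation_spec, base))
  stk <- generate_sticky_trajectory(do.call(simulation_spec, c(base,
    list(sticky = list(k_off = 1e9, capture_shell = 0.5,
                       bound_d_scale = 1)))))
  disp <- function(g) {
    cen <- which(g$trajectory$atoms$role == "other")
    unw <- unwrap_coords(g$trajectory)[cen, , ]
    as.vector(unw[, , -1] - unw[, , -200])
  }
  ks <- suppressWarnings(stats::ks.test(disp(free), disp(stk)))
  expect_gt(ks$p.value, 0.01)
})

test_that("the bound-interval log matches detected contact events", {
  spec <- simulation_spec(box_edge = 3.5, n_hfip = 40, n_water = 0,
                          d_hfip = 4.8e-10, closest_approach_b = 0.3,
                          snapshot_dt = 10, n_frames = 4000, seed = 10,
                          sticky = list(k_off = 0.5, capture_shell = 0.5,
                                        bound_d_scale = 0.1))
  g <- generate_sticky_trajectory(spec)
  det <- contact_events(g$trajectory, cutoffs = c(fluorine = 0.5),
                        species = "fluorine", per_molecule = TRUE)
  expect_gte(interval_overlap(det, g$events), 0.9)
})

test_that("distance fixtures reproduce the requested series exactly", {
  tr <- make_distance_fixture(c(0.45, 0.45, 0.55, 0.45), dt = 10)
  expect_equal(as.numeric(distance_series(tr, 1, 2)),
               c(0.45, 0.45, 0.55, 0.45))
  expect_error(make_distance_fixture(numeric(0)), "non-empty")
  expect_error(make_distance_fixture(c(0.3, -0.1)), "non-negative")
})
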