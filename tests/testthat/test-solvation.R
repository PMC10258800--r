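test_that("box composition arithmetic reproduces the stated mixture", {
  comp <- solvent_composition(482, 7434)
  expect_equal(comp$n_fluorines, 2892)
  expect_equal(comp$water_fluorine_ratio, 7434 / 2892)
  expect_equal(round(comp$water_fluorine_ratio, 2), 2.57)
  expect_equal(comp$hfip_mole_fraction, 482 / (482 + 7434))
  expect_equal(round(comp$hfip_mole_fraction, 3), 0.061)
})

test_that("constructed configurations bin into the right shells", {
  # 3 F at 0.3 nm (shell 1), 2 water O at 0.8 nm (shell 2)
  box <- 8
  coords <- array(box / 2, dim = c(6L, 3L, 2L))
  coords[2L, 1L, ] <- box / 2 + 0.3
  coords[3L, 2L, ] <- box / 2 + 0.3
  coords[4L, 3L, ] <- box / 2 + 0.3
  coords[5L, 1L, ] <- box / 2 - 0.8
  coords[6L, 2L, ] <- box / 2 - 0.8
  atoms <- data.frame(
    name = c("HE1", "F1", "F2", "F3", "OW", "OW"),
    resname = c("TRP", "HFP", "HFP", "HFP", "SOL", "SOL"),
    resid = c(6L, 1L, 1L, 1L, 2L, 3L),
    role = c("peptide-H", rep("fluorine", 3), rep("water-O", 2)),
    mol_id = c(0L, 1L, 1L, 1L, 2L, 3L), stringsAsFactors = FALSE)
  tr <- trajectory(coords, box_edge = box, dt = 10, atoms = atoms)
  occ <- shell_occupancy(tr, shells = shell_definition(0.556, 5))
  expect_equal(occ$fluorine[1, ], c(3L, 0L, 0L, 0L, 0L))
  expect_equal(occ$water[1, ], c(0L, 2L, 0L, 0L, 0L))
})

test_that("shell counts partition the solvent inside the outer bound", {
  g <- small_free(n_hfip = 20, n_water = 40, box = 6, n_frames = 50,
                  seed = 61)
  tr <- g$trajectory
  shells <- shell_definition(0.556, 5)
  occ <- shell_occupancy(tr, shells = shells)
  f <- which(tr$atoms$role == "fluorine")
  d <- solvnoe:::.dist_to_ref_cpp(tr$coords, 0L, f - 1L, tr$box_edge)
  within <- rowSums(d < max(shells$bounds))
  expect_equal(rowSums(occ$fluorine), as.numeric(within))
  expect_error(shell_occupancy(tr, shells = shell_definition(0.7, 5)),
               "half the box")
})

test_that("a uniform mixture shows the bulk ratio in the outer shell", {
  # composition chosen to give the bulk water:F ratio 463/180 = 2.57
  g <- small_free(n_hfip = 30, n_water = 463, box = 6.7, b = 0.3,
                  d_hfip = 21.8e-10, d_water = 40e-10, n_frames = 400,
                  dt = 20, seed = 62, substeps_per_snapshot = 30)
  occ <- shell_occupancy(g$trajectory, shells = shell_definition(0.556, 5))
  bulk <- 463 / 180
  ratio5 <- mean(occ$water[, 5]) / mean(occ$fluorine[, 5])
  per_frame <- occ$water[, 5] / pmax(occ$fluorine[, 5], 1)
  se <- stats::sd(per_frame) / sqrt(length(per_frame) / 4)  # ~decorrelated
  expect_lt(abs(ratio5 - bulk), 3 * se + 0.05)
  tab <- shell_average_table(list(occ), bulk_ratio = bulk)
  expect_true(all(tab$enriched[4:5] == "bulk-like"))
})

test_that("shell averages and deviations follow the two-point arithmetic", {
  mk <- function(f1) {
    structure(list(fluorine = matrix(c(f1, 42), 1), water = matrix(c(2, 80), 1),
                   shells = shell_definition(0.556, 2),
                   reference = "6TrpHE1", dt = 10),
              class = "shell_occupancy")
  }
  tab <- shell_average_table(list(mk(6), mk(8)), bulk_ratio = 2.57)
  expect_equal(tab$mean_F[1], 7)
  expect_equal(tab$mean_dev_F[1], 1)
  expect_equal(tab$ratio_Ow_F[1], 2 / 7)
  expect_equal(tab$enriched[1], "HFIP")
  zero <- shell_average_table(list(structure(
    list(fluorine = matrix(0, 1), water = matrix(3, 1),
         shells = shell_definition(0.556, 1), reference = "x", dt = 10),
    class = "shell_occupancy")))
  expect_true(zero$ratio_undefined[1])
  expect_true(is.na(zero$ratio_Ow_F[1]))
})

test_that("contact events follow the strict consecutive-snapshot rule", {
  tr <- make_distance_fixture(c(0.45, 0.45, 0.55, 0.45), dt = 10)
  ev <- contact_events(tr, cutoffs = c(fluorine = 0.5),
                       species = "fluorine")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$duration_ps, c(20, 10))
  expect_true(ev$censored_start[1])
  expect_true(ev$censored_end[2])
  # constant series: one event spanning the whole trajectory
  tr2 <- make_distance_fixture(rep(0.3, 100), dt = 10)
  ev2 <- contact_events(tr2, cutoffs = c(fluorine = 0.5),
                        species = "fluorine")
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$duration_ps, 1000)
  expect_true(ev2$censored_start && ev2$censored_end)
  # water species uses its own cutoff
  trw <- make_distance_fixture(c(0.45, 0.35, 0.35), dt = 10,
                               species = "water")
  evw <- contact_events(trw, cutoffs = c(water = 0.4), species = "water")
  expect_equal(evw$duration_ps, 20)
  expect_error(contact_events(trw, cutoffs = c(fluorine = 0.5),
                              species = "water"), "no cutoff")
})

test_that("contact statistics implement the stated arithmetic", {
  ev <- data.frame(atom = 2L, id = "f", species = "fluorine", mol_id = 1L,
                   start_frame = 5L, end_frame = 6L,
                   duration_ps = c(rep(10, 8), 70, 90),
                   censored_start = FALSE, censored_end = FALSE)
  st <- contact_stats(ev, trajectory_length_ns = 2, threshold = 60)
  expect_equal(st$contacts_per_ns, 5)
  expect_equal(st$percent_long, 20)
  expect_equal(st$mean_long_duration_ps, 80)
  none <- contact_stats(ev[0, ], trajectory_length_ns = 2)
  expect_true(none$no_events)
  expect_equal(none$contacts_per_ns, 0)
  expect_equal(none$percent_long, 0)
  expect_error(contact_stats(ev, trajectory_length_ns = 0), "zero-length")
})

test_that("censored events are excluded from the long-duration mean", {
  ev <- data.frame(atom = 2L, id = "f", species = "fluorine", mol_id = 1L,
                   start_frame = 1L, end_frame = 9L,
                   duration_ps = c(90, 200),
                   censored_start = c(FALSE, TRUE),
                   censored_end = FALSE)
  st <- contact_stats(ev, trajectory_length_ns = 1, threshold = 60)
  expect_equal(st$percent_long, 100)
  expect_equal(st$mean_long_duration_ps, 90)
  expect_equal(st$n_censored_excluded, 1L)
})

test_that("mean contact duration sits at the Brownian crossing scale", {
  # free diffusion: a contact ends when the fluorine diffuses out of the
  # 0.5 nm shell; an independent single-particle first-passage simulation
  # serves as the oracle for the expected mean duration
  D <- 4.8e-10
  g <- small_free(n_hfip = 60, n_water = 0, box = 5, b = 0.3, d_hfip = D,
                  n_frames = 4000, dt = 2, seed = 63)
  ev <- contact_events(g$trajectory, cutoffs = c(fluorine = 0.5),
                       species = "fluorine")
  obs <- mean(ev$duration_ps[!(ev$censored_start | ev$censored_end)])
  set.seed(64)
  dn <- D * 1e6
  oracle <- replicate(400, {
    r <- c(stats::runif(1, 0.3, 0.5), 0, 0)
    steps <- 0L
    repeat {
      r <- r + stats::rnorm(3, 0, sqrt(2 * dn * 2))
      rr <- sqrt(sum(r^2))
      if (rr < 0.3) r <- r * (2 * 0.3 - rr) / rr
      steps <- steps + 1L
      if (sqrt(sum(r^2)) > 0.5 || steps > 5000) break
    }
    steps * 2
  })
  expect_lt(abs(log(obs / mean(oracle))), log(2))  # within a factor of 2
})

test_that("shell-1 occupancy and contact rate scale together", {
  occ1 <- numeric(4); rate <- numeric(4)
  ns <- c(10, 25, 45, 70)
  for (i in seq_along(ns)) {
    g <- small_free(n_hfip = ns[i], n_water = 0, box = 6, b = 0.3,
                    n_frames = 600, dt = 10, seed = 65 + i)
    occ <- shell_occupancy(g$trajectory,
                           shells = shell_definition(0.556, 5))
    occ1[i] <- mean(occ$fluorine[, 1])
    ev <- contact_events(g$trajectory, cutoffs = c(fluorine = 0.5),
                         species = "fluorine")
    rate[i] <- nrow(ev) / ((600 - 1) * 10 / 1000)
  }
  expect_gt(stats::cor(occ1, rate), 0.95)
})
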