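# fixture: molecules given as single centre atoms at fixed positions
cluster_traj <- function(pos_list, box = 6) {
  frames <- lapply(pos_list, function(p) p)
  na <- nrow(pos_list[[1]])
  atoms <- data.frame(name = "C2", resname = "HFP", resid = seq_len(na),
                      role = "other", mol_id = seq_len(na),
                      stringsAsFactors = FALSE)
  make_traj(frames, box = box, dt = 10, atoms = atoms)
}

test_that("components are transitive along chains", {
  pos <- rbind(c(1, 1, 1), c(1.3, 1, 1), c(1.6, 1, 1), c(4, 4, 4))
  tr <- cluster_traj(list(pos))
  lab <- find_clusters(tr, cutoff = 0.35, mode = "centers")
  expect_equal(unname(lab[1:3]), c(1L, 1L, 1L))  # A-B, B-C link A-C
  expect_equal(unname(lab[4]), 4L)
})

test_that("isolated molecules stay singletons with zero aggregation", {
  pos <- rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5), c(4.5, 0.5, 0.5),
               c(0.5, 2.5, 0.5), c(2.5, 2.5, 2.5))
  tr <- cluster_traj(list(pos))
  lab <- find_clusters(tr, cutoff = 0.35, mode = "centers")
  expect_equal(unname(lab), 1:5)
  st <- aggregation_stats(tr, cutoff = 0.35, mode = "centers")
  expect_equal(st$fraction_aggregated, 0)
  expect_equal(st$max_size, 1L)
})

test_that("labels equal a brute-force connected-components oracle", {
  set.seed(81)
  for (rep in 1:5) {
    pos <- matrix(stats::runif(90, 0, 3), ncol = 3)
    tr <- cluster_traj(list(pos), box = 3)
    lab <- find_clusters(tr, cutoff = 0.4, mode = "centers")
    # oracle: boolean transitive closure of the adjacency matrix
    n <- 30
    adj <- diag(TRUE, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - 3 * round(d / 3)
      if (sqrt(sum(d^2)) <= 0.4) adj[i, j] <- adj[j, i] <- TRUE
    }
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    oracle <- apply(adj, 1, function(row) min(which(row)))
    expect_equal(unname(lab), as.integer(oracle))
  }
})

test_that("labels are invariant under molecule re-ordering", {
  set.seed(82)
  pos <- matrix(stats::runif(45, 0, 3), ncol = 3)
  tr <- cluster_traj(list(pos), box = 3)
  lab <- find_clusters(tr, cutoff = 0.5, mode = "centers")
  perm <- sample(15)
  tr2 <- cluster_traj(list(pos[perm, , drop = FALSE]), box = 3)
  tr2$atoms$mol_id <- perm
  tr2$atoms$resid <- perm
  lab2 <- find_clusters(tr2, cutoff = 0.5, mode = "centers")
  expect_equal(lab2[order(as.integer(names(lab2)))],
               lab[order(as.integer(names(lab)))])
})

test_that("aggregation grows monotonically with the cutoff", {
  g <- small_free(n_hfip = 40, n_water = 0, box = 5, n_frames = 3,
                  seed = 83)
  fr <- vapply(c(0.25, 0.35, 0.5, 0.7), function(cc)
    aggregation_stats(g$trajectory, cutoff = cc)$fraction_aggregated, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("frozen configurations persist for the whole trajectory", {
  pos <- rbind(c(1, 1, 1), c(1.2, 1, 1), c(3, 3, 3))
  tr <- cluster_traj(list(pos, pos, pos, pos))
  st <- aggregation_stats(tr, cutoff = 0.35, mode = "centers")
  expect_equal(unique(st$fraction_by_frame), 2 / 3)
  expect_equal(st$mean_lifetime_ps, 4 * 10)
})

test_that("reshuffled clusterings in successive frames live one frame", {
  # frame 1: two triples; frame 2: three pairs, each sharing only one
  # molecule with any earlier triple (overlap < 50%)
  f1 <- rbind(c(1, 1, 1), c(1.3, 1, 1), c(1.15, 1.25, 1),
              c(3, 3, 3), c(3.3, 3, 3), c(3.15, 3.25, 3))
  f2 <- rbind(c(1, 1, 1), c(2, 2, 2), c(4, 4, 4),
              c(1.3, 1, 1), c(2.3, 2, 2), c(4.3, 4, 4))
  tr <- cluster_traj(list(f1, f2))
  st <- aggregation_stats(tr, cutoff = 0.35, mode = "centers")
  expect_equal(st$mean_lifetime_ps, 10)
})

test_that("an ideal gas matches the Poisson proximity probability", {
  # fraction of molecules with a neighbour within the cutoff, for
  # independently placed centres: 1 - (1 - Vc/V)^(n-1)
  cc <- 0.45
  g <- small_free(n_hfip = 40, n_water = 0, box = 5, b = 0.2,
                  d_hfip = 21.8e-10, n_frames = 150, dt = 50, seed = 84,
                  substeps_per_snapshot = 300)
  st <- aggregation_stats(g$trajectory, cutoff = cc, mode = "centers")
  vc <- 4 / 3 * pi * cc^3
  expected <- 1 - (1 - vc / 5^3)^(40 - 1)
  se <- stats::sd(st$fraction_by_frame) / sqrt(150)
  expect_lt(abs(st$fraction_aggregated - expected), 3 * se + 0.01)
})

test_that("oversized cutoffs are rejected", {
  g <- small_free(n_hfip = 3, n_water = 0, box = 4, n_frames = 2, seed = 1)
  expect_error(find_clusters(g$trajectory, cutoff = 2.5), "half the box")
})
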