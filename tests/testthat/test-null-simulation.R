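test_that("per-capita contributions average over occupied sites only", {
  b <- rbind(s1 = c(x = 10, y = 4, z = 0),
             s2 = c(x = 6, y = 0, z = 0))
  a <- rbind(s1 = c(x = 5, y = 4, z = 0),
             s2 = c(x = 2, y = 0, z = 0))
  pc <- mean_per_capita(b, a)
  expect_equal(pc[["x"]], (10 / 5 + 6 / 2) / 2)
  expect_equal(pc[["y"]], 1)
  expect_false("z" %in% names(pc))  # absent everywhere
})

test_that("positive biomass with zero abundance is rejected", {
  b <- rbind(s1 = c(x = 10)); a <- rbind(s1 = c(x = 0))
  expect_error(mean_per_capita(b, a), "per-capita")
})

test_that("randomized matrices preserve richness and biomass bounds", {
  sim <- generate_metacommunity(small_config(seed = 31))
  spec <- null_spec(sim$matrix, sim$abundance)
  set.seed(42)
  for (i in 1:5) {
    nm <- simulate_null_matrix(spec)
    expect_equal(dim(nm$biomass), dim(sim$matrix$biomass))
    expect_equal(rowSums(nm$biomass > 0), spec$richness_targets)
    # each simulated biomass within [min*percap, max*percap] per species
    for (sp in sample(spec$species, 10)) {
      v <- nm$biomass[, sp]
      v <- v[v > 0]
      expect_true(all(v >= spec$abundance_min[[sp]] *
                        spec$mean_per_capita[[sp]] - 1e-9))
      expect_true(all(v <= spec$abundance_max[[sp]] *
                        spec$mean_per_capita[[sp]] + 1e-9))
    }
  }
})

test_that("randomization is deterministic under a fixed seed", {
  sim <- generate_metacommunity(small_config(seed = 32))
  spec <- null_spec(sim$matrix, sim$abundance)
  set.seed(7); m1 <- simulate_null_matrix(spec)
  set.seed(7); m2 <- simulate_null_matrix(spec)
  expect_identical(m1, m2)
})

test_that("degenerate abundance bounds give identical per-species biomass", {
  b <- rbind(s1 = c(x = 2, y = 4), s2 = c(x = 2, y = 4),
             s3 = c(x = 2, y = 4))
  a <- b / 2
  co <- data.frame(site_id = rownames(b), latitude = 0,
                   longitude = c(0, 0.1, 0.2))
  m <- community_matrix(b, co)
  spec <- null_spec(m, a)
  set.seed(5)
  nm <- simulate_null_matrix(spec)
  # min = max everywhere, so any present species has its one possible value
  expect_true(all(nm$biomass[, "x"][nm$biomass[, "x"] > 0] == 2))
  expect_true(all(nm$biomass[, "y"][nm$biomass[, "y"] > 0] == 4))
  d <- partition_pair(nm$biomass["s1", ], nm$biomass["s2", ])
  expect_equal(d$components[["comp_l"]], 0)
  expect_equal(d$components[["comp_g"]], 0)
})

test_that("richness targets equal to the pool disable subsampling", {
  b <- rbind(s1 = c(x = 2, y = 4), s2 = c(x = 3, y = 5))
  a <- rbind(s1 = c(x = 1, y = 1), s2 = c(x = 1, y = 1))
  m <- community_matrix(b, data.frame(site_id = c("s1", "s2"), latitude = 0,
                                      longitude = c(0, 0.1)))
  spec <- null_spec(m, a)
  set.seed(3)
  nm <- simulate_null_matrix(spec)
  expect_true(all(nm$biomass > 0))
})

test_that("a degenerate null distribution yields empirical p of 1", {
  # all replicates identical to the observed data: no variation anywhere
  b <- rbind(s1 = c(x = 2, y = 4), s2 = c(x = 2, y = 4),
             s3 = c(x = 2, y = 4), s4 = c(x = 2, y = 4),
             s5 = c(x = 2, y = 4), s6 = c(x = 2, y = 4))
  a <- b
  co <- data.frame(site_id = rownames(b), latitude = 0,
                   longitude = seq(0, 0.5, by = 0.1))
  m <- community_matrix(b, co)
  nd <- null_test(m, a, n_reps = 5, seed = 1, radius_km = 100)
  expect_true(all(nd$p_empirical == 1))
  expect_true(all(nd$p_ttest == 1))
})

test_that("null means approach the observed mean when bias is absent", {
  sim <- generate_metacommunity(small_config(seed = 33))
  nd_small <- suppressWarnings(null_test(sim$matrix, sim$abundance,
                                         n_reps = 8, seed = 2,
                                         radius_km = 100))
  nd_big <- suppressWarnings(null_test(sim$matrix, sim$abundance,
                                       n_reps = 64, seed = 2,
                                       radius_km = 100))
  gap <- function(nd) abs(mean(nd$null_means[, "comp_l"]) -
                            nd$observed[["comp_l"]])
  expect_lt(gap(nd_big), gap(nd_small) + 0.05)
  # observed inside the sampled null range for the unbiased generator
  expect_gt(nd_big$p_empirical[["comp_l"]], 0.05)
})

test_that("frozen pairing reuses the observed comparison sets", {
  sim <- generate_metacommunity(small_config(seed = 34))
  nd <- suppressWarnings(null_test(sim$matrix, sim$abundance, n_reps = 3,
                                   seed = 4, radius_km = 100,
                                   repairing = "freeze"))
  expect_equal(nd$repairing, "freeze")
  expect_equal(nrow(nd$null_means), 3)
  expect_true(all(is.finite(nd$null_means)))
})

test_that("too few replicates are rejected", {
  sim <- generate_metacommunity(small_config(seed = 35))
  expect_error(null_test(sim$matrix, sim$abundance, n_reps = 1, seed = 1),
               "n_reps")
})
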