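test_that("worked pair decomposes into the expected five components", {
  wp <- worked_pair()
  d <- partition_pair(wp$reference, wp$comparison)
  expect_equal(unname(d$components), c(-4, -6, 4, -3, 0))
  expect_equal(d$delta_T, -9)
  expect_equal(d$div, -9)
  expect_equal(d$s_uB, 1)
  expect_equal(d$s_c, 2)
  expect_equal(d$s_uF, 1)
  expect_equal(d$T_B, d$s_uB * d$z_uB + d$s_c * d$z_cB)
  expect_equal(d$T_F, d$s_uF * d$z_uF + d$s_c * d$z_cF)
})

test_that("one-sided pairs zero out the gain terms", {
  d <- partition_pair(c(A = 10, B = 6, C = 2), c(B = 4, C = 4))
  expect_equal(unname(d$components), c(-4, -6, 0, 0, 0))
  expect_equal(d$delta_T, -10)
})

test_that("identical communities give all-zero components", {
  x <- c(A = 3, B = 5)
  d <- partition_pair(x, x)
  expect_equal(unname(d$components), rep(0, 5))
  expect_equal(unname(scale_components(d)), rep(0, 5))
})

test_that("pairs without shared species are an error", {
  expect_error(partition_pair(c(A = 1), c(B = 1)), "no shared species")
})

test_that("invalid communities are rejected", {
  expect_error(partition_pair(c(A = -1, B = 2), c(A = 1, B = 1)), "negative")
  expect_error(partition_pair(c(1, 2), c(A = 1, B = 1)), "species names")
  expect_error(partition_pair(c(A = 0, B = 0), c(A = 1, B = 1)), "empty")
})

test_that("conservation holds on random pairs", {
  set.seed(101)
  for (i in 1:500) {
    p <- random_pair()
    d <- partition_pair(p$reference, p$comparison)
    tol <- 1e-9 * max(abs(d$T_B), abs(d$T_F), 1)
    expect_lt(abs(sum(d$components) - d$delta_T), tol)
  }
})

test_that("swapping reference and comparison mirrors the components", {
  set.seed(202)
  for (i in 1:100) {
    p <- random_pair()
    d <- partition_pair(p$reference, p$comparison)
    r <- partition_pair(p$comparison, p$reference)
    expect_equal(r$components[["rich_g"]], -d$components[["rich_l"]])
    expect_equal(r$components[["comp_g"]], -d$components[["comp_l"]])
    expect_equal(r$components[["rich_l"]], -d$components[["rich_g"]])
    expect_equal(r$components[["comp_l"]], -d$components[["comp_g"]])
    expect_equal(r$components[["cde"]], -d$components[["cde"]])
  }
})

test_that("component signs follow the unique-vs-shared mean comparison", {
  set.seed(303)
  for (i in 1:100) {
    p <- random_pair(n_only_b = sample(1:5, 1), n_only_f = sample(1:5, 1))
    d <- partition_pair(p$reference, p$comparison)
    expect_lte(d$components[["rich_l"]], 0)
    expect_gte(d$components[["rich_g"]], 0)
    expect_identical(d$components[["comp_l"]] < 0, d$z_uB > d$z_cB)
    expect_identical(d$components[["comp_g"]] > 0, d$z_uF > d$z_cF)
  }
})

test_that("richness terms vanish exactly when there are no unique species", {
  p <- random_pair(n_only_b = 0, n_only_f = 0)
  d <- partition_pair(p$reference, p$comparison)
  expect_identical(d$components[["rich_l"]], 0)
  expect_identical(d$components[["rich_g"]], 0)
  expect_identical(d$components[["comp_l"]], 0)
  expect_identical(d$components[["comp_g"]], 0)
})

test_that("scaled components sum to unit absolute mass", {
  expect_equal(unname(scale_components(c(-4, -6, 4, -3, 0))),
               c(-4, -6, 4, -3, 0) / 17)
  expect_equal(unname(scale_components(c(-5, 0, 0, 0, 0))),
               c(-1, 0, 0, 0, 0))
  set.seed(404)
  for (i in 1:100) {
    p <- random_pair()
    sc <- scale_components(partition_pair(p$reference, p$comparison))
    expect_equal(sum(abs(sc)), 1, tolerance = 1e-12)
    expect_true(all(sc >= -1 & sc <= 1))
  }
})

test_that("whole-community-mean partition matches the worked example", {
  wp <- worked_pair()
  fk <- fox_kerr_partition(wp$reference, wp$comparison)
  expect_equal(unname(fk$components), c(-6, -4, 3, -2, 0))
  expect_equal(fk$div, -9)
})

test_that("the two partitions agree on CDE and DIV for random pairs", {
  set.seed(505)
  for (i in 1:200) {
    p <- random_pair()
    d <- partition_pair(p$reference, p$comparison)
    fk <- fox_kerr_partition(p$reference, p$comparison)
    expect_identical(fk$components[["cde"]], d$components[["cde"]])
    tol <- 1e-9 * max(abs(d$T_B), abs(d$T_F), 1)
    expect_lt(abs(fk$div - d$div), tol)
    expect_lt(abs(sum(fk$components) - d$delta_T), tol)
  }
})

test_that("a richness loss larger than the reference total is flagged", {
  # unique species tiny, shared species huge: |RICH_L| = 2*100 > T_B = 201
  d <- partition_pair(c(A = 1, B = 100, C = 100), c(B = 1, C = 1))
  expect_false(d$rich_l_exceeds_tb)
  d2 <- partition_pair(c(A = 1, B = 100, C = 100, D = 100),
                       c(B = 1, C = 1, D = 1))
  # |RICH_L| = 1 * 100 vs T_B = 301: not exceeded; build a real exceedance
  d3 <- partition_pair(c(tiny1 = 0.1, tiny2 = 0.1, big = 100),
                       c(big = 90))
  expect_true(abs(d3$components[["rich_l"]]) > d3$T_B)
  expect_true(d3$rich_l_exceeds_tb)
  expect_false(d2$rich_l_exceeds_tb)
})
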