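test_that("Q equals the unique-to-shared mean ratio", {
  wp <- worked_pair()
  d <- partition_pair(wp$reference, wp$comparison)
  expect_equal(q_statistic(d), 10 / 4)
  # algebraic identity with the component form
  expect_equal(q_statistic(d),
               (d$components[["comp_l"]] + d$components[["rich_l"]]) /
                 d$components[["rich_l"]])
  # z_uB = z_cB gives exactly 1
  d1 <- partition_pair(c(A = 4, B = 4, C = 4), c(B = 4, C = 4))
  expect_equal(q_statistic(d1), 1)
  # undefined without unique reference species
  d2 <- partition_pair(c(B = 4, C = 4), c(B = 2, C = 2))
  expect_true(is.na(q_statistic(d2)))
})

test_that("Q identity holds across random pairs", {
  set.seed(606)
  for (i in 1:200) {
    p <- random_pair(n_only_b = sample(1:5, 1))
    d <- partition_pair(p$reference, p$comparison)
    expect_equal(q_statistic(d),
                 (d$components[["comp_l"]] + d$components[["rich_l"]]) /
                   d$components[["rich_l"]],
                 tolerance = 1e-9)
    expect_equal(q_statistic(d), d$z_uB / d$z_cB, tolerance = 1e-12)
  }
})

test_that("DIV/CDE ratio handles sign and degeneracy", {
  wp <- worked_pair()
  d <- partition_pair(wp$reference, wp$comparison)
  expect_true(is.na(ratio_div_cde(d)))  # CDE is 0 for the worked pair
  d2 <- partition_pair(c(A = 10, B = 6, C = 2), c(B = 2.5, C = 2.5, D = 1))
  expect_equal(d2$components[["cde"]], -3)
  expect_equal(ratio_div_cde(d2), d2$div / -3)
  expect_equal(ratio_div_cde(d2, absolute = TRUE), abs(d2$div) / 3)
})

test_that("geometric mean matches the brute-force product root", {
  gm <- geometric_mean_bootstrap
  expect_equal(gm(c(2, 8), n_boot = 10, seed = 1)$point, 4)
  expect_equal(gm(c(1, 10, 100), n_boot = 10, seed = 1)$point, 10)
  set.seed(707)
  vals <- rlnorm(11, 1, 0.5)
  expect_equal(gm(vals, n_boot = 10, seed = 1)$point,
               prod(vals)^(1 / length(vals)),
               tolerance = 1e-12)
})

test_that("degenerate and excluded inputs are handled", {
  rs <- geometric_mean_bootstrap(4, n_boot = 50, seed = 2)
  expect_equal(rs$point, 4)
  expect_equal(rs$ci_low, 4)
  expect_equal(rs$ci_high, 4)
  rs2 <- geometric_mean_bootstrap(c(-1, 0, 2, 8, NA), n_boot = 50, seed = 2)
  expect_equal(rs2$point, 4)
  expect_equal(rs2$n_used, 2)
  expect_equal(rs2$n_excluded, 2)
  expect_error(geometric_mean_bootstrap(c(-1, 0), n_boot = 10, seed = 1),
               "no positive values")
})

test_that("bootstrap is reproducible under a seed and tightens with n", {
  vals <- exp(seq(log(0.5), log(20), length.out = 200))
  a <- geometric_mean_bootstrap(vals, n_boot = 300, seed = 11)
  b <- geometric_mean_bootstrap(vals, n_boot = 300, seed = 11)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$point)
  expect_gte(a$ci_high, a$point)
  small <- geometric_mean_bootstrap(vals[seq(1, 200, by = 10)],
                                    n_boot = 300, seed = 11)
  width <- function(x) x$ci_high - x$ci_low
  expect_lt(width(a), width(small))
})

test_that("size-class shares normalize within groups", {
  rec <- data.frame(
    group = c("unique_ref", "unique_ref", "shared_ref"),
    size_class_cm = c(10, 300, 60),
    biomass = c(60, 40, 5)
  )
  out <- size_class_contributions(rec)
  ur <- out[out$group == "unique_ref", ]
  expect_equal(ur$biomass_share[ur$bin == "<50"], 0.6)
  expect_equal(ur$biomass_share[ur$bin == ">200"], 0.4)
  expect_equal(out$biomass_share[out$group == "shared_ref"], 1)
  shares <- tapply(out$biomass_share, out$group, sum)
  expect_equal(unname(shares), rep(1, 2), ignore_attr = TRUE)
})

test_that("bins are half-open on the lower edge", {
  rec <- data.frame(group = "g", size_class_cm = c(50, 200), biomass = c(1, 1))
  out <- size_class_contributions(rec)
  expect_setequal(out$bin, c("50-200", ">200"))
})

test_that("groups without size classes are dropped with a warning", {
  rec <- data.frame(group = c("a", "b"), size_class_cm = c(NA, 10),
                    biomass = c(1, 1))
  expect_warning(out <- size_class_contributions(rec), "a")
  expect_equal(unique(out$group), "b")
})
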