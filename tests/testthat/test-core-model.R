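test_that("loading probabilities match the Poisson model", {
  expect_identical(prob_nonempty(poisson_load(0, 0)), 0)
  expect_identical(prob_multiplet(poisson_load(0, 0)), 0)
  expect_equal(prob_nonempty(poisson_load(log(2), log(2))), 0.75)
  expect_equal(prob_nonempty(poisson_load(0.05001, 0.05001)),
               1 - exp(-0.10002), tolerance = 1e-12)
  # multiplet probability against direct pmf summation at the Table-1 row-3 rate
  mu_half <- -log(0.6)
  expect_equal(prob_multiplet(poisson_load(mu_half, mu_half)),
               sum(dpois(2:50, 2 * mu_half)), tolerance = 1e-12)

  # event nesting holds for arbitrary loads
  set.seed(11)
  for (i in 1:50) {
    load <- poisson_load(runif(1, 0, 3), runif(1, 0, 3))
    expect_lte(prob_multiplet(load), prob_nonempty(load))
  }
})

test_that("multiplet frequency depends only on the rate sum, grows with it, and vanishes like mu/2", {
  set.seed(21)
  for (i in 1:25) {
    mu <- runif(1, 0.01, 4)
    split <- runif(1)
    expect_equal(multiplet_frequency(poisson_load(mu * split, mu * (1 - split))),
                 multiplet_frequency(poisson_load(mu, 0)), tolerance = 1e-13)
  }
  grid <- seq(0.05, 5, length.out = 100)
  m <- vapply(grid, function(mu) multiplet_frequency(poisson_load(mu, 0)),
              numeric(1))
  expect_true(all(diff(m) > 0))
  # first-order limit M -> mu/2
  expect_equal(multiplet_frequency(poisson_load(1e-6, 0)), 5e-7,
               tolerance = 1e-5)
  expect_error(multiplet_frequency(poisson_load(0, 0)),
               class = "barnyard_validation_error")
})

test_that("total-droplet inference follows the independence relation and rejects impossible counts", {
  expect_equal(infer_total_droplets(droplet_counts(2050, 2050, 100)), 42025)
  expect_equal(infer_total_droplets(droplet_counts(3950, 150, 100)), 5925)
  # fractional totals are kept real-valued
  expect_equal(infer_total_droplets(droplet_counts(2005, 2005, 10)), 402002.5)
  expect_error(infer_total_droplets(droplet_counts(10, 10, 0)),
               class = "barnyard_unidentifiable_total")
  expect_error(infer_total_droplets(droplet_counts(10, 10, 10)),
               class = "barnyard_inconsistent_counts")
  expect_error(infer_total_droplets(droplet_counts(50, 10, 10)),
               class = "barnyard_inconsistent_counts")
})

test_that("rate inversion reproduces known rates and is symmetric in the two types", {
  load <- infer_rates(droplet_counts(2050, 2050, 100))
  expect_equal(load$mu1, -log(39975 / 42025), tolerance = 1e-12)
  expect_equal(load$mu2, load$mu1)

  load4 <- infer_rates(droplet_counts(3850, 250, 100))
  expect_equal(load4$mu1, -log(0.6), tolerance = 1e-12)
  expect_equal(load4$mu2, 0.0263173083173734, tolerance = 1e-10)

  load5 <- infer_rates(droplet_counts(3950, 150, 100))
  expect_equal(load5$mu1, log(3), tolerance = 1e-12)

  swapped <- infer_rates(droplet_counts(250, 3850, 100))
  expect_identical(c(swapped$mu1, swapped$mu2), c(load4$mu2, load4$mu1))
})

test_that("expected_counts is the exact inverse of infer_rates", {
  for (counts in random_valid_counts(100, seed = 31)) {
    back <- expected_counts(infer_rates(counts))
    expect_equal(back$n_type1, counts$n_type1, tolerance = 1e-9)
    expect_equal(back$n_type2, counts$n_type2, tolerance = 1e-9)
    expect_equal(back$n_mixed, counts$n_mixed, tolerance = 1e-9)
  }
  zero <- expected_counts(poisson_load(0, 0, n_droplets = 1000))
  expect_identical(c(zero$n_type1, zero$n_type2, zero$n_mixed), c(0, 0, 0))
})

test_that("estimate_from_counts fills every field and is invariant under type swap", {
  est <- estimate_from_counts(droplet_counts(3050, 1050, 100))
  expect_s3_class(est, "multiplet_estimate")
  expect_equal(round(est$multiplet_frequency, 3), 0.065)
  expect_equal(est$load$n_droplets, 3050 * 1050 / 100)
  expect_equal(est$doublet_approximation, 2 * 100 / 4000)
  expect_false(est$degenerate)

  swapped <- estimate_from_counts(droplet_counts(1050, 3050, 100))
  expect_equal(swapped$multiplet_frequency, est$multiplet_frequency,
               tolerance = 1e-13)
  expect_equal(swapped$doublet_approximation, est$doublet_approximation)
})

test_that("doublet approximation is the exact cross-type ratio", {
  expect_equal(doublet_approximation(droplet_counts(2500, 2500, 1000)), 0.5)
  expect_equal(doublet_approximation(droplet_counts(2005, 2005, 10)),
               20 / 4000)
  set.seed(41)
  for (counts in random_valid_counts(20, seed = 41)) {
    expect_equal(doublet_approximation(counts),
                 2 * counts$n_mixed / (counts$n_type1 + counts$n_type2 -
                                         counts$n_mixed))
  }
})

test_that("droplet_counts enforces its invariants at construction", {
  expect_error(droplet_counts(-1, 5, 0), class = "barnyard_validation_error")
  expect_error(droplet_counts(5, 5, 6), class = "barnyard_validation_error")
  expect_error(droplet_counts(NA, 5, 1), class = "barnyard_validation_error")
  expect_message(droplet_counts(10.5, 20, 1), "non-integer")
  expect_equal(droplet_counts(30, 20, 5)$n_nonempty, 45)
})

test_that("parametric bootstrap is seed-reproducible and brackets the point estimate", {
  counts <- droplet_counts(2050, 2050, 100)
  ci <- bootstrap_interval(counts, n_boot = 200, level = 0.95, seed = 7)
  ci2 <- bootstrap_interval(counts, n_boot = 200, level = 0.95, seed = 7)
  expect_identical(ci[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
  expect_equal(ci$estimate, 0.049176878824, tolerance = 1e-9)
  # narrower level gives a narrower interval collapsing toward the estimate
  narrow <- bootstrap_interval(counts, n_boot = 200, level = 0.10, seed = 7)
  expect_lt(narrow$upper - narrow$lower, ci$upper - ci$lower)
  expect_error(bootstrap_interval(counts, n_boot = 10),
               class = "barnyard_validation_error")
})
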