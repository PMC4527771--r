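test_that("log prior is the product of uniform densities on the box", {
  p <- im_parameters(1, 2, 3, 0.1, 0.2, 4)
  expect_equal(log_prior(p, im_priors()), -6 * log(10))
  expect_equal(log_prior(p, im_priors(5, 5, 5, 5, 5, 5)), -6 * log(5))
  expect_equal(log_prior(im_parameters(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                         im_priors(1, 1, 1, 1, 1, 1)), 0)
  p2 <- p; p2[["theta1"]] <- 10.5
  expect_identical(log_prior(p2, im_priors()), -Inf)
  # scale consistency: doubling all bounds lowers the density by 6 log 2
  b2 <- im_priors(20, 20, 20, 20, 20, 20)
  expect_equal(log_prior(p, b2), log_prior(p, im_priors()) - 6 * log(2))
})

test_that("prior draws are uniform, in-support, and reproducible", {
  set.seed(42)
  draws <- replicate(50000, unclass(sample_prior(im_priors())))
  expect_lt(max(abs(rowMeans(draws) - 5)), 0.1)
  expect_true(all(draws >= 0 & draws <= 10))
  set.seed(7); a <- sample_prior(im_priors())
  set.seed(7); b <- sample_prior(im_priors())
  expect_identical(a, b)
})

test_that("sliding-window proposal reflects and stays symmetric", {
  p <- im_parameters(5, 1, 1, 0, 0, 1)
  set.seed(1)
  for (i in 1:200) {
    out <- propose_scalar_update(p, "theta1", 2, im_priors())
    expect_equal(out$log_hastings, 0)
    expect_true(out$params[["theta1"]] >= 4 && out$params[["theta1"]] <= 6)
    expect_equal(out$params[["theta2"]], 1) # others untouched
  }
  # reflection arithmetic at the lower boundary
  expect_equal(imcoal:::reflect01(0.1 - 0.4, 10), 0.3)
  expect_equal(imcoal:::reflect01(10.3, 10), 9.7)
  expect_error(propose_scalar_update(p, "bogus", 1), "unknown parameter")
  expect_error(propose_scalar_update(p, "theta1", -1), "window")

  # symmetry: empirical transition density v -> near-zero region equals the
  # reflected density (counts of landing in mirrored bins agree)
  set.seed(2)
  start <- im_parameters(0.3, 1, 1, 0, 0, 1)
  hits <- replicate(40000,
    propose_scalar_update(start, "theta1", 1, im_priors())$params[["theta1"]])
  # proposal from 0.3 with window 1: raw mass on (-0.2, 0) folds onto
  # (0, 0.2), doubling the density there relative to the unfolded region
  expect_true(all(hits >= 0 & hits <= 0.8))
  d1 <- mean(hits < 0.1)                    # folded bin, density 2
  d2 <- mean(hits >= 0.6 & hits < 0.7)      # plain bin, density 1
  expect_gt(d1 / d2, 1.7)
  expect_lt(d1 / d2, 2.3)
})
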