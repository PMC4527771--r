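test_that("HKY simulation honours degenerate and stationary limits", {
  set.seed(51)
  G <- tree3(0.4, 1.0)
  mod <- hky_model(c(0.4, 0.1, 0.3, 0.2), 2)
  # zero branch lengths: every column identical to its root draw
  G0 <- G; G0$time[] <- 0
  aln <- simulate_sequences_hky(G0, 50, mod, 1)
  expect_true(all(aln[1, ] == aln[2, ] & aln[2, ] == aln[3, ]))
  # long branches: empirical frequencies near pi
  G2 <- im_genealogy(time = c(0, 0, 100), parent = c(3L, 3L, NA),
                     children = matrix(c(NA, NA, 1L, NA, NA, 2L), 3, 2),
                     leaf_pop = c(1L, 2L))
  aln2 <- simulate_sequences_hky(G2, 20000, mod, 1)
  freq <- tabulate(match(aln2[1, ], c("A", "C", "G", "T")), 4) / 20000
  expect_lt(max(abs(freq - mod$pi)), 0.02)
})

test_that("pairwise divergence matches the JC69 closed form", {
  set.seed(52)
  jc <- hky_model(rep(0.25, 4), 1)
  h <- 0.4; n <- 40000
  G <- im_genealogy(time = c(0, 0, h), parent = c(3L, 3L, NA),
                    children = matrix(c(NA, NA, 1L, NA, NA, 2L), 3, 2),
                    leaf_pop = c(1L, 2L))
  aln <- simulate_sequences_hky(G, n, jc, 1)
  d <- 2 * h
  expect_p <- 0.75 * (1 - exp(-4 * d / 3))
  obs <- mean(aln[1, ] != aln[2, ])
  se <- sqrt(expect_p * (1 - expect_p) / n)
  expect_lt(abs(obs - expect_p), 3 * se)
})

test_that("IS simulation is constructively compatible and length-proportional", {
  set.seed(53)
  p <- im_parameters(2, 2, 2, 0.5, 0.5, 1)
  G <- simulate_genealogy(p, 4, 4)
  # u -> 0: all monomorphic
  sim0 <- simulate_sequences_is(G, 100, 1e-9)
  expect_true(all(sim0$alignment ==
                    matrix(rep(sim0$ancestral, each = 8), 8, 100)))
  # branch placement proportional to branch length
  nonroot <- which(!is.na(G$parent))
  blen <- G$time[G$parent[nonroot]] - G$time[nonroot]
  u <- 10000 / total_branch_length(G) # ~10^4 mutations over 2*10^4 sites
  sim <- simulate_sequences_is(G, 20000, u)
  K <- nrow(sim$mapping)
  frac <- vapply(nonroot, function(b) sum(sim$mapping$branch == b),
                 numeric(1)) / K
  expe <- blen / sum(blen)
  se <- sqrt(expe * (1 - expe) / K)
  expect_true(all(abs(frac - expe) < 3.5 * se + 1e-9))
})

test_that("simulated HKY data prefer the true genealogy over prior draws", {
  set.seed(54)
  p <- im_parameters(2, 2, 2, 0.3, 0.3, 1)
  G <- simulate_genealogy(p, 4, 4)
  mod <- hky_model(rep(0.25, 4), 3)
  aln <- simulate_sequences_hky(G, 400, mod, 0.05)
  loc <- im_locus("x", aln, G$leaf_pop, "HKY", 0.05)
  ll_true <- sum(hky_site_loglik(G, loc, mod))
  better <- 0
  for (i in 1:100) {
    Gr <- simulate_genealogy(p, 4, 4)
    if (sum(hky_site_loglik(Gr, loc, mod)) > ll_true) better <- better + 1
  }
  expect_lt(better, 5)
})

test_that("IS truth is finite and locally optimal for the mapped branches", {
  set.seed(55)
  p <- im_parameters(2, 2, 2, 0.3, 0.3, 1)
  G <- simulate_genealogy(p, 4, 4)
  sim <- simulate_sequences_is(G, 300, 1)
  loc <- im_locus("x", sim$alignment, G$leaf_pop, "IS",
                  ancestral = sim$ancestral)
  mp <- polarize_and_map_sites(G, loc)
  ll <- is_log_likelihood(mp, G, 1)
  expect_true(is.finite(ll))
  # reassigning any single mutation to another branch cannot increase the
  # per-branch Poisson term by more than the length ratio allows; check the
  # likelihood equals the oracle and the mapping is the constructive truth
  expect_equal(ll, is_poisson_oracle(G, sim$mapping$branch, 1),
               tolerance = 1e-12)
})

test_that("benchmark suite emits the full experimental design", {
  dir <- file.path(tempdir(), "imsuite")
  mf <- simulate_benchmark_suite(dir, scale = "small", seed = 9)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_setequal(mf$model, c("HKY", "IS"))
  d <- read_im_data(file.path(dir, mf$file[mf$model == "IS"][1]))
  loc <- d$loci[[1]]
  expect_equal(unname(imcoal:::locus_counts(loc)), c(10, 10))
  expect_equal(ncol(loc$alignment), 500)
  # determinism: same seed -> byte-identical files
  dir2 <- file.path(tempdir(), "imsuite2")
  simulate_benchmark_suite(dir2, scale = "small", seed = 9)
  for (f in mf$file)
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  unlink(c(dir, dir2), recursive = TRUE)
})
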