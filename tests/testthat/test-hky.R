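test_that("transition matrix has the analytic limits and symmetries", {
  mod <- hky_model(c(0.1, 0.2, 0.3, 0.4), kappa = 3)
  expect_equal(hky_transition_matrix(0, mod), diag(4),
               ignore_attr = TRUE)
  # stationarity at long times
  P <- hky_transition_matrix(1e4, mod)
  for (i in 1:4) expect_equal(unname(P[i, ]), mod$pi, tolerance = 1e-8)
  # rows are distributions, detailed balance holds
  P <- hky_transition_matrix(0.37, mod)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  F <- diag(mod$pi) %*% P
  expect_equal(F, t(F), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(hky_transition_matrix(-0.1, mod), "nonnegative")
})

test_that("kappa = 1 with uniform frequencies reproduces JC69", {
  mod <- hky_model(rep(0.25, 4), kappa = 1)
  for (t in seq(0.02, 3, length.out = 50)) {
    P <- hky_transition_matrix(t, mod)
    expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-4 * t / 3), 4),
                 tolerance = 1e-12)
  }
})

test_that("transition matrix equals the matrix-exponential oracle", {
  set.seed(21)
  for (i in 1:20) {
    pi <- as.numeric(rdirichlet1())
    kappa <- runif(1, 0.2, 8)
    t <- runif(1, 0.01, 3)
    expect_equal(unname(hky_transition_matrix(t, hky_model(pi, kappa))),
                 hky_pmat_expm(t, pi, kappa), tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(22)
  for (rep in 1:25) {
    n_leaf <- sample(3:4, 1)
    G <- random_tree(n_leaf, rate = runif(1, 0.5, 2))
    pi <- as.numeric(rdirichlet1())
    mod <- hky_model(pi, kappa = runif(1, 0.3, 6))
    u <- runif(1, 0.1, 1.5)
    aln <- random_alignment(n_leaf, 4)
    loc <- im_locus("x", aln, c(1, rep(2, n_leaf - 1)), "HKY", u)
    SL <- hky_site_loglik(G, loc, mod)
    bf <- hky_brute_force(G, loc, mod)
    expect_equal(SL, bf, tolerance = 1e-10)
    # R reference path agrees with the compiled path
    SL2 <- site_log_likelihoods(prune_conditional_likelihoods(G, loc, mod),
                                mod)
    expect_equal(SL2, SL, tolerance = 1e-10)
  }
})

test_that("conditional likelihoods have the structural properties", {
  set.seed(23)
  G <- tree3(0.3, 0.9)
  mod <- hky_model(c(0.1, 0.2, 0.3, 0.4), 2)
  # zero branch lengths: root CL is the indicator of the shared base
  G0 <- G; G0$time[] <- 0
  # (degenerate equal times are fine for the pruning recursion itself)
  loc <- im_locus("x", matrix("A", 3, 2), c(1, 1, 2), "HKY")
  CL <- prune_conditional_likelihoods(G0, loc, mod)
  expect_equal(as.numeric(CL[5, 1, ]), c(1, 0, 0, 0))
  # permuting site columns permutes CL columns identically
  aln <- random_alignment(3, 6)
  locA <- im_locus("x", aln, c(1, 1, 2), "HKY")
  locB <- im_locus("x", aln[, 6:1], c(1, 1, 2), "HKY")
  CA <- prune_conditional_likelihoods(G, locA, mod)
  CB <- prune_conditional_likelihoods(G, locB, mod)
  expect_equal(CA[5, , ], CB[5, 6:1, ])
  # root CL = pi gives log(sum pi^2)
  expect_equal(site_log_likelihoods(structure(
    array(rep(mod$pi, each = 5 * 1), c(5, 1, 4)), root = 5L,
    class = "im_cl_table"), mod), log(sum(mod$pi^2)))
})

test_that("site likelihoods sum to one over all patterns", {
  set.seed(24)
  for (rep in 1:5) {
    G <- random_tree(3, rate = runif(1, 0.5, 2))
    mod <- hky_model(as.numeric(rdirichlet1()), runif(1, 0.5, 4))
    u <- runif(1, 0.2, 1)
    pats <- as.matrix(expand.grid(1:4, 1:4, 1:4))
    aln <- matrix(c("A", "C", "G", "T")[t(pats)], ncol = 64)
    loc <- im_locus("x", aln, c(1, 2, 2), "HKY", u)
    expect_equal(sum(exp(hky_site_loglik(G, loc, mod))), 1,
                 tolerance = 1e-10)
  }
})

test_that("time reversibility: root placement on a two-leaf path is irrelevant", {
  set.seed(25)
  # for a reversible model the likelihood of two leaves joined at height h
  # depends only on the total path length 2h: pi_x P_xy(2h)
  mod <- hky_model(c(0.15, 0.35, 0.2, 0.3), 2.5)
  u <- 0.7
  for (h in c(0.1, 0.6, 1.7)) {
    G <- im_genealogy(time = c(0, 0, h), parent = c(3L, 3L, NA),
                      children = matrix(c(NA, NA, 1L, NA, NA, 2L), 3, 2),
                      leaf_pop = c(1L, 2L))
    P2 <- hky_transition_matrix(2 * h * u, mod)
    for (pat in list(c("A", "A"), c("A", "G"), c("C", "T"))) {
      loc <- im_locus("x", matrix(pat, 2, 1), c(1, 2), "HKY", u)
      x <- match(pat[1], c("A", "C", "G", "T"))
      y <- match(pat[2], c("A", "C", "G", "T"))
      expect_equal(hky_site_loglik(G, loc, mod),
                   log(mod$pi[x] * P2[x, y]), tolerance = 1e-12)
    }
  }
  # join order / child order of equal-split trees does not change the total
  aln <- random_alignment(4, 30)
  h <- c(0.2, 0.5, 0.9)
  G1 <- im_genealogy(time = c(0, 0, 0, 0, h),
                     parent = c(5L, 5L, 6L, 7L, 6L, 7L, NA),
                     children = matrix(c(NA, NA, NA, NA, 1L, 5L, 6L,
                                         NA, NA, NA, NA, 2L, 3L, 4L), 7, 2),
                     leaf_pop = c(1L, 1L, 1L, 2L))
  G2 <- im_genealogy(time = c(0, 0, 0, 0, h),
                     parent = c(5L, 5L, 6L, 7L, 6L, 7L, NA),
                     children = matrix(c(NA, NA, NA, NA, 2L, 3L, 6L,
                                         NA, NA, NA, NA, 1L, 5L, 4L), 7, 2),
                     leaf_pop = c(1L, 1L, 1L, 2L))
  loc <- im_locus("x", aln, c(1, 1, 1, 2), "HKY", 0.7)
  expect_equal(sum(hky_site_loglik(G1, loc, mod)),
               sum(hky_site_loglik(G2, loc, mod)), tolerance = 1e-10)
})

test_that("blocked reduction is invariant to block size", {
  set.seed(26)
  SL <- rnorm(16000, -2, 1)
  direct <- sum(SL)
  for (bs in c(1, 7, 64, 256, 16000)) {
    out <- blocked_total_loglik(SL, bs)
    expect_equal(out$total, direct, tolerance = 1e-9)
    expect_equal(sum(out$block_sums), out$total)
    expect_length(out$block_sums, ceiling(16000 / bs))
  }
  expect_equal(blocked_total_loglik(SL, 16000)$block_sums, sum(SL))
  expect_equal(blocked_total_loglik(SL[1:5], 1)$block_sums, SL[1:5])
  expect_error(blocked_total_loglik(SL, 0), "block_size")
})
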