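test_that("total branch length matches hand arithmetic and edge enumeration", {
  G2 <- im_genealogy(time = c(0, 0, 0.5), parent = c(3L, 3L, NA),
                     children = matrix(c(NA, NA, 1L, NA, NA, 2L), 3, 2),
                     leaf_pop = c(1L, 1L))
  expect_equal(total_branch_length(G2), 1.0)
  G3 <- tree3(0.2, 0.6)
  expect_equal(total_branch_length(G3), 0.2 + 0.2 + 0.6 + 0.4)
  set.seed(11)
  p <- im_parameters(2, 1, 3, 0.5, 0.2, 1)
  for (i in 1:100) {
    G <- simulate_genealogy(p, 3, 2)
    nonroot <- which(!is.na(G$parent))
    oracle <- sum(vapply(nonroot, function(v)
      G$time[G$parent[v]] - G$time[v], numeric(1)))
    expect_equal(total_branch_length(G), oracle)
  }
})

test_that("validator accepts simulated genealogies and flags broken ones", {
  set.seed(12)
  p <- im_parameters(2, 2, 2, 0.5, 0.5, 1)
  for (i in 1:50) {
    G <- simulate_genealogy(p, 3, 3)
    expect_length(validate_genealogy(G, p), 0)
  }
  G <- simulate_genealogy(p, 3, 3)
  Gbad <- G
  rt <- which(is.na(G$parent))
  v <- G$children[rt, 1]
  if (is.na(Gbad$children[v, 1])) v <- G$children[rt, 2]
  # make a child older than its parent
  Gbad$time[v] <- G$time[rt] + 1
  expect_gt(length(validate_genealogy(Gbad, p)), 0)
  # migration above t_split
  Gm <- G
  Gm$migrations <- data.frame(node = G$children[rt, 1],
                              time = unclass(p)[["t"]] + 0.5,
                              from = 1L, to = 2L)
  expect_gt(length(validate_genealogy(Gm, p)), 0)
})

test_that("genealogy density matches hand formulas on tiny cases", {
  # two leaves, one population, t_split = 0: pure ancestral exponential
  p <- im_parameters(1, 1, 4, 0, 0, 0)
  tau <- 0.8
  G <- im_genealogy(time = c(0, 0, tau), parent = c(3L, 3L, NA),
                    children = matrix(c(NA, NA, 1L, NA, NA, 2L), 3, 2),
                    leaf_pop = c(1L, 1L))
  expect_equal(log_genealogy_density(G, p), log(2 / 4) - (2 / 4) * tau)

  # leaves in pops 1 and 2, one migration then a within-pop-2 coalescence
  # below t_split: hand interval scan over the two intervals
  p2 <- im_parameters(2, 3, 1, 0.7, 0.4, 5)
  a <- 0.6; b <- 1.4
  Gm <- im_genealogy(time = c(0, 0, b), parent = c(3L, 3L, NA),
                     children = matrix(c(NA, NA, 1L, NA, NA, 2L), 3, 2),
                     leaf_pop = c(1L, 2L),
                     migrations = data.frame(node = 1L, time = a,
                                             from = 1L, to = 2L))
  hand <- log(0.7) + log(2 / 3) -
    a * (0.7 + 0.4) -      # k1=1,k2=1: no coalescence possible, only migration
    (b - a) * (2 * 1 / 3 + 2 * 0.4)  # k2=2: coal rate 2/theta2, migration 2*m2
  expect_equal(log_genealogy_density(Gm, p2), hand)
})

test_that("density agrees with an independent interval-scan oracle", {
  set.seed(13)
  p <- im_parameters(1.5, 2.5, 2, 0.8, 0.3, 1.2)
  for (i in 1:60) {
    G <- simulate_genealogy(p, 3, 3)
    expect_equal(log_genealogy_density(G, p), coal_density_oracle(G, p),
                 tolerance = 1e-10)
  }
})

test_that("pair-coalescence time has mean thetaA/2 and split blocks early coalescence", {
  set.seed(14)
  p <- im_parameters(1, 1, 4, 0, 0, 0)
  tm <- replicate(5000, max(simulate_genealogy(p, 2, 0)$time))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2), 3 * se)
  # no migration, large t_split, leaves in different populations
  p2 <- im_parameters(2, 2, 2, 0, 0, 4)
  first <- replicate(500, min(simulate_genealogy(p2, 1, 1)$time[3]))
  expect_true(all(first > 4))
})

test_that("simulated genealogies satisfy structural bounds", {
  set.seed(15)
  p <- im_parameters(2, 2, 2, 1, 1, 0.8)
  for (i in 1:50) {
    G <- simulate_genealogy(p, 4, 3)
    expect_gte(total_branch_length(G), 2 * max(G$time))
  }
})

test_that("newick export contains every leaf and parses as a tree", {
  set.seed(16)
  G <- simulate_genealogy(im_parameters(2, 2, 2, 0.5, 0.5, 1), 3, 2)
  nw <- genealogy_newick(G)
  expect_match(nw, ";$")
  for (i in 1:5) expect_match(nw, paste0("p", G$leaf_pop[i], "_", i))
  ph <- ape::read.tree(text = gsub("\\[[^]]*\\]", "", nw))
  expect_equal(ape::Ntip(ph), 5L)
})
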