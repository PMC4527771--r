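test_that("clade mapping classifies the textbook cases", {
  G <- tree3(0.4, 1.0)
  anc <- rep("A", 3)
  # derived allele in leaves 1 and 2 only -> edge above their ancestor
  aln <- matrix(c("G", "G", "A", "A", "A", "A", "A", "C", "A"), 3, 3)
  loc <- im_locus("x", aln, c(1, 1, 2), "IS", ancestral = anc)
  mp <- polarize_and_map_sites(G, loc)
  expect_equal(as.character(mp$status), c("mapped", "monomorphic", "mapped"))
  expect_equal(mp$branch[1], 4L) # internal node joining leaves 1, 2
  expect_equal(mp$branch[3], 2L) # leaf edge
  expect_equal(mp$B[1], 1.0 - 0.4)
  expect_equal(sum(mp$M), 2L)
  # non-monophyletic carriers (leaves 1 and 3) -> incompatible
  aln2 <- matrix(c("G", "A", "G"), 3, 1)
  mp2 <- polarize_and_map_sites(G, im_locus("x", aln2, c(1, 1, 2), "IS",
                                            ancestral = "A"))
  expect_equal(as.character(mp2$status), "incompatible")
  # all-monomorphic alignment
  mp3 <- polarize_and_map_sites(G, im_locus("x", matrix("T", 3, 5),
                                            c(1, 1, 2), "IS",
                                            ancestral = rep("T", 5)))
  expect_true(all(mp3$status == "monomorphic"))
  expect_equal(sum(mp3$m_b), 0L)
  # three alleles at a site -> incompatible
  aln4 <- matrix(c("A", "C", "G"), 3, 1)
  mp4 <- polarize_and_map_sites(G, im_locus("x", aln4, c(1, 1, 2), "IS",
                                            ancestral = "A"))
  expect_equal(as.character(mp4$status), "incompatible")
})

test_that("Poisson likelihood matches the closed forms and the dpois oracle", {
  G <- tree3(0.4, 1.0)
  anc <- rep("A", 6)
  # no mutations anywhere: log L = -BT * u
  loc0 <- im_locus("x", matrix("A", 3, 6), c(1, 1, 2), "IS", u = 0.7,
                   ancestral = anc)
  mp0 <- polarize_and_map_sites(G, loc0)
  expect_equal(is_log_likelihood(mp0, G, 0.7),
               -total_branch_length(G) * 0.7)
  # exactly one mutation on a known branch, u = 1
  aln1 <- matrix("A", 3, 6); aln1[c(1, 2), 1] <- "G"
  mp1 <- polarize_and_map_sites(G, im_locus("x", aln1, c(1, 1, 2), "IS",
                                            ancestral = anc))
  expect_equal(is_log_likelihood(mp1, G, 1),
               -total_branch_length(G) + log(0.6))
  expect_error(is_log_likelihood(mp1, G, 0), "positive")
  # random mappings vs per-branch Poisson oracle
  set.seed(31)
  for (rep in 1:40) {
    p <- im_parameters(2, 2, 2, 0.4, 0.4, 1)
    Gr <- simulate_genealogy(p, 3, 3)
    sim <- simulate_sequences_is(Gr, 100, runif(1, 0.5, 2))
    u <- runif(1, 0.3, 2)
    loc <- im_locus("x", sim$alignment, Gr$leaf_pop, "IS", u,
                    ancestral = sim$ancestral)
    mp <- polarize_and_map_sites(Gr, loc)
    expect_equal(is_log_likelihood(mp, Gr, u),
                 is_poisson_oracle(Gr, sim$mapping$branch, u),
                 tolerance = 1e-12)
  }
})

test_that("simulated IS data maps back to the simulating branches exactly", {
  set.seed(32)
  for (rep in 1:10) {
    p <- im_parameters(2, 2, 2, 0.5, 0.5, 1)
    G <- simulate_genealogy(p, 5, 5)
    sim <- simulate_sequences_is(G, 300, 1)
    loc <- im_locus("x", sim$alignment, G$leaf_pop, "IS",
                    ancestral = sim$ancestral)
    mp <- polarize_and_map_sites(G, loc)
    expect_equal(sum(mp$status == "incompatible"), 0L)
    got <- data.frame(site = which(mp$status == "mapped"),
                      branch = mp$branch[mp$status == "mapped"])
    tru <- sim$mapping[order(sim$mapping$site), ]
    expect_equal(got$branch, as.integer(tru$branch))
    expect_equal(got$site, as.integer(tru$site))
    expect_equal(sum(mp$M), sum(mp$m_b))
  }
})

test_that("Poisson masses over count configurations sum correctly", {
  # exp(loglik) summed over all per-branch count vectors with total K must
  # equal the Poisson probability that K events fall on the tree
  G <- tree3(0.3, 0.8)
  u <- 1.3
  nonroot <- which(!is.na(G$parent))
  blen <- G$time[G$parent[nonroot]] - G$time[nonroot]
  BT <- sum(blen)
  for (K in 0:3) {
    cfgs <- expand.grid(rep(list(0:K), length(nonroot)))
    cfgs <- cfgs[rowSums(cfgs) == K, , drop = FALSE]
    tot <- sum(apply(cfgs, 1, function(m)
      exp(sum(dpois(as.numeric(m), blen * u, log = TRUE)))))
    expect_equal(tot, dpois(K, BT * u), tolerance = 1e-12)
  }
})

test_that("either-polarity mode maps without an ancestral designation", {
  set.seed(33)
  G <- simulate_genealogy(im_parameters(2, 2, 2, 0.5, 0.5, 1), 4, 4)
  sim <- simulate_sequences_is(G, 200, 1)
  loc <- im_locus("x", sim$alignment, G$leaf_pop, "IS")
  expect_error(polarize_and_map_sites(G, loc), "ancestral")
  mp <- polarize_and_map_sites(G, loc, polarity = "either")
  expect_equal(sum(mp$status == "incompatible"), 0L)
  expect_true(is.finite(is_log_likelihood(mp, G, 1)))
})

test_that("compatibility equals the clade test on random perturbations", {
  set.seed(34)
  G <- simulate_genealogy(im_parameters(2, 2, 2, 0, 0, 0.5), 4, 2)
  L <- imcoal:::leafset_matrix(G)
  clades <- apply(L[which(!is.na(G$parent)), , drop = FALSE], 1, paste,
                  collapse = "")
  for (rep in 1:50) {
    carriers <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    if (!any(carriers) || all(carriers)) next
    aln <- matrix("A", 6, 1); aln[carriers, 1] <- "T"
    mp <- polarize_and_map_sites(G, im_locus("x", aln, G$leaf_pop, "IS",
                                             ancestral = "A"))
    is_clade <- paste(carriers, collapse = "") %in% clades
    expect_equal(mp$status[1] == "mapped", is_clade)
  }
})
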