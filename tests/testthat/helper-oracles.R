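# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: likelihoods by exhaustive state enumeration,
# transition matrices by matrix exponentials, densities by a hand-written
# interval scan.

# random timed genealogy on n1+n2 leaves (no migrations) built directly
random_tree <- function(n1, n2 = 0, rate = 1) {
  p <- im_parameters(theta1 = 2, theta2 = 2, thetaA = 2 / rate,
                     m1 = 0, m2 = 0, t = 0)
  simulate_genealogy(p, n1 + n2, 0) # single-pool tree, then relabel
}

# HKY rate matrix normalized to mean rate 1 (base order A,C,G,T)
hky_rate_matrix <- function(pi, kappa) {
  Q <- matrix(0, 4, 4)
  transitions <- list(c(1, 3), c(3, 1), c(2, 4), c(4, 2))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- any(vapply(transitions, function(x) all(x == c(i, j)), logical(1)))
    Q[i, j] <- pi[j] * ifelse(ts, kappa, 1)
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# transition matrix by matrix exponential (Matrix::expm)
hky_pmat_expm <- function(t, pi, kappa) {
  as.matrix(Matrix::expm(hky_rate_matrix(pi, kappa) * t))
}

# total per-site log-likelihood by brute-force enumeration of all internal
# state assignments (trees with <= 4 leaves)
hky_brute_force_site <- function(G, codes_col, model, u) {
  ints <- which(!is.na(G$children[, 1L]))
  rt <- which(is.na(G$parent))
  nonroot <- which(!is.na(G$parent))
  states <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    st <- c(codes_col, rep(NA_integer_, length(ints)))
    st[ints] <- states[r, ]
    pr <- model$pi[st[rt]]
    for (v in nonroot) {
      P <- hky_transition_matrix((G$time[G$parent[v]] - G$time[v]) * u, model)
      pr <- pr * P[st[G$parent[v]], st[v]]
    }
    tot <- tot + pr
  }
  log(tot)
}

hky_brute_force <- function(G, locus, model) {
  codes <- matrix(match(locus$alignment, c("A", "C", "G", "T")),
                  nrow(locus$alignment))
  vapply(seq_len(ncol(codes)), function(j)
    hky_brute_force_site(G, codes[, j], model, locus$u), numeric(1))
}

# infinite-sites likelihood as an explicit product of per-branch Poisson
# probability masses
is_poisson_oracle <- function(G, branch_of_mutation, u) {
  nonroot <- which(!is.na(G$parent))
  blen <- G$time[G$parent[nonroot]] - G$time[nonroot]
  cnt <- vapply(nonroot, function(b) sum(branch_of_mutation == b), numeric(1))
  sum(dpois(cnt, blen * u, log = TRUE))
}

# structured-coalescent log-density by an independent R interval scan over
# explicitly constructed event tables
coal_density_oracle <- function(G, params) {
  p <- unclass(params)
  N <- G$N
  M <- length(G$time)
  ev <- rbind(
    data.frame(t = G$time[(N + 1):M], type = "coal",
               idx = (N + 1):M),
    if (nrow(G$migrations))
      data.frame(t = G$migrations$time, type = "mig",
                 idx = seq_len(nrow(G$migrations)))
  )
  ev <- ev[order(ev$t), ]
  lab <- rep(NA_integer_, M)
  lab[seq_len(N)] <- G$leaf_pop
  k <- c(sum(G$leaf_pop == 1), sum(G$leaf_pop == 2))
  cur <- 0; ld <- 0; anc <- !(p[["t"]] > 0)
  add_interval <- function(to) {
    dt <- to - cur
    if (dt > 0) {
      rate <- if (!anc)
        k[1] * (k[1] - 1) / p[["theta1"]] + k[2] * (k[2] - 1) / p[["theta2"]] +
          k[1] * p[["m1"]] + k[2] * p[["m2"]]
      else sum(k) * (sum(k) - 1) / p[["thetaA"]]
      ld <<- ld - dt * rate
    }
    cur <<- to
  }
  for (r in seq_len(nrow(ev))) {
    if (!anc && ev$t[r] >= p[["t"]]) { add_interval(p[["t"]]); anc <- TRUE }
    add_interval(ev$t[r])
    if (ev$type[r] == "mig") {
      mg <- G$migrations[ev$idx[r], ]
      lab[mg$node] <- mg$to
      ld <- ld + log(p[[paste0("m", mg$from)]])
      k[mg$from] <- k[mg$from] - 1
      k[mg$to] <- k[mg$to] + 1
    } else {
      v <- ev$idx[r]
      if (!anc) {
        l <- lab[G$children[v, 1]]
        lab[v] <- l
        ld <- ld + log(2 / p[[paste0("theta", l)]])
        k[l] <- k[l] - 1
      } else {
        ld <- ld + log(2 / p[["thetaA"]])
        if (k[1] > 0) k[1] <- k[1] - 1 else k[2] <- k[2] - 1
      }
    }
  }
  ld
}

# small helper: a fully specified 3-leaf genealogy (leaves 1,2 join at t12,
# with 3 at t123), all one population
tree3 <- function(t12, t123, pops = c(1L, 1L, 1L)) {
  im_genealogy(time = c(0, 0, 0, t12, t123),
               parent = c(4L, 4L, 5L, 5L, NA),
               children = matrix(c(NA, NA, NA, 1L, 3L,
                                   NA, NA, NA, 2L, 4L), 5, 2),
               leaf_pop = pops)
}

# one draw of base frequencies bounded away from zero
rdirichlet1 <- function() {
  x <- rexp(4) + 0.3
  x / sum(x)
}

# random alignment over ACGT
random_alignment <- function(n_seq, n_sites) {
  matrix(sample(c("A", "C", "G", "T"), n_seq * n_sites, replace = TRUE),
         n_seq, n_sites)
}
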