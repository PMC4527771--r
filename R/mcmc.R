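#' Metropolis-Hastings acceptance probability
#'
#' `min(1, exp(beta * (log_post_new - log_post_old) + log_hastings))`; heated
#' chains raise the posterior ratio to `beta`.
#'
#' @param log_post_new,log_post_old Log posteriors of proposed and current
#'   state (either may be `-Inf`, not both).
#' @param log_hastings Log proposal-ratio correction.
#' @param beta Heating exponent in (0, 1].
#' @return Acceptance probability in \[0, 1\].
#' @export
mh_accept_probability <- function(log_post_new, log_post_old,
                                  log_hastings = 0, beta = 1) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  if (is.infinite(log_post_new) && is.infinite(log_post_old) &&
      log_post_new < 0 && log_post_old < 0)
    stop("both posteriors are zero; the chain must never occupy such a state")
  if (is.infinite(log_post_new) && log_post_new < 0) return(0)
  x <- beta * (log_post_new - log_post_old) + log_hastings
  if (is.nan(x)) return(0)
  min(1, exp(x))
}

#' Heating temperatures for Metropolis-coupled chains
#'
#' Incremental scheme `beta_k = 1 / (1 + lambda * (k - 1))`: the first
#' (cold) chain has `beta = 1` and temperatures decrease strictly.
#'
#' @param n_chains Number of chains (>= 1).
#' @param lambda Positive heating increment.
#' @return Numeric vector of `beta` values.
#' @export
heating_schedule <- function(n_chains, lambda = 0.05) {
  if (n_chains < 1L) stop("n_chains must be >= 1")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  1 / (1 + lambda * (seq_len(n_chains) - 1))
}

#' Attempt a state swap between two Metropolis-coupled chains
#'
#' Standard exchange move: accepted with probability
#' `min(1, exp((beta_cold - beta_hot) * (logpost_hot - logpost_cold)))`. On
#' acceptance the full states (parameters and all genealogies) exchange
#' while the temperatures stay with the chain slots.
#'
#' @param cold,hot Chain states (lists carrying `beta` and the cached
#'   log-posterior pieces `loglik`, `dens_tot` (or `logdens`) and
#'   `logprior`, as produced by the sampler).
#' @return List `(cold, hot, accepted)`.
#' @export
mc3_swap <- function(cold, hot) {
  lp_c <- chain_log_posterior(cold)
  lp_h <- chain_log_posterior(hot)
  pr <- min(1, exp((cold$beta - hot$beta) * (lp_h - lp_c)))
  accepted <- runif(1L) < pr
  if (accepted) {
    bc <- cold$beta; bh <- hot$beta
    tmp <- cold; cold <- hot; hot <- tmp
    cold$beta <- bc; hot$beta <- bh
  }
  list(cold = cold, hot = hot, accepted = accepted)
}

chain_log_posterior <- function(st) {
  ld <- if (!is.null(st$dens_tot)) st$dens_tot else sum(st$logdens)
  sum(st$loglik) + ld + st$logprior
}

#' Sampler tuning options
#'
#' @param windows Named list of sliding-window widths for the six
#'   parameters; defaults to bound/5.
#' @param kappa `"sample"` (per-HKY-locus kappa sampled with a Uniform(0,
#'   `kappa_bound`) prior; default) or a fixed positive number.
#' @param kappa_bound,kappa_window Prior bound and proposal window for
#'   sampled kappa.
#' @param pi `"empirical"` (per-locus base frequencies from the alignment
#'   with a +1 pseudocount) or a numeric 4-vector.
#' @param likelihood `"on"` or `"off"` (validation mode: the sequence
#'   likelihood is held at a constant so the sampler targets the prior).
#' @param tempering `"posterior"` (heat the full posterior; default) or
#'   `"likelihood"` (heat only the likelihood).
#' @param root_delta Half-width of the log-uniform root-height multiplier.
#' @param scale_delta Half-width of the log-uniform factor of the joint
#'   (t, genealogy-times) rescaling move (0 disables the move); a second
#'   attempt with triple the width runs each generation for long jumps.
#' @param shift_delta Half-width of the uniform offset of the split-shift
#'   move, which translates `t` together with every genealogy event time
#'   above it.
#' @param gibbs Use exact Gibbs draws from the closed-form full
#'   conditionals of the migration rates and population mutation
#'   parameters in addition to the window scan.
#' @param refresh_prob Per-locus per-generation probability of an
#'   independence proposal that redraws the genealogy from the structured
#'   coalescent at the current parameters (accepted with the likelihood
#'   ratio; 0 disables).
#' @param lambda Heating increment for [heating_schedule()].
#' @param polarity Infinite-sites polarization rule, see
#'   [polarize_and_map_sites()].
#' @param audit_every Recompute all cached log-posterior terms from scratch
#'   through the reference (uncompiled) code path every this many
#'   generations and stop on disagreement beyond 1e-8 (0 disables).
#' @param init_retries Prior draws attempted before giving up on finding a
#'   starting state with positive posterior.
#' @return List of class `im_control`.
#' @export
im_control <- function(windows = NULL, kappa = "sample", kappa_bound = 100,
                       kappa_window = kappa_bound / 5, pi = "empirical",
                       likelihood = c("on", "off"),
                       tempering = c("posterior", "likelihood"),
                       root_delta = 0.5, scale_delta = 0.3, shift_delta = 2,
                       gibbs = TRUE, refresh_prob = 0.15, lambda = 0.05,
                       polarity = c("ancestral_row", "either"),
                       audit_every = 2500, init_retries = 50L) {
  structure(list(windows = windows, kappa = kappa, kappa_bound = kappa_bound,
                 kappa_window = kappa_window, pi = pi,
                 likelihood = match.arg(likelihood),
                 tempering = match.arg(tempering),
                 root_delta = root_delta, scale_delta = scale_delta,
                 shift_delta = shift_delta,
                 gibbs = gibbs, refresh_prob = refresh_prob,
                 lambda = lambda,
                 polarity = match.arg(polarity),
                 audit_every = audit_every,
                 init_retries = as.integer(init_retries)),
            class = "im_control")
}

# ---------------------------------------------------------------------------
# locus caches: everything the per-generation loop needs, precomputed
# ---------------------------------------------------------------------------

build_locus_cache <- function(locus, control) {
  N1 <- sum(locus$pop_labels == 1L)
  N2 <- sum(locus$pop_labels == 2L)
  cache <- list(name = locus$name, model = locus$model, u = locus$u,
                N1 = N1, N2 = N2, locus = locus)
  if (locus$model == "HKY") {
    cache$codes <- locus_codes(locus)
    cache$pi <- if (identical(control$pi, "empirical")) empirical_pi(locus)
                else as.numeric(control$pi)
  } else {
    if (control$polarity == "ancestral_row") {
      if (is.null(locus$ancestral))
        stop("IS locus '", locus$name, "' has no ancestral designation")
      aln <- locus$alignment
      nallele <- apply(aln, 2L, function(x) length(unique(x)))
      bi <- which(nallele == 2L)
      carr <- if (length(bi))
        t(aln[, bi, drop = FALSE] !=
            matrix(locus$ancestral[bi], nrow(aln), length(bi), byrow = TRUE))
      else matrix(FALSE, 0L, nrow(aln))
      full <- rowSums(carr) == nrow(aln)
      cache$has_incompatible <- any(nallele > 2L) || any(full)
      cache$carriers <- carr[!full, , drop = FALSE]
    } else {
      cache$either <- TRUE
    }
  }
  cache
}

# ---------------------------------------------------------------------------
# array-form genealogies: the chain state holds compact arrays; classed
# genealogy objects are materialized only where needed (audits, output)
# ---------------------------------------------------------------------------

gen_arrays <- function(G) {
  p0 <- G$parent; p0[is.na(p0)] <- 0L
  list(time = G$time, parent0 = p0, ch0 = children0(G),
       post = internal_postorder(G), leaf_pop = G$leaf_pop, N = G$N,
       mt = G$migrations$time, mn = G$migrations$node,
       mf = G$migrations$from, mto = G$migrations$to)
}

genealogy_from_arrays <- function(ar) {
  parent <- ar$parent0; parent[parent == 0L] <- NA_integer_
  ch <- ar$ch0; ch[ch == 0L] <- NA_integer_
  im_genealogy(ar$time, parent, ch, ar$leaf_pop,
               data.frame(node = ar$mn, time = ar$mt, from = ar$mf,
                          to = ar$mto))
}

# array-form draw from the structured coalescent (internal nodes are
# created in time order, so the postorder is just N+1 .. 2N-1)
simulate_gen_arrays <- function(params, N1, N2) {
  p <- unclass(params)
  r <- cpp_simulate_genealogy(p[["theta1"]], p[["theta2"]], p[["thetaA"]],
                              p[["m1"]], p[["m2"]], p[["t"]],
                              as.integer(N1), as.integer(N2))
  N <- N1 + N2
  list(time = r$time, parent0 = r$parent0, ch0 = r$children0,
       post = (N + 1L):(2L * N - 1L),
       leaf_pop = c(rep(1L, N1), rep(2L, N2)), N = N,
       mt = r$mig_time, mn = r$mig_node, mf = r$mig_from,
       mto = 3L - r$mig_from)
}

coal_stats <- function(ar, tsplit) {
  cpp_coal_stats(ar$time, ar$parent0, ar$ch0, ar$leaf_pop, ar$N,
                 ar$mt, ar$mn, ar$mf, ar$mto, tsplit)
}

# all loci in one call: list(stats = list per locus, total, ok)
coal_stats_all <- function(arrays, tsplit) {
  r <- cpp_coal_stats_multi(arrays, tsplit)
  list(stats = lapply(seq_along(arrays), function(i) r$stats[, i]),
       total = r$total, ok = r$ok)
}

# structured-coalescent log-density from sufficient statistics
# (c1, c2, cA, n1, n2, S1, S2, SA, L1, L2); the density is log-linear in
# these, so statistics summed over loci give the total density directly
dens_from_stats <- function(S, p) {
  if (is.na(S[1L])) return(-Inf)
  th1 <- p[["theta1"]]; th2 <- p[["theta2"]]; thA <- p[["thetaA"]]
  m1 <- p[["m1"]]; m2 <- p[["m2"]]
  val <- 0
  if (S[1L] > 0 || S[6L] > 0) {
    if (th1 <= 0) return(-Inf)
    val <- val + S[1L] * log(2 / th1) - S[6L] / th1
  }
  if (S[2L] > 0 || S[7L] > 0) {
    if (th2 <= 0) return(-Inf)
    val <- val + S[2L] * log(2 / th2) - S[7L] / th2
  }
  if (S[3L] > 0 || S[8L] > 0) {
    if (thA <= 0) return(-Inf)
    val <- val + S[3L] * log(2 / thA) - S[8L] / thA
  }
  if (S[4L] > 0) {
    if (m1 <= 0) return(-Inf)
    val <- val + S[4L] * log(m1)
  }
  if (S[5L] > 0) {
    if (m2 <= 0) return(-Inf)
    val <- val + S[5L] * log(m2)
  }
  val - S[9L] * m1 - S[10L] * m2
}

# density of all genealogies under params via the reference interval scan
all_logdens <- function(Gs, params) {
  vapply(Gs, log_genealogy_density, numeric(1), params = params,
         check = FALSE)
}

# locus log-likelihood from the array form
locus_loglik_ar <- function(ar, cache, kappa, control) {
  if (control$likelihood == "off") return(0)
  if (cache$model == "HKY") {
    sum(cpp_hky_site_loglik(ar$ch0, ar$post, ar$time, cache$codes, cache$pi,
                            kappa, cache$u))
  } else if (isTRUE(cache$either)) {
    G <- genealogy_from_arrays(ar)
    mp <- polarize_and_map_sites(G, cache$locus, polarity = "either")
    is_log_likelihood(mp, G, cache$u)
  } else {
    if (cache$has_incompatible) return(-Inf)
    nz <- which(ar$parent0 > 0L)
    BT <- sum(ar$time[ar$parent0[nz]] - ar$time[nz])
    if (nrow(cache$carriers) == 0L) return(-BT * cache$u)
    map <- cpp_is_map(ar$ch0, ar$post, ar$N, cache$carriers)
    if (any(map == 0L)) return(-Inf)
    blen <- ar$time[ar$parent0[map]] - ar$time[map]
    cnt <- tabulate(map, length(ar$time))
    cnt <- cnt[cnt > 1L]
    -BT * cache$u + sum(log(blen * cache$u)) - sum(lgamma(cnt + 1))
  }
}

locus_loglik <- function(G, cache, kappa, control, ar = NULL) {
  if (is.null(ar)) ar <- gen_arrays(G)
  locus_loglik_ar(ar, cache, kappa, control)
}

# ---------------------------------------------------------------------------
# starting genealogies
# ---------------------------------------------------------------------------

# Perfect-phylogeny-guided starting tree for an IS locus: every derived
# carrier set becomes a clade, clades mixing the two populations are placed
# above t_split, and no migration events are used. Initialization heuristic
# only; returns NULL when the site patterns are not pairwise compatible.
init_genealogy_is <- function(locus, params, control) {
  N <- nrow(locus$alignment)
  tsplit <- unclass(params)[["t"]]
  aln <- locus$alignment
  nallele <- apply(aln, 2L, function(x) length(unique(x)))
  if (any(nallele > 2L)) return(NULL)
  bi <- which(nallele == 2L)
  sets <- list()
  if (length(bi)) {
    if (!is.null(locus$ancestral)) {
      carr <- t(aln[, bi, drop = FALSE] !=
                  matrix(locus$ancestral[bi], N, length(bi), byrow = TRUE))
    } else {
      carr <- t(aln[, bi, drop = FALSE] !=
                  matrix(aln[1L, bi], N, length(bi), byrow = TRUE))
      flip <- rowSums(carr) > N / 2
      carr[flip, ] <- !carr[flip, ]
    }
    keep <- rowSums(carr) >= 2L & rowSums(carr) < N
    sets <- unique(lapply(which(keep), function(k) which(carr[k, ])))
    if (length(sets) > 1L) {
      for (i in seq_along(sets)[-1L]) for (j in seq_len(i - 1L)) {
        a <- sets[[i]]; b <- sets[[j]]
        ov <- length(intersect(a, b))
        if (ov > 0L && ov < min(length(a), length(b)) ||
            (ov == min(length(a), length(b)) &&
             !(all(a %in% b) || all(b %in% a))))
          return(NULL) # not laminar
      }
    }
  }
  M <- 2L * N - 1L
  time <- numeric(M); parent <- rep(NA_integer_, M)
  children <- matrix(NA_integer_, M, 2L)
  nxt <- N + 1L
  base_gap <- max(0.05, tsplit / max(2L, N))
  join <- function(a, b, floor_t) {
    v <- nxt; nxt <<- nxt + 1L
    tv <- max(time[a], time[b], floor_t) + runif(1L, 0.5, 1.5) * base_gap
    time[v] <<- tv
    children[v, ] <<- c(a, b)
    parent[a] <<- v; parent[b] <<- v
    v
  }
  pops <- locus$pop_labels
  build <- function(leafset) {
    if (length(leafset) == 1L) return(leafset)
    inner <- Filter(function(s) length(s) < length(leafset) &&
                      all(s %in% leafset), sets)
    if (length(inner) > 1L) { # maximal proper subsets only
      maximal <- vapply(seq_along(inner), function(i)
        !any(vapply(seq_along(inner), function(j)
          i != j && length(inner[[i]]) < length(inner[[j]]) &&
            all(inner[[i]] %in% inner[[j]]), logical(1))), logical(1))
      inner <- inner[maximal]
    }
    used <- unlist(inner)
    groups <- c(inner, as.list(setdiff(leafset, used)))
    ids <- vapply(groups, build, integer(1))
    gpop <- vapply(groups, function(s) {
      pp <- unique(pops[s]); if (length(pp) == 1L) pp else 0L
    }, integer(1))
    fold <- function(idx) {
      cur <- ids[idx[1L]]
      for (k in idx[-1L]) cur <- join(cur, ids[k], 0)
      cur
    }
    parts <- list()
    for (p in 1:2) if (any(gpop == p)) parts <- c(parts, fold(which(gpop == p)))
    if (any(gpop == 0L)) for (k in which(gpop == 0L)) parts <- c(parts, ids[k])
    cur <- parts[[1L]]
    if (length(parts) > 1L) {
      for (k in seq_along(parts)[-1L]) {
        # union across populations: force above t_split
        cur <- join(cur, parts[[k]], tsplit)
      }
    }
    cur
  }
  rt <- build(seq_len(N))
  if (rt != M) return(NULL)
  im_genealogy(time, parent, children, locus$pop_labels)
}

init_chain_state <- function(data, caches, priors, control, beta) {
  for (try in seq_len(control$init_retries)) {
    params <- sample_prior(priors)
    Gs <- lapply(seq_along(data$loci), function(i) {
      loc <- data$loci[[i]]
      cnt <- locus_counts(loc)
      if (loc$model == "IS") {
        g <- init_genealogy_is(loc, params, control)
        if (!is.null(g)) return(g)
      }
      simulate_genealogy(params, cnt[["N1"]], cnt[["N2"]])
    })
    kappas <- numeric(0)
    hky <- which(vapply(caches, function(c) c$model == "HKY", logical(1)))
    if (length(hky)) {
      nm <- vapply(caches[hky], `[[`, character(1), "name")
      kappas <- if (identical(control$kappa, "sample"))
        setNames(runif(length(hky), 0, control$kappa_bound), nm)
      else setNames(rep(as.numeric(control$kappa), length(hky)), nm)
    }
    arrays <- lapply(Gs, gen_arrays)
    stats <- lapply(arrays, coal_stats, tsplit = unclass(params)[["t"]])
    logdens <- vapply(stats, dens_from_stats, numeric(1), p = params)
    loglik <- vapply(seq_along(arrays), function(i)
      locus_loglik_ar(arrays[[i]], caches[[i]],
                      kappa_for(caches[[i]], kappas, control), control),
      numeric(1))
    logprior <- log_prior(params, priors)
    if (all(is.finite(c(logdens, loglik, logprior))))
      return(list(params = params, kappas = kappas,
                  arrays = arrays, stats = stats,
                  stats_sum = Reduce(`+`, stats),
                  dens_tot = sum(logdens),
                  loglik = loglik, logprior = logprior,
                  beta = beta,
                  acc = c(par_try = 0, par_acc = 0, tree_try = 0,
                          tree_acc = 0, scale_try = 0, scale_acc = 0)))
  }
  stop("could not find a starting state with positive posterior after ",
       control$init_retries, " prior draws")
}

kappa_for <- function(cache, kappas, control) {
  if (cache$model != "HKY") return(NA_real_)
  if (identical(control$kappa, "sample")) kappas[[cache$name]]
  else as.numeric(control$kappa)
}

# ---------------------------------------------------------------------------
# one generation of one chain
# ---------------------------------------------------------------------------

accept_delta <- function(x) {
  !is.nan(x) && (x >= 0 || runif(1L) < exp(x))
}

chain_step <- function(st, caches, priors, control, windows) {
  beta <- st$beta
  post_temp <- control$tempering == "posterior"
  # scalar demographic parameters: density via summed sufficient statistics
  for (pn in PAR_NAMES) {
    prop <- propose_scalar_update(st$params, pn, windows[[pn]], priors)
    lp <- log_prior(prop$params, priors)
    if (pn == "t") {
      cs <- coal_stats_all(st$arrays, unclass(prop$params)[["t"]])
      newstats <- cs$stats
      newsum <- cs$total
    } else {
      newstats <- NULL
      newsum <- st$stats_sum
    }
    nd_tot <- dens_from_stats(newsum, prop$params)
    d <- (nd_tot + lp) - (st$dens_tot + st$logprior)
    if (post_temp) d <- beta * d
    st$acc[["par_try"]] <- st$acc[["par_try"]] + 1
    if (accept_delta(d)) {
      st$params <- prop$params
      if (!is.null(newstats)) st$stats <- newstats
      st$stats_sum <- newsum
      st$dens_tot <- nd_tot
      st$logprior <- lp
      st$acc[["par_acc"]] <- st$acc[["par_acc"]] + 1
    }
  }
  # Gibbs draws from the closed-form full conditionals (kept alongside the
  # window scan; they decorrelate the rate parameters from the genealogy
  # statistics): m_p | rest ~ Gamma(w n_p + 1, w L_p) truncated to
  # [0, bound]; 1/theta | rest ~ Gamma(w c - 1, w S) truncated to
  # 1/theta >= 1/bound (skipped when the shape is not positive), with
  # w = beta under posterior tempering.
  if (isTRUE(control$gibbs)) {
  w <- if (post_temp) beta else 1
  Ssum <- st$stats_sum
  bnd <- unclass(priors)
  newpar <- st$params
  for (k in 1:2) {
    n_k <- Ssum[3L + k]; L_k <- Ssum[8L + k]; b <- bnd[[paste0("m", k)]]
    if (L_k > 0) {
      hi <- pgamma(b, w * n_k + 1, rate = w * L_k)
      if (hi > 0)
        newpar[[paste0("m", k)]] <-
          min(b, qgamma(runif(1L, 0, hi), w * n_k + 1, rate = w * L_k))
    } else newpar[[paste0("m", k)]] <- runif(1L, 0, b)
  }
  for (k in 1:3) {
    c_k <- Ssum[k]; S_k <- Ssum[5L + k]
    nm <- c("theta1", "theta2", "thetaA")[k]
    shape <- w * c_k - 1
    if (shape > 0 && S_k > 0) {
      lo <- pgamma(1 / bnd[[nm]], shape, rate = w * S_k)
      if (lo < 1) {
        x <- qgamma(runif(1L, lo, 1), shape, rate = w * S_k)
        if (x > 0 && is.finite(x)) newpar[[nm]] <- min(bnd[[nm]], 1 / x)
      }
    }
  }
  if (!identical(newpar, st$params)) {
    st$params <- newpar
    st$dens_tot <- dens_from_stats(Ssum, newpar)
  }
  }
  # joint rescaling of t and every genealogy event time by a common
  # log-uniform factor (breaks the rigid coupling between the divergence
  # time and the tree heights; Hastings = D log eps with D scaled
  # coordinates)
  # slice-sampling update of t from its full conditional (shrinkage slice
  # on [0, bound]; the conditional density comes from the per-locus
  # sufficient-statistic sweep, tempered for heated chains); run on
  # average every other generation
  if (runif(1L) < 0.5) {
    wtemp <- if (post_temp) beta else 1
    t0 <- unclass(st$params)[["t"]]
    f <- function(tt) {
      pp <- st$params; pp[["t"]] <- tt
      cs <- coal_stats_all(st$arrays, tt)
      dd <- dens_from_stats(cs$total, pp)
      list(v = wtemp * dd, stats = cs$stats, sum = cs$total, dens = dd)
    }
    y <- wtemp * st$dens_tot - rexp(1L)
    lo <- 0; hi <- unclass(priors)[["t"]]
    for (it in 1:50) {
      tprop <- runif(1L, lo, hi)
      cand <- f(tprop)
      if (is.finite(cand$v) && cand$v >= y) {
        st$params[["t"]] <- tprop
        st$stats <- cand$stats
        st$stats_sum <- cand$sum
        st$dens_tot <- cand$dens
        break
      }
      if (tprop < t0) lo <- tprop else hi <- tprop
      if (hi - lo < 1e-12) break
    }
  }
  if (control$scale_delta > 0) {
    # one local and one wide rescaling attempt per generation
    for (delta_s in c(control$scale_delta, 3 * control$scale_delta)) {
      st$acc[["scale_try"]] <- st$acc[["scale_try"]] + 1
      eps <- exp(runif(1L, -delta_s, delta_s))
      tnew <- unclass(st$params)[["t"]] * eps
      if (tnew > unclass(priors)[["t"]]) next
      D <- 1L
      newar <- st$arrays
      for (i in seq_along(newar)) {
        ar <- newar[[i]]
        int <- (ar$N + 1L):(2L * ar$N - 1L)
        ar$time[int] <- ar$time[int] * eps
        ar$mt <- ar$mt * eps
        newar[[i]] <- ar
        D <- D + (ar$N - 1L) + length(ar$mt)
      }
      newp <- st$params
      newp[["t"]] <- tnew
      cs <- coal_stats_all(newar, tnew)
      newstats <- cs$stats
      newsum <- cs$total
      nd_tot <- dens_from_stats(newsum, newp)
      if (!is.finite(nd_tot)) next
      newll <- vapply(seq_along(newar), function(i)
        locus_loglik_ar(newar[[i]], caches[[i]],
                        kappa_for(caches[[i]], st$kappas, control), control),
        numeric(1))
      d <- if (post_temp)
        beta * ((nd_tot + sum(newll)) - (st$dens_tot + sum(st$loglik)))
      else (nd_tot - st$dens_tot) + beta * (sum(newll) - sum(st$loglik))
      if (accept_delta(d + D * log(eps))) {
        st$params <- newp
        st$arrays <- newar
        st$stats <- newstats
        st$stats_sum <- newsum
        st$dens_tot <- nd_tot
        st$loglik <- newll
        st$acc[["scale_acc"]] <- st$acc[["scale_acc"]] + 1
      }
    }
    # split-shift: translate t and every event time above it by a common
    # offset, leaving the data-constrained below-split structure in place
    # (pure translation: symmetric, Hastings 0; invalid shifts are caught
    # by the sufficient-statistic sweep)
    told <- unclass(st$params)[["t"]]
    delta <- runif(1L, -control$shift_delta, control$shift_delta)
    tnew <- told + delta
    if (tnew > 0 && tnew <= unclass(priors)[["t"]]) {
      newar <- st$arrays
      ok <- TRUE
      for (i in seq_along(newar)) {
        ar <- newar[[i]]
        sel <- ar$time > told
        if (delta < 0) {
          # the reverse move shifts everything above tnew; for the pair to
          # be symmetric no unshifted coordinate may lie in (tnew, told]
          if (any(!sel & ar$time > tnew) || any(ar$mt > tnew)) {
            ok <- FALSE
            break
          }
        }
        ar$time[sel] <- ar$time[sel] + delta
        newar[[i]] <- ar
      }
      if (ok) {
        newp <- st$params
        newp[["t"]] <- tnew
        cs <- coal_stats_all(newar, tnew)
        newstats <- cs$stats
        newsum <- cs$total
        nd_tot <- dens_from_stats(newsum, newp)
        if (is.finite(nd_tot)) {
          newll <- vapply(seq_along(newar), function(i)
            locus_loglik_ar(newar[[i]], caches[[i]],
                            kappa_for(caches[[i]], st$kappas, control),
                            control),
            numeric(1))
          d <- if (post_temp)
            beta * ((nd_tot + sum(newll)) - (st$dens_tot + sum(st$loglik)))
          else (nd_tot - st$dens_tot) + beta * (sum(newll) - sum(st$loglik))
          if (accept_delta(d)) {
            st$params <- newp
            st$arrays <- newar
            st$stats <- newstats
            st$stats_sum <- newsum
            st$dens_tot <- nd_tot
            st$loglik <- newll
          }
        }
      }
    }
  }
  # per-locus kappa (nuisance, uniform prior, reflected window)
  if (length(st$kappas) && identical(control$kappa, "sample") &&
      control$likelihood == "on") {
    for (ln in names(st$kappas)) {
      i <- which(vapply(caches, `[[`, character(1), "name") == ln)
      newk <- reflect01(st$kappas[[ln]] +
                          runif(1L, -control$kappa_window / 2,
                                control$kappa_window / 2),
                        control$kappa_bound)
      ll <- locus_loglik_ar(st$arrays[[i]], caches[[i]], newk, control)
      if (accept_delta(beta * (ll - st$loglik[i]))) {
        st$kappas[[ln]] <- newk
        st$loglik[i] <- ll
      }
    }
  }
  # occasional genealogy independence refresh: propose G' from the
  # structured coalescent at the current parameters; the coalescent
  # densities cancel against the proposal, leaving the likelihood ratio
  # (exact refresh when the likelihood is off or flat)
  pvec <- unclass(st$params)[PAR_NAMES]
  if (control$refresh_prob > 0) {
    for (i in seq_along(st$arrays)) {
      if (runif(1L) >= control$refresh_prob) next
      cache <- caches[[i]]
      ar <- simulate_gen_arrays(st$params, cache$N1, cache$N2)
      Snew <- coal_stats(ar, pvec[["t"]])
      nd <- dens_from_stats(Snew, st$params)
      if (!is.finite(nd)) next
      ll <- locus_loglik_ar(ar, cache, kappa_for(cache, st$kappas, control),
                            control)
      di <- dens_from_stats(st$stats[[i]], st$params)
      d <- if (post_temp)
        beta * (ll - st$loglik[i]) + (beta - 1) * (nd - di)
      else ll - st$loglik[i]
      if (accept_delta(d)) {
        st$stats_sum <- st$stats_sum - st$stats[[i]] + Snew
        st$dens_tot <- st$dens_tot - di + nd
        st$arrays[[i]] <- ar
        st$stats[[i]] <- Snew
        st$loglik[i] <- ll
      }
    }
  }
  # one genealogy move per locus (compiled propose/evaluate/accept)
  for (i in seq_along(st$arrays)) {
    st$acc[["tree_try"]] <- st$acc[["tree_try"]] + 1
    cache <- caches[[i]]
    di <- dens_from_stats(st$stats[[i]], st$params)
    if (isTRUE(cache$either)) { # reference path for either-polarity loci
      G <- genealogy_from_arrays(st$arrays[[i]])
      pr <- propose_genealogy_update(G, st$params,
                                     list(root_delta = control$root_delta))
      if (!is.finite(pr$log_hastings)) next
      ar <- gen_arrays(pr$genealogy)
      Snew <- coal_stats(ar, pvec[["t"]])
      nd <- dens_from_stats(Snew, st$params)
      ll <- if (is.finite(nd))
        locus_loglik_ar(ar, cache, kappa_for(cache, st$kappas, control),
                        control)
      else -Inf
      d <- if (post_temp) beta * ((nd + ll) - (di + st$loglik[i]))
           else (nd - di) + beta * (ll - st$loglik[i])
      if (accept_delta(d + pr$log_hastings)) {
        st$stats_sum <- st$stats_sum - st$stats[[i]] + Snew
        st$dens_tot <- st$dens_tot - di + nd
        st$arrays[[i]] <- ar
        st$stats[[i]] <- Snew
        st$loglik[i] <- ll
        st$acc[["tree_acc"]] <- st$acc[["tree_acc"]] + 1
      }
      next
    }
    likmode <- if (control$likelihood == "off") 0L
               else if (cache$model == "IS") 1L else 2L
    ar <- st$arrays[[i]]
    res <- cpp_tree_update(ar$time, ar$parent0, ar$ch0, ar$leaf_pop, ar$N,
                           ar$mt, ar$mn, ar$mf, ar$mto,
                           pvec, di, st$loglik[i],
                           beta, post_temp, likmode,
                           if (likmode == 1L) cache$carriers
                           else matrix(FALSE, 0L, 0L),
                           if (likmode == 2L) cache$codes
                           else matrix(0L, 0L, 0L),
                           if (likmode == 2L) cache$pi else numeric(4),
                           if (likmode == 2L)
                             kappa_for(cache, st$kappas, control) else 1,
                           cache$u, control$root_delta)
    if (res$accepted) {
      nt <- res$time
      post <- ar$post
      if (!identical(nt, ar$time)) { # postorder = internal ids by time
        int <- (ar$N + 1L):length(nt)
        post <- int[order(nt[int])]
      }
      st$arrays[[i]] <- list(time = nt, parent0 = res$parent0,
                             ch0 = res$children0, post = post,
                             leaf_pop = ar$leaf_pop, N = ar$N,
                             mt = res$mig_time, mn = res$mig_node,
                             mf = res$mig_from, mto = res$mig_to)
      st$stats_sum <- st$stats_sum - st$stats[[i]] + res$stats
      st$dens_tot <- st$dens_tot - di + res$dens
      st$stats[[i]] <- res$stats
      st$loglik[i] <- res$loglik
      st$acc[["tree_acc"]] <- st$acc[["tree_acc"]] + 1
    }
  }
  st
}

# from-scratch recomputation through the reference code path
audit_state <- function(st, caches, priors, control, generation) {
  Gs <- lapply(st$arrays, genealogy_from_arrays)
  nd <- all_logdens(Gs, st$params)
  ll <- vapply(seq_along(Gs), function(i)
    locus_loglik(Gs[[i]], caches[[i]],
                 kappa_for(caches[[i]], st$kappas, control), control),
    numeric(1))
  lp <- log_prior(st$params, priors)
  if (max(abs(c(sum(nd) - st$dens_tot, ll - st$loglik,
                lp - st$logprior))) > 1e-8)
    stop("cache audit failed at generation ", generation,
         ": cached log-posterior terms drifted from recomputation")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# the fitting function
# ---------------------------------------------------------------------------

#' Fit the isolation-with-migration model by MCMC
#'
#' Samples the joint posterior of the six scaled IM parameters and the
#' per-locus genealogies by Metropolis-Hastings: each generation cycles one
#' reflected sliding-window move per parameter, one move per sampled
#' kappa, and one genealogy move per locus, optionally across several
#' Metropolis-coupled (heated) chains with one adjacent-pair swap attempt
#' per generation. Cold-chain draws after burn-in are recorded.
#'
#' @param data An [im_dataset()].
#' @param priors [im_priors()].
#' @param burn_in,generations Burn-in and sampling generations (defaults
#'   10,000 each).
#' @param sample_every Thinning interval for the recorded trace.
#' @param n_chains Number of Metropolis-coupled chains.
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @param control [im_control()] tuning options.
#' @param verbose Print progress to standard error.
#' @return An object of class `im_fit`: list with `trace` (data frame of
#'   cold-chain draws), `priors`, `acceptance`, `betas`, `swap_rate`,
#'   `data_summary`, `final_state`, `seed`, and the call.
#' @export
im_mcmc <- function(data, priors = im_priors(), burn_in = 10000L,
                    generations = 10000L, sample_every = 1L, n_chains = 1L,
                    seed = NULL, control = im_control(), verbose = FALSE) {
  stopifnot(inherits(data, "im_dataset"))
  if (burn_in < 0L || generations < 1L || sample_every < 1L || n_chains < 1L)
    stop("invalid run configuration")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  caches <- lapply(data$loci, build_locus_cache, control = control)
  windows <- control$windows
  if (is.null(windows)) windows <- default_windows(priors)

  betas <- heating_schedule(n_chains, control$lambda)
  set.seed(seed)
  master <- .Random.seed
  streams <- vector("list", n_chains)
  states <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    set.seed((seed + 77777L * k) %% .Machine$integer.max)
    states[[k]] <- init_chain_state(data, caches, priors, control, betas[k])
    streams[[k]] <- .Random.seed
  }

  total <- burn_in + generations
  nrec <- floor(generations / sample_every)
  loc_names <- names(data$loci)
  kap_names <- names(states[[1L]]$kappas)
  cols <- c("generation", PAR_NAMES,
            if (length(kap_names)) paste0("kappa.", kap_names),
            paste0("loglik.", loc_names), "loglik_total", "logdens_total",
            "logprior", "beta", "chain",
            "par_try", "par_acc", "tree_try", "tree_acc")
  trace <- matrix(NA_real_, nrec, length(cols),
                  dimnames = list(NULL, cols))
  ri <- 0L
  swap_try <- 0L; swap_acc <- 0L

  for (g in seq_len(total)) {
    for (k in seq_len(n_chains)) {
      assign(".Random.seed", streams[[k]], envir = .GlobalEnv)
      states[[k]] <- chain_step(states[[k]], caches, priors, control,
                                windows)
      streams[[k]] <- get(".Random.seed", envir = .GlobalEnv)
    }
    if (n_chains > 1L) {
      assign(".Random.seed", master, envir = .GlobalEnv)
      j <- if (n_chains == 2L) 1L else sample.int(n_chains - 1L, 1L)
      if (control$tempering == "posterior") {
        sw <- mc3_swap(states[[j]], states[[j + 1L]])
      } else {
        d <- (states[[j]]$beta - states[[j + 1L]]$beta) *
          (sum(states[[j + 1L]]$loglik) - sum(states[[j]]$loglik))
        acc <- accept_delta(d)
        sw <- list(cold = states[[j]], hot = states[[j + 1L]],
                   accepted = acc)
        if (acc) {
          bc <- states[[j]]$beta; bh <- states[[j + 1L]]$beta
          sw$cold <- states[[j + 1L]]; sw$hot <- states[[j]]
          sw$cold$beta <- bc; sw$hot$beta <- bh
        }
      }
      states[[j]] <- sw$cold
      states[[j + 1L]] <- sw$hot
      swap_try <- swap_try + 1L
      swap_acc <- swap_acc + sw$accepted
      master <- get(".Random.seed", envir = .GlobalEnv)
    }
    if (control$audit_every > 0 && g %% control$audit_every == 0L)
      audit_state(states[[1L]], caches, priors, control, g)
    if (g > burn_in && (g - burn_in) %% sample_every == 0L && ri < nrec) {
      ri <- ri + 1L
      st <- states[[1L]]
      trace[ri, ] <- c(g, unclass(st$params)[PAR_NAMES],
                       if (length(kap_names)) st$kappas[kap_names],
                       st$loglik, sum(st$loglik), st$dens_tot,
                       st$logprior, st$beta, 1,
                       st$acc[["par_try"]], st$acc[["par_acc"]],
                       st$acc[["tree_try"]], st$acc[["tree_acc"]])
    }
    if (verbose && g %% 1000L == 0L)
      message(sprintf("gen %d / %d  logpost %.3f  acc par %.2f tree %.2f",
                      g, total, chain_log_posterior(states[[1L]]),
                      states[[1L]]$acc[["par_acc"]] /
                        max(1, states[[1L]]$acc[["par_try"]]),
                      states[[1L]]$acc[["tree_acc"]] /
                        max(1, states[[1L]]$acc[["tree_try"]])))
  }

  st <- states[[1L]]
  st$genealogies <- lapply(st$arrays, genealogy_from_arrays)
  structure(list(trace = as.data.frame(trace[seq_len(ri), , drop = FALSE]),
                 priors = priors,
                 acceptance = c(
                   params = unname(st$acc[["par_acc"]] /
                                     max(1, st$acc[["par_try"]])),
                   trees = unname(st$acc[["tree_acc"]] /
                                    max(1, st$acc[["tree_try"]])),
                   scale = unname(st$acc[["scale_acc"]] /
                                    max(1, st$acc[["scale_try"]]))),
                 betas = betas,
                 swap_rate = if (swap_try) swap_acc / swap_try else NA_real_,
                 data_summary = list(
                   loci = loc_names,
                   models = vapply(data$loci, `[[`, character(1), "model"),
                   sizes = vapply(data$loci, function(l)
                     paste(locus_counts(l), collapse = "+"), character(1))),
                 final_state = st,
                 seed = seed, burn_in = burn_in, generations = generations,
                 sample_every = sample_every, n_chains = n_chains,
                 control = control, call = match.call()),
            class = "im_fit")
}
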