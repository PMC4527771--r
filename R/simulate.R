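#' Simulate sequences on a genealogy under HKY
#'
#' Draws the root state from the stationary frequencies per site and
#' propagates states down every edge with the HKY transition probabilities,
#' branch lengths scaled by the locus mutation scale `u`.
#'
#' @param G An [im_genealogy()].
#' @param n Number of sites.
#' @param model An [hky_model()].
#' @param u Positive locus mutation scale.
#' @return Character matrix (leaves x sites) in leaf order.
#' @export
simulate_sequences_hky <- function(G, n, model, u = 1) {
  if (n < 1L) stop("need at least one site")
  M <- length(G$time)
  states <- matrix(0L, M, n)
  rt <- root_node(G)
  states[rt, ] <- sample.int(4L, n, replace = TRUE, prob = model$pi)
  for (v in rev(internal_postorder(G))) {
    for (c in G$children[v, ]) {
      P <- cpp_hky_pmat((G$time[v] - G$time[c]) * u, model$pi, model$kappa)
      cp <- t(apply(P, 1L, cumsum))
      m <- cp[states[v, ], 1:3, drop = FALSE]
      U <- runif(n)
      states[c, ] <- 1L + (U > m[, 1L]) + (U > m[, 2L]) + (U > m[, 3L])
    }
  }
  matrix(BASES[states[seq_len(G$N), ]], G$N, n)
}

# logical leaf-set matrix: entry [v, i] TRUE when leaf i descends from v
leafset_matrix <- function(G) {
  M <- length(G$time)
  L <- matrix(FALSE, M, G$N)
  L[cbind(seq_len(G$N), seq_len(G$N))] <- TRUE
  for (v in internal_postorder(G))
    L[v, ] <- L[G$children[v, 1L], ] | L[G$children[v, 2L], ]
  L
}

#' Simulate infinite-sites sequences on a genealogy
#'
#' The total mutation count is Poisson with mean `BT * u` (total branch
#' length times the locus mutation scale); each mutation lands on a branch
#' with probability proportional to its length and claims a previously
#' unmutated site, whose derived allele is assigned to the leaves subtended
#' by that branch.
#'
#' @param G An [im_genealogy()].
#' @param n Number of sites (must accommodate the mutations drawn).
#' @param u Positive locus mutation scale.
#' @param on_overflow `"resample"` (redraw the mutation count until it fits;
#'   default) or `"error"`.
#' @return List with `alignment` (character matrix), `ancestral` (character
#'   vector of true ancestral bases), and `mapping` (data frame `site`,
#'   `branch` of the true mutation placement).
#' @export
simulate_sequences_is <- function(G, n, u = 1,
                                  on_overflow = c("resample", "error")) {
  on_overflow <- match.arg(on_overflow)
  if (n < 1L) stop("need at least one site")
  BT <- total_branch_length(G)
  K <- rpois(1L, BT * u)
  if (K > n) {
    if (on_overflow == "error")
      stop("drew ", K, " mutations for ", n, " sites")
    while (K > n) K <- rpois(1L, BT * u)
  }
  anc <- BASES[sample.int(4L, n, replace = TRUE)]
  aln <- matrix(rep(anc, each = G$N), G$N, n)
  mapping <- data.frame(site = integer(), branch = integer())
  if (K > 0L) {
    nonroot <- which(!is.na(G$parent))
    blen <- G$time[G$parent[nonroot]] - G$time[nonroot]
    branches <- nonroot[sample.int(length(nonroot), K, replace = TRUE,
                                   prob = blen)]
    sites <- sample.int(n, K)
    L <- leafset_matrix(G)
    for (j in seq_len(K)) {
      derived <- BASES[-match(anc[sites[j]], BASES)][sample.int(3L, 1L)]
      aln[L[branches[j], ], sites[j]] <- derived
    }
    mapping <- data.frame(site = sites, branch = branches)
  }
  list(alignment = aln, ancestral = anc, mapping = mapping)
}

#' Simulate a complete IM dataset
#'
#' Draws one genealogy per locus from the structured coalescent at `params`
#' and simulates sequences under the requested model, returning both the
#' dataset and the simulating truth (genealogies and IS mutation maps) for
#' validation work.
#'
#' @param params [im_parameters()] used as the simulation truth.
#' @param n_loci Number of loci.
#' @param N1,N2 Sample sizes per population.
#' @param n Sites per locus (recycled).
#' @param model `"HKY"` or `"IS"` (recycled).
#' @param u Locus mutation scale (recycled).
#' @param hky An [hky_model()] used for HKY loci.
#' @param prefix Locus name prefix.
#' @return List with `dataset` ([im_dataset()]), `genealogies`, `mappings`.
#' @export
simulate_im_dataset <- function(params, n_loci = 1L, N1 = 10L, N2 = 10L,
                                n = 500L, model = "IS", u = 1,
                                hky = hky_model(rep(0.25, 4), kappa = 3),
                                prefix = "locus") {
  n <- rep_len(n, n_loci)
  model <- rep_len(model, n_loci)
  u <- rep_len(u, n_loci)
  loci <- vector("list", n_loci)
  gens <- vector("list", n_loci)
  maps <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    G <- simulate_genealogy(params, N1, N2)
    gens[[i]] <- G
    nm <- paste0(prefix, i)
    if (model[i] == "HKY") {
      aln <- simulate_sequences_hky(G, n[i], hky, u[i])
      loci[[i]] <- im_locus(nm, aln, G$leaf_pop, "HKY", u[i])
    } else {
      sim <- simulate_sequences_is(G, n[i], u[i])
      maps[[i]] <- sim$mapping
      loci[[i]] <- im_locus(nm, sim$alignment, G$leaf_pop, "IS", u[i],
                            ancestral = sim$ancestral)
    }
  }
  list(dataset = im_dataset(loci, metadata = "simulated"),
       genealogies = gens, mappings = maps)
}

#' Generate the benchmark simulation suite
#'
#' Writes the simulation design used for benchmarking the sampler: at full
#' scale, single-locus datasets for both mutation models at sequence
#' lengths 1000, 6000, 11000 and 16000 with 150 + 40 sampled sequences,
#' plus multi-locus combinations of 1, 2, 4 and 8 loci (length 1000) per
#' model; at small scale, one 10 + 10, 500-site dataset per model. All
#' datasets are simulated at a documented default truth point and written
#' in im-text format together with a manifest listing seeds and truth
#' parameters. Byte-identical across runs with the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param scale `"full"` or `"small"`.
#' @param seed Integer seed.
#' @param params Truth point; defaults to
#'   `im_parameters(2, 2, 2, 0.5, 0.5, 1)`.
#' @param hky [hky_model()] for HKY loci (default: uniform frequencies,
#'   kappa 3); HKY loci use mutation scale 0.01 (realistic per-site
#'   divergence), IS loci use 1.
#' @return Data frame manifest (also written as `manifest.tsv`), invisibly.
#' @export
simulate_benchmark_suite <- function(dir, scale = c("full", "small"),
                                     seed = 1L,
                                     params = im_parameters(2, 2, 2,
                                                            0.5, 0.5, 1),
                                     hky = hky_model(rep(0.25, 4),
                                                     kappa = 3)) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  if (scale == "full") {
    N1 <- 150L; N2 <- 40L
    lens <- c(1000L, 6000L, 11000L, 16000L)
    nloci <- c(1L, 2L, 4L, 8L)
  } else {
    N1 <- 10L; N2 <- 10L
    lens <- 500L
    nloci <- 1L
  }
  rows <- list()
  emit <- function(model, n, L) {
    u <- if (model == "HKY") 0.01 else 1
    sim <- simulate_im_dataset(params, n_loci = L, N1 = N1, N2 = N2, n = n,
                               model = model, u = u, hky = hky,
                               prefix = sprintf("%s_n%d_", tolower(model), n))
    fn <- sprintf("%s_n%d_L%d.im", tolower(model), n, L)
    write_im_data(sim$dataset, file.path(dir, fn))
    rows[[length(rows) + 1L]] <<- data.frame(
      file = fn, model = model, n = n, loci = L, N1 = N1, N2 = N2, u = u,
      seed = seed, theta1 = params[["theta1"]], theta2 = params[["theta2"]],
      thetaA = params[["thetaA"]], m1 = params[["m1"]], m2 = params[["m2"]],
      t = params[["t"]])
  }
  for (model in c("HKY", "IS")) for (n in lens) emit(model, n, 1L)
  if (scale == "full")
    for (model in c("HKY", "IS")) for (L in nloci[nloci > 1L])
      emit(model, 1000L, L)
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
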