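#' HKY85 substitution model
#'
#' @param pi Base frequencies in order A, C, G, T; positive, summing to 1.
#' @param kappa Transition/transversion rate ratio, > 0.
#' @return An object of class `hky_model`.
#' @export
hky_model <- function(pi = rep(0.25, 4), kappa = 2) {
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-12)
    stop("pi must be 4 positive frequencies summing to 1")
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be positive")
  structure(list(pi = pi, kappa = kappa), class = "hky_model")
}

#' HKY transition probability matrix
#'
#' Closed-form transition probabilities with the rate matrix normalized to
#' mean rate 1, so `branch` is in expected substitutions per site. Rows are
#' the starting base, columns the ending base, order A, C, G, T.
#'
#' @param branch Nonnegative branch length.
#' @param model An [hky_model()].
#' @return 4x4 row-stochastic matrix.
#' @export
hky_transition_matrix <- function(branch, model) {
  if (branch < 0) stop("branch length must be nonnegative")
  P <- cpp_hky_pmat(branch, model$pi, model$kappa)
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Conditional likelihood table by Felsenstein pruning
#'
#' Postorder dynamic program: for every internal node and site, the
#' probability of the observed bases below the node given each of the four
#' states at the node. Leaf entries are indicators of the observed base.
#' This reference implementation carries unscaled values; the MCMC engine
#' uses the scaled compiled path ([hky_site_loglik()]).
#'
#' @param G An [im_genealogy()].
#' @param locus An [im_locus()] with `model == "HKY"`.
#' @param model An [hky_model()].
#' @return Array `(2N-1) x sites x 4` of class `im_cl_table` with the root id
#'   in attribute `root`.
#' @export
prune_conditional_likelihoods <- function(G, locus, model) {
  if (locus$model != "HKY") stop("locus is not tagged HKY")
  codes <- locus_codes(locus)
  if (nrow(codes) != G$N)
    stop("leaf count and sequence count disagree")
  n <- ncol(codes)
  M <- length(G$time)
  CL <- array(0, c(M, n, 4L))
  for (v in seq_len(G$N))
    for (b in 1:4) CL[v, , b] <- as.numeric(codes[v, ] == b)
  for (v in internal_postorder(G)) {
    fac <- matrix(1, n, 4L)
    for (c in G$children[v, ]) {
      P <- cpp_hky_pmat((G$time[v] - G$time[c]) * locus$u, model$pi,
                        model$kappa)
      fac <- fac * (CL[c, , , drop = TRUE] %*% t(P))
    }
    CL[v, , ] <- fac
  }
  structure(CL, root = root_node(G), class = "im_cl_table")
}

#' Per-site log-likelihoods from a conditional likelihood table
#'
#' `SL_j = log(sum_b pi_b * CL(root, j, b))`.
#'
#' @param CL An `im_cl_table` from [prune_conditional_likelihoods()].
#' @param model An [hky_model()].
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_log_likelihoods <- function(CL, model) {
  rt <- attr(CL, "root")
  log(as.numeric(CL[rt, , , drop = TRUE] %*% model$pi))
}

#' Per-site HKY log-likelihoods (compiled path)
#'
#' Scaled pruning used by the sampler; identical to
#' [prune_conditional_likelihoods()] + [site_log_likelihoods()] up to
#' floating-point scaling.
#'
#' @inheritParams prune_conditional_likelihoods
#' @return Numeric vector of per-site log-likelihoods.
#' @export
hky_site_loglik <- function(G, locus, model) {
  if (locus$model != "HKY") stop("locus is not tagged HKY")
  codes <- locus_codes(locus)
  if (nrow(codes) != G$N) stop("leaf count and sequence count disagree")
  cpp_hky_site_loglik(children0(G), internal_postorder(G), G$time, codes,
                      model$pi, model$kappa, locus$u)
}

#' Chunked reduction of per-site log-likelihoods
#'
#' Partitions the per-site values into consecutive blocks of `block_size`
#' (last block possibly shorter), sums each block, and totals the block
#' sums. The total is invariant to `block_size` up to floating-point
#' reassociation, which is the exactness contract for the chunked reduction.
#'
#' @param SL Numeric vector of per-site log-likelihoods.
#' @param block_size Positive integer.
#' @return List with `total` and `block_sums`.
#' @export
blocked_total_loglik <- function(SL, block_size) {
  if (!is.numeric(block_size) || block_size < 1L)
    stop("block_size must be >= 1")
  block_size <- as.integer(block_size)
  idx <- ceiling(seq_along(SL) / block_size)
  bs <- as.numeric(tapply(SL, idx, sum))
  list(total = sum(bs), block_sums = bs)
}
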