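#' Polarize sites and map mutations onto branches (infinite sites)
#'
#' Under the infinite-sites model each polymorphic site carries exactly one
#' mutation, which must sit on the unique branch whose subtended leaves are
#' exactly the derived-allele carriers. Sites are classified as monomorphic,
#' mapped (with the target branch and its length), or incompatible (carriers
#' non-monophyletic on `G`, more than two alleles, or derived allele in all
#' leaves). Any incompatible site forces the locus likelihood to zero.
#'
#' Polarization uses the locus ancestral designation when available
#' (`ancestral` sequence or `ancestral_row`); with `polarity = "either"` a
#' site is accepted if either orientation of its two alleles maps to a
#' clade, preferring the orientation that maps, and the smaller derived set
#' when both do.
#'
#' @param G An [im_genealogy()].
#' @param locus An [im_locus()] with `model == "IS"`.
#' @param polarity `"ancestral_row"` (use the locus designation; default) or
#'   `"either"`.
#' @return An object of class `im_mutation_map`: list with per-site `status`
#'   (factor: monomorphic/mapped/incompatible), `branch` (child-node id of
#'   the mapped edge or NA), `B` (mapped branch length or NA), `M` (per-site
#'   mutation count), and `m_b` (named per-branch counts).
#' @export
polarize_and_map_sites <- function(G, locus,
                                   polarity = c("ancestral_row", "either")) {
  polarity <- match.arg(polarity)
  if (locus$model != "IS") stop("locus is not tagged IS")
  aln <- locus$alignment
  if (nrow(aln) != G$N) stop("leaf count and sequence count disagree")
  n <- ncol(aln)
  status <- rep("monomorphic", n)
  branch <- rep(NA_integer_, n)
  if (polarity == "ancestral_row" && is.null(locus$ancestral))
    stop("locus has no ancestral designation; set one or use polarity = 'either'")

  nallele <- apply(aln, 2L, function(x) length(unique(x)))
  poly <- which(nallele > 1L)
  status[nallele > 2L] <- "incompatible"
  bi <- poly[nallele[poly] == 2L]

  if (length(bi)) {
    if (polarity == "ancestral_row") {
      carriers <- t(aln[, bi, drop = FALSE] !=
                      matrix(locus$ancestral[bi], G$N, length(bi), byrow = TRUE))
      # a biallelic site where no allele matches the ancestral base carries
      # two mutations: incompatible under infinite sites
      twohit <- vapply(seq_along(bi), function(k)
        !any(!carriers[k, ]), logical(1))
      full <- rowSums(carriers) == G$N
      map <- cpp_is_map(children0(G), internal_postorder(G), G$N,
                        carriers)
      ok <- !twohit & !full & map > 0L
      status[bi[ok]] <- "mapped"
      branch[bi[ok]] <- map[ok]
      status[bi[!ok]] <- "incompatible"
    } else {
      ref <- aln[1L, bi]
      car1 <- t(aln[, bi, drop = FALSE] !=
                  matrix(ref, G$N, length(bi), byrow = TRUE))
      car2 <- !car1
      m1 <- cpp_is_map(children0(G), internal_postorder(G), G$N, car1)
      m2 <- cpp_is_map(children0(G), internal_postorder(G), G$N, car2)
      for (k in seq_along(bi)) {
        s1 <- sum(car1[k, ]); s2 <- sum(car2[k, ])
        ok1 <- m1[k] > 0L && s1 < G$N
        ok2 <- m2[k] > 0L && s2 < G$N
        pick <- if (ok1 && ok2) { if (s1 <= s2) 1L else 2L }
                else if (ok1) 1L else if (ok2) 2L else 0L
        if (pick == 0L) status[bi[k]] <- "incompatible"
        else {
          status[bi[k]] <- "mapped"
          branch[bi[k]] <- if (pick == 1L) m1[k] else m2[k]
        }
      }
    }
  }

  blen <- rep(NA_real_, n)
  mapped <- which(status == "mapped")
  if (length(mapped))
    blen[mapped] <- G$time[G$parent[branch[mapped]]] - G$time[branch[mapped]]
  m_b <- table(factor(branch[mapped],
                      levels = which(!is.na(G$parent))))
  structure(list(status = factor(status,
                                 c("monomorphic", "mapped", "incompatible")),
                 branch = branch, B = blen,
                 M = as.integer(status == "mapped"),
                 m_b = m_b),
            class = "im_mutation_map")
}

#' @export
print.im_mutation_map <- function(x, ...) {
  cat("<im_mutation_map>", paste(names(table(x$status)),
                                 as.integer(table(x$status)),
                                 sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Infinite-sites log-likelihood of a mutation mapping
#'
#' Poisson likelihood of the per-branch mutation counts: each branch b of
#' length `B_b` receives `m_b ~ Poisson(B_b * u)` mutations independently,
#' so `log L = -BT*u + sum_b [m_b log(B_b u) - log(m_b!)]` with `BT` the
#' total branch length. Any incompatible site gives `-Inf` (likelihood 0).
#'
#' @param mapping An `im_mutation_map` from [polarize_and_map_sites()].
#' @param G The [im_genealogy()] the mapping was computed on.
#' @param u Positive locus mutation scale.
#' @return Log-likelihood, or `-Inf`.
#' @export
is_log_likelihood <- function(mapping, G, u) {
  if (!is.numeric(u) || u <= 0) stop("u must be positive")
  if (any(mapping$status == "incompatible")) return(-Inf)
  BT <- total_branch_length(G)
  m <- as.integer(mapping$m_b)
  b <- as.integer(names(mapping$m_b))
  blen <- G$time[G$parent[b]] - G$time[b]
  pos <- m > 0L
  -BT * u + sum(m[pos] * log(blen[pos] * u) - lgamma(m[pos] + 1))
}

# fast combined path used by the sampler: precomputed carrier matrix for the
# biallelic sites; any multiallelic or two-hit site makes the locus cache
# carry has_incompatible = TRUE and the likelihood is -Inf regardless of G.
is_loglik_fast <- function(G, carriers, u, ch0 = children0(G),
                           post = internal_postorder(G)) {
  BT <- total_branch_length(G)
  if (nrow(carriers) == 0L) return(-BT * u)
  map <- cpp_is_map(ch0, post, G$N, carriers)
  if (any(map == 0L)) return(-Inf)
  blen <- G$time[G$parent[map]] - G$time[map]
  cnt <- tabulate(map, length(G$time))
  cnt <- cnt[cnt > 1L]
  -BT * u + sum(log(blen * u)) - sum(lgamma(cnt + 1))
}
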