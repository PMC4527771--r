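# Reversible genealogy update moves. Each move has a deterministic core
# (apply_*) taking the random draws as arguments and computing its exact
# log-Hastings ratio, plus the random wrapper propose_genealogy_update().
# Moves that would break a structural invariant return the input genealogy
# with log_hastings = -Inf (proposed-and-rejected at the MCMC level); label
# inconsistencies with the parameters are caught by the density (-Inf).

migs_on_edge <- function(G, v) which(G$migrations$node == v)

# legal sliding interval for an internal non-root node: bounded by child and
# parent node times, tightened by migration events on the three adjacent
# edges. The interval does not depend on the node's current time, so a
# uniform redraw is symmetric.
slide_bounds <- function(G, v) {
  a <- G$children[v, 1L]; b <- G$children[v, 2L]
  lo <- max(G$time[a], G$time[b])
  for (c in c(a, b)) {
    r <- migs_on_edge(G, c)
    if (length(r)) lo <- max(lo, max(G$migrations$time[r]))
  }
  hi <- G$time[G$parent[v]]
  r <- migs_on_edge(G, v)
  if (length(r)) hi <- min(hi, min(G$migrations$time[r]))
  c(lo, hi)
}

apply_node_slide <- function(G, v, newtime) {
  bb <- slide_bounds(G, v)
  if (!(newtime > bb[1L] && newtime < bb[2L]))
    return(list(genealogy = G, log_hastings = -Inf))
  G$time[v] <- newtime
  list(genealogy = G, log_hastings = 0)
}

# root height rescaling by a log-uniform multiplier; Hastings = log(eps)
apply_root_slide <- function(G, eps) {
  rt <- root_node(G)
  a <- G$children[rt, 1L]; b <- G$children[rt, 2L]
  lo <- max(G$time[a], G$time[b])
  for (c in c(a, b)) {
    r <- migs_on_edge(G, c)
    if (length(r)) lo <- max(lo, max(G$migrations$time[r]))
  }
  newtime <- G$time[rt] * eps
  if (!(newtime > lo)) return(list(genealogy = G, log_hastings = -Inf))
  G$time[rt] <- newtime
  list(genealogy = G, log_hastings = log(eps))
}

# Candidate attachment intervals after pruning node v (and its parent).
# Returns NULL when the move is structurally impossible. The pruned
# configuration is identical for the forward and reverse transition, so a
# length-uniform attachment draw has Hastings ratio 0.
prune_for_regraft <- function(G, v) {
  p <- G$parent[v]
  if (is.na(p) || is.na(G$parent[p])) return(NULL)   # v root or child of root
  if (length(migs_on_edge(G, v))) return(NULL)       # keep dimension fixed
  sib <- setdiff(G$children[p, ], v)
  g <- G$parent[p]
  Gp <- G
  Gp$parent[sib] <- g
  Gp$children[g, Gp$children[g, ] == p] <- sib
  Gp$parent[p] <- NA_integer_
  Gp$children[p, ] <- NA_integer_
  Gp$migrations$node[Gp$migrations$node == p] <- sib
  # nodes detached with v
  sub <- v
  frontier <- v
  while (length(frontier)) {
    kids <- Gp$children[frontier, ]
    kids <- kids[!is.na(kids)]
    sub <- c(sub, kids)
    frontier <- kids
  }
  cand <- setdiff(which(!is.na(Gp$parent)), c(sub, p))
  lo <- pmax(G$time[v], Gp$time[cand])
  hi <- Gp$time[Gp$parent[cand]]
  len <- pmax(0, hi - lo)
  keep <- len > 0
  list(Gp = Gp, p = p, sib = sib, cand = cand[keep], lo = lo[keep],
       len = len[keep], total = sum(len[keep]))
}

apply_regraft <- function(G, v, dest, tau) {
  pr <- prune_for_regraft(G, v)
  if (is.null(pr) || pr$total <= 0)
    return(list(genealogy = G, log_hastings = -Inf))
  i <- match(dest, pr$cand)
  if (is.na(i) || !(tau > pr$lo[i] && tau < pr$lo[i] + pr$len[i]))
    return(list(genealogy = G, log_hastings = -Inf))
  Gp <- pr$Gp
  p <- pr$p
  q <- Gp$parent[dest]
  Gp$children[p, ] <- c(v, dest)
  Gp$parent[dest] <- p
  Gp$parent[v] <- p
  Gp$parent[p] <- q
  Gp$children[q, Gp$children[q, ] == dest] <- p
  Gp$time[p] <- tau
  mv <- which(Gp$migrations$node == dest & Gp$migrations$time > tau)
  if (length(mv)) Gp$migrations$node[mv] <- p
  list(genealogy = Gp, log_hastings = 0)
}

# total edge length available for migration events (below t_split)
migratable_edges <- function(G, tsplit) {
  nonroot <- which(!is.na(G$parent))
  lo <- G$time[nonroot]
  hi <- pmin(G$time[G$parent[nonroot]], tsplit)
  len <- pmax(0, hi - lo)
  keep <- len > 0
  list(node = nonroot[keep], lo = lo[keep], hi = hi[keep], len = len[keep],
       total = sum(len[keep]))
}

# consecutive same-edge migration pairs (deletable by the death move)
mig_pairs <- function(G) {
  mg <- G$migrations
  if (nrow(mg) < 2L) return(NULL)
  out <- NULL
  for (v in unique(mg$node)) {
    r <- which(mg$node == v)
    if (length(r) < 2L) next
    r <- r[order(mg$time[r])]
    out <- rbind(out, cbind(first = r[-length(r)], second = r[-1L]))
  }
  out
}

n_mig_pairs <- function(G) {
  pp <- mig_pairs(G)
  if (is.null(pp)) 0L else nrow(pp)
}

# population label on the edge above `v` at time `tt` (requires tt < tsplit).
# Walks down to one descendant leaf and counts the label flips back up: in a
# label-consistent genealogy every migration event flips the lineage label,
# so only the flip count matters.
edge_label_at <- function(G, tsplit, v, tt) {
  w <- v
  while (!is.na(G$children[w, 1L])) w <- G$children[w, 1L]
  lab <- G$leaf_pop[w]
  path <- integer()
  while (w != v) {
    path <- c(path, w)
    w <- G$parent[w]
  }
  mg <- G$migrations
  flips <- sum(mg$node %in% path) + sum(mg$node == v & mg$time <= tt)
  if (flips %% 2L == 1L) 3L - lab else lab
}

# Split-crossing edges (child below t_split, parent above): the edge-top
# label is unconstrained above t_split, so a single flip is consistent.
# Single-event birth/death on those edges changes migration-count parity,
# which the pair moves preserve.
split_edges <- function(G, tsplit) {
  nonroot <- which(!is.na(G$parent))
  keep <- G$time[G$parent[nonroot]] > tsplit & G$time[nonroot] < tsplit
  v <- nonroot[keep]
  list(node = v, lo = G$time[v], len = tsplit - G$time[v],
       total = sum(tsplit - G$time[v]))
}

# insert one migration at tau on split-crossing edge v (topmost on the edge)
apply_mig_birth_single <- function(G, tsplit, v, tau) {
  se <- split_edges(G, tsplit)
  i <- match(v, se$node)
  if (is.na(i) || !(tau > se$lo[i] && tau < tsplit))
    return(list(genealogy = G, log_hastings = -Inf))
  r <- migs_on_edge(G, v)
  if (length(r) && any(G$migrations$time[r] > tau))
    return(list(genealogy = G, log_hastings = -Inf))
  lab <- edge_label_at(G, tsplit, v, tau)
  mg <- G$migrations
  G2 <- G
  G2$migrations <- data.frame(node = c(mg$node, v), time = c(mg$time, tau),
                              from = c(mg$from, lab), to = c(mg$to, 3L - lab))
  Ds <- sum(se$node %in% G2$migrations$node)
  list(genealogy = G2, log_hastings = log(se$total) - log(Ds))
}

# delete the topmost migration of the j-th split-crossing edge carrying one
apply_mig_death_single <- function(G, tsplit, j) {
  se <- split_edges(G, tsplit)
  loaded <- se$node[se$node %in% G$migrations$node]
  if (j < 1L || j > length(loaded))
    return(list(genealogy = G, log_hastings = -Inf))
  r <- migs_on_edge(G, loaded[j])
  del <- r[which.max(G$migrations$time[r])]
  G2 <- G
  G2$migrations <- G$migrations[-del, , drop = FALSE]
  list(genealogy = G2,
       log_hastings = log(length(loaded)) - log(se$total))
}

# insert a flip-and-return migration pair on edge v at tau1 < tau2
apply_mig_birth <- function(G, tsplit, v, tau1, tau2) {
  me <- migratable_edges(G, tsplit)
  i <- match(v, me$node)
  if (is.na(i) || !(tau1 > me$lo[i] && tau2 < me$hi[i] && tau1 < tau2))
    return(list(genealogy = G, log_hastings = -Inf))
  r <- migs_on_edge(G, v)
  if (length(r) && any(G$migrations$time[r] > tau1 &
                       G$migrations$time[r] < tau2))
    return(list(genealogy = G, log_hastings = -Inf)) # would break the flips
  lab <- edge_label_at(G, tsplit, v, tau1)
  if (is.na(lab)) return(list(genealogy = G, log_hastings = -Inf))
  mg <- G$migrations
  G2 <- G
  G2$migrations <- data.frame(node = c(mg$node, v, v),
                              time = c(mg$time, tau1, tau2),
                              from = c(mg$from, lab, 3L - lab),
                              to = c(mg$to, 3L - lab, lab))
  h <- log(me$total) + log(me$hi[i] - tau1) - log(n_mig_pairs(G2))
  list(genealogy = G2, log_hastings = h)
}

# delete the j-th consecutive same-edge pair
apply_mig_death <- function(G, tsplit, j) {
  pp <- mig_pairs(G)
  if (is.null(pp) || j < 1L || j > nrow(pp))
    return(list(genealogy = G, log_hastings = -Inf))
  r1 <- pp[j, 1L]; r2 <- pp[j, 2L]
  v <- G$migrations$node[r1]
  tau1 <- G$migrations$time[r1]
  me <- migratable_edges(G, tsplit)
  i <- match(v, me$node)
  if (is.na(i)) return(list(genealogy = G, log_hastings = -Inf))
  G2 <- G
  G2$migrations <- G$migrations[-c(r1, r2), , drop = FALSE]
  # deleting the pair un-flips the stretch between the two events; the
  # surrounding labels are unchanged, so validity is preserved
  h <- log(nrow(pp)) - log(me$total) - log(me$hi[i] - tau1)
  list(genealogy = G2, log_hastings = h)
}

#' Propose a reversible genealogy update
#'
#' One of three move families, chosen uniformly: a node-time slide (internal
#' nodes redraw their time uniformly in the legal interval; the root height
#' is rescaled by a log-uniform multiplier), a subtree regraft (a non-root
#' edge is detached and reattached uniformly by length among
#' time-compatible locations), or a migration birth/death move that inserts
#' or deletes a same-edge flip-and-return pair of migration events. The
#' returned log-Hastings ratio is exact for the move performed; structurally
#' impossible proposals return the input genealogy with `-Inf`.
#'
#' @param G An [im_genealogy()].
#' @param params [im_parameters()] (supplies the `t` ceiling for migration
#'   events).
#' @param tuning List; `root_delta` is the half-width of the log-uniform root
#'   multiplier (default 0.5).
#' @return List with `genealogy`, `log_hastings`, and `move` (a label).
#' @export
propose_genealogy_update <- function(G, params, tuning = list()) {
  root_delta <- if (is.null(tuning$root_delta)) 0.5 else tuning$root_delta
  tsplit <- unclass(params)[["t"]]
  mv <- sample.int(3L, 1L)
  if (mv == 1L) { # node-time slide
    int <- setdiff(which(!is.na(G$children[, 1L])), integer(0))
    v <- if (length(int) == 1L) int else sample(int, 1L)
    if (is.na(G$parent[v])) {
      out <- apply_root_slide(G, exp(runif(1L, -root_delta, root_delta)))
      out$move <- "root_slide"
    } else {
      bb <- slide_bounds(G, v)
      out <- apply_node_slide(G, v, runif(1L, bb[1L], bb[2L]))
      out$move <- "node_slide"
    }
  } else if (mv == 2L) { # subtree regraft
    nonroot <- which(!is.na(G$parent))
    v <- if (length(nonroot) == 1L) nonroot else sample(nonroot, 1L)
    pr <- prune_for_regraft(G, v)
    if (is.null(pr) || pr$total <= 0) {
      out <- list(genealogy = G, log_hastings = -Inf)
    } else {
      x <- runif(1L, 0, pr$total)
      cs <- cumsum(pr$len)
      i <- which(x <= cs)[1L]
      tau <- pr$lo[i] + (x - c(0, cs)[i])
      out <- apply_regraft(G, v, pr$cand[i], tau)
    }
    out$move <- "regraft"
  } else { # migration birth/death (single on split-crossing edges, or pair)
    if (runif(1L) < 0.5) {
      se <- split_edges(G, tsplit)
      if (runif(1L) < 0.5) {
        if (se$total <= 0) {
          out <- list(genealogy = G, log_hastings = -Inf)
        } else {
          x <- runif(1L, 0, se$total)
          cs <- cumsum(se$len)
          i <- which(x <= cs)[1L]
          out <- apply_mig_birth_single(G, tsplit, se$node[i],
                                        se$lo[i] + (x - c(0, cs)[i]))
        }
        out$move <- "mig_birth_single"
      } else {
        loaded <- sum(se$node %in% G$migrations$node)
        if (loaded == 0L) {
          out <- list(genealogy = G, log_hastings = -Inf)
        } else {
          out <- apply_mig_death_single(G, tsplit, sample.int(loaded, 1L))
        }
        out$move <- "mig_death_single"
      }
    } else if (runif(1L) < 0.5) {
      me <- migratable_edges(G, tsplit)
      if (me$total <= 0) {
        out <- list(genealogy = G, log_hastings = -Inf)
      } else {
        x <- runif(1L, 0, me$total)
        cs <- cumsum(me$len)
        i <- which(x <= cs)[1L]
        tau1 <- me$lo[i] + (x - c(0, cs)[i])
        tau2 <- runif(1L, tau1, me$hi[i])
        out <- apply_mig_birth(G, tsplit, me$node[i], tau1, tau2)
      }
      out$move <- "mig_birth"
    } else {
      np <- n_mig_pairs(G)
      if (np == 0L) {
        out <- list(genealogy = G, log_hastings = -Inf)
      } else {
        out <- apply_mig_death(G, tsplit, sample.int(np, 1L))
      }
      out$move <- "mig_death"
    }
  }
  out
}
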