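#' Construct a timed, population-labeled genealogy
#'
#' Nodes are numbered 1..(2N-1): leaves 1..N (time 0), internal nodes
#' N+1..2N-1. Time increases into the past in expected-mutations units.
#' Migration events are recorded on the edge above `node` as
#' `(node, time, from, to)`: tracing the lineage from the leaves toward the
#' root, its population label switches from `from` to `to` at `time`.
#'
#' @param time Numeric vector of node times, length 2N-1.
#' @param parent Integer vector of parent ids (NA for the root).
#' @param children Integer matrix (2N-1) x 2 of child ids (NA rows for
#'   leaves).
#' @param leaf_pop Integer vector of leaf population labels (1 or 2).
#' @param migrations Data frame with columns `node`, `time`, `from`, `to`
#'   (zero rows allowed).
#' @return An object of class `im_genealogy`.
#' @export
im_genealogy <- function(time, parent, children, leaf_pop,
                         migrations = empty_migrations()) {
  N <- length(leaf_pop)
  structure(list(time = as.numeric(time), parent = as.integer(parent),
                 children = matrix(as.integer(children), ncol = 2L),
                 leaf_pop = as.integer(leaf_pop),
                 migrations = migrations, N = N),
            class = "im_genealogy")
}

empty_migrations <- function() {
  data.frame(node = integer(), time = numeric(), from = integer(),
             to = integer())
}

#' @export
print.im_genealogy <- function(x, ...) {
  cat(sprintf(
    "<im_genealogy> %d leaves (%d + %d), root height %.4g, %d migration(s)\n",
    x$N, sum(x$leaf_pop == 1L), sum(x$leaf_pop == 2L),
    max(x$time), nrow(x$migrations)))
  invisible(x)
}

root_node <- function(G) which(is.na(G$parent))

# internal nodes in a valid postorder (children before parents): because every
# child is strictly younger than its parent, sorting internal nodes by time
# gives one.
internal_postorder <- function(G) {
  int <- which(!is.na(G$children[, 1L]))
  int[order(G$time[int])]
}

children0 <- function(G) {
  ch <- G$children
  ch[is.na(ch)] <- 0L
  ch
}

#' Total branch length of a genealogy
#'
#' Sum over all non-root nodes of (parent time - node time).
#'
#' @param G An [im_genealogy()].
#' @return Nonnegative scalar.
#' @export
total_branch_length <- function(G) {
  nonroot <- which(!is.na(G$parent))
  sum(G$time[G$parent[nonroot]] - G$time[nonroot])
}

# Population label of every node at its own time (NA at/above t_split) and of
# every non-root lineage at its top (just below the parent, after the edge's
# migrations). Assumes a structurally valid genealogy; returns NULL when the
# label trace is inconsistent.
genealogy_labels <- function(G, tsplit) {
  M <- length(G$time)
  node_lab <- rep(NA_integer_, M)
  node_lab[seq_len(G$N)] <- G$leaf_pop
  edge_top <- rep(NA_integer_, M)
  mg <- G$migrations
  trace_edge <- function(v) {
    lab <- node_lab[v]
    if (is.na(lab)) return(NA_integer_)
    rows <- which(mg$node == v)
    if (length(rows)) {
      rows <- rows[order(mg$time[rows])]
      for (r in rows) {
        if (mg$from[r] != lab) return(-1L) # inconsistent flip
        lab <- mg$to[r]
      }
    }
    lab
  }
  for (v in internal_postorder(G)) {
    a <- G$children[v, 1L]; b <- G$children[v, 2L]
    for (c in c(a, b)) edge_top[c] <- trace_edge(c)
    if (any(vapply(c(a, b), function(c) identical(edge_top[c], -1L),
                   logical(1)))) return(NULL)
    if (G$time[v] < tsplit) {
      if (is.na(edge_top[a]) || is.na(edge_top[b]) ||
          edge_top[a] != edge_top[b]) return(NULL)
      node_lab[v] <- edge_top[a]
    }
  }
  rt <- root_node(G)
  for (c in which(!is.na(G$parent))) {
    if (is.na(edge_top[c])) edge_top[c] <- trace_edge(c)
    if (identical(edge_top[c], -1L)) return(NULL)
  }
  list(node = node_lab, edge_top = edge_top, root = rt)
}

#' Validate a genealogy against the model invariants
#'
#' @param G An [im_genealogy()].
#' @param params [im_parameters()] (for the `t` divergence-time constraints).
#' @return Character vector of violations (empty when valid).
#' @export
validate_genealogy <- function(G, params) {
  v <- character()
  M <- length(G$time)
  N <- G$N
  if (M != 2L * N - 1L) v <- c(v, "node count is not 2N-1")
  if (!all(G$time[seq_len(N)] == 0)) v <- c(v, "leaves must sit at time 0")
  roots <- which(is.na(G$parent))
  if (length(roots) != 1L) {
    v <- c(v, "genealogy must have exactly one root")
    return(v)
  }
  if (G$time[roots] < max(G$time)) v <- c(v, "root is not the oldest node")
  nonroot <- setdiff(seq_len(M), roots)
  if (any(is.na(G$children[setdiff(seq_len(M), seq_len(N)), ])))
    v <- c(v, "internal node with missing child")
  for (w in nonroot) {
    p <- G$parent[w]
    if (!w %in% G$children[p, ]) {
      v <- c(v, sprintf("parent/child tables disagree at node %d", w))
      next
    }
    if (!(G$time[w] < G$time[p]))
      v <- c(v, sprintf("node %d is not younger than its parent", w))
  }
  mg <- G$migrations
  tsplit <- unclass(params)[["t"]]
  if (nrow(mg)) {
    for (r in seq_len(nrow(mg))) {
      w <- mg$node[r]
      if (is.na(G$parent[w])) {
        v <- c(v, "migration on the root"); next
      }
      if (!(G$time[w] < mg$time[r] && mg$time[r] < G$time[G$parent[w]]))
        v <- c(v, sprintf("migration at %.4g outside its edge", mg$time[r]))
      if (!(mg$time[r] < tsplit))
        v <- c(v, sprintf("migration at %.4g not below t = %.4g",
                          mg$time[r], tsplit))
      if (!(mg$from[r] %in% 1:2 && mg$to[r] %in% 1:2 &&
            mg$from[r] != mg$to[r]))
        v <- c(v, "malformed migration labels")
    }
  }
  ev <- c(G$time[setdiff(seq_len(M), seq_len(N))], mg$time)
  if (anyDuplicated(ev)) v <- c(v, "two events share a time")
  if (!length(v)) {
    lb <- genealogy_labels(G, tsplit)
    if (is.null(lb))
      v <- c(v, "inconsistent population labels along a lineage")
  }
  v
}

#' Structured-coalescent log-density of a genealogy
#'
#' Interval-scan density of the timed genealogy with migration events under
#' the two-population IM model: below `t`, pairs within population p coalesce
#' at rate `2/theta_p` and each lineage in p migrates (backward in time) at
#' rate `m_p`; above `t` all lineages form one ancestral pool with pair rate
#' `2/thetaA`.
#'
#' @param G An [im_genealogy()].
#' @param params [im_parameters()].
#' @param check Validate `G` first (set `FALSE` inside tight loops).
#' @return Log density (may be `-Inf` when an event of a zero-rate class is
#'   realized).
#' @export
log_genealogy_density <- function(G, params, check = TRUE) {
  if (check) {
    bad <- validate_genealogy(G, params)
    if (length(bad)) stop("invalid genealogy: ", bad[1L])
  }
  p <- unclass(params)
  cpp_coal_logdens(G$time, ifelse(is.na(G$parent), 0L, G$parent),
                   children0(G), G$leaf_pop, G$N,
                   G$migrations$time, G$migrations$node,
                   G$migrations$from, G$migrations$to,
                   p[["theta1"]], p[["theta2"]], p[["thetaA"]],
                   p[["m1"]], p[["m2"]], p[["t"]])
}

#' Simulate a genealogy from the IM structured coalescent
#'
#' Draws a genealogy for `N1 + N2` sampled lineages: exponential waiting
#' times between events, event class chosen proportionally to its rate, and
#' all surviving lineages pooled into the ancestral population at time `t`.
#'
#' @param params [im_parameters()] (requires `thetaA > 0`).
#' @param N1,N2 Sample sizes in populations 1 and 2 (`N1 + N2 >= 2`).
#' @return An [im_genealogy()].
#' @export
simulate_genealogy <- function(params, N1, N2) {
  p <- unclass(params)
  if (N1 + N2 < 2L) stop("need at least two lineages")
  if (p[["thetaA"]] <= 0) stop("thetaA must be positive")
  r <- cpp_simulate_genealogy(p[["theta1"]], p[["theta2"]], p[["thetaA"]],
                              p[["m1"]], p[["m2"]], p[["t"]],
                              as.integer(N1), as.integer(N2))
  parent <- r$parent0; parent[parent == 0L] <- NA_integer_
  ch <- r$children0; ch[ch == 0L] <- NA_integer_
  im_genealogy(r$time, parent, ch, c(rep(1L, N1), rep(2L, N2)),
               data.frame(node = r$mig_node, time = r$mig_time,
                          from = r$mig_from, to = 3L - r$mig_from))
}

#' Export a genealogy as a Newick string
#'
#' Debugging aid: node times become branch lengths; migration events on an
#' edge are listed in a bracketed comment on that edge.
#'
#' @param G An [im_genealogy()].
#' @return A Newick string.
#' @export
genealogy_newick <- function(G) {
  mg <- G$migrations
  lab <- function(v) {
    rows <- which(mg$node == v)
    if (!length(rows)) return("")
    ev <- sprintf("%d>%d@%.6g", mg$from[rows], mg$to[rows], mg$time[rows])
    paste0("[&mig={", paste(ev, collapse = ","), "}]")
  }
  bl <- function(v) {
    p <- G$parent[v]
    if (is.na(p)) "" else sprintf(":%.10g%s", G$time[p] - G$time[v], lab(v))
  }
  rec <- function(v) {
    if (is.na(G$children[v, 1L]))
      paste0("p", G$leaf_pop[v], "_", v, bl(v))
    else
      paste0("(", rec(G$children[v, 1L]), ",", rec(G$children[v, 2L]), ")",
             bl(v))
  }
  paste0(rec(root_node(G)), ";")
}
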