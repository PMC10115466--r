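# Independent oracles and random-instance generators used across the suite.
# These deliberately avoid the package's own code paths: dense matrices and
# hand-rolled BFS instead of igraph, exhaustive enumeration instead of
# branch and bound.

# --- random instances -------------------------------------------------------

random_cell_net <- function(n = 12L, p_edge = 0.25, contact_frac = 0.3,
                            label = "cellX") {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  ids <- sprintf("P%02d", seq_len(n))
  em <- cbind(ids[pairs[keep, 1L]], ids[pairs[keep, 2L]])
  contacts <- sample(ids, max(1L, round(contact_frac * n)))
  cell_network(label, em, proteins = ids, contacts = contacts)
}

# random bipartite pair-cover instance with random positive costs
random_bridge_instance <- function(n_pairs = 10L, n1 = 5L, n2 = 5L) {
  n_pairs <- min(n_pairs, n1 * n2)
  u <- sprintf("U%02d", sample.int(n1, n_pairs, replace = TRUE))
  v <- sprintf("V%02d", sample.int(n2, n_pairs, replace = TRUE))
  em <- unique(cbind(u, v))
  while (nrow(em) < n_pairs) {
    em <- unique(rbind(em, cbind(sprintf("U%02d", sample.int(n1, 1L)),
                                 sprintf("V%02d", sample.int(n2, 1L)))))
  }
  inter <- inter_network("cA", "cB", em)
  bridge_problem(inter, alpha = 1,
                 cost = stats::runif(nrow(inter$edges), 0.1, 2))
}

# --- PageRank oracle: dense synchronous power iteration ---------------------

oracle_pagerank <- function(net, damping = 0.85, epsilon = 0.001) {
  n <- length(net$proteins)
  A <- matrix(0, n, n, dimnames = list(net$proteins, net$proteins))
  if (nrow(net$edges) > 0L) {
    A[net$edges] <- 1
    A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  p <- rep(1 / n, n)
  repeat {
    inflow <- as.vector(crossprod(A, ifelse(deg > 0, p / deg, 0)))
    p_new <- (1 - damping) / n + damping * (inflow + sum(p[deg == 0]) / n)
    if (sum(abs(p_new - p)) < epsilon) {
      p <- p_new
      break
    }
    p <- p_new
  }
  stats::setNames(p / sum(p), net$proteins)
}

# --- BFS + IIS oracle: first principles, no igraph --------------------------

# hop distances from `src` on an edge list, via a hand-rolled queue BFS
oracle_bfs <- function(nodes, edge_mat, src) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edge_mat) > 0L) {
    for (r in seq_len(nrow(edge_mat))) {
      a <- edge_mat[r, 1L]; b <- edge_mat[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# re-derives the IIS from scratch: rebuilds both pruned graphs from the raw
# edge list and runs the per-contact BFS sums independently
oracle_iis <- function(net, scores) {
  contacts <- net$contacts
  em <- net$edges
  is_cc <- em[, 1L] %in% contacts & em[, 2L] %in% contacts
  g1_edges <- em[!is_cc, , drop = FALSE]
  g2_edges <- em[is_cc, , drop = FALSE]
  out <- stats::setNames(numeric(length(contacts)), contacts)
  for (i in contacts) {
    d1 <- oracle_bfs(net$proteins, g1_edges, i)
    term1 <- 0
    for (j in setdiff(net$proteins, contacts)) {
      if (is.finite(d1[j]) && d1[j] > 0) term1 <- term1 + scores[j] / d1[j]
    }
    d2 <- oracle_bfs(contacts, g2_edges, i)
    term2 <- 0
    for (k in setdiff(contacts, i)) {
      if (is.finite(d2[k]) && d2[k] > 0) term2 <- term2 + scores[k] / d2[k]
    }
    out[i] <- term1 + term2
  }
  out
}

# --- betweenness oracle: geodesic enumeration -------------------------------

# all-shortest-paths betweenness by explicit DFS path enumeration (tiny n
# only); no graph library involved
oracle_betweenness <- function(net) {
  nodes <- net$proteins
  bt <- stats::setNames(numeric(length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(net$edges) > 0L) {
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges[r, 1L]; b <- net$edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  enum_paths <- function(from, to, maxlen) {
    paths <- list()
    dfs <- function(path) {
      cur <- path[length(path)]
      if (cur == to) {
        if (length(path) - 1L == maxlen) paths[[length(paths) + 1L]] <<- path
        return(invisible(NULL))
      }
      if (length(path) - 1L >= maxlen) return(invisible(NULL))
      for (nb in adj[[cur]]) {
        if (!nb %in% path) dfs(c(path, nb))
      }
    }
    dfs(from)
    paths
  }
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (a >= b) next
      d <- oracle_bfs(nodes, net$edges, nodes[a])[nodes[b]]
      if (is.infinite(d)) next
      sp <- enum_paths(nodes[a], nodes[b], d)
      inner <- lapply(sp, function(p) p[-c(1L, length(p))])
      for (v in unique(unlist(inner))) {
        bt[v] <- bt[v] +
          sum(vapply(inner, function(x) v %in% x, logical(1))) / length(sp)
      }
    }
  }
  bt
}

# --- misc -------------------------------------------------------------------

toy_iis <- function(net, metric = "pagerank") {
  normalize_iis(compute_iis(net, pagerank_centrality(net)))
}
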